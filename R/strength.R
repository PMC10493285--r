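#' Decode an 8-bit PWAM synaptic strength code
#'
#' The synaptic strength carried by an address event is a single byte whose
#' four least-significant bits are the pulse-width mantissa \code{W} (0--15)
#' and whose four most-significant bits are the pulse-amplitude exponent
#' \code{A} (0--15).  The conductance step realized by the code is
#' proportional to \code{(1 + W/16) * 2^A}, so the 256 codes tile a
#' geometric ladder spanning more than three decades.
#'
#' @param byte integer vector of codes in 0--255.
#' @return A list of class \code{"ifat_strength"} with integer fields
#'   \code{byte}, \code{W} (mantissa) and \code{A} (exponent), each the same
#'   length as the input.
#' @seealso [conductance_step()], [encode_strength()]
#' @examples
#' decode_strength(80)   # W = 0, A = 5
#' @export
decode_strength <- function(byte) {
  byte <- check_int_range(byte, 0L, 255L, "byte")
  out <- list(byte = byte, W = byte %% 16L, A = byte %/% 16L)
  class(out) <- "ifat_strength"
  out
}

#' Re-encode a mantissa/exponent pair as a strength byte
#'
#' Inverse of [decode_strength()]: \code{byte = 16*A + W}.
#'
#' @param W mantissa, integer 0--15.
#' @param A exponent, integer 0--15.
#' @return integer byte in 0--255.
#' @export
encode_strength <- function(W, A) {
  W <- check_int_range(W, 0L, 15L, "W")
  A <- check_int_range(A, 0L, 15L, "A")
  16L * A + W
}

#' @export
print.ifat_strength <- function(x, ...) {
  cat("<ifat_strength> ", length(x$byte), " code(s)\n", sep = "")
  n <- min(length(x$byte), 10L)
  for (i in seq_len(n)) {
    cat(sprintf("  byte %3d  ->  W = %2d, A = %2d\n", x$byte[i], x$W[i], x$A[i]))
  }
  if (length(x$byte) > n) cat("  ...\n")
  invisible(x)
}

#' Conductance step of a PWAM strength code
#'
#' Returns the instantaneous synaptic conductance increment realized by a
#' strength code: \code{dG = g0 * (1 + W/16) * 2^A}.  \code{g0} is the
#' conductance-step quantum, a single constant folding the synapse circuit's
#' device prefactors and the base pulse width; it fixes the physical scale
#' while the byte code selects a point on the geometric ladder.
#'
#' @param code an \code{"ifat_strength"} object from [decode_strength()], or
#'   an integer byte vector (decoded internally).
#' @param g0 conductance-step quantum in siemens (> 0).
#' @return conductance step(s) in siemens.
#' @examples
#' conductance_step(decode_strength(80), g0 = 1e-12)  # 32 pS
#' @export
conductance_step <- function(code, g0) {
  if (!inherits(code, "ifat_strength")) code <- decode_strength(code)
  if (!is.numeric(g0) || any(g0 <= 0)) stop("'g0' must be > 0")
  g0 * (1 + code$W / 16) * 2^code$A
}

# internal: validate integer-valued vector within [lo, hi]
check_int_range <- function(x, lo, hi, name) {
  if (length(x) == 0) return(integer(0))
  if (!is.numeric(x) || anyNA(x)) {
    stop(sprintf("'%s' must be a numeric vector without NA", name))
  }
  if (any(x != floor(x))) {
    stop(sprintf("'%s' must be integer-valued", name))
  }
  if (any(x < lo | x > hi)) {
    stop(sprintf("'%s' out of range [%d, %d]", name, lo, hi))
  }
  as.integer(x)
}
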