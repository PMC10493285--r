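# File formats: event streams (CSV and packed binary), routing tables
# (CSV), unit-suffixed configuration (YAML) and 8-bit grayscale images
# (plain/raw PGM and PNG).  Event timestamps are stored as integer
# microseconds so that files round-trip without floating drift.

#' Read and write input event streams
#'
#' CSV dialect: header \code{t_us,core,neuron,syn_type,strength}, one event
#' per row, times in integer microseconds, rows time-sorted.  Binary
#' dialect: little-endian records of a 32-bit unsigned microsecond
#' timestamp followed by a 32-bit word whose low 24 bits are the packed
#' input event (high byte zero).  The two dialects interconvert losslessly
#' at microsecond resolution; the format is chosen by the \code{format}
#' argument or the file extension (\code{.csv} vs anything else = binary).
#'
#' @param path file path.
#' @param format \code{"auto"}, \code{"csv"} or \code{"binary"}.
#' @return [input_events()] data frame (times in seconds).
#' @export
read_events <- function(path, format = c("auto", "csv", "binary")) {
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") {
    df <- utils::read.csv(path, colClasses = "numeric")
    need <- c("t_us", "core", "neuron", "syn_type", "strength")
    if (!identical(names(df), need)) {
      stop("bad event CSV header: expected ", paste(need, collapse = ","))
    }
    check_event_rows(df)
    with(df, input_events(t_us * 1e-6, core, neuron, syn_type, strength))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    raw <- readBin(con, "integer", n = file.size(path) %/% 4L, size = 4,
                   endian = "little")
    if (length(raw) %% 2 != 0) stop("truncated binary event file")
    if (any(raw < 0)) stop("binary event field out of range")
    t_us <- raw[seq(1, length(raw), by = 2)]
    word <- raw[seq(2, length(raw), by = 2)]
    if (any(word > 16777215)) stop("event word exceeds 24 bits")
    if (is.unsorted(t_us)) stop("binary event stream not time-sorted")
    ev <- unpack_input_event(word, t = t_us * 1e-6)
    ev
  }
}

#' @rdname read_events
#' @param events an [input_events()] data frame.
#' @export
write_events <- function(events, path, format = c("auto", "csv", "binary")) {
  format <- resolve_format(match.arg(format), path)
  t_us <- as.integer(round(events$t * 1e6))
  if (format == "csv") {
    df <- data.frame(t_us = t_us, core = events$core, neuron = events$neuron,
                     syn_type = events$syn_type, strength = events$strength)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    word <- as.integer(pack_input_event(events))
    con <- file(path, "wb")
    on.exit(close(con))
    inter <- integer(2L * length(t_us))
    if (length(t_us)) {
      inter[seq(1, length(inter), by = 2)] <- t_us
      inter[seq(2, length(inter), by = 2)] <- word
    }
    writeBin(inter, con, size = 4, endian = "little")
  }
  invisible(path)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "binary"
}

check_event_rows <- function(df) {
  bad <- which(df$t_us < 0 | df$t_us != floor(df$t_us) |
               df$core < 0 | df$core > 7 |
               df$neuron < 0 | df$neuron > 2047 |
               df$syn_type < 0 | df$syn_type > 3 |
               df$strength < 0 | df$strength > 255 |
               df$core != floor(df$core) | df$neuron != floor(df$neuron) |
               df$syn_type != floor(df$syn_type) |
               df$strength != floor(df$strength))
  if (length(bad)) {
    stop(sprintf("malformed event at line %d (after header)", bad[1]))
  }
  if (is.unsorted(df$t_us)) stop("event stream not time-sorted")
}

#' Read and write routing tables
#'
#' CSV with header \code{pre_id,core,neuron,syn_type,strength}; fan-out
#' order is row order and is preserved through a round trip.
#'
#' @param path file path.
#' @return [routing_table()].
#' @export
read_routing <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  need <- c("pre_id", "core", "neuron", "syn_type", "strength")
  if (!identical(names(df), need)) {
    stop("bad routing CSV header: expected ", paste(need, collapse = ","))
  }
  with(df, routing_table(pre_id, core, neuron, syn_type, strength))
}

#' @rdname read_routing
#' @param table [routing_table()].
#' @export
write_routing <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# ---- configuration -------------------------------------------------------

#' Default configuration
#'
#' The full configuration tree with all tunable parameters at their
#' defaults, values as unit-suffixed strings.  Sections: \code{neuron}
#' (passive parameters, reversal potentials, threshold/reset, time
#' constants, conductance quantum), \code{mismatch} (offset/slope
#' distributions and seed), \code{timing} (handshake latency and base
#' pulse width), \code{sim} (substep, duration, probes), \code{encoders}
#' (rate unit and nominal weight).
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    neuron = list(
      C_mem0 = "1 pF", G_leak0 = "50 pS", E_leak0 = "0 V",
      C_mem1 = "1 pF", G_leak1 = "50 pS", E_leak1 = "0 V",
      G_comp = "1 nS", V_thresh = "0.5 V", V_reset = "0 V",
      t_refr = "0.1 ms", E_exc = "1 V", E_inh = "0 V",
      tau_syn = "5 ms", g0 = "1 pS"
    ),
    mismatch = list(
      mu_off = 0, sigma_off = 8, mu_slope = 0.0185, sigma_slope = 0.0068,
      seed = 1
    ),
    timing = list(T_latency = "50 ns", dt_pulse_base = "10 us"),
    sim = list(dt = "10 us", duration = "1 s", probes = integer(0),
               probe_dt = "0.1 ms"),
    encoders = list(rate_unit = "31.25 Hz", w_nom = 80)
  )
}

#' Read a configuration file
#'
#' YAML document with the sections of [default_config()].  Unknown keys are
#' rejected; missing keys take their defaults; unit-suffixed strings
#' (e.g. \code{"50 pS"}, \code{"20 ms"}, \code{"0.5 V"}) are parsed to SI
#' numbers by [parse_quantity()].
#'
#' @param path YAML file path.
#' @return nested list with all values as plain SI numbers (the
#'   \code{mismatch} distribution moments, \code{encoders$w_nom} and
#'   \code{sim$probes} are dimensionless and pass through).
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- default_config()
  if (is.null(raw)) raw <- list()
  bad_sec <- setdiff(names(raw), names(defaults))
  if (length(bad_sec)) stop("unknown config section: ", bad_sec[1])
  out <- defaults
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), names(defaults[[sec]]))
    if (length(bad)) stop(sprintf("unknown key '%s' in section '%s'", bad[1], sec))
    out[[sec]][names(raw[[sec]])] <- raw[[sec]]
  }
  plain <- c("mismatch", "encoders")
  for (sec in setdiff(names(out), plain)) {
    for (k in names(out[[sec]])) {
      if (k == "probes") next
      out[[sec]][[k]] <- parse_quantity(out[[sec]][[k]])
    }
  }
  for (k in names(out$encoders)) {
    if (k == "rate_unit") out$encoders$rate_unit <- parse_quantity(out$encoders$rate_unit)
  }
  out
}

#' Parse a unit-suffixed quantity
#'
#' Accepts a bare number or a string \code{"<number> <unit>"} where the
#' unit is an SI unit (V, S, F, s, Hz) with an optional prefix among
#' f, p, n, u, m, k, M, G.  Returns the value in base SI units.
#'
#' @param x number or string.
#' @return numeric scalar.
#' @examples
#' parse_quantity("50 pS")   # 5e-11
#' parse_quantity("20 ms")   # 0.02
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  s <- trimws(as.character(x))
  m <- regmatches(s, regexec(
    "^([-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?)\\s*([fpnumkMG]?)(V|S|F|s|Hz)$",
    s))[[1]]
  if (length(m) == 0) stop("cannot parse quantity: '", s, "'")
  mult <- c(f = 1e-15, p = 1e-12, n = 1e-9, u = 1e-6, m = 1e-3,
            k = 1e3, M = 1e6, G = 1e9)
  pre <- m[3]
  as.numeric(m[2]) * if (nzchar(pre)) mult[[pre]] else 1
}

#' Build neuron parameters from a parsed configuration
#'
#' @param cfg list from [read_config()] (or [default_config()] values
#'   already parsed).
#' @return [neuron_params()].
#' @export
neuron_from_config <- function(cfg) {
  n <- cfg$neuron
  neuron_params(
    distal = compartment_params(n$C_mem0, n$G_leak0, n$E_leak0),
    proximal = compartment_params(n$C_mem1, n$G_leak1, n$E_leak1),
    G_comp = n$G_comp, V_thresh = n$V_thresh, V_reset = n$V_reset,
    t_refr = n$t_refr,
    synapses = default_synapses(E_exc = n$E_exc, E_inh = n$E_inh,
                                tau_syn = n$tau_syn, g0 = n$g0))
}

# ---- images --------------------------------------------------------------

#' Read and write 8-bit grayscale images
#'
#' PGM (plain \code{P2} and raw \code{P5}) and PNG, intensities 0--255,
#' returned and accepted as a rows x cols numeric matrix.
#'
#' @param path file path; format chosen by extension (\code{.png} vs
#'   \code{.pgm}).
#' @return intensity matrix.
#' @export
read_image <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    return(round(img * 255))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file")
  toks <- character(0)
  while (length(toks) < 3) {
    line <- readLines(con, 1)
    line <- sub("#.*", "", line)
    toks <- c(toks, strsplit(trimws(line), "\\s+")[[1]])
    toks <- toks[nzchar(toks)]
  }
  w <- as.integer(toks[1]); h <- as.integer(toks[2]); mx <- as.integer(toks[3])
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", n = w * h))
  } else {
    vals <- utils::head(scan(con, integer(), quiet = TRUE), w * h)
  }
  if (length(vals) < w * h) stop("truncated PGM data")
  matrix(vals * (255 / mx), nrow = h, byrow = TRUE)
}

#' @rdname read_image
#' @param image intensity matrix in [0, 255].
#' @param format for PGM, \code{"raw"} (P5, default) or \code{"plain"} (P2).
#' @export
write_image <- function(image, path, format = c("raw", "plain")) {
  format <- match.arg(format)
  v <- pmin(pmax(round(image), 0), 255)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(v / 255, path)
    return(invisible(path))
  }
  if (format == "plain") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(v), nrow(v)), "255"), con)
    utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", ncol(v), nrow(v)), con, eos = NULL)
    writeBin(as.raw(t(v)), con)
  }
  invisible(path)
}
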