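#' Input event stream constructor
#'
#' Builds a validated data frame of timed input address events for one
#' quadrant.  Each event targets one synapse of one neuron: a 3-bit core
#' address (0--7), an 11-bit in-core neuron address (0--2047; row =
#' neuron \%/\% 32, column = neuron \%\% 32), a 2-bit synapse type (0--3)
#' and an 8-bit strength code.  Events must be sorted by time (ties
#' allowed).
#'
#' @param t event times, seconds.
#' @param core core address 0--7.
#' @param neuron in-core neuron address 0--2047.
#' @param syn_type synapse index 0--3.
#' @param strength strength byte 0--255.
#' @return data.frame with class \code{c("ifat_events", "data.frame")}.
#' @export
input_events <- function(t, core, neuron, syn_type, strength) {
  n <- length(t)
  stopifnot(is.numeric(t), all(is.finite(t)))
  if (is.unsorted(t)) stop("event times must be sorted (ties allowed)")
  core <- check_int_range(rep_len(core, n), 0L, 7L, "core")
  neuron <- check_int_range(rep_len(neuron, n), 0L, 2047L, "neuron")
  syn_type <- check_int_range(rep_len(syn_type, n), 0L, 3L, "syn_type")
  strength <- check_int_range(rep_len(strength, n), 0L, 255L, "strength")
  structure(data.frame(t = as.numeric(t), core = core, neuron = neuron,
                       syn_type = syn_type, strength = strength),
            class = c("ifat_events", "data.frame"))
}

empty_events <- function() {
  input_events(numeric(0), integer(0), integer(0), integer(0), integer(0))
}

#' Pack input events into 24-bit words
#'
#' Word layout, MSB first: core address in bits \code{[23:21]}, neuron
#' address in \code{[20:10]}, synapse type in \code{[9:8]}, strength in
#' \code{[7:0]}; i.e. \code{word = core*2^21 + neuron*2^10 + syn_type*2^8 +
#' strength}.  The core bits sit on top so that the three splitter stages
#' can each peel one MSB while descending to the target core.
#'
#' @param events an [input_events()] data frame (or one with those columns).
#' @return numeric vector of words in \code{[0, 2^24)}.
#' @seealso [unpack_input_event()]
#' @export
pack_input_event <- function(events) {
  core <- check_int_range(events$core, 0L, 7L, "core")
  neuron <- check_int_range(events$neuron, 0L, 2047L, "neuron")
  syn <- check_int_range(events$syn_type, 0L, 3L, "syn_type")
  s <- check_int_range(events$strength, 0L, 255L, "strength")
  core * 2^21 + neuron * 2^10 + syn * 2^8 + s
}

#' Unpack 24-bit input event words
#'
#' @param word numeric vector of words in \code{[0, 2^24)}.
#' @param t optional event times to attach (default 0).
#' @return an [input_events()] data frame.
#' @export
unpack_input_event <- function(word, t = 0) {
  word <- check_int_range(word, 0L, 16777215L, "word")
  input_events(t = rep_len(t, length(word)),
               core = word %/% 2^21,
               neuron = (word %/% 2^10) %% 2048L,
               syn_type = (word %/% 2^8) %% 4L,
               strength = word %% 256L)
}

#' Pack an output spike as a 14-bit address event
#'
#' A neuron firing in a core is encoded as its 11-bit in-core address; each
#' of the three merger stages on the way to the quadrant output bus
#' prepends one MSB identifying the winning path, accumulating the 3-bit
#' core address above the neuron address: \code{address = core*2^11 +
#' neuron}.
#'
#' @param core core address 0--7.
#' @param neuron in-core neuron address 0--2047.
#' @return integer address in \code{[0, 2^14)}.
#' @export
pack_output_event <- function(core, neuron) {
  core <- check_int_range(core, 0L, 7L, "core")
  neuron <- check_int_range(neuron, 0L, 2047L, "neuron")
  core * 2048L + neuron
}

#' Unpack a 14-bit output address event
#'
#' @param address integer in \code{[0, 2^14)}.
#' @return data.frame with columns \code{core}, \code{neuron}.
#' @export
unpack_output_event <- function(address) {
  address <- check_int_range(address, 0L, 16383L, "address")
  data.frame(core = address %/% 2048L, neuron = address %% 2048L)
}

#' Build a synaptic routing table
#'
#' The routing table is the external memory realizing virtual wiring: for
#' each presynaptic global neuron id it lists the fan-out of synaptic
#' targets (core, neuron, synapse type, strength), in order.  Global ids
#' are \code{core * 2048 + neuron} within a quadrant.
#'
#' @param pre_id presynaptic global neuron id (integer >= 0).
#' @param core,neuron,syn_type,strength per-entry target fields (recycled).
#' @return data.frame of class \code{c("ifat_routing", "data.frame")}.
#' @export
routing_table <- function(pre_id = integer(0), core = integer(0),
                          neuron = integer(0), syn_type = integer(0),
                          strength = integer(0)) {
  n <- length(pre_id)
  if (n == 0) {
    return(structure(data.frame(pre_id = integer(0), core = integer(0),
                                neuron = integer(0), syn_type = integer(0),
                                strength = integer(0)),
                     class = c("ifat_routing", "data.frame")))
  }
  if (!is.numeric(pre_id) || any(pre_id < 0) || any(pre_id != floor(pre_id))) {
    stop("'pre_id' must be non-negative integers")
  }
  core <- check_int_range(rep_len(core, n), 0L, 7L, "core")
  neuron <- check_int_range(rep_len(neuron, n), 0L, 2047L, "neuron")
  syn_type <- check_int_range(rep_len(syn_type, n), 0L, 3L, "syn_type")
  strength <- check_int_range(rep_len(strength, n), 0L, 255L, "strength")
  structure(data.frame(pre_id = as.integer(pre_id), core = core,
                       neuron = neuron, syn_type = syn_type,
                       strength = strength),
            class = c("ifat_routing", "data.frame"))
}

#' Route one presynaptic spike through the table
#'
#' Expands a spike of neuron \code{presyn_id} at time \code{t} into one
#' input event per routing entry, in table order, each stamped
#' \code{t + axonal_delay}.  An id absent from the table yields an empty
#' event list.
#'
#' @param table [routing_table()].
#' @param presyn_id presynaptic global neuron id.
#' @param t spike time, seconds.
#' @param axonal_delay added to every generated event time (default 0).
#' @return an [input_events()] data frame.
#' @export
route_spike <- function(table, presyn_id, t, axonal_delay = 0) {
  rows <- table[table$pre_id == presyn_id, , drop = FALSE]
  if (nrow(rows) == 0) return(empty_events())
  input_events(t = rep(t + axonal_delay, nrow(rows)),
               core = rows$core, neuron = rows$neuron,
               syn_type = rows$syn_type, strength = rows$strength)
}

#' Deterministic three-stage merge of per-core output streams
#'
#' Emulates the binary tree of asynchronous mergers collecting the eight
#' per-core output streams of one quadrant onto the shared 14-bit output
#' bus.  Each stage merges two time-sorted streams; at equal timestamps the
#' lower port index wins, so ties resolve to the lower core number.  Every
#' stage prepends one MSB identifying the winning path, accumulating the
#' core address.  No event is lost or duplicated and distinct timestamps
#' come out in global time order.
#'
#' @param streams list of 8 data frames with columns \code{t} (sorted) and
#'   \code{neuron} (11-bit in-core address); element \code{i} is core
#'   \code{i - 1}.  Empty data frames allowed.
#' @return data.frame with columns \code{t}, \code{address} (14-bit),
#'   \code{core}, \code{neuron}.
#' @export
arbitrate_merge <- function(streams) {
  stopifnot(is.list(streams), length(streams) == 8)
  streams <- lapply(seq_along(streams), function(i) {
    s <- streams[[i]]
    if (is.null(s) || nrow(s) == 0) {
      return(data.frame(t = numeric(0), path = integer(0), neuron = integer(0)))
    }
    if (is.unsorted(s$t)) stop(sprintf("stream %d is not time-sorted", i))
    check_int_range(s$neuron, 0L, 2047L, "neuron")
    data.frame(t = as.numeric(s$t), path = 0L, neuron = as.integer(s$neuron))
  })
  # three stages of pairwise arbitration, each adding one MSB to 'path'
  for (stage in 1:3) {
    merged <- vector("list", length(streams) / 2)
    for (k in seq_along(merged)) {
      merged[[k]] <- merge_two(streams[[2 * k - 1]], streams[[2 * k]], stage)
    }
    streams <- merged
  }
  out <- streams[[1]]
  out$core <- out$path
  out$address <- pack_output_event(out$core, out$neuron)
  out[, c("t", "address", "core", "neuron")]
}

# merge two sorted streams; port 0 wins ties; the port bit becomes the new
# MSB of the accumulated path (bit position stage-1 counted from the neuron
# side: after stage s, path has s bits, port bit on top)
merge_two <- function(a, b, stage) {
  a$path <- a$path            # port 0: new MSB 0, path unchanged
  b$path <- b$path + 2^(stage - 1)
  na <- nrow(a); nb <- nrow(b)
  if (na == 0) return(b)
  if (nb == 0) return(a)
  # stable merge preferring stream a on ties
  ord <- order(c(a$t, b$t), c(rep(0L, na), rep(1L, nb)), method = "radix")
  rbind(a, b)[ord, , drop = FALSE]
}

#' Splitter: deliver packed input words to their target cores
#'
#' Emulates the three-stage asynchronous splitter of one quadrant: each
#' stage decodes one MSB of the 24-bit word, so a word reaches exactly the
#' core named in bits \code{[23:21]}.
#'
#' @param word numeric vector of 24-bit input event words.
#' @return integer vector of core indices 0--7, one per word.
#' @export
split_events <- function(word) {
  word <- check_int_range(word, 0L, 16777215L, "word")
  core <- integer(length(word))
  rem <- word
  for (stage in 1:3) {                 # peel one MSB per stage
    bit <- rem %/% 2^(24 - stage)
    core <- core * 2L + as.integer(bit)
    rem <- rem %% 2^(24 - stage)
  }
  core
}

#' Global neuron id helpers
#'
#' Within a quadrant a neuron's global id is \code{core * 2048 + neuron}.
#'
#' @param core core 0--7; @param neuron in-core address 0--2047.
#' @return integer global id 0--16383.
#' @export
global_id <- function(core, neuron) {
  pack_output_event(core, neuron)
}

#' @rdname global_id
#' @param id global id 0--16383.
#' @export
id_to_address <- function(id) {
  unpack_output_event(id)
}
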