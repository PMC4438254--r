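# Memory fabric: sparse Master RAM keyed by full 26-bit address, the per-slot
# Local cache / DA-address / polarity state (owned by the adaptor array), the
# 16-bit maximal LFSR behind the stochastic bistable-weight expansion, and the
# MINSTD stream behind the re-binarization threshold.

LFSR_MASK <- 65535L

#' Seed a 16-bit LFSR
#'
#' Maximal-length Fibonacci register with taps (16, 15, 13, 4); the state
#' sequence visits all 65535 nonzero 16-bit values before repeating.
#'
#' @param seed Integer in `[1, 65535]` (the all-zero state is absorbing and
#'   rejected).
#' @return The initial state, an integer.
#' @export
lfsr_new <- function(seed = 0xACE1L) {
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 1L || seed > LFSR_MASK)
    stop("LFSR seed must be a nonzero 16-bit integer")
  seed
}

#' Advance the LFSR one step
#'
#' @param state Current nonzero 16-bit state.
#' @param bits How many low-order bits of the new state to return (default 3,
#'   the random bits of the bistable-weight expansion).
#' @return List with `state` (next state) and `value` (low `bits` bits).
#' @export
lfsr_next <- function(state, bits = 3L) {
  state <- as.integer(state)
  if (is.na(state) || state < 1L || state > LFSR_MASK)
    stop("LFSR state must be a nonzero 16-bit integer")
  # taps 16,15,13,4 counted from the input end == shifts 0,1,3,12 from LSB
  fb <- bitwXor(bitwXor(bitwAnd(state, 1L),
                        bitwAnd(bitwShiftR(state, 1L), 1L)),
                bitwXor(bitwAnd(bitwShiftR(state, 3L), 1L),
                        bitwAnd(bitwShiftR(state, 12L), 1L)))
  nxt <- bitwOr(bitwShiftR(state, 1L), bitwShiftL(fb, 15L))
  list(state = nxt, value = bitwAnd(nxt, bitwShiftL(1L, as.integer(bits)) - 1L))
}

#' Expand a bistable bit into a 4-bit working weight
#'
#' The 1-bit persistent weight becomes the most significant bit of the 4-bit
#' working weight; the low 3 bits are pseudo-random, keeping the transitions
#' between the two stable states stochastic.
#'
#' @param bit 0 or 1 (the stored bistable weight).
#' @param rand3 Integer in `[0, 7]` (LFSR output).
#' @return Integer weight in `[0, 7]` for bit 0, `[8, 15]` for bit 1.
#' @export
expand_bistable <- function(bit, rand3) {
  bit <- as.integer(bit); rand3 <- as.integer(rand3)
  if (any(!bit %in% c(0L, 1L))) stop("bistable bit must be 0 or 1")
  if (any(rand3 < 0L) || any(rand3 > 7L)) stop("rand3 out of range [0, 7]")
  bit * 8L + rand3
}

#' Re-binarize a 4-bit weight against a stochastic threshold
#'
#' The bistable bit written back to the Master RAM is 1 iff the modified
#' 4-bit weight strictly exceeds the threshold, a pseudo-random number drawn
#' uniformly from \{4, ..., 11\}.
#'
#' @param weight Integer in `[0, 15]`.
#' @param threshold Integer in `[4, 11]`.
#' @return 0 or 1.
#' @export
encode_bistable <- function(weight, threshold) {
  weight <- as.integer(weight); threshold <- as.integer(threshold)
  if (any(weight < 0L) || any(weight > 15L))
    stop("weight out of 4-bit range [0, 15]")
  if (any(threshold < 4L) || any(threshold > 11L))
    stop("threshold must lie in [4, 11]")
  as.integer(weight > threshold)
}

#' Seeded generator for the bistable threshold
#'
#' A MINSTD (Park-Miller) multiplicative congruential stream mapped to
#' uniform integers on \{4, ..., 11\}; a fresh threshold is drawn at every
#' committing slot visit.
#'
#' @param seed Integer seed.
#' @return An environment holding the stream state.
#' @export
threshold_rng <- function(seed = 1L) {
  rng <- new.env(parent = emptyenv())
  rng$state <- as.integer(abs(as.numeric(seed)) %% 2147483646) + 1L
  class(rng) <- "threshold_rng"
  rng
}

#' @param rng A [threshold_rng()].
#' @rdname threshold_rng
#' @export
threshold_next <- function(rng) {
  s <- (16807 * as.numeric(rng$state)) %% 2147483647
  rng$state <- as.integer(s)
  4L + as.integer(s / 2147483647 * 8)
}

# --- Master RAM: sparse map, unwritten addresses read as 0 ------------------

master_new <- function() {
  m <- new.env(parent = emptyenv(), hash = TRUE)
  class(m) <- "master_ram"
  m
}

master_get <- function(master, address) {
  v <- get0(as.character(address), envir = master, inherits = FALSE)
  if (is.null(v)) 0L else v
}

master_set <- function(master, address, value) {
  assign(as.character(address), as.integer(value), envir = master)
  invisible(master)
}

#' Snapshot the Master RAM
#'
#' Exports every written (address, value) pair; unwritten addresses read as 0
#' (weak bistable weight / zero delay) and are not listed.
#'
#' @param master A Master RAM (or an [adaptor_array()], whose Master RAM is
#'   then snapshotted).
#' @return A `data.frame` with columns `address` and `value`, sorted by
#'   address.
#' @export
master_snapshot <- function(master) {
  if (inherits(master, "adaptor_array")) master <- master$master
  keys <- ls(master)
  if (length(keys) == 0L)
    return(data.frame(address = integer(0), value = integer(0)))
  addr <- as.integer(keys)
  val <- vapply(keys, function(k) get(k, envir = master), integer(1),
                USE.NAMES = FALSE)
  o <- order(addr)
  data.frame(address = addr[o], value = val[o])
}

#' Write / read a Master RAM snapshot as CSV
#'
#' Plain text with header `address,value`; used for fixtures and for the
#' dynamic-assignment validation experiment's read-back.
#'
#' @param snapshot A `data.frame` with columns `address`, `value`.
#' @param path File path.
#' @export
write_master_snapshot <- function(snapshot, path) {
  utils::write.csv(snapshot[, c("address", "value")], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_master_snapshot
#' @export
read_master_snapshot <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("address", "value") %in% names(df)))
    stop("snapshot must have columns address, value")
  data.frame(address = as.integer(df$address), value = as.integer(df$value))
}

#' Assign a DA adaptor to a TM slot (direct-mapped)
#'
#' Compares the incoming spike's 13-bit prefix with the slot's stored DA
#' prefix. On a hit nothing changes. On a miss the DA-address entry is
#' overwritten and the Local cache is refilled from the Master RAM: for STDP
#' the stored bistable bit is expanded to a random 4-bit weight via the LFSR;
#' for STDDP the stored 4-bit delay is copied verbatim. The evicted value is
#' not written back -- write-through at commit time makes that redundant.
#'
#' @param aa An [adaptor_array()] (owns cache, DA-address RAM, Master RAM and
#'   LFSR).
#' @param slot Slot index (0-based).
#' @param prefix Incoming 13-bit DA prefix.
#' @return `TRUE` on a hit, `FALSE` on a miss (state updated), invisibly
#'   returned visibly for inspection.
#' @export
assign_slot <- function(aa, slot, prefix) {
  slot <- as.integer(slot); prefix <- as.integer(prefix)
  if (slot < 0L || slot >= aa$n_slots) stop("slot out of range")
  if (prefix < 0L || prefix >= N_SLOTS) stop("prefix out of range [0, 8192)")
  i <- slot + 1L
  if (aa$assigned[i] && aa$prefix[i] == prefix) return(TRUE)
  addr <- prefix * N_SLOTS + slot
  if (aa$mode == "stdp") {
    nx <- lfsr_next(aa$lfsr, 3L)
    aa$lfsr <- nx$state
    aa$cache[i] <- expand_bistable(as.integer(master_get(aa$master, addr) > 0L),
                                   nx$value)
  } else {
    aa$cache[i] <- master_get(aa$master, addr)
  }
  aa$prefix[i] <- prefix
  aa$assigned[i] <- TRUE
  FALSE
}

#' Commit a modified weight or delay (write-through)
#'
#' Updates the Local cache and simultaneously the Master RAM entry of the
#' resident DA adaptor: the re-binarized bistable bit for STDP (against a
#' fresh stochastic threshold), the full 4-bit value for STDDP. The Master
#' RAM is therefore never stale after a modification.
#'
#' @param aa An [adaptor_array()].
#' @param slot Slot index (0-based); must currently be assigned.
#' @param new_value Integer in `[0, 15]`.
#' @return The value written to the Master RAM, invisibly.
#' @export
commit_modification <- function(aa, slot, new_value) {
  slot <- as.integer(slot)
  i <- slot + 1L
  if (!aa$assigned[i])
    stop("commit_modification: slot ", slot, " has no assigned DA adaptor")
  new_value <- as.integer(new_value)
  if (new_value < 0L || new_value > 15L) stop("new_value out of [0, 15]")
  aa$cache[i] <- new_value
  addr <- aa$prefix[i] * N_SLOTS + slot
  mval <- if (aa$mode == "stdp") {
    encode_bistable(new_value, threshold_next(aa$thr))
  } else {
    new_value
  }
  master_set(aa$master, addr, mval)
  invisible(mval)
}
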