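# AER spike events, the 13/13 address split and per-tick event alignment.

# 8192 time-multiplexed slots; the low 13 address bits select the slot, the
# high 13 bits name the dynamically-assigned (DA) adaptor resident in it.
N_SLOTS <- 8192L
ADDR_SPACE <- N_SLOTS * N_SLOTS  # 2^26

#' Construct a table of spike events
#'
#' A spike event is a timestamped pre- or post-synaptic spike carrying a
#' 26-bit AER address. One tick equals 1 ms of simulated time. Emitted
#' (weighted or delayed) pre-synaptic spikes additionally carry a 4-bit
#' weight; input events leave the weight `NA`.
#'
#' @param tick Non-negative integer tick of arrival.
#' @param kind `"pre"` or `"post"`.
#' @param address Integer in `[0, 2^26)`.
#' @param weight Optional integer in `[0, 15]`; `NA` for input events.
#' @return A `data.frame` with columns `tick`, `kind`, `address`, `weight`.
#' @export
#' @examples
#' spike_events(tick = c(0, 3), kind = c("pre", "post"), address = c(5, 5))
spike_events <- function(tick, kind, address, weight = NA_integer_) {
  tick <- as.integer(tick)
  ev <- data.frame(tick = tick,
                   kind = rep_len(as.character(kind), length(tick)),
                   address = rep_len(as.integer(address), length(tick)),
                   weight = rep_len(as.integer(weight), length(tick)),
                   stringsAsFactors = FALSE)
  validate_events(ev)
}

validate_events <- function(events) {
  need <- c("tick", "kind", "address")
  if (!is.data.frame(events) || !all(need %in% names(events)))
    stop("events must be a data.frame with columns tick, kind, address")
  if (is.null(events$weight)) events$weight <- NA_integer_
  if (nrow(events) == 0L) return(events)
  if (any(is.na(events$tick)) || any(events$tick < 0L))
    stop("event ticks must be non-negative integers")
  if (!all(events$kind %in% c("pre", "post")))
    stop("event kind must be 'pre' or 'post'")
  if (any(is.na(events$address)) ||
      any(events$address < 0L) || any(events$address >= ADDR_SPACE))
    stop("event address out of range [0, 2^26)")
  w <- events$weight[!is.na(events$weight)]
  if (length(w) && (any(w < 0L) || any(w > 15L)))
    stop("event weight, when present, must lie in [0, 15]")
  events
}

#' Split a 26-bit AER address into slot and DA prefix
#'
#' The least-significant 13 bits select the time-multiplexed slot; the
#' most-significant 13 bits are the dynamically-assigned adaptor prefix that
#' gets stored in the DA address RAM.
#'
#' @param address Integer vector, each element in `[0, 2^26)`.
#' @return A list with integer vectors `slot` and `prefix`, both in
#'   `[0, 8192)`.
#' @seealso [compose_output_address()] for the inverse.
#' @export
#' @examples
#' split_address(3 * 8192 + 5)  # slot 5, prefix 3
split_address <- function(address) {
  address <- as.integer(address)
  if (any(is.na(address)) || any(address < 0L) || any(address >= ADDR_SPACE))
    stop("address out of range [0, 2^26)")
  list(slot = address %% N_SLOTS, prefix = address %/% N_SLOTS)
}

#' Compose the 26-bit output address of an emitted spike
#'
#' Emitted weighted/delayed pre-synaptic spikes carry an address that
#' combines the stored DA prefix with the value of the global slot counter.
#'
#' @param prefix Integer vector in `[0, 8192)` (13-bit DA prefix).
#' @param global_counter Integer vector in `[0, 8192)` (slot index).
#' @return Integer vector of 26-bit addresses; round-trips with
#'   [split_address()].
#' @export
#' @examples
#' compose_output_address(3, 5)  # 24581
compose_output_address <- function(prefix, global_counter) {
  prefix <- as.integer(prefix)
  global_counter <- as.integer(global_counter)
  bad <- function(x) any(is.na(x)) || any(x < 0L) || any(x >= N_SLOTS)
  if (bad(prefix) || bad(global_counter))
    stop("prefix and global_counter must lie in [0, 8192)")
  prefix * N_SLOTS + global_counter
}

#' Resolve the events of one tick with last-wins collision semantics
#'
#' Multiple same-kind spikes targeting the same slot within one tick collide;
#' only the last arriving (last in input order) survives, the earlier ones are
#' discarded. Pre- and post-synaptic streams are resolved independently, so a
#' pre and a post spike on the same slot both survive.
#'
#' @param events Event `data.frame` (see [spike_events()]); all rows must
#'   carry `tick`.
#' @param tick The tick being aligned.
#' @return A list with `pre` and `post` (surviving events, at most one per
#'   slot each) and `discarded` (count of collided events).
#' @export
align_tick_events <- function(events, tick) {
  events <- validate_events(events)
  if (nrow(events) && any(events$tick != tick))
    stop("align_tick_events: all events must belong to tick ", tick)
  pick <- function(k) {
    ev <- events[events$kind == k, , drop = FALSE]
    if (nrow(ev) <= 1L) return(ev)
    ev[!duplicated(ev$address %% N_SLOTS, fromLast = TRUE), , drop = FALSE]
  }
  pre <- pick("pre")
  post <- pick("post")
  list(pre = pre, post = post,
       discarded = nrow(events) - nrow(pre) - nrow(post))
}

#' Read / write a spike event trace
#'
#' Traces are plain comma-separated text with a `tick,kind,address,weight`
#' header, 0-based ticks and decimal addresses; the weight field is blank for
#' input events. On read, events are returned sorted by tick with file order
#' preserved within a tick (the order matters for last-wins collision
#' resolution).
#'
#' @param path File path.
#' @return `read_event_trace` returns a validated event `data.frame`.
#' @export
read_event_trace <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || trimws(lines[1L]) != "tick,kind,address,weight")
    stop("event trace must start with header 'tick,kind,address,weight'")
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L)
    return(spike_events(integer(0), character(0), integer(0)))
  parts <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L | nf > 4L))
    stop("malformed row at line ", which(nf < 3L | nf > 4L)[1L] + 1L,
         ": expected 3 or 4 comma-separated fields")
  field <- function(i) vapply(parts, function(p) {
    if (length(p) >= i) trimws(p[i]) else ""
  }, character(1))
  tick <- suppressWarnings(as.integer(field(1)))
  kind <- field(2)
  address <- suppressWarnings(as.integer(field(3)))
  wtxt <- field(4)
  weight <- suppressWarnings(as.integer(ifelse(wtxt == "", NA, wtxt)))
  bad <- is.na(tick) | tick < 0L | !(kind %in% c("pre", "post")) |
    is.na(address) | (wtxt != "" & is.na(weight))
  if (any(bad))
    stop("malformed row at line ", which(bad)[1L] + 1L, ": ",
         body[which(bad)[1L]])
  oor <- address < 0L | address >= ADDR_SPACE
  if (any(oor))
    stop("address out of range [0, 2^26) at line ", which(oor)[1L] + 1L)
  ev <- data.frame(tick = tick, kind = kind, address = address,
                   weight = weight, stringsAsFactors = FALSE)
  ev <- ev[order(ev$tick), , drop = FALSE]  # stable: keeps file order per tick
  rownames(ev) <- NULL
  validate_events(ev)
}

#' @param events Event `data.frame` to write.
#' @rdname read_event_trace
#' @export
write_event_trace <- function(events, path) {
  events <- validate_events(events)
  utils::write.table(events[, c("tick", "kind", "address", "weight")],
                     path, sep = ",", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
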