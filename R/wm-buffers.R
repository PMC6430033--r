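# Theta-gamma working-memory buffers, abstract slot mode: an ordered set of up
# to 7 gamma slots per theta cycle, each holding one chunked triplet.

#' Working-memory capacity in gamma slots per theta cycle
#' @return 7L.
#' @export
wm_capacity <- function() 7L

#' Create an empty theta-gamma buffer
#'
#' @param gamma_freq gamma frequency in Hz; the comparator's element stream
#'   runs at three times this frequency.
#' @return an object of class `tqa_buffer` with 7 empty slots.
#' @export
theta_gamma_state <- function(gamma_freq = 30) {
  structure(list(slots = vector("list", wm_capacity()),
                 gamma_freq = gamma_freq,
                 theta_cycle_index = 0L),
            class = "tqa_buffer")
}

.as_slot <- function(x) {
  if (inherits(x, "tqa_triplet"))
    list(chunk = chunk_triplet(x), triplet = x)
  else if (is.numeric(x))
    list(chunk = x, triplet = NULL)
  else stop("buffer slots hold triplets or chunked patterns")
}

#' Load an ordered sequence of triplets into a buffer
#'
#' Triplet k occupies gamma slot k; earlier buffer content is cleared. A
#' sentence longer than 7 triplets cannot be held.
#'
#' @param buffer a `tqa_buffer`.
#' @param triplets list of `tqa_triplet` (or raw chunked vectors), or a
#'   realized `tqa_sentence`.
#' @return the loaded buffer.
#' @export
load_sequence <- function(buffer, triplets) {
  stopifnot(inherits(buffer, "tqa_buffer"))
  if (inherits(triplets, "tqa_sentence")) {
    if (is.null(triplets$realized) && length(triplets$triplets) > 0L)
      stop("sentence must be realized before loading into a buffer")
    triplets <- triplets$realized
  }
  if (length(triplets) > wm_capacity())
    stop("buffer capacity exceeded: at most ", wm_capacity(),
         " triplets fit in the gamma slots of a theta cycle")
  buffer$slots <- vector("list", wm_capacity())
  for (k in seq_along(triplets))
    buffer$slots[[k]] <- .as_slot(triplets[[k]])
  buffer
}

#' Read the content of a gamma slot
#'
#' @param buffer a `tqa_buffer`.
#' @param k slot index in 1..7.
#' @return the slot content (list with `chunk` and `triplet`) or `NULL` for an
#'   empty slot. Never mutates the buffer.
#' @export
read_slot <- function(buffer, k) {
  stopifnot(inherits(buffer, "tqa_buffer"))
  if (k < 1L || k > wm_capacity()) stop("slot index out of range: ", k)
  buffer$slots[[k]]
}

#' Indices of occupied gamma slots
#' @param buffer a `tqa_buffer`.
#' @return integer vector.
#' @export
occupied_slots <- function(buffer) {
  which(!vapply(buffer$slots, is.null, logical(1)))
}

#' Advance the buffer through theta cycles
#'
#' Working memory is maintained by reactivation: absent external input, slot
#' contents and order are unchanged from cycle to cycle.
#'
#' @param buffer a `tqa_buffer`.
#' @param n number of theta cycles to advance.
#' @return the buffer with an advanced cycle counter.
#' @export
advance_theta <- function(buffer, n = 1L) {
  stopifnot(inherits(buffer, "tqa_buffer"))
  buffer$theta_cycle_index <- buffer$theta_cycle_index + as.integer(n)
  buffer
}

#' Conceptually align a question buffer to an answer buffer (slot mode)
#'
#' Each question triplet whose best answer-buffer match (chunked-pattern
#' overlap) reaches the threshold is moved to that answer triplet's gamma
#' slot, so matching contents become synchronized. When two question triplets
#' claim the same answer slot the higher-overlap pair wins and the loser falls
#' through to its next-best match. Unmatched question triplets are packed into
#' the lowest free slots in their original relative order. The answer buffer
#' is never modified.
#'
#' @param qwm question buffer (`tqa_buffer`).
#' @param awm answer buffer (`tqa_buffer`).
#' @param threshold minimum overlap for a conceptual match.
#' @return the realigned question buffer, with an `"alignment"` attribute
#'   (data frame: `q_from`, `q_to`, `matched`, `score`).
#' @export
align_slots_abstract <- function(qwm, awm, threshold = 0.5) {
  stopifnot(inherits(qwm, "tqa_buffer"), inherits(awm, "tqa_buffer"))
  qocc <- occupied_slots(qwm)
  aocc <- occupied_slots(awm)
  assign_to <- stats::setNames(rep(NA_integer_, length(qocc)),
                               as.character(qocc))
  if (length(qocc) && length(aocc)) {
    pairs <- expand.grid(qi = qocc, ai = aocc)
    pairs$score <- mapply(function(qi, ai) {
      overlap(qwm$slots[[qi]]$chunk, awm$slots[[ai]]$chunk)
    }, pairs$qi, pairs$ai)
    pairs <- pairs[pairs$score >= threshold, , drop = FALSE]
    pairs <- pairs[order(-pairs$score, pairs$qi, pairs$ai), , drop = FALSE]
    used_a <- integer()
    for (p in seq_len(nrow(pairs))) {
      qi <- pairs$qi[p]; ai <- pairs$ai[p]
      if (!is.na(assign_to[as.character(qi)]) || ai %in% used_a) next
      assign_to[as.character(qi)] <- ai
      used_a <- c(used_a, ai)
    }
  }
  new_slots <- vector("list", wm_capacity())
  for (qi in qocc) {
    ai <- assign_to[as.character(qi)]
    if (!is.na(ai)) new_slots[[ai]] <- qwm$slots[[qi]]
  }
  free <- setdiff(seq_len(wm_capacity()),
                  stats::na.omit(assign_to))
  unmatched <- qocc[is.na(assign_to[as.character(qocc)])]
  for (i in seq_along(unmatched))
    new_slots[[free[i]]] <- qwm$slots[[unmatched[i]]]
  out <- qwm
  out$slots <- new_slots
  scores <- vapply(qocc, function(qi) {
    ai <- assign_to[as.character(qi)]
    if (is.na(ai)) NA_real_
    else overlap(qwm$slots[[qi]]$chunk, awm$slots[[ai]]$chunk)
  }, numeric(1))
  q_to <- vapply(qocc, function(qi) {
    ai <- assign_to[as.character(qi)]
    if (!is.na(ai)) ai
    else free[match(qi, unmatched)]
  }, numeric(1))
  attr(out, "alignment") <- data.frame(q_from = qocc,
                                       q_to = as.integer(q_to),
                                       matched = !is.na(assign_to),
                                       score = scores)
  out
}
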