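# Second dechunking (triplet -> element sequence at 3x gamma) and the
# element-by-element comparator: Y/N subtraction mode, WH placeholder mode,
# and recursive pointer unpacking.

#' Construct an answer object
#'
#' @param verdict one of `"yes"`, `"no"`, `"value"`, `"not_answerable"`.
#' @param payload ordered word symbols (WH answers, after unpacking).
#' @param trace provenance: matched slots, residuals, unpacking chain.
#' @return an object of class `tqa_answer`.
#' @export
answer <- function(verdict = c("yes", "no", "value", "not_answerable"),
                   payload = character(), trace = list()) {
  verdict <- match.arg(verdict)
  if ((verdict == "value") != (length(payload) > 0L))
    stop("verdict 'value' requires a nonempty payload, and vice versa")
  structure(list(verdict = verdict, payload = payload, trace = trace),
            class = "tqa_answer")
}

#' @export
print.tqa_answer <- function(x, ...) {
  cat("answer:", x$verdict,
      if (length(x$payload)) paste0("[", paste(x$payload, collapse = " "), "]")
      else "", "\n")
  invisible(x)
}

#' Serialize an answer to JSON
#' @param ans a `tqa_answer`.
#' @return JSON string with verdict, payload and trace.
#' @export
answer_to_json <- function(ans) {
  stopifnot(inherits(ans, "tqa_answer"))
  jsonlite::toJSON(list(verdict = ans$verdict, payload = ans$payload,
                        trace = ans$trace),
                   auto_unbox = TRUE, null = "null")
}

#' Second dechunking: expand buffer slots into an element stream
#'
#' Each occupied gamma slot expands into exactly three stream items in role
#' order (subject, verb, object), clocked at three times the gamma frequency
#' so that only one element is active at a time.
#'
#' @param buffer a `tqa_buffer` whose slots hold chunked triplets.
#' @return an object of class `tqa_stream`: `items` (list of `slot`, `role`,
#'   `values`, `symbol`, `kind`) and `fast_freq` (Hz).
#' @export
dechunk_elements <- function(buffer) {
  stopifnot(inherits(buffer, "tqa_buffer"))
  items <- list()
  for (k in occupied_slots(buffer)) {
    slot <- buffer$slots[[k]]
    if (!is.null(slot$triplet)) {
      for (r in triplet_roles) {
        el <- slot$triplet[[r]]
        items[[length(items) + 1L]] <-
          list(slot = k, role = r, values = el$values, symbol = el$symbol,
               kind = el$kind)
      }
    } else {
      parts <- dechunk_triplet(slot$chunk)
      for (r in triplet_roles) {
        items[[length(items) + 1L]] <-
          list(slot = k, role = r, values = parts[[r]],
               symbol = NA_character_, kind = "word")
      }
    }
  }
  structure(list(items = items, gamma_freq = buffer$gamma_freq,
                 fast_freq = 3 * buffer$gamma_freq),
            class = "tqa_stream")
}

.stream_item <- function(stream, slot, role) {
  for (it in stream$items)
    if (it$slot == slot && it$role == role) return(it)
  NULL
}

.stream_slots <- function(stream) {
  sort(unique(vapply(stream$items, function(it) it$slot, integer(1))))
}

# subtraction/subsumption: the aWM element cancels the qWM element when it
# covers at least sim_threshold of the question element's active units
.cancels <- function(q_values, a_values, sim_threshold) {
  aq <- active_set(q_values)
  if (length(aq) == 0L) return(list(cancelled = TRUE, residual = 0L))
  resid <- setdiff(aq, active_set(a_values))
  list(cancelled = 1 - length(resid) / length(aq) >= sim_threshold,
       residual = length(resid))
}

#' Yes/No comparison of aligned question and answer element streams
#'
#' For every gamma slot filled in both buffers the comparator subtracts the
#' answer elements from the question elements; similar elements (overlap at
#' or above the similarity threshold, so synonyms count) cancel. The verdict
#' is yes only if all co-filled slots cancel on all three roles and every
#' question slot synchronizes with an answer slot; a question triplet with no
#' answer counterpart means no match. Slots empty in both buffers are not
#' compared.
#'
#' @param q,a `tqa_stream` objects for the (already aligned) question and
#'   answer buffers.
#' @param sim_threshold similarity threshold for cancellation.
#' @return a `tqa_answer` with per-slot residuals in the trace.
#' @export
compare_yn <- function(q, a, sim_threshold = 0.5) {
  stopifnot(inherits(q, "tqa_stream"), inherits(a, "tqa_stream"))
  qslots <- .stream_slots(q)
  aslots <- .stream_slots(a)
  co <- intersect(qslots, aslots)
  if (length(qslots) > 0L && length(co) == 0L)
    stop(errorCondition(
      paste("no co-filled gamma slots: the buffers appear not to have been",
            "aligned"),
      class = c("tqa_unaligned_error", "error", "condition")))
  residuals <- data.frame(slot = integer(), role = character(),
                          q_symbol = character(), a_symbol = character(),
                          residual_units = integer(), cancelled = logical())
  uncovered <- setdiff(qslots, aslots)
  mismatch_slot <- NA_integer_
  for (s in co) {
    for (r in triplet_roles) {
      qi <- .stream_item(q, s, r)
      ai <- .stream_item(a, s, r)
      res <- .cancels(qi$values, ai$values, sim_threshold)
      residuals <- rbind(residuals, data.frame(
        slot = s, role = r, q_symbol = qi$symbol, a_symbol = ai$symbol,
        residual_units = res$residual, cancelled = res$cancelled))
      if (!res$cancelled && is.na(mismatch_slot)) mismatch_slot <- s
    }
  }
  ok <- length(uncovered) == 0L && all(residuals$cancelled)
  mismatch_symbols <- if (!is.na(mismatch_slot)) {
    vapply(triplet_roles,
           function(r) .stream_item(a, mismatch_slot, r)$symbol, character(1))
  } else NULL
  answer(if (ok) "yes" else "no",
         trace = list(compared_slots = co,
                      unsynchronized_q_slots = uncovered,
                      residuals = residuals,
                      mismatch_slot = mismatch_slot,
                      mismatch_triplet = mismatch_symbols))
}

# placeholder category -> categories of acceptable lexical answers
.wh_compat <- list(wh_person = "person", wh_place = "place",
                   wh_time = "time", wh_manner = "manner",
                   wh_something = c("thing", "event"))

# only "what"-type placeholders cover whole events, so only they accept a
# pointer candidate
.wh_accepts_pointer <- function(wh_cat) identical(wh_cat, "wh_something")

#' WH comparison: fill a typed placeholder from the answer buffer
#'
#' The question must contain exactly one WH placeholder element. The answer
#' element at the placeholder's (slot, role) position is the candidate: a
#' lexical word is returned if its category is compatible with the
#' placeholder's type; a pointer is unpacked recursively (only event-type
#' placeholders accept pointers); anything else makes the question not
#' answerable.
#'
#' @param q,a aligned `tqa_stream` objects.
#' @param lexicon a `tqa_lexicon` (category table and placeholder typing).
#' @param awm the answer `tqa_buffer`, needed to unpack pointer candidates.
#' @param sim_threshold similarity threshold shared with the Y/N mode.
#' @return a `tqa_answer` (`value` with the ordered answer symbols, or
#'   `not_answerable`).
#' @export
compare_wh <- function(q, a, lexicon, awm = NULL, sim_threshold = 0.5) {
  stopifnot(inherits(q, "tqa_stream"), inherits(a, "tqa_stream"),
            inherits(lexicon, "tqa_lexicon"))
  ph <- Filter(function(it) !is.na(it$symbol) &&
                 is_placeholder_symbol(it$symbol, lexicon), q$items)
  if (length(ph) == 0L)
    stop("no WH placeholder in the question: use the Y/N comparator mode")
  if (length(ph) > 1L)
    stop("questions with multiple WH placeholders are not supported")
  ph <- ph[[1L]]
  wh_cat <- word_category(ph$symbol, lexicon)
  cand <- .stream_item(a, ph$slot, ph$role)
  base_trace <- list(placeholder = ph$symbol, slot = ph$slot, role = ph$role)
  if (is.null(cand) || length(active_set(cand$values)) == 0L)
    return(answer("not_answerable",
                  trace = c(base_trace,
                            list(reason = "no stored element at the sought position"))))
  lex <- is_lexical(cand$values, lexicon)
  if (identical(cand$kind, "pointer") || !lex$lexical) {
    if (!.wh_accepts_pointer(wh_cat))
      return(answer("not_answerable",
                    trace = c(base_trace,
                              list(candidate = cand$symbol,
                                   reason = paste("event pointer does not overlap a",
                                                  sub("wh_", "", wh_cat),
                                                  "placeholder")))))
    if (is.null(awm))
      stop("pointer candidate requires the answer buffer for unpacking")
    up <- unpack_pointer(cand$values, awm, lexicon, host_slot = ph$slot,
                         threshold = sim_threshold)
    if (is.null(up))
      return(answer("not_answerable",
                    trace = c(base_trace,
                              list(candidate = cand$symbol,
                                   reason = "pointer could not be unpacked"))))
    return(answer("value", payload = up$symbols,
                  trace = c(base_trace,
                            list(candidate = cand$symbol,
                                 unpacking_chain = up$chain))))
  }
  base_sym <- utils::tail(strsplit(cand$symbol, "-", fixed = TRUE)[[1]], 1L)
  cand_cat <- word_category(base_sym, lexicon)
  if (!is.na(cand_cat) && cand_cat %in% .wh_compat[[wh_cat]])
    return(answer("value", payload = cand$symbol,
                  trace = c(base_trace, list(candidate = cand$symbol,
                                             candidate_category = cand_cat))))
  answer("not_answerable",
         trace = c(base_trace,
                   list(candidate = cand$symbol,
                        candidate_category = cand_cat,
                        reason = "candidate category incompatible with placeholder")))
}

#' Recursively unpack a pointer against the answer buffer
#'
#' Among the answer-buffer triplets in slots after the pointer's host triplet,
#' the one whose element superposition most closely matches the pointer is
#' selected (min-normalized overlap; Jaccard overlap breaks containment ties
#' in favour of the tightest superposition; remaining ties go to the earliest
#' slot). Its three elements are emitted in role order, recursively unpacking
#' any element that is itself a pointer. Because a pointer's content is always
#' stored at a later slot, the recursion terminates in at most one step per
#' remaining slot.
#'
#' @param candidate a pointer `tqa_element` or its raw rate vector.
#' @param awm the answer `tqa_buffer` (slots must carry triplets).
#' @param lexicon a `tqa_lexicon`.
#' @param host_slot slot of the triplet the pointer came from; only later
#'   slots are searched.
#' @param threshold minimum overlap for a credible target.
#' @return list with `symbols` (ordered, fully lexical) and `chain` (slot
#'   indices visited), or `NULL` when no target reaches the threshold.
#' @export
unpack_pointer <- function(candidate, awm, lexicon, host_slot = 0L,
                           threshold = 0.5) {
  stopifnot(inherits(awm, "tqa_buffer"))
  values <- if (inherits(candidate, "tqa_element")) candidate$values
  else candidate
  slots <- occupied_slots(awm)
  slots <- slots[slots > host_slot]
  slots <- slots[vapply(slots, function(s) !is.null(awm$slots[[s]]$triplet),
                        logical(1))]
  if (length(slots) == 0L) return(NULL)
  score <- vapply(slots, function(s) {
    sup <- superpose_triplet(awm$slots[[s]]$triplet)
    c(overlap(values, sup), jaccard_overlap(values, sup))
  }, numeric(2))
  ord <- order(-score[1L, ], -score[2L, ], slots)
  best <- slots[ord[1L]]
  if (score[1L, ord[1L]] < threshold) return(NULL)
  tr <- awm$slots[[best]]$triplet
  symbols <- character()
  chain <- best
  for (r in triplet_roles) {
    el <- tr[[r]]
    if (identical(el$kind, "pointer") ||
        !is_lexical(el$values, lexicon)$lexical) {
      inner <- unpack_pointer(el$values, awm, lexicon, host_slot = best,
                              threshold = threshold)
      if (is.null(inner)) return(NULL)
      symbols <- c(symbols, inner$symbols)
      chain <- c(chain, inner$chain)
    } else {
      symbols <- c(symbols, el$symbol)
    }
  }
  list(symbols = symbols, chain = chain)
}
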