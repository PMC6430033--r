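# End-to-end pipelines: storing sentences (parse -> chunk -> WM -> eLTM) and
# answering questions (parse -> qWM -> broadcast -> finalize -> aWM -> align
# -> element streams -> comparator -> template rendering).

#' Engine configuration
#'
#' One place for the representation, memory and buffer parameters.
#'
#' @param N units per element subregion.
#' @param a active units per word.
#' @param seed seed for all stochastic constructors.
#' @param sim_threshold similarity/synonymy threshold.
#' @param lex_threshold lexicality threshold (pointer detection).
#' @param match_threshold eLTM broadcast match threshold.
#' @param gamma_freq working-memory gamma frequency, Hz.
#' @return a named list of class `tqa_config`.
#' @export
qa_config <- function(N = 1000L, a = 10L, seed = 42L, sim_threshold = 0.5,
                      lex_threshold = 0.5, match_threshold = 0.6,
                      gamma_freq = 30) {
  structure(list(N = as.integer(N), a = as.integer(a), seed = as.integer(seed),
                 sim_threshold = sim_threshold, lex_threshold = lex_threshold,
                 match_threshold = match_threshold, gamma_freq = gamma_freq),
            class = "tqa_config")
}

#' Encode a sentence into episodic memory
#'
#' Full storage pipeline: parse the notation, realize word vectors, chunk each
#' triplet, hold the sequence in a theta-gamma buffer (which enforces the
#' 7-triplet capacity), then store it as a spatial pattern in eLTM.
#'
#' @param x sentence in triplet notation, or a `tqa_sentence`.
#' @param eltm a `tqa_eltm`.
#' @param lexicon a `tqa_lexicon`.
#' @param memory_id optional identifier.
#' @return the updated eLTM state.
#' @export
encode_sentence <- function(x, eltm, lexicon, memory_id = NA) {
  if (is.character(x)) x <- parse_notation(x, memory_id = memory_id)
  stopifnot(inherits(x, "tqa_sentence"))
  if (sentence_length(x) == 0L) return(eltm)
  if (is.null(x$realized)) x <- realize_sentence(x, lexicon)
  wm <- load_sequence(theta_gamma_state(), x)
  sm <- x
  sm$realized <- lapply(occupied_slots(wm),
                        function(k) read_slot(wm, k)$triplet)
  store_sentence(eltm, sm)
}

#' Retrieve the stored memory closest to a question
#'
#' Loads the question triplets into the question buffer, broadcasts each slot
#' to all eLTM modules, and finalizes the search.
#'
#' @param question question in triplet notation, or a realized
#'   `tqa_sentence`.
#' @param eltm a `tqa_eltm` with stored sentences.
#' @param lexicon a `tqa_lexicon`.
#' @param gamma_freq buffer gamma frequency, Hz.
#' @return list: `memory` (sentence or NULL), `failure`, `state` (settled
#'   eLTM), `qwm` (loaded question buffer).
#' @export
retrieve_memory <- function(question, eltm, lexicon, gamma_freq = 30) {
  if (is.character(question)) question <- parse_notation(question)
  if (is.null(question$realized) && sentence_length(question) > 0L)
    question <- realize_sentence(question, lexicon)
  qwm <- load_sequence(theta_gamma_state(gamma_freq), question)
  state <- begin_query(eltm)
  for (k in occupied_slots(qwm))
    state <- broadcast_query(state, read_slot(qwm, k)$chunk, slot_index = k)
  res <- finalize_retrieval(state)
  res$qwm <- qwm
  res
}

#' Answer a question against episodic memory
#'
#' The full Fig-1C style pipeline: retrieval, first dechunking into the answer
#' buffer, conceptual alignment of the question buffer, second dechunking into
#' element streams, and the comparator in Y/N or WH mode (WH when the question
#' carries a placeholder). Retrieval failure renders as "I do not know."
#'
#' @param question question in triplet notation.
#' @param eltm a `tqa_eltm` holding at least one sentence.
#' @param lexicon a `tqa_lexicon`.
#' @param config a `tqa_config`.
#' @return a `tqa_answer` with an added `rendered` string and a trace
#'   covering retrieval, alignment and comparison.
#' @export
answer_question <- function(question, eltm, lexicon, config = qa_config()) {
  stopifnot(inherits(eltm, "tqa_eltm"))
  if (eltm_size(eltm) == 0L)
    stop("episodic memory is empty; store sentences before asking")
  if (is.character(question)) question <- parse_notation(question)
  if (is.null(question$realized))
    question <- realize_sentence(question, lexicon)
  ret <- retrieve_memory(question, eltm, lexicon,
                         gamma_freq = config$gamma_freq)
  if (ret$failure) {
    ans <- answer("not_answerable",
                  trace = list(stage = "retrieval",
                               reason = "no stored memory matched the question"))
    ans$rendered <- render_answer(ans)
    return(ans)
  }
  awm <- dechunk_to_awm(ret$memory, gamma_freq = config$gamma_freq)
  qwm <- align_slots_abstract(ret$qwm, awm,
                              threshold = config$sim_threshold)
  qs <- dechunk_elements(qwm)
  as_ <- dechunk_elements(awm)
  has_ph <- any(vapply(question$realized, function(tr) {
    any(vapply(tr$symbols, is_placeholder_symbol, logical(1),
               lexicon = lexicon))
  }, logical(1)))
  ans <- if (has_ph)
    compare_wh(qs, as_, lexicon, awm = awm,
               sim_threshold = config$sim_threshold)
  else compare_yn(qs, as_, sim_threshold = config$sim_threshold)
  ans$trace$retrieved_id <- ret$memory$memory_id
  ans$trace$retrieved <- lapply(ret$memory$realized, function(tr) tr$symbols)
  ans$trace$alignment <- attr(qwm, "alignment")
  ans$trace$eltm_trace <- ret$state$trace
  ans$rendered <- render_answer(ans)
  ans
}

.expand_cword <- function(sym) gsub("-", " ", sym, fixed = TRUE)

#' Render an answer with a fixed template
#'
#' A deliberately minimal stand-in for a language generator: the verdict word
#' plus the relevant symbols with compositional-word hyphens expanded. No
#' morphology, tense or agreement.
#'
#' @param ans a `tqa_answer`.
#' @return character scalar.
#' @export
render_answer <- function(ans) {
  stopifnot(inherits(ans, "tqa_answer"))
  switch(ans$verdict,
         yes = "Yes.",
         no = {
           mm <- ans$trace$mismatch_triplet
           if (!is.null(mm) && !anyNA(mm))
             paste0("No, ", paste(.expand_cword(mm), collapse = " "), ".")
           else "No."
         },
         value = {
           txt <- paste(.expand_cword(ans$payload), collapse = " ")
           paste0(toupper(substr(txt, 1L, 1L)), substr(txt, 2L, nchar(txt)),
                  ".")
         },
         not_answerable = "I do not know.")
}

#' Run a named worked-example demonstration
#'
#' Executes one of the bundled scenarios end to end (memory retrieval with
#' distractors and all broadcast orders, the Yes/No and WH comparator cases,
#' or the spiking alignment simulation) and reports the outcome against the
#' scenario's expected result.
#'
#' @param name one of `"fig2"`, `"fig3a"`, `"fig3b"`, `"fig3c"`, `"fig3d"`,
#'   `"fig5"`.
#' @param config a `tqa_config`.
#' @return list with `name`, `pass`, `expected`, `actual` and a run report.
#' @export
run_demo <- function(name, config = qa_config()) {
  fx <- demo_fixtures()
  if (!name %in% names(fx))
    stop("unknown demo '", name, "'; available: ",
         paste(names(fx), collapse = ", "))
  f <- fx[[name]]
  if (f$type == "alignment") {
    al <- do.call(align_buffers, f$setup)
    sep <- slot_separation(al, f$expected$pattern_pair[1],
                           f$expected$pattern_pair[2])
    pass <- !is.na(al$convergence_cycle) &&
      al$convergence_cycle <= f$expected$max_convergence_cycles &&
      sep == f$expected$separation
    return(list(name = name, pass = pass,
                expected = f$expected,
                actual = list(separation = sep,
                              convergence_cycle = al$convergence_cycle),
                report = al))
  }
  lexicon <- fixture_lexicon(config)
  eltm <- eltm_state(match_threshold = config$match_threshold)
  for (i in seq_along(f$corpus))
    eltm <- encode_sentence(f$corpus[i], eltm, lexicon,
                            memory_id = paste0(name, "_m", i))
  if (f$type == "retrieval") {
    ret <- retrieve_memory(f$question, eltm, lexicon)
    actual <- if (ret$failure) NULL else
      lapply(ret$memory$realized, function(tr) tr$symbols)
    pass <- !ret$failure && identical(actual, f$expected$memory_symbols)
    return(list(name = name, pass = pass, expected = f$expected,
                actual = list(memory_symbols = actual),
                report = ret$state$trace))
  }
  ans <- answer_question(f$question, eltm, lexicon, config)
  pass <- identical(ans$verdict, f$expected$verdict) &&
    (is.null(f$expected$payload) ||
       identical(ans$payload, f$expected$payload))
  list(name = name, pass = pass, expected = f$expected,
       actual = list(verdict = ans$verdict, payload = ans$payload,
                     rendered = ans$rendered),
       report = ans$trace)
}
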