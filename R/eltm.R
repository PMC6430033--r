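# Modular episodic long-term memory (eLTM): one-shot second-chunking storage
# of sentences across 7 triplet modules, prime-then-excite parallel search,
# and finalization to the single closest stored sentence.

#' Create an empty episodic long-term memory
#'
#' The network has 7 modules (one per gamma slot of the working-memory
#' buffer), each divided into 3 element subregions (subject, verb, object).
#' Each module is an attractor store of chunked triplet patterns; inter-module
#' priming links are learned one-shot when a sentence is stored.
#'
#' @param match_threshold minimum chunked-pattern overlap for a broadcast
#'   query to evoke a stored triplet. The default 0.6 lets a triplet matching
#'   on two of three elements (overlap 2/3) count as close - necessary so a
#'   question with one wrong or substituted element still retrieves the
#'   memory it asks about - while excluding single-element coincidences (1/3).
#' @param full_match_threshold overlap above which an evoked triplet counts
#'   as fully shared with the query (a synonym substitution stays above this;
#'   a wrong element falls below it). The closest memory is the sentence with
#'   the most fully shared query triplets, partial evocations breaking ties.
#' @param n_modules number of triplet modules (7 in the architecture).
#' @return an object of class `tqa_eltm`.
#' @export
eltm_state <- function(match_threshold = 0.6, full_match_threshold = 0.8,
                       n_modules = 7L) {
  structure(list(n_modules = as.integer(n_modules),
                 subregions_per_module = 3L,
                 match_threshold = match_threshold,
                 full_match_threshold = full_match_threshold,
                 modules = rep(list(list()), n_modules),
                 links = data.frame(from_module = integer(),
                                    from_entry = integer(),
                                    to_module = integer(),
                                    to_entry = integer()),
                 status = rep(list(integer(0)), n_modules),
                 synapse_mode = "prime_only",
                 ever_active = rep(list(integer(0)), n_modules),
                 sentence_order = character(),
                 next_auto_id = 1L,
                 query_broadcasts = list(),
                 trace = list()),
            class = "tqa_eltm")
}

#' Geometry of the memory network
#' @param state a `tqa_eltm`.
#' @return named integer vector: modules, subregions per module, and total
#'   element subregions.
#' @export
eltm_geometry <- function(state) {
  stopifnot(inherits(state, "tqa_eltm"))
  c(modules = state$n_modules,
    subregions_per_module = state$subregions_per_module,
    element_subregions = state$n_modules * state$subregions_per_module)
}

#' Number of stored sentences
#' @param state a `tqa_eltm`.
#' @return integer.
#' @export
eltm_size <- function(state) length(state$sentence_order)

#' @export
print.tqa_eltm <- function(x, ...) {
  cat("episodic LTM:", eltm_size(x), "sentences over", x$n_modules,
      "modules; synapse mode:", x$synapse_mode, "\n")
  invisible(x)
}

.trace_add <- function(state, ...) {
  state$trace[[length(state$trace) + 1L]] <- list(...)
  state
}

#' Store a sentence in episodic long-term memory (second chunking)
#'
#' Triplet k becomes an attractor of module k, so the serial order of the
#' working-memory buffer is laid out as a spatial pattern. Hebbian one-shot
#' learning links every pair of the sentence's triplets across their modules
#' with directed priming connections.
#'
#' @param state a `tqa_eltm`.
#' @param sm a realized `tqa_sentence` of at most 7 triplets.
#' @return the updated state.
#' @export
store_sentence <- function(state, sm) {
  stopifnot(inherits(state, "tqa_eltm"), inherits(sm, "tqa_sentence"))
  k <- sentence_length(sm)
  if (k == 0L) return(state)
  if (is.null(sm$realized))
    stop("sentence must be realized (word vectors) before storage")
  if (k > state$n_modules)
    stop("a sentence of ", k, " triplets exceeds the ", state$n_modules,
         "-module capacity")
  id <- sm$memory_id
  if (is.null(id) || is.na(id)) {
    id <- paste0("s", state$next_auto_id)
    state$next_auto_id <- state$next_auto_id + 1L
  }
  id <- as.character(id)
  coords <- matrix(0L, nrow = k, ncol = 2L)
  for (pos in seq_len(k)) {
    tr <- sm$realized[[pos]]
    entry <- list(pattern = chunk_triplet(tr), triplet = tr,
                  sentence_id = id, position = pos)
    state$modules[[pos]] <- c(state$modules[[pos]], list(entry))
    state$status[[pos]] <- c(state$status[[pos]], 0L)
    coords[pos, ] <- c(pos, length(state$modules[[pos]]))
  }
  if (k > 1L) {
    pairs <- expand.grid(i = seq_len(k), j = seq_len(k))
    pairs <- pairs[pairs$i != pairs$j, ]
    state$links <- rbind(state$links,
                         data.frame(from_module = coords[pairs$i, 1L],
                                    from_entry = coords[pairs$i, 2L],
                                    to_module = coords[pairs$j, 1L],
                                    to_entry = coords[pairs$j, 2L]))
  }
  state$sentence_order <- c(state$sentence_order, id)
  state
}

#' Reset transient query state
#'
#' Statuses (active/primed) are transient: they are cleared when a new query
#' starts. Stored patterns and synaptic links persist; retrieval never mutates
#' them.
#'
#' @param state a `tqa_eltm`.
#' @return the state with all triplets inactive and synapses in prime-only
#'   mode.
#' @export
begin_query <- function(state) {
  stopifnot(inherits(state, "tqa_eltm"))
  state$status <- lapply(state$status, function(s) rep(0L, length(s)))
  state$synapse_mode <- "prime_only"
  state$ever_active <- rep(list(integer(0)), state$n_modules)
  state$query_broadcasts <- list()
  state$trace <- list()
  state
}

#' Broadcast one question triplet to all memory modules in parallel
#'
#' Every module holding a stored triplet close to the broadcast pattern reacts:
#' if the module has no active attractor the match becomes active; if a
#' different attractor is already active, the match can replace it only when
#' the match had been primed (the advantage needed to win the competition) -
#' otherwise the pre-existing attractor wins. Every newly active triplet then
#' primes its sentence-mates in other modules; priming alone never activates
#' anything, which keeps crosstalk minimal during the search.
#'
#' @param state a `tqa_eltm` in prime-only mode.
#' @param query a chunked triplet pattern (length 3N) or a `tqa_triplet`.
#' @param slot_index gamma slot the query came from (for the trace).
#' @return the updated state.
#' @export
broadcast_query <- function(state, query, slot_index = NA_integer_) {
  stopifnot(inherits(state, "tqa_eltm"))
  if (state$synapse_mode != "prime_only")
    stop("broadcast requires prime-only synapses; call begin_query() first")
  if (inherits(query, "tqa_triplet")) query <- chunk_triplet(query)
  state$query_broadcasts <- c(state$query_broadcasts, list(query))
  newly_active <- list()
  for (m in seq_len(state$n_modules)) {
    entries <- state$modules[[m]]
    if (length(entries) == 0L) next
    scores <- vapply(entries, function(e) overlap(query, e$pattern),
                     numeric(1))
    cand <- which(scores >= state$match_threshold)
    if (length(cand) == 0L) next
    primed <- state$status[[m]] == 1L
    cand <- cand[order(-scores[cand], -as.integer(primed[cand]), cand)]
    best <- cand[1L]
    act <- which(state$status[[m]] == 2L)
    if (length(act) == 0L) {
      state$status[[m]][best] <- 2L
      state$ever_active[[m]] <- union(state$ever_active[[m]], best)
      state <- .trace_add(state, stage = "broadcast", gamma_slot = slot_index,
                          module = m, entry = best,
                          sentence_id = entries[[best]]$sentence_id,
                          from = "inactive", to = "active",
                          reason = "matched broadcast, module free")
      newly_active <- c(newly_active, list(c(m, best)))
    } else if (act != best) {
      # a primed match can displace the incumbent attractor, but only when
      # the broadcast drives it strongly (a weak partial evocation never
      # overturns an established attractor)
      if (primed[best] && scores[best] >= state$full_match_threshold) {
        state$status[[m]][act] <- 0L
        state$status[[m]][best] <- 2L
        state$ever_active[[m]] <- union(state$ever_active[[m]], best)
        state <- .trace_add(state, stage = "broadcast",
                            gamma_slot = slot_index, module = m, entry = act,
                            sentence_id = entries[[act]]$sentence_id,
                            from = "active", to = "inactive",
                            reason = "displaced by primed match")
        state <- .trace_add(state, stage = "broadcast",
                            gamma_slot = slot_index, module = m, entry = best,
                            sentence_id = entries[[best]]$sentence_id,
                            from = "primed", to = "active",
                            reason = "primed match replaces active attractor")
        newly_active <- c(newly_active, list(c(m, best)))
      } else {
        state <- .trace_add(state, stage = "broadcast",
                            gamma_slot = slot_index, module = m, entry = best,
                            sentence_id = entries[[best]]$sentence_id,
                            from = "inactive", to = "inactive",
                            reason = "pre-existing attractor wins competition")
      }
    }
  }
  # priming pass: activations within one gamma slot are simultaneous, so
  # priming takes effect only after all modules have competed. Priming
  # spreads from the active cells, not from a sentence label: every stored
  # entry in the module whose pattern the active assembly reproduces sends
  # its learned inter-module links, so sentences sharing a triplet in one
  # module both prime their mates when that pattern lights up.
  for (coord in newly_active) {
    m <- coord[1L]
    pat <- state$modules[[m]][[coord[2L]]]$pattern
    sources <- which(vapply(state$modules[[m]], function(e) {
      overlap(e$pattern, pat) >= state$full_match_threshold
    }, logical(1)))
    ln <- state$links
    tg <- ln[ln$from_module == m & ln$from_entry %in% sources, ,
             drop = FALSE]
    for (r in seq_len(nrow(tg))) {
      m2 <- tg$to_module[r]; e2 <- tg$to_entry[r]
      if (state$status[[m2]][e2] == 0L) {
        state$status[[m2]][e2] <- 1L
        state <- .trace_add(state, stage = "broadcast",
                            gamma_slot = slot_index, module = m2, entry = e2,
                            sentence_id =
                              state$modules[[m2]][[e2]]$sentence_id,
                            from = "inactive", to = "primed",
                            reason = "primed by active sentence-mate")
      }
    }
  }
  state
}

#' Switch synapses to excitatory mode and retrieve the closest memory
#'
#' After all question triplets have been broadcast, the synapses change from
#' prime-only to excitatory mode and the network settles into a single global
#' attractor: the stored sentence with the most active (query-matched)
#' triplets wins, its primed members become active, and every other attractor
#' is extinguished. Ties go to the earliest-stored sentence.
#'
#' @param state a `tqa_eltm` after at least one [broadcast_query()].
#' @return list with `memory` (a realized `tqa_sentence` in module order, or
#'   `NULL`), `failure` (logical: no stored triplet ever activated) and
#'   `state` (the settled memory state, synapses in excite mode).
#' @export
finalize_retrieval <- function(state) {
  stopifnot(inherits(state, "tqa_eltm"))
  if (length(state$query_broadcasts) == 0L)
    stop("no broadcast has occurred; nothing to finalize")
  state$synapse_mode <- "excite"
  active <- do.call(rbind, lapply(seq_len(state$n_modules), function(m) {
    idx <- which(state$status[[m]] == 2L)
    if (length(idx) == 0L) return(NULL)
    data.frame(module = m, entry = idx,
               sentence_id = vapply(state$modules[[m]][idx],
                                    function(e) e$sentence_id, character(1)))
  }))
  if (is.null(active) || nrow(active) == 0L) {
    state <- .trace_add(state, stage = "finalize", gamma_slot = NA_integer_,
                        module = NA_integer_, entry = NA_integer_,
                        sentence_id = NA_character_, from = "-", to = "-",
                        reason = "retrieval failure: no attractor activated")
    return(list(memory = NULL, failure = TRUE, state = state))
  }
  # excitatory competition: the closest memory is the sentence sharing the
  # most query triplets whose evidence was instantiated during the search.
  # A broadcast supports a sentence when the sentence holds a matching
  # triplet in a module where that pattern was active at some point (later
  # displacement does not erase the trace of having won the attractor), and
  # support follows the pattern, not the sentence label: sentences sharing a
  # triplet in one module share its active cells. Fully shared broadcasts
  # rank first, partial evocations break ties, then storage order.
  ids <- state$sentence_order
  support <- vapply(ids, function(i) {
    n_full <- 0; n_any <- 0
    for (q in state$query_broadcasts) {
      best_full <- FALSE; best_any <- FALSE
      for (m in seq_len(state$n_modules)) {
        ever <- state$ever_active[[m]]
        if (length(ever) == 0L) next
        own <- which(vapply(state$modules[[m]],
                            function(e) e$sentence_id == i, logical(1)))
        for (e in own) {
          pat <- state$modules[[m]][[e]]$pattern
          qov <- overlap(q, pat)
          if (qov < state$match_threshold) next
          inst <- max(vapply(ever, function(e2) {
            overlap(pat, state$modules[[m]][[e2]]$pattern)
          }, numeric(1)))
          if (inst >= state$full_match_threshold) {
            best_any <- TRUE
            if (qov >= state$full_match_threshold) best_full <- TRUE
          }
        }
      }
      n_full <- n_full + best_full
      n_any <- n_any + best_any
    }
    c(n_full, n_any)
  }, numeric(2))
  ord <- order(-support[1L, ], -support[2L, ], seq_along(ids))
  winner <- ids[ord[1L]]
  trips <- list()
  for (m in seq_len(state$n_modules)) {
    own <- which(vapply(state$modules[[m]],
                        function(e) e$sentence_id == winner, logical(1)))
    state$status[[m]][] <- 0L
    if (length(own) == 1L) {
      state$status[[m]][own] <- 2L
      trips[[state$modules[[m]][[own]]$position]] <-
        state$modules[[m]][[own]]$triplet
      state <- .trace_add(state, stage = "finalize", gamma_slot = NA_integer_,
                          module = m, entry = own, sentence_id = winner,
                          from = "any", to = "active",
                          reason = "coalition completion (excitatory mode)")
    }
  }
  list(memory = sentence_from_triplets(trips, memory_id = winner),
       failure = FALSE, state = state)
}

#' Dechunk a retrieved memory into the answer buffer (first dechunking)
#'
#' The spatial sentence pattern is routed to the answer working-memory buffer
#' one module at a time, in storage order: the triplet in module k lands in
#' gamma slot k.
#'
#' @param memory a realized `tqa_sentence` (at most 7 triplets).
#' @param gamma_freq gamma frequency of the target buffer, Hz.
#' @return a loaded `tqa_buffer`.
#' @export
dechunk_to_awm <- function(memory, gamma_freq = 30) {
  stopifnot(inherits(memory, "tqa_sentence"))
  load_sequence(theta_gamma_state(gamma_freq), memory)
}

#' Check the one-active-attractor-per-module invariant
#' @param state a `tqa_eltm`.
#' @return logical.
#' @export
one_active_per_module <- function(state) {
  all(vapply(state$status, function(s) sum(s == 2L) <= 1L, logical(1)))
}

#' Verify priming safety over the current query's trace
#'
#' Before finalization, a triplet may only become active if it matches one of
#' the broadcast query patterns: a triplet that is not in the query is never
#' activated until the end of the search.
#'
#' @param state a `tqa_eltm` (after broadcasts, before or after finalize).
#' @return logical: TRUE if no pre-finalization activation violated the rule.
#' @export
verify_priming_safety <- function(state) {
  stopifnot(inherits(state, "tqa_eltm"))
  for (ev in state$trace) {
    if (ev$stage != "broadcast" || !identical(ev$to, "active")) next
    pat <- state$modules[[ev$module]][[ev$entry]]$pattern
    ok <- any(vapply(state$query_broadcasts,
                     function(q) overlap(q, pat) >= state$match_threshold,
                     logical(1)))
    if (!ok) return(FALSE)
  }
  TRUE
}
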