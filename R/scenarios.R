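# Worked-example fixtures and the synthetic corpus generator with its
# exhaustive-search oracle. The fixtures are the package's regression surface;
# the generator produces randomized corpora with controlled triplet overlap,
# synonym substitution and pointer depth for property tests.

.placeholder_specs <- data.frame(
  symbol = c("something_WH", "person_WH", "place_WH", "time_WH", "manner_WH"),
  category = c("wh_something", "wh_person", "wh_place", "wh_time",
               "wh_manner"),
  group = NA_character_)

#' Lexicon covering the bundled worked examples
#'
#' @param config a `tqa_config` (network size, sparsity, thresholds, seed).
#' @return a `tqa_lexicon` with the demo vocabulary, the `man`/`guy` synonym
#'   pair, the WH placeholders and the `nice` modifier.
#' @export
fixture_lexicon <- function(config = qa_config()) {
  persons <- c("John", "Boris", "Natasha", "Marco", "Ole", "Rusty")
  verbs <- c("eat", "drink", "cook", "bake", "see", "hit", "bother")
  things <- c("cake", "tea", "beer", "baguette", "scallop", "pizza",
              "chocolate", "meal", "bread", "movie", "coffee")
  specs <- rbind(
    data.frame(symbol = persons, category = "person", group = NA_character_),
    data.frame(symbol = c("man", "guy"), category = "person", group = "man"),
    data.frame(symbol = verbs, category = "event", group = NA_character_),
    data.frame(symbol = things, category = "thing", group = NA_character_),
    .placeholder_specs)
  lex <- build_lexicon(specs, N = config$N, a = config$a, seed = config$seed,
                       sim_threshold = config$sim_threshold,
                       lex_threshold = config$lex_threshold)
  add_modifier(lex, "nice")
}

#' The worked-example fixture set
#'
#' Machine-readable versions of the bundled scenarios: the four-clause
#' retrieval episode with distractors, the four comparator cases (simple
#' No, alignment Yes, WH value, WH with nested pointer unpacking) and the
#' spiking-buffer alignment scenario, each with its expected outcome.
#'
#' @return named list of fixtures; each has `type`, inputs and `expected`.
#' @export
demo_fixtures <- function() {
  fig2_corpus <- c(
    paste("<Rusty,eat,baguette> <John,cook,scallop> <Ole,bake,pizza>",
          "<Boris,eat,chocolate>"),
    "<John,cook,scallop> <Natasha,drink,tea>",
    "<Marco,eat,bread> <Natasha,see,movie> <Boris,eat,chocolate>",
    "<Natasha,drink,beer> <Ole,eat,cake> <Rusty,eat,baguette>")
  fig2_expected <- list(
    memory_symbols = list(c("Rusty", "eat", "baguette"),
                          c("John", "cook", "scallop"),
                          c("Ole", "bake", "pizza"),
                          c("Boris", "eat", "chocolate")))
  nested <- "<[N+s+J+h+B],bother,Marco> <Natasha,see,[J+h+B]> <John,hit,Boris>"
  list(
    fig2 = list(
      type = "retrieval",
      corpus = fig2_corpus,
      question = "<John,cook,scallop> <Boris,eat,chocolate> <Rusty,eat,baguette>",
      expected = fig2_expected),
    fig3a = list(
      type = "yn",
      corpus = "<John,eat,cake> <Boris,drink,tea>",
      question = "<Boris,drink,beer>",
      expected = list(verdict = "no", mismatch = "tea")),
    fig3b = list(
      type = "yn",
      corpus = nested,
      question = "<John,hit,Boris>",
      expected = list(verdict = "yes", aligned_to_slot = 3L)),
    fig3c = list(
      type = "wh",
      corpus = "<John,eat,cake> <Boris,drink,tea>",
      question = "<Boris,drink,something_WH> <John,eat,cake>",
      expected = list(verdict = "value", payload = "tea")),
    fig3d = list(
      type = "wh",
      corpus = nested,
      question = "<something_WH,bother,Marco>",
      expected = list(verdict = "value",
                      payload = c("Natasha", "see", "John", "hit", "Boris"),
                      unpacking_chain = c(2L, 3L))),
    fig5 = list(
      type = "alignment",
      setup = fig5_scenario(),
      expected = list(pattern_pair = c("B", "D"), separation = 2L,
                      max_convergence_cycles = 4L)))
}

#' Inputs of the spiking-buffer alignment scenario
#'
#' The question buffer holds patterns B and D (10 neurons each) in adjacent
#' gamma slots (the two slots after the answer buffer's occupied region, so
#' both are misaligned); the answer buffer holds A, B, C, D in four
#' consecutive slots. Alignment should leave qWM's B and D in their aWM
#' counterparts' slots, two gamma cycles apart.
#'
#' @param config a `tqa_spiking_config`.
#' @param n_theta number of theta cycles to simulate.
#' @return argument list for [align_buffers()].
#' @export
fig5_scenario <- function(config = spiking_buffer_config(), n_theta = 4L) {
  grid <- default_slot_times(5L, config)
  pitch <- grid[2] - grid[1]
  list(qwm_patterns = list(B = 11:20, D = 31:40),
       awm_patterns = list(A = 1:10, B = 11:20, C = 21:30, D = 31:40),
       config = config,
       n_theta = n_theta,
       qwm_init_times = c(B = grid[4], D = grid[4] + pitch),
       awm_init_times = c(A = grid[1], B = grid[2], C = grid[3],
                          D = grid[4]))
}

#' Specification for a synthetic corpus
#'
#' @param n_sentences number of stored sentences.
#' @param triplets_per_sentence clauses per sentence (at most 7).
#' @param vocab_size number of base content words.
#' @param overlap_rate probability that a clause is copied from an earlier
#'   sentence.
#' @param pointer_depth length of the embedded-clause pointer chain appended
#'   to each sentence (0 = none, at most 3).
#' @param synonym_rate fraction of each word pool given a synonym twin
#'   (questions substitute twins to test synonym tolerance).
#' @param seed generator seed; identical seeds give byte-identical corpora.
#' @return a validated list of class `tqa_scenario_spec`.
#' @export
scenario_spec <- function(n_sentences = 4L, triplets_per_sentence = 3L,
                          vocab_size = 24L, overlap_rate = 0.2,
                          pointer_depth = 0L, synonym_rate = 0.25,
                          seed = 1L) {
  spec <- list(n_sentences = as.integer(n_sentences),
               triplets_per_sentence = as.integer(triplets_per_sentence),
               vocab_size = as.integer(vocab_size),
               overlap_rate = overlap_rate,
               pointer_depth = as.integer(pointer_depth),
               synonym_rate = synonym_rate,
               seed = as.integer(seed))
  stopifnot(spec$n_sentences >= 1L,
            spec$triplets_per_sentence >= 1L,
            spec$triplets_per_sentence + spec$pointer_depth <= 7L,
            spec$vocab_size >= 9L,
            spec$overlap_rate >= 0, spec$overlap_rate <= 1,
            spec$pointer_depth >= 0L, spec$pointer_depth <= 3L,
            spec$synonym_rate >= 0, spec$synonym_rate <= 1)
  structure(spec, class = "tqa_scenario_spec")
}

.gen_pools <- function(spec) {
  n_per <- max(3L, round(spec$vocab_size * 0.3))
  n_act <- max(3L, round(spec$vocab_size * 0.3))
  n_obj <- max(3L, spec$vocab_size - n_per - n_act)
  list(person = sprintf("per%02d", seq_len(n_per)),
       event = sprintf("act%02d", seq_len(n_act)),
       thing = sprintf("obj%02d", seq_len(n_obj)))
}

#' Generate a random corpus with its ground-truth question table
#'
#' Sentences are random subject-verb-object clauses over a symbolic
#' vocabulary; with probability `overlap_rate` a clause is shared with an
#' earlier sentence (usually landing in a different module). For every
#' sentence three question types are derived: a verbatim sub-selection
#' (shuffled), a synonym-substituted variant, and a variant with one element
#' corrupted across synonym-group boundaries, so the expected verdict is
#' unambiguous. The expected answer of every question is computed by the
#' symbolic exhaustive-search oracle, independent of the network pipeline.
#'
#' @param spec a `tqa_scenario_spec`.
#' @return list: `spec`, `corpus` (sentences: `id`, `triplets`, `pointers`),
#'   `questions` (with `expected_verdict` and `expected_best`),
#'   `lexicon_specs`, `groups` (symbol to synonym-group map).
#' @export
generate_corpus <- function(spec = scenario_spec()) {
  stopifnot(inherits(spec, "tqa_scenario_spec"))
  .with_seed(spec$seed * 1000L + 17L, .generate_corpus_impl(spec))
}

.generate_corpus_impl <- function(spec) {
  pools <- .gen_pools(spec)
  # synonym twins: the first synonym_rate fraction of each pool gets a twin
  twins <- lapply(pools, function(p) {
    k <- floor(spec$synonym_rate * length(p))
    if (k == 0L) character() else paste0(p[seq_len(k)], "_syn")
  })
  groups <- character()
  for (pool in names(pools)) {
    for (tw in twins[[pool]]) {
      base <- sub("_syn$", "", tw)
      groups[base] <- base
      groups[tw] <- base
    }
  }
  specs <- do.call(rbind, lapply(names(pools), function(pool) {
    syms <- c(pools[[pool]], twins[[pool]])
    grp <- ifelse(syms %in% names(groups), groups[syms], NA_character_)
    data.frame(symbol = syms, category = pool, group = unname(grp))
  }))
  specs <- rbind(specs, .placeholder_specs)

  rand_triplet <- function() c(sample(pools$person, 1L),
                               sample(pools$event, 1L),
                               sample(pools$thing, 1L))
  corpus <- list()
  all_triplets <- list()
  for (s in seq_len(spec$n_sentences)) {
    trips <- list()
    for (pos in seq_len(spec$triplets_per_sentence)) {
      tr <- NULL
      for (attempt in 1:50) {
        cand <- if (length(all_triplets) && s > 1L &&
                    stats::runif(1) < spec$overlap_rate)
          all_triplets[[sample.int(length(all_triplets), 1L)]]
        else rand_triplet()
        if (!any(vapply(trips, identical, logical(1), y = cand))) {
          tr <- cand
          break
        }
      }
      if (is.null(tr)) stop("vocabulary too small to draw distinct triplets")
      trips[[pos]] <- tr
    }
    pointers <- data.frame(triplet = integer(), role = character(),
                           target = integer())
    if (spec$pointer_depth > 0L) {
      base_len <- length(trips)
      for (d in seq_len(spec$pointer_depth))
        trips[[base_len + d]] <- rand_triplet()
      for (d in seq_len(spec$pointer_depth)) {
        from <- base_len + d - 1L
        if (from >= 1L)
          pointers <- rbind(pointers,
                            data.frame(triplet = from, role = "object",
                                       target = base_len + d))
      }
    }
    corpus[[s]] <- list(id = paste0("s", s), triplets = trips,
                        pointers = pointers)
    all_triplets <- c(all_triplets, trips[seq_len(spec$triplets_per_sentence)])
  }

  plain <- lapply(corpus, function(sen) {
    keep <- setdiff(seq_along(sen$triplets), sen$pointers$triplet)
    sen$triplets[keep]
  })
  questions <- list()
  qid <- 0L
  for (s in seq_len(spec$n_sentences)) {
    pool_q <- plain[[s]]
    len <- length(pool_q)
    for (type in c("verbatim", "synonym", "corrupt")) {
      qlen <- if (len == 1L) 1L else sample(2:len, 1L)
      qt <- pool_q[sample.int(len, qlen)]
      if (type == "synonym") {
        subst <- .synonym_substitution(qt, groups)
        if (is.null(subst)) next
        qt <- subst
      } else if (type == "corrupt") {
        qt <- .corrupting_substitution(qt, pools, groups)
      }
      oracle <- oracle_answer(plain, qt, groups)
      qid <- qid + 1L
      questions[[qid]] <- list(id = paste0("q", qid),
                               sentence_id = paste0("s", s),
                               type = type, triplets = qt,
                               expected_verdict = oracle$verdict,
                               expected_best = oracle$best_id)
    }
  }
  list(spec = spec, corpus = corpus, questions = questions,
       lexicon_specs = specs, groups = groups)
}

# replace one element of one question triplet with its synonym twin
.synonym_substitution <- function(qt, groups) {
  slots <- expand.grid(i = seq_along(qt), k = 1:3)
  slots <- slots[sample.int(nrow(slots)), , drop = FALSE]
  for (r in seq_len(nrow(slots))) {
    sym <- qt[[slots$i[r]]][slots$k[r]]
    if (sym %in% names(groups)) {
      twin <- if (endsWith(sym, "_syn")) sub("_syn$", "", sym)
      else paste0(sym, "_syn")
      qt[[slots$i[r]]][slots$k[r]] <- twin
      return(qt)
    }
  }
  NULL
}

# replace one element with a different word from the same pool, crossing any
# synonym-group boundary so the oracle verdict is unambiguously "no"
.corrupting_substitution <- function(qt, pools, groups) {
  i <- sample.int(length(qt), 1L)
  k <- sample.int(3L, 1L)
  sym <- qt[[i]][k]
  pool <- pools[[k]]
  grp <- function(x) if (x %in% names(groups)) groups[[x]] else
    paste0("#", x)
  cand <- pool[pool != sym & vapply(pool, grp, character(1)) != grp(sym)]
  qt[[i]][k] <- sample(cand, 1L)
  qt
}

#' Symbolic oracle for Y/N questions over a corpus
#'
#' Model-independent ground truth by exhaustive search: two elements are
#' similar when they are the same symbol or share a synonym group; a question
#' clause supports a sentence when a stored clause matches it on at least two
#' of three elements (which is what makes a memory retrievable at all), and
#' matches it fully when all three are similar. The closest memory maximizes
#' the number of supporting question clauses (ties to the earliest sentence);
#' the verdict is yes only if the closest memory fully matches every question
#' clause, no if it is retrievable but mismatched, and not answerable when no
#' clause supports any sentence. Fully matched clauses dominate the ranking;
#' partial matches only break ties (they make a memory retrievable but do not
#' make it the closest one).
#'
#' @param sentences list of sentences, each a list of symbol triplets
#'   (pointer clauses excluded).
#' @param q_triplets the question's symbol triplets.
#' @param groups named map symbol -> synonym group.
#' @return list with `verdict` and `best_id` (index of the closest sentence,
#'   or NA).
#' @export
oracle_answer <- function(sentences, q_triplets, groups = character()) {
  sim_el <- function(x, y) {
    x == y || (x %in% names(groups) && y %in% names(groups) &&
                 groups[[x]] == groups[[y]])
  }
  n_sim <- function(qt, st) sum(mapply(sim_el, qt, st))
  score <- vapply(sentences, function(sen) {
    part <- sum(vapply(q_triplets, function(qt) {
      any(vapply(sen, function(st) n_sim(qt, st) >= 2L, logical(1)))
    }, logical(1)))
    full <- sum(vapply(q_triplets, function(qt) {
      any(vapply(sen, function(st) n_sim(qt, st) == 3L, logical(1)))
    }, logical(1)))
    c(part, full)
  }, numeric(2))
  if (max(score[1L, ]) == 0L)
    return(list(verdict = "not_answerable", best_id = NA_integer_))
  ord <- order(-score[2L, ], -score[1L, ], seq_along(sentences))
  best <- ord[1L]
  list(verdict = if (score[2L, best] == length(q_triplets)) "yes" else "no",
       best_id = best)
}

#' Render a list of symbol triplets as notation text
#' @param triplets list of length-3 character vectors.
#' @return character scalar in triplet notation.
#' @export
triplets_to_notation <- function(triplets) {
  paste(vapply(triplets, function(tr) {
    paste0("<", paste(tr, collapse = ","), ">")
  }, character(1)), collapse = " ")
}

# notation for a generated sentence, expanding pointer elements to full-symbol
# bracket form
.sentence_to_notation <- function(sen) {
  expand <- function(i) {
    syms <- character()
    for (k in 1:3) {
      role <- c("subject", "verb", "object")[k]
      tgt <- sen$pointers$target[sen$pointers$triplet == i &
                                   sen$pointers$role == role]
      syms <- c(syms, if (length(tgt) == 1L) expand(tgt)
                else sen$triplets[[i]][k])
    }
    syms
  }
  parts <- vapply(seq_along(sen$triplets), function(i) {
    el <- vapply(1:3, function(k) {
      role <- c("subject", "verb", "object")[k]
      tgt <- sen$pointers$target[sen$pointers$triplet == i &
                                   sen$pointers$role == role]
      if (length(tgt) == 1L)
        paste0("[", paste(expand(tgt), collapse = "+"), "]")
      else sen$triplets[[i]][k]
    }, character(1))
    paste0("<", paste(el, collapse = ","), ">")
  }, character(1))
  paste(parts, collapse = " ")
}

#' Build the lexicon and episodic memory for a generated corpus
#'
#' @param gen output of [generate_corpus()].
#' @param config a `tqa_config`.
#' @return list with `lexicon` and `eltm` (all sentences stored).
#' @export
encode_generated_corpus <- function(gen, config = qa_config()) {
  lex <- build_lexicon(gen$lexicon_specs, N = config$N, a = config$a,
                       seed = config$seed,
                       sim_threshold = config$sim_threshold,
                       lex_threshold = config$lex_threshold)
  eltm <- eltm_state(match_threshold = config$match_threshold)
  for (sen in gen$corpus)
    eltm <- encode_sentence(.sentence_to_notation(sen), eltm, lex,
                            memory_id = sen$id)
  list(lexicon = lex, eltm = eltm)
}

#' Write a corpus as JSON lines
#'
#' One sentence per line: `{"id": ..., "triplets": [[s,v,o], ...],
#' "pointers": [{"triplet": i, "role": r, "target": j}, ...]}`.
#'
#' @param corpus the `corpus` element of [generate_corpus()] output.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- vapply(corpus, function(sen) {
    ptr <- if (nrow(sen$pointers)) sen$pointers else list()
    as.character(jsonlite::toJSON(
      list(id = sen$id, triplets = sen$triplets, pointers = ptr),
      auto_unbox = TRUE, dataframe = "rows"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines corpus
#'
#' @param path corpus file written by [write_corpus()] (or by hand in the
#'   same schema).
#' @return a corpus list (`id`, `triplets`, `pointers` per sentence).
#' @export
read_corpus <- function(path) {
  lapply(readLines(path), function(ln) {
    x <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    ptr <- if (length(x$pointers))
      do.call(rbind, lapply(x$pointers, function(p) {
        data.frame(triplet = p$triplet, role = p$role, target = p$target)
      }))
    else data.frame(triplet = integer(), role = character(),
                    target = integer())
    list(id = x$id,
         triplets = lapply(x$triplets, function(tr) unlist(tr)),
         pointers = ptr)
  })
}

#' Infer lexicon specifications from a corpus
#'
#' Role positions type the vocabulary (subjects as persons, verbs as events,
#' objects as things); `*_WH` symbols become typed placeholders; the `X_syn`
#' twin convention defines synonym groups; hyphenated compositional words
#' contribute their modifier prefixes.
#'
#' @param corpus a corpus list (see [read_corpus()]).
#' @param extra_symbols optional additional symbols (e.g. from questions),
#'   given as length-3 triplet vectors.
#' @return list with `word_specs` (data frame) and `modifiers` (character).
#' @export
infer_lexicon_specs <- function(corpus, extra_symbols = list()) {
  cat_of_pos <- c("person", "event", "thing")
  syms <- list()
  mods <- character()
  note <- function(sym, pos) {
    if (grepl("^\\[", sym)) return()
    parts <- strsplit(sym, "-", fixed = TRUE)[[1]]
    if (length(parts) > 1L) mods <<- union(mods, parts[-length(parts)])
    base <- parts[length(parts)]
    if (base %in% .placeholder_specs$symbol) return()
    if (is.null(syms[[base]])) syms[[base]] <<- cat_of_pos[pos]
  }
  for (sen in corpus)
    for (tr in sen$triplets)
      for (k in 1:3) note(tr[k], k)
  for (tr in extra_symbols)
    for (k in 1:3) note(tr[k], k)
  base_syms <- names(syms)
  grp <- vapply(base_syms, function(s) {
    b <- sub("_syn$", "", s)
    if (endsWith(s, "_syn") || paste0(b, "_syn") %in% base_syms) b
    else NA_character_
  }, character(1))
  specs <- rbind(data.frame(symbol = base_syms,
                            category = unlist(syms, use.names = FALSE),
                            group = unname(grp)),
                 .placeholder_specs)
  list(word_specs = specs, modifiers = mods)
}

#' Write a lexicon specification as JSON
#'
#' The sparse vectors themselves are reproducible from `N`, `a` and the seed,
#' so only the specification is serialized.
#'
#' @param lexicon a `tqa_lexicon`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "tqa_lexicon"))
  words <- lapply(names(lexicon$entries), function(s) {
    list(symbol = s, category = lexicon$categories[[s]],
         group = if (is.na(lexicon$groups[[s]])) NULL
         else lexicon$groups[[s]],
         modifiers = list())
  })
  jsonlite::write_json(list(N = lexicon$N, a = lexicon$a,
                            seed = lexicon$seed,
                            sim_threshold = lexicon$sim_threshold,
                            lex_threshold = lexicon$lex_threshold,
                            words = words,
                            modifiers = as.list(names(lexicon$modifiers))),
                       path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a lexicon specification from JSON
#'
#' Categories are validated against the fixed vocabulary; the word vectors
#' are rebuilt deterministically from the stored seed.
#'
#' @param path file written by [write_lexicon()].
#' @return a `tqa_lexicon`.
#' @export
read_lexicon <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  specs <- do.call(rbind, lapply(x$words, function(w) {
    data.frame(symbol = w$symbol, category = w$category,
               group = if (is.null(w$group)) NA_character_ else w$group)
  }))
  lex <- build_lexicon(specs, N = x$N, a = x$a, seed = x$seed,
                       sim_threshold = x$sim_threshold,
                       lex_threshold = x$lex_threshold)
  for (m in unlist(x$modifiers)) lex <- add_modifier(lex, m)
  lex
}
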