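# Episodic long-term memory: storage geometry, prime-then-excite search,
# finalization, and the retrieval invariants.

fig2_setup <- function(config = tiny_config()) {
  fx <- demo_fixtures()$fig2
  lex <- fixture_lexicon(config)
  eltm <- eltm_state(match_threshold = config$match_threshold)
  for (i in seq_along(fx$corpus))
    eltm <- encode_sentence(fx$corpus[i], eltm, lex,
                            memory_id = paste0("m", i))
  list(fx = fx, lex = lex, eltm = eltm)
}

test_that("the memory network has 7 modules of 3 element subregions", {
  g <- eltm_geometry(eltm_state())
  expect_equal(unname(g["modules"]), 7L)
  expect_equal(unname(g["subregions_per_module"]), 3L)
  expect_equal(unname(g["element_subregions"]), 21L)
})

test_that("storing a sentence fills one module per triplet and links all pairs", {
  env <- fig2_setup()
  # first stored sentence: 4 triplets in modules 1-4
  per_module <- vapply(env$eltm$modules, function(m) {
    sum(vapply(m, function(e) e$sentence_id == "m1", logical(1)))
  }, integer(1))
  expect_equal(per_module, c(1L, 1L, 1L, 1L, 0L, 0L, 0L))
  # 4 triplets -> 12 directed priming links
  first <- env$eltm$links[seq_len(12L), ]
  expect_equal(nrow(first[first$from_module <= 4L, ]), 12L)

  expect_equal(eltm_size(store_sentence(eltm_state(),
                                        parse_notation(""))), 0L)
  lex <- env$lex
  too_long <- sentence_from_triplets(
    replicate(8, realized("<John,eat,cake>", lex)$realized[[1]],
              simplify = FALSE))
  expect_error(store_sentence(eltm_state(), too_long), "capacity")
})

test_that("a triplet shared by two sentences lives independently in both modules", {
  env <- fig2_setup()
  # <John,cook,scallop> is stored in module 2 (sentence 1) and module 1
  # (distractor), <Boris,eat,chocolate> in modules 4 and 3
  holds <- function(m, syms) {
    any(vapply(env$eltm$modules[[m]],
               function(e) identical(e$triplet$symbols, syms), logical(1)))
  }
  expect_true(holds(2L, c("John", "cook", "scallop")))
  expect_true(holds(1L, c("John", "cook", "scallop")))
  expect_true(holds(4L, c("Boris", "eat", "chocolate")))
  expect_true(holds(3L, c("Boris", "eat", "chocolate")))
})

test_that("broadcasts activate, prime, replace when primed, and defer to incumbents", {
  env <- fig2_setup()
  q <- realize_sentence(parse_notation(env$fx$question), env$lex)
  state <- begin_query(env$eltm)
  chunks <- lapply(q$realized, chunk_triplet)

  state <- broadcast_query(state, chunks[[1]], 1L)   # <John,cook,scallop>
  active_mods <- which(vapply(state$status, function(s) any(s == 2L),
                              logical(1)))
  expect_equal(active_mods, c(1L, 2L))
  primed_mods <- which(vapply(state$status, function(s) any(s == 1L),
                              logical(1)))
  expect_true(all(c(3L, 4L) %in% primed_mods))
  expect_true(one_active_per_module(state))

  state <- broadcast_query(state, chunks[[2]], 2L)   # <Boris,eat,chocolate>
  expect_true(any(state$status[[4L]] == 2L))
  expect_true(one_active_per_module(state))

  state <- broadcast_query(state, chunks[[3]], 3L)   # <Rusty,eat,baguette>
  reasons <- vapply(state$trace, function(e) e$reason, character(1))
  expect_true(any(grepl("replaces active attractor", reasons)))
  expect_true(any(grepl("pre-existing attractor wins", reasons)))
  # module 1 now holds the target sentence's triplet
  act1 <- which(state$status[[1L]] == 2L)
  expect_identical(state$modules[[1L]][[act1]]$triplet$symbols,
                   c("Rusty", "eat", "baguette"))
  expect_true(one_active_per_module(state))
  expect_true(verify_priming_safety(state))
})

test_that("finalization retrieves the full stored sentence, including unqueried clauses", {
  env <- fig2_setup()
  ret <- retrieve_memory(env$fx$question, env$eltm, env$lex)
  expect_false(ret$failure)
  expect_identical(lapply(ret$memory$realized, function(tr) tr$symbols),
                   env$fx$expected$memory_symbols)
  expect_identical(ret$state$synapse_mode, "excite")
  # <Ole,bake,pizza> was never broadcast yet is part of the answer
  expect_true(any(vapply(ret$memory$realized, function(tr) {
    identical(tr$symbols, c("Ole", "bake", "pizza"))
  }, logical(1))))
})

test_that("all six broadcast orders retrieve the same memory", {
  env <- fig2_setup()
  q <- realize_sentence(parse_notation(env$fx$question), env$lex)
  for (p in asplit(all_permutations(3L), 1L)) {
    ret <- retrieve_memory(sentence_from_triplets(q$realized[p]),
                           env$eltm, env$lex)
    expect_identical(lapply(ret$memory$realized, function(tr) tr$symbols),
                     env$fx$expected$memory_symbols)
  }
})

test_that("a single stored sentence is retrieved in full from its first triplet", {
  lex <- tiny_lexicon()
  eltm <- encode_sentence("<John,eat,cake> <Boris,drink,tea>",
                          eltm_state(), lex)
  ret <- retrieve_memory("<John,eat,cake>", eltm, lex)
  expect_false(ret$failure)
  expect_equal(sentence_length(ret$memory), 2L)
})

test_that("a question about an unknown episode signals retrieval failure", {
  lex <- tiny_lexicon()
  eltm <- encode_sentence("<John,eat,cake>", eltm_state(), lex)
  ret <- retrieve_memory("<Ole,bake,pizza>", eltm, lex)
  expect_true(ret$failure)
  expect_null(ret$memory)
  expect_error(finalize_retrieval(begin_query(eltm)), "no broadcast")
})

test_that("query state resets between queries and stored weights are untouched", {
  env <- fig2_setup()
  before <- env$eltm$modules
  ret <- retrieve_memory(env$fx$question, env$eltm, env$lex)
  state <- begin_query(ret$state)
  expect_identical(state$synapse_mode, "prime_only")
  expect_true(all(vapply(state$status, function(s) all(s == 0L),
                         logical(1))))
  expect_identical(state$modules, before)
})

test_that("retrieval maximizes shared-triplet count on random corpora (vs oracle)", {
  for (seed in 1:12) {
    spec <- scenario_spec(n_sentences = 3L + seed %% 4L,
                          triplets_per_sentence = 2L + seed %% 4L,
                          seed = seed)
    gen <- generate_corpus(spec)
    env <- encode_generated_corpus(gen, tiny_config())
    plain <- lapply(gen$corpus, function(s) s$triplets)
    for (q in gen$questions[seq_len(min(3L, length(gen$questions)))]) {
      ret <- retrieve_memory(triplets_to_notation(q$triplets), env$eltm,
                             env$lexicon)
      expect_true(one_active_per_module(ret$state))
      expect_true(verify_priming_safety(ret$state))
      if (ret$failure) next
      got <- match(ret$memory$memory_id, vapply(gen$corpus, `[[`, "",
                                                "id"))
      full_count <- function(sen) {
        sum(vapply(q$triplets, function(qt) {
          any(vapply(sen, function(st) {
            sum(mapply(function(x, y) {
              x == y || (x %in% names(gen$groups) && y %in% names(gen$groups)
                         && gen$groups[[x]] == gen$groups[[y]])
            }, qt, st)) == 3L
          }, logical(1)))
        }, logical(1)))
      }
      counts <- vapply(plain, full_count, integer(1))
      expect_gte(counts[got], max(counts))
    }
  }
})

test_that("dechunking a retrieved memory fills answer-buffer slots in module order", {
  env <- fig2_setup()
  ret <- retrieve_memory(env$fx$question, env$eltm, env$lex)
  awm <- dechunk_to_awm(ret$memory)
  expect_equal(occupied_slots(awm), 1:4)
  for (k in 1:4)
    expect_identical(read_slot(awm, k)$triplet$symbols,
                     env$fx$expected$memory_symbols[[k]])
  empty <- dechunk_to_awm(sentence_from_triplets(list()))
  expect_length(occupied_slots(empty), 0L)
})

test_that("a seven-triplet sentence survives the store-retrieve-dechunk round trip", {
  lex <- random_lexicon(30L, N = 500L, seed = 19L)
  set.seed(43)
  trips <- replicate(7, random_triplet(lex), simplify = FALSE)
  sm <- sentence_from_triplets(trips, memory_id = "long")
  eltm <- store_sentence(eltm_state(), sm)
  ret <- retrieve_memory(sentence_from_triplets(trips[c(4, 1)]), eltm, lex)
  awm <- dechunk_to_awm(ret$memory)
  expect_equal(occupied_slots(awm), 1:7)
  for (k in 1:7)
    expect_identical(read_slot(awm, k)$triplet$symbols, trips[[k]]$symbols)
})
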