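test_that("synonym groups overlap above threshold, unrelated words below", {
  specs <- data.frame(symbol = c("man", "guy", "tea", "beer"),
                      category = c("person", "person", "thing", "thing"),
                      group = c("man", "man", NA, NA))
  lex <- build_lexicon(specs, N = 1000L, a = 10L, seed = 5L)
  expect_gte(overlap(lex$entries$man, lex$entries$guy), 0.5)
  expect_equal(overlap(lex$entries$tea, lex$entries$tea), 1.0)
  expect_lt(overlap(lex$entries$tea, lex$entries$beer), 0.5)
})

test_that("random cross-talk between 50 unrelated words stays below the lexicality threshold", {
  lex <- random_lexicon(50L, N = 1000L, a = 10L, seed = 7L)
  syms <- names(lex$entries)
  worst <- 0
  for (i in seq_along(syms)[-1]) {
    for (j in seq_len(i - 1L)) {
      worst <- max(worst, overlap(lex$entries[[i]], lex$entries[[j]]))
    }
  }
  expect_lt(worst, lex$lex_threshold)
})

test_that("lexicon construction rejects bad specifications and is reproducible", {
  expect_error(build_lexicon(c("dup", "dup")), "duplicate")
  expect_error(build_lexicon("w", N = 10L, a = 10L), "smaller than")
  expect_error(build_lexicon(data.frame(symbol = "x", category = "verbish",
                                        group = NA)), "category")
  a <- random_lexicon(5L, seed = 9L)
  b <- random_lexicon(5L, seed = 9L)
  expect_identical(a$entries, b$entries)
})

test_that("modifiers remap rates without touching the active set", {
  lex <- tiny_lexicon()
  base <- lex$entries$meal
  nice <- compose_modifier(base, "nice", lex)
  expect_setequal(active_set(nice), active_set(base))
  expect_false(isTRUE(all.equal(nice, base)))

  lex <- add_modifier(lex, "plain", scaling = rep(1, lex$N))
  expect_equal(compose_modifier(base, "plain", lex), base)

  lex <- add_modifier(lex, "huge")
  huge <- compose_modifier(base, "huge", lex)
  expect_setequal(active_set(huge), active_set(nice))
  expect_true(any(huge[active_set(huge)] != nice[active_set(nice)]))

  expect_error(compose_modifier(base, "unregistered", lex), "unknown modifier")
})

test_that("a pointer is the superposition of its triplet and is non-lexical", {
  lex <- tiny_lexicon()
  sm <- realized("<John,hit,Boris>", lex)
  tr <- sm$realized[[1]]
  p <- make_pointer(tr)
  expect_setequal(active_set(p$values),
                  Reduce(union, lapply(c("John", "hit", "Boris"),
                                       function(s) active_set(lex$entries[[s]]))))
  res <- is_lexical(p$values, lex)
  expect_false(res$lexical)
  # a contained word still scores 1 under the min-normalized similarity
  expect_equal(overlap(lex$entries$John, p$values), 1.0)
})

test_that("a nested pointer is closest to its own target's superposition", {
  lex <- tiny_lexicon()
  sm <- nested_sentence(lex)
  outer <- sm$realized[[1]]$subject       # [N+s+J+h+B]
  sup2 <- superpose_triplet(sm$realized[[2]])
  sup3 <- superpose_triplet(sm$realized[[3]])
  s2 <- c(overlap(outer$values, sup2), jaccard_overlap(outer$values, sup2))
  s3 <- c(overlap(outer$values, sup3), jaccard_overlap(outer$values, sup3))
  # lexicographic (overlap, jaccard): the true target wins
  expect_true(s2[1] > s3[1] || (s2[1] == s3[1] && s2[2] > s3[2]))
})

test_that("pointers are non-lexical for at least 99% of random triplets", {
  lex <- random_lexicon(60L, N = 500L, a = 10L, seed = 13L)
  set.seed(17)
  n_lex <- 0L
  for (i in 1:100) {
    tr <- random_triplet(lex)
    if (is_lexical(make_pointer(tr)$values, lex)$lexical) n_lex <- n_lex + 1L
  }
  expect_lte(n_lex, 1L)
})

test_that("lexicality recognizes words and compositional words", {
  lex <- tiny_lexicon()
  expect_true(is_lexical(lex$entries$tea, lex)$lexical)
  expect_identical(is_lexical(lex$entries$tea, lex)$symbol, "tea")
  cw <- word_element("nice-meal", lex)
  r <- is_lexical(cw$values, lex)
  expect_true(r$lexical)
  expect_identical(r$symbol, "meal")
  empty <- structure(list(N = 10L, entries = list(), lex_threshold = 0.5),
                     class = "tqa_lexicon")
  expect_error(is_lexical(rep(1, 10), empty), "empty lexicon")
})

test_that("chunking concatenates role segments and dechunking inverts it", {
  lex <- tiny_lexicon()
  sm <- realized("<John,eat,cake>", lex)
  v <- chunk_triplet(sm$realized[[1]])
  expect_length(v, 3L * lex$N)
  expect_equal(v[seq_len(lex$N)], lex$entries$John)
  expect_equal(v[lex$N + seq_len(lex$N)], lex$entries$eat)
  expect_equal(v[2L * lex$N + seq_len(lex$N)], lex$entries$cake)

  zero <- triplet(element(numeric(9), "z"), element(numeric(9), "z"),
                  element(numeric(9), "z"))
  expect_equal(chunk_triplet(zero), numeric(27))
  expect_error(dechunk_triplet(numeric(10)), "divisible by 3")
})

test_that("dechunk after chunk is the identity on random triplets", {
  set.seed(23)
  for (i in 1:100) {
    N <- sample(5:40, 1L)
    els <- replicate(3, {
      v <- numeric(N)
      v[sample.int(N, 3L)] <- runif(3, 0.1, 2)
      v
    }, simplify = FALSE)
    tr <- triplet(element(els[[1]], "a"), element(els[[2]], "b"),
                  element(els[[3]], "c"))
    back <- dechunk_triplet(chunk_triplet(tr))
    expect_identical(back$subject, els[[1]])
    expect_identical(back$verb, els[[2]])
    expect_identical(back$object, els[[3]])
  }
})

test_that("overlap is symmetric and reflexive", {
  set.seed(31)
  for (i in 1:25) {
    u <- numeric(50); u[sample.int(50, 6)] <- runif(6)
    v <- numeric(50); v[sample.int(50, 6)] <- runif(6)
    expect_equal(overlap(u, v), overlap(v, u))
    expect_equal(jaccard_overlap(u, v), jaccard_overlap(v, u))
    expect_equal(overlap(u, u), 1.0)
  }
  expect_equal(overlap(numeric(10), numeric(10)), 0)
})
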