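# Second dechunking and the element-wise comparator (Y/N, WH, unpacking).

test_that("each occupied slot expands to three role-ordered items at 3x gamma", {
  lex <- tiny_lexicon()
  buf <- load_sequence(theta_gamma_state(gamma_freq = 30),
                       realized("<John,eat,cake> <Boris,drink,tea>", lex))
  st <- dechunk_elements(buf)
  expect_length(st$items, 6L)
  expect_equal(st$fast_freq, 90)
  expect_equal(vapply(st$items, `[[`, "", "role"),
               rep(c("subject", "verb", "object"), 2L))
  # regrouping the stream by slot reproduces the chunked buffer exactly
  for (k in occupied_slots(buf)) {
    vals <- unlist(lapply(Filter(function(it) it$slot == k, st$items),
                          `[[`, "values"))
    expect_equal(vals, read_slot(buf, k)$chunk, ignore_attr = TRUE)
  }
})

test_that("identical aligned streams compare as yes", {
  lex <- tiny_lexicon()
  sm <- realized("<John,eat,cake> <Boris,drink,tea>", lex)
  buf <- load_sequence(theta_gamma_state(), sm)
  st <- dechunk_elements(buf)
  ans <- compare_yn(st, st)
  expect_identical(ans$verdict, "yes")
  expect_true(all(ans$trace$residuals$cancelled))
})

test_that("changing any single element to a non-synonym flips the verdict to no", {
  lex <- tiny_lexicon()
  mem <- realized("<John,eat,cake>", lex)
  a <- dechunk_elements(load_sequence(theta_gamma_state(), mem))
  variants <- c("<Boris,eat,cake>", "<John,drink,cake>", "<John,eat,tea>")
  for (v in variants) {
    q <- dechunk_elements(load_sequence(theta_gamma_state(),
                                        realized(v, lex)))
    ans <- compare_yn(q, a)
    expect_identical(ans$verdict, "no")
    expect_equal(sum(!ans$trace$residuals$cancelled), 1L)
    expect_identical(ans$trace$mismatch_triplet,
                     c(subject = "John", verb = "eat", object = "cake"))
  }
})

test_that("synonyms cancel in the subtraction", {
  lex <- tiny_lexicon()
  a <- dechunk_elements(load_sequence(theta_gamma_state(),
                                      realized("<guy,drink,tea>", lex)))
  q <- dechunk_elements(load_sequence(theta_gamma_state(),
                                      realized("<man,drink,tea>", lex)))
  expect_identical(compare_yn(q, a)$verdict, "yes")
})

test_that("a question triplet with no synchronized answer triplet means no", {
  lex <- tiny_lexicon()
  a <- dechunk_elements(load_sequence(theta_gamma_state(),
                                      realized("<John,eat,cake>", lex)))
  q <- dechunk_elements(load_sequence(
    theta_gamma_state(),
    realized("<John,eat,cake> <Boris,drink,tea>", lex)))
  ans <- compare_yn(q, a)
  expect_identical(ans$verdict, "no")
  expect_equal(ans$trace$unsynchronized_q_slots, 2L)
})

test_that("zero co-filled slots signals skipped alignment", {
  lex <- tiny_lexicon()
  a <- load_sequence(theta_gamma_state(), realized("<John,eat,cake>", lex))
  q <- theta_gamma_state()
  q$slots[[3L]] <- list(chunk = chunk_triplet(realized("<Boris,drink,tea>",
                                                       lex)$realized[[1]]),
                        triplet = realized("<Boris,drink,tea>",
                                           lex)$realized[[1]])
  expect_error(compare_yn(dechunk_elements(q), dechunk_elements(a)),
               class = "tqa_unaligned_error")
})

test_that("a WH placeholder is filled by the aligned lexical element", {
  lex <- tiny_lexicon()
  awm <- load_sequence(theta_gamma_state(),
                       realized("<John,eat,cake> <Boris,drink,tea>", lex))
  qwm <- load_sequence(theta_gamma_state(),
                       realized("<John,eat,cake> <Boris,drink,something_WH>",
                                lex))
  ans <- compare_wh(dechunk_elements(qwm), dechunk_elements(awm), lex,
                    awm = awm)
  expect_identical(ans$verdict, "value")
  expect_identical(ans$payload, "tea")
})

test_that("placeholder type gates the answer: pointers only fit event placeholders", {
  lex <- tiny_lexicon()
  awm <- load_sequence(theta_gamma_state(), nested_sentence(lex))
  # where-type placeholder aligned with a pointer candidate: not answerable
  qwm <- load_sequence(theta_gamma_state(),
                       realized("<place_WH,bother,Marco>", lex))
  qwm <- align_slots_abstract(qwm, awm)
  ans <- compare_wh(dechunk_elements(qwm), dechunk_elements(awm), lex,
                    awm = awm)
  expect_identical(ans$verdict, "not_answerable")
  # person placeholder against a thing candidate: not answerable
  awm2 <- load_sequence(theta_gamma_state(),
                        realized("<Boris,drink,tea>", lex))
  qwm2 <- load_sequence(theta_gamma_state(),
                        realized("<Boris,drink,person_WH>", lex))
  ans2 <- compare_wh(dechunk_elements(qwm2), dechunk_elements(awm2), lex,
                     awm = awm2)
  expect_identical(ans2$verdict, "not_answerable")
})

test_that("a placeholder aligned with an empty answer position is not answerable", {
  lex <- tiny_lexicon()
  awm <- load_sequence(theta_gamma_state(),
                       realized("<John,eat,cake>", lex))
  qwm <- load_sequence(theta_gamma_state(),
                       realized("<John,eat,cake> <Boris,drink,something_WH>",
                                lex))
  ans <- compare_wh(dechunk_elements(qwm), dechunk_elements(awm), lex,
                    awm = awm)
  expect_identical(ans$verdict, "not_answerable")
})

test_that("WH mode rejects zero or multiple placeholders", {
  lex <- tiny_lexicon()
  buf <- load_sequence(theta_gamma_state(), realized("<John,eat,cake>", lex))
  st <- dechunk_elements(buf)
  expect_error(compare_wh(st, st, lex), "no WH placeholder")
  two <- load_sequence(theta_gamma_state(),
                       realized("<person_WH,eat,something_WH>", lex))
  expect_error(compare_wh(dechunk_elements(two), st, lex),
               "multiple WH placeholders")
})

test_that("pointer unpacking follows the chain to fully lexical symbols", {
  lex <- tiny_lexicon()
  sm <- nested_sentence(lex)
  awm <- load_sequence(theta_gamma_state(), sm)
  up <- unpack_pointer(sm$realized[[1]]$subject, awm, lex, host_slot = 1L)
  expect_identical(up$symbols, c("Natasha", "see", "John", "hit", "Boris"))
  expect_equal(up$chain, c(2L, 3L))
  # chain length bounded by the number of slots (termination)
  expect_lte(length(up$chain), length(occupied_slots(awm)))
  # single-step unpack of a pointer to a pointer-free triplet
  inner <- sm$realized[[2]]$object
  up2 <- unpack_pointer(inner, awm, lex, host_slot = 2L)
  expect_identical(up2$symbols, c("John", "hit", "Boris"))
  expect_equal(up2$chain, 3L)
})

test_that("unpacking selects the brute-force best superposition match", {
  lex <- tiny_lexicon()
  sm <- nested_sentence(lex)
  awm <- load_sequence(theta_gamma_state(), sm)
  for (host in 1:2) {
    cand <- if (host == 1L) sm$realized[[1]]$subject else
      sm$realized[[2]]$object
    later <- occupied_slots(awm)
    later <- later[later > host]
    scores <- t(vapply(later, function(s) {
      sup <- superpose_triplet(read_slot(awm, s)$triplet)
      c(overlap(cand$values, sup), jaccard_overlap(cand$values, sup))
    }, numeric(2)))
    best <- later[order(-scores[, 1], -scores[, 2], later)][1]
    up <- unpack_pointer(cand, awm, lex, host_slot = host)
    expect_equal(up$chain[1], best)
  }
})

test_that("unpacking fails cleanly when nothing matches the pointer", {
  lex <- tiny_lexicon()
  sm <- realized("<John,eat,cake> <Boris,drink,tea>", lex)
  awm <- load_sequence(theta_gamma_state(), sm)
  stray <- make_pointer(realized("<Ole,bake,pizza>", lex)$realized[[1]])
  expect_null(unpack_pointer(stray, awm, lex, host_slot = 0L))
})
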