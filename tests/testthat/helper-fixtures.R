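# shared fixtures built in code

tiny_config <- function(seed = 11L) qa_config(N = 400L, a = 10L, seed = seed)

tiny_lexicon <- function(seed = 11L) fixture_lexicon(tiny_config(seed))

# lexicon of n unrelated words for representation-level properties
random_lexicon <- function(n, N = 1000L, a = 10L, seed = 3L) {
  build_lexicon(sprintf("w%03d", seq_len(n)), N = N, a = a, seed = seed)
}

# realized sentence from notation against a lexicon
realized <- function(text, lexicon) {
  realize_sentence(parse_notation(text), lexicon)
}

# random realized triplet of distinct words from a lexicon
random_triplet <- function(lexicon) {
  syms <- sample(names(lexicon$entries), 3L)
  triplet(word_element(syms[1], lexicon), word_element(syms[2], lexicon),
          word_element(syms[3], lexicon))
}

# all permutations of 1..n as rows of a matrix (for brute-force oracles)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# the nested-pointer sentence used across comparator tests
nested_sentence <- function(lexicon) {
  realized(paste("<[N+s+J+h+B],bother,Marco> <Natasha,see,[J+h+B]>",
                 "<John,hit,Boris>"), lexicon)
}
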