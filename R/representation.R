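# Sparse distributed word/triplet representation: lexicon construction,
# compositional (rate-remapping) coding, pointer algebra, chunking.

#' Active set of a rate vector
#'
#' Indices of the units with strictly positive rate. The active set carries
#' lexical identity; the rates on those units carry modifiers.
#'
#' @param v numeric rate vector.
#' @return integer vector of active unit indices.
#' @export
active_set <- function(v) which(v > 0)

#' Assembly overlap between two rate vectors
#'
#' Similarity of two neural assemblies, measured on their active sets and
#' normalized by the smaller assembly, so that a superposition pointer fully
#' contains each of its constituent words (overlap 1 with each).
#'
#' @param u,v numeric rate vectors of equal length.
#' @return overlap in `[0, 1]`; 0 if either vector is silent.
#' @export
overlap <- function(u, v) {
  au <- active_set(u)
  av <- active_set(v)
  if (length(au) == 0L || length(av) == 0L) return(0)
  length(intersect(au, av)) / min(length(au), length(av))
}

#' Jaccard overlap of two active sets
#'
#' Used as a deterministic tie-break where min-normalized [overlap()] saturates
#' (containment scores 1 regardless of the containing assembly's size).
#'
#' @inheritParams overlap
#' @return Jaccard index in `[0, 1]`.
#' @export
jaccard_overlap <- function(u, v) {
  au <- active_set(u)
  av <- active_set(v)
  if (length(au) == 0L || length(av) == 0L) return(0)
  length(intersect(au, av)) / length(union(au, av))
}

# fixed category vocabulary; wh_* categories mark WH placeholders
.tqa_categories <- c("person", "thing", "place", "time", "manner", "event",
                     "wh_something", "wh_person", "wh_place", "wh_time",
                     "wh_manner")

#' Word categories recognized by the lexicon
#' @return character vector of valid category labels.
#' @export
lexicon_categories <- function() .tqa_categories

# deterministic per-symbol stream offset (polynomial rolling hash) so vectors
# depend only on the symbol and the lexicon seed, not on listing order
.symbol_offset <- function(symbol) {
  h <- 0
  for (c in utf8ToInt(symbol)) h <- (h * 131 + c) %% 1000003
  h
}

#' Build a sparse random lexicon
#'
#' Each word symbol is assigned a sparse binary base word vector of `a` active
#' units out of `N`. Members of a synonym group share a fixed fraction of their
#' active units, so within-group overlap exceeds the similarity threshold while
#' unrelated words overlap only by chance (about `a/N` per unit). This is a
#' deterministic stand-in for semantic memory: similarity of two concepts is
#' the overlap between their assemblies.
#'
#' @param word_specs data frame with columns `symbol`, `category`, and
#'   optionally `group` (NA for ungrouped words). A bare character vector is
#'   accepted and treated as ungrouped "thing" words.
#' @param N network size (units per element subregion).
#' @param a number of active units per word (sparsity), `a < N`.
#' @param seed integer seed; the lexicon is reproducible given the seed.
#' @param sim_threshold similarity threshold used for synonymy and element
#'   cancellation in the comparator.
#' @param lex_threshold lexicality threshold used by [is_lexical()].
#' @param synonym_shared_frac fraction of active units members of a synonym
#'   group share with the group prototype (must be >= `sim_threshold`).
#' @return an object of class `tqa_lexicon`.
#' @export
build_lexicon <- function(word_specs, N = 1000L, a = 10L, seed = 1L,
                          sim_threshold = 0.5, lex_threshold = 0.5,
                          synonym_shared_frac = 0.6) {
  if (is.character(word_specs)) {
    word_specs <- data.frame(symbol = word_specs, category = "thing",
                             group = NA_character_)
  }
  stopifnot(is.data.frame(word_specs), all(c("symbol", "category") %in%
                                             names(word_specs)))
  if (!"group" %in% names(word_specs)) word_specs$group <- NA_character_
  if (anyDuplicated(word_specs$symbol))
    stop("duplicate word symbol in lexicon specification")
  if (a >= N) stop("sparsity 'a' must be smaller than network size 'N'")
  bad <- setdiff(unique(word_specs$category), .tqa_categories)
  if (length(bad))
    stop("unknown word category: ", paste(bad, collapse = ", "))
  if (synonym_shared_frac < sim_threshold)
    stop("synonym_shared_frac below sim_threshold would break synonymy")

  lex <- structure(list(N = as.integer(N), a = as.integer(a),
                        seed = as.integer(seed),
                        sim_threshold = sim_threshold,
                        lex_threshold = lex_threshold,
                        entries = list(), categories = list(),
                        groups = character(), modifiers = list()),
                   class = "tqa_lexicon")

  n_shared <- ceiling(synonym_shared_frac * a)
  groups <- unique(stats::na.omit(word_specs$group))
  protos <- list()
  for (g in groups) {
    protos[[g]] <- .with_seed(seed + .symbol_offset(paste0("group:", g)),
                              sample.int(N, a))
  }
  for (i in seq_len(nrow(word_specs))) {
    sym <- word_specs$symbol[i]
    grp <- word_specs$group[i]
    idx <- .with_seed(seed + .symbol_offset(sym), {
      if (!is.na(grp)) {
        shared <- sort(protos[[grp]])[seq_len(n_shared)]
        own <- sample(setdiff(seq_len(N), protos[[grp]]), a - n_shared)
        c(shared, own)
      } else {
        sample.int(N, a)
      }
    })
    v <- numeric(N)
    v[idx] <- 1
    lex$entries[[sym]] <- v
    lex$categories[[sym]] <- word_specs$category[i]
    lex$groups[sym] <- if (is.na(grp)) NA_character_ else grp
  }
  lex
}

# evaluate expr under a temporary RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

#' @export
print.tqa_lexicon <- function(x, ...) {
  cat("tripletQA lexicon:", length(x$entries), "words, N =", x$N,
      ", a =", x$a, "\n")
  cat("  modifiers:", if (length(x$modifiers))
    paste(names(x$modifiers), collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Register a modifier (adjective/adverb) transform
#'
#' Modifiers are diagonal positive rate scalings: they change the relative
#' rates of a word vector but can never change which units are active, which
#' is what makes compositional words keep their lexical identity.
#'
#' @param lexicon a `tqa_lexicon`.
#' @param symbol modifier symbol, e.g. `"nice"`.
#' @param scaling optional explicit positive scaling vector of length `N`;
#'   drawn reproducibly from the lexicon seed when omitted.
#' @return the updated lexicon.
#' @export
add_modifier <- function(lexicon, symbol, scaling = NULL) {
  stopifnot(inherits(lexicon, "tqa_lexicon"))
  if (is.null(scaling)) {
    scaling <- .with_seed(lexicon$seed + .symbol_offset(paste0("mod:", symbol)),
                          stats::runif(lexicon$N, min = 0.25, max = 2.5))
  }
  stopifnot(length(scaling) == lexicon$N, all(scaling > 0))
  lexicon$modifiers[[symbol]] <- scaling
  lexicon
}

#' Apply a modifier to a base word vector
#'
#' Rate-remapping composition: the returned vector has exactly the base word's
#' active set but altered rates, modeling compositional words such as
#' `nice-meal` without spending an extra triplet on the adjective.
#'
#' @param base numeric rate vector of a lexical word.
#' @param modifier modifier symbol registered in the lexicon.
#' @param lexicon a `tqa_lexicon`.
#' @return the modified rate vector.
#' @export
compose_modifier <- function(base, modifier, lexicon) {
  stopifnot(inherits(lexicon, "tqa_lexicon"))
  sc <- lexicon$modifiers[[modifier]]
  if (is.null(sc))
    stop("unknown modifier '", modifier,
         "': parser output does not match the lexicon")
  base * sc
}

#' Triplet element
#'
#' An element of a triplet slot: either a (possibly modified) lexical word
#' vector or a superposition pointer standing in for an embedded triplet.
#'
#' @param values numeric rate vector of length `N`.
#' @param symbol surface symbol, for tracing and rendering.
#' @param kind `"word"` or `"pointer"`.
#' @param target_hint for pointers, index of the pointed triplet within its
#'   sentence. Tracing only; retrieval and comparison never consult it.
#' @return an object of class `tqa_element`.
#' @export
element <- function(values, symbol, kind = c("word", "pointer"),
                    target_hint = NA_integer_) {
  kind <- match.arg(kind)
  structure(list(values = values, symbol = symbol, kind = kind,
                 target_hint = as.integer(target_hint)),
            class = "tqa_element")
}

#' Build a triplet from three elements
#'
#' @param subject,verb,object `tqa_element` objects.
#' @return an object of class `tqa_triplet` with fixed role order.
#' @export
triplet <- function(subject, verb, object) {
  stopifnot(inherits(subject, "tqa_element"), inherits(verb, "tqa_element"),
            inherits(object, "tqa_element"))
  structure(list(subject = subject, verb = verb, object = object,
                 symbols = c(subject$symbol, verb$symbol, object$symbol)),
            class = "tqa_triplet")
}

#' @export
print.tqa_triplet <- function(x, ...) {
  cat("<", paste(x$symbols, collapse = ","), ">\n", sep = "")
  invisible(x)
}

triplet_roles <- c("subject", "verb", "object")

#' Superposition pointer to a triplet
#'
#' A pointer is the element-wise sum of the pointed triplet's three element
#' vectors: its active set is the union of the three active sets, a compact
#' representation that resembles no single lexical word and is therefore
#' recognizable as a pointer by [is_lexical()].
#'
#' @param t a `tqa_triplet` (its elements may themselves be pointers).
#' @param target_hint optional index of the pointed triplet, tracing only.
#' @param symbol optional display symbol; defaults to `[s+v+o]` built from the
#'   triplet's surface symbols.
#' @return a pointer `tqa_element`.
#' @export
make_pointer <- function(t, target_hint = NA_integer_, symbol = NULL) {
  stopifnot(inherits(t, "tqa_triplet"))
  values <- t$subject$values + t$verb$values + t$object$values
  if (is.null(symbol))
    symbol <- paste0("[", paste(t$symbols, collapse = "+"), "]")
  element(values, symbol, kind = "pointer", target_hint = target_hint)
}

#' Superposition of a triplet's elements
#'
#' The pattern a pointer to this triplet would carry; used when ranking
#' candidate triplets during pointer unpacking.
#'
#' @param t a `tqa_triplet`.
#' @return numeric rate vector of length `N`.
#' @export
superpose_triplet <- function(t) {
  t$subject$values + t$verb$values + t$object$values
}

#' Is a rate vector a known lexical word?
#'
#' Scores the probe against every base word vector by the fraction of the
#' probe's active units covered by the entry. A word (however modified) covers
#' itself fully; a pointer spreads over the union of three words, so no single
#' entry covers more than about a third of it and the probe is flagged
#' non-lexical -- this is how pointers are recognized.
#'
#' @param v numeric rate vector of length `N`.
#' @param lexicon a `tqa_lexicon`.
#' @return list with `lexical` (logical), `symbol` (best-matching entry) and
#'   `score`.
#' @export
is_lexical <- function(v, lexicon) {
  stopifnot(inherits(lexicon, "tqa_lexicon"))
  if (length(lexicon$entries) == 0L) stop("empty lexicon")
  av <- active_set(v)
  if (length(av) == 0L)
    return(list(lexical = FALSE, symbol = NA_character_, score = 0))
  scores <- vapply(lexicon$entries, function(w) {
    length(intersect(av, active_set(w))) / length(av)
  }, numeric(1))
  best <- which.max(scores)
  list(lexical = unname(scores[best]) >= lexicon$lex_threshold,
       symbol = names(scores)[best], score = unname(scores[best]))
}

#' Chunk a triplet into a single spatial pattern
#'
#' First chunking: the three element vectors are concatenated into one length
#' `3N` pattern, with segment k holding role k (subject, verb, object).
#'
#' @param t a `tqa_triplet`.
#' @return numeric vector of length `3N`.
#' @export
chunk_triplet <- function(t) {
  stopifnot(inherits(t, "tqa_triplet"))
  c(t$subject$values, t$verb$values, t$object$values)
}

#' Split a chunked triplet pattern back into its three element vectors
#'
#' Exact inverse of [chunk_triplet()] at the vector level; element-by-element
#' comparison downstream requires this separation.
#'
#' @param v numeric vector whose length is divisible by 3.
#' @return named list of three length-`N` vectors (subject, verb, object).
#' @export
dechunk_triplet <- function(v) {
  if (length(v) %% 3L != 0L)
    stop("chunked triplet length must be divisible by 3")
  N <- length(v) %/% 3L
  list(subject = v[seq_len(N)],
       verb = v[N + seq_len(N)],
       object = v[2L * N + seq_len(N)])
}

#' Look up a word's category
#' @param symbol word symbol.
#' @param lexicon a `tqa_lexicon`.
#' @return category label, or `NA` if unknown.
#' @export
word_category <- function(symbol, lexicon) {
  cat <- lexicon$categories[[symbol]]
  if (is.null(cat)) NA_character_ else cat
}

#' Is a symbol a WH placeholder?
#' @inheritParams word_category
#' @return logical.
#' @export
is_placeholder_symbol <- function(symbol, lexicon) {
  cat <- word_category(symbol, lexicon)
  !is.na(cat) && startsWith(cat, "wh_")
}

#' Realize a surface symbol as a triplet element
#'
#' Resolves compositional words: in `very-nice-meal` the final component is
#' the base word and the preceding components are modifiers applied as rate
#' scalings.
#'
#' @param symbol surface symbol (word or hyphenated cWORD; not a pointer).
#' @param lexicon a `tqa_lexicon`; unknown modifiers are an error.
#' @return a word `tqa_element`.
#' @export
word_element <- function(symbol, lexicon) {
  parts <- strsplit(symbol, "-", fixed = TRUE)[[1]]
  base_sym <- parts[length(parts)]
  base <- lexicon$entries[[base_sym]]
  if (is.null(base))
    stop("unknown word '", base_sym, "' in lexicon")
  v <- base
  for (m in rev(parts[-length(parts)]))
    v <- compose_modifier(v, m, lexicon)
  element(v, symbol, kind = "word")
}
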