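# Canonical triplet notation: "<subj,verb,obj>" per clause, cWORDs hyphenated
# ("nice-meal"), embedded clauses as superposition pointers "[J+h+B]" (initials
# or full symbols), WH placeholders as "*_WH" symbols.

#' Parse canonical triplet notation into a sentence structure
#'
#' A sentence is a whitespace-separated sequence of `<a,b,c>` triplets. A
#' pointer element `[x+y+z]` refers to the later triplet whose (recursively
#' expanded) element symbols match the pointer's components, either by initial
#' letters (`[J+h+B]`) or by full symbols (`[John+hit+Boris]`); the parser is
#' assumed to emit pointers always before (to the left of) the triplet they
#' point to. Empty-slot markers (`<...>`) are ignored.
#'
#' @param text character scalar in triplet notation.
#' @param memory_id optional identifier carried by the resulting sentence.
#' @return an object of class `tqa_sentence` (symbolic; see
#'   [realize_sentence()] for the vector-level form).
#' @export
parse_notation <- function(text, memory_id = NA) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- regmatches(text, gregexpr("<[^<>]*>", text))[[1]]
  rest <- gsub("<[^<>]*>", " ", text)
  if (grepl("[^[:space:]]", rest))
    stop("malformed triplet notation near: ", trimws(rest))
  # drop empty-slot markers
  toks <- toks[!grepl("^<\\s*(…|\\.{3})?\\s*>$", toks)]
  if (length(toks) == 0L)
    return(.new_sentence(list(), memory_id))
  if (length(toks) > 7L)
    stop("a sentence may hold at most 7 triplets (", length(toks),
         " given): working-memory capacity exceeded")
  triplets <- lapply(toks, function(tok) {
    inner <- substr(tok, 2L, nchar(tok) - 1L)
    elems <- trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
    if (length(elems) != 3L || any(!nzchar(elems)))
      stop("malformed triplet (need exactly 3 elements): ", tok)
    ptr <- lapply(elems, function(e) {
      if (grepl("^\\[.*\\]$", e))
        trimws(strsplit(substr(e, 2L, nchar(e) - 1L), "+", fixed = TRUE)[[1]])
      else NULL
    })
    names(ptr) <- triplet_roles
    list(raw = elems, symbols = elems, pointer_tokens = ptr)
  })
  sm <- .new_sentence(triplets, memory_id)
  .resolve_pointers(sm)
}

.new_sentence <- function(triplets, memory_id) {
  structure(list(triplets = triplets,
                 links = data.frame(from = integer(), role = character(),
                                    to = integer()),
                 memory_id = memory_id,
                 realized = NULL),
            class = "tqa_sentence")
}

# token matches a word symbol if equal (case-insensitive) or a proper initial
# prefix of it
.token_matches <- function(token, word) {
  tl <- tolower(token); wl <- tolower(word)
  tl == wl || (nchar(tl) < nchar(wl) && startsWith(wl, tl))
}

# flattened word-symbol expansion of triplet i, following resolved pointers
.expansion <- function(sm, i) {
  tr <- sm$triplets[[i]]
  out <- character()
  for (r in triplet_roles) {
    link <- sm$links[sm$links$from == i & sm$links$role == r, "to"]
    if (length(link) == 1L) {
      out <- c(out, .expansion(sm, link))
    } else {
      out <- c(out, tr$symbols[[match(r, triplet_roles)]])
    }
  }
  out
}

# resolve pointer targets right-to-left so inner pointers resolve first
.resolve_pointers <- function(sm) {
  n <- length(sm$triplets)
  for (i in rev(seq_len(n))) {
    for (r in triplet_roles) {
      toks <- sm$triplets[[i]]$pointer_tokens[[r]]
      if (is.null(toks)) next
      target <- NA_integer_
      for (j in seq_len(n)[-seq_len(i)]) {
        exp_j <- .expansion(sm, j)
        if (length(exp_j) == length(toks) &&
            all(mapply(.token_matches, toks, exp_j))) {
          target <- j
          break
        }
      }
      if (is.na(target))
        stop("pointer ", sm$triplets[[i]]$raw[[match(r, triplet_roles)]],
             " has no matching later triplet (pointers must precede their",
             " targets)")
      sm$links <- rbind(sm$links,
                        data.frame(from = i, role = r, to = target))
    }
  }
  sm
}

#' Number of triplets in a sentence
#' @param sm a `tqa_sentence`.
#' @return integer count.
#' @export
sentence_length <- function(sm) length(sm$triplets)

#' Render a sentence structure back to triplet notation
#'
#' Inverse of [parse_notation()] up to whitespace: original element spellings
#' (including pointer bracket tokens) are preserved.
#'
#' @param sm a `tqa_sentence`.
#' @return character scalar.
#' @export
format_notation <- function(sm) {
  stopifnot(inherits(sm, "tqa_sentence"))
  paste(vapply(sm$triplets, function(tr) {
    paste0("<", paste(tr$raw, collapse = ","), ">")
  }, character(1)), collapse = " ")
}

#' @export
print.tqa_sentence <- function(x, ...) {
  cat(if (length(x$triplets)) format_notation(x) else "(empty sentence)", "\n")
  invisible(x)
}

#' Realize a symbolic sentence as word vectors
#'
#' Looks every element up in the lexicon (applying modifier scalings for
#' compositional words) and builds pointer elements as the superposition of
#' their target triplet's element vectors. Targets are realized first, so
#' nested pointers compose correctly; a pointer's target always lies at a
#' strictly later index, which guarantees termination.
#'
#' @param sm a `tqa_sentence` from [parse_notation()].
#' @param lexicon a `tqa_lexicon` covering the sentence's vocabulary.
#' @return the sentence with a `realized` field: a list of `tqa_triplet`.
#' @export
realize_sentence <- function(sm, lexicon) {
  stopifnot(inherits(sm, "tqa_sentence"), inherits(lexicon, "tqa_lexicon"))
  n <- length(sm$triplets)
  realized <- vector("list", n)
  for (i in rev(seq_len(n))) {
    tr <- sm$triplets[[i]]
    els <- lapply(seq_along(triplet_roles), function(k) {
      r <- triplet_roles[k]
      link <- sm$links[sm$links$from == i & sm$links$role == r, "to"]
      if (length(link) == 1L) {
        if (link <= i) stop("pointer target must follow the pointer")
        make_pointer(realized[[link]], target_hint = link,
                     symbol = tr$raw[[k]])
      } else {
        word_element(tr$symbols[[k]], lexicon)
      }
    })
    realized[[i]] <- triplet(els[[1]], els[[2]], els[[3]])
  }
  sm$realized <- realized
  sm
}

#' Build a sentence directly from realized triplets
#'
#' Used by long-term-memory retrieval, which returns stored triplets in module
#' order.
#'
#' @param triplets list of `tqa_triplet`.
#' @param memory_id identifier of the stored sentence.
#' @return a realized `tqa_sentence`.
#' @export
sentence_from_triplets <- function(triplets, memory_id = NA) {
  sm <- .new_sentence(lapply(triplets, function(tr) {
    list(raw = tr$symbols, symbols = tr$symbols,
         pointer_tokens = stats::setNames(vector("list", 3L), triplet_roles))
  }), memory_id)
  sm$realized <- triplets
  sm
}
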