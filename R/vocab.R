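#' IUPAC term vocabularies
#'
#' Systematic IUPAC names are concatenations of *terms*: short strings of
#' letters, digits and punctuation that denote functional groups, locants and
#' connections. A `term_vocabulary` holds the ordered term list, a flag marking
#' the subset of terms that count as *attributes* (moiety-denoting terms,
#' predicted by the first-stage network), and two reserved special tokens,
#' `startseq` and `endseq`, appended after the ordinary terms. Integer ids are
#' 1-based and contiguous; id 0 is reserved for sequence padding and is never a
#' term.
#'
#' @param terms character vector of terms, no duplicates, no empty strings.
#' @param attributes character vector (subset of `terms`) flagged as
#'   attributes.
#' @return An object of class `term_vocabulary`: a list with elements `terms`
#'   (including the two specials at the end), `is_attribute` (logical, same
#'   length), and `n_base` (number of ordinary terms).
#' @seealso [load_term_vocabulary()], [tokenize_name()]
#' @export
term_vocabulary <- function(terms, attributes = character()) {
  terms <- as.character(terms)
  if (length(terms) == 0L) stop("vocabulary must contain at least one term")
  if (any(!nzchar(terms))) stop("vocabulary contains an empty term")
  dup <- terms[duplicated(terms)]
  if (length(dup) > 0L)
    stop("duplicate term in vocabulary: ", sQuote(dup[[1L]]))
  if (any(c("startseq", "endseq") %in% terms))
    stop("'startseq'/'endseq' are reserved special tokens")
  bad <- setdiff(attributes, terms)
  if (length(bad) > 0L)
    stop("attribute not present in vocabulary: ", sQuote(bad[[1L]]))
  all_terms <- c(terms, "startseq", "endseq")
  structure(
    list(
      terms = all_terms,
      is_attribute = c(terms %in% attributes, FALSE, FALSE),
      n_base = length(terms)
    ),
    class = "term_vocabulary"
  )
}

#' @export
print.term_vocabulary <- function(x, ...) {
  cat(sprintf(
    "<term_vocabulary> %d terms (+2 specials), %d attributes\n",
    x$n_base, sum(x$is_attribute)
  ))
  invisible(x)
}

#' @rdname term_vocabulary
#' @param vocab a `term_vocabulary`.
#' @export
startseq_id <- function(vocab) vocab$n_base + 1L

#' @rdname term_vocabulary
#' @export
endseq_id <- function(vocab) vocab$n_base + 2L

#' @rdname term_vocabulary
#' @export
vocab_size <- function(vocab) length(vocab$terms)

#' Map terms to ids and back
#'
#' Ids are 1-based positions in the vocabulary; 0 is the padding id and maps
#' to `NA` / the empty string.
#'
#' @param vocab a `term_vocabulary`.
#' @param terms character vector of terms.
#' @param ids integer vector of ids (0 allowed, maps to `""`).
#' @return `term_ids()`: integer vector; `id_terms()`: character vector.
#' @export
term_ids <- function(vocab, terms) {
  idx <- match(terms, vocab$terms)
  if (anyNA(idx))
    stop("unknown term: ", sQuote(terms[which(is.na(idx))[1L]]))
  idx
}

#' @rdname term_ids
#' @export
id_terms <- function(vocab, ids) {
  out <- character(length(ids))
  nz <- ids != 0L
  out[nz] <- vocab$terms[ids[nz]]
  out
}

#' Load a term vocabulary from a flag-column text file
#'
#' The file is UTF-8 text with one term per line; an optional tab-separated
#' second column flags attribute terms (`1`) versus plain terms (`0`, the
#' default when the column is absent). Only trailing whitespace is tolerated;
#' leading whitespace is considered part of the term. `startseq`/`endseq` are
#' appended automatically and must not appear in the file.
#'
#' @param path path to the vocabulary file.
#' @return a [term_vocabulary()].
#' @export
load_term_vocabulary <- function(path) {
  if (!file.exists(path)) stop("vocabulary file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("[ \t\r]+$", "", lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("vocabulary file is empty: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- vapply(parts, `[[`, character(1), 1L)
  flags <- vapply(parts, function(p) {
    if (length(p) >= 2L && p[[2L]] == "1") TRUE else FALSE
  }, logical(1))
  term_vocabulary(terms, attributes = terms[flags])
}

#' @rdname load_term_vocabulary
#' @param vocab a `term_vocabulary` to write.
#' @export
write_term_vocabulary <- function(vocab, path) {
  base <- seq_len(vocab$n_base)
  writeLines(
    paste(vocab$terms[base], as.integer(vocab$is_attribute[base]), sep = "\t"),
    path, useBytes = TRUE
  )
  invisible(path)
}

#' Packaged vocabularies
#'
#' `default_vocabulary()` returns the reduced working vocabulary that covers
#' every name the packaged nomenclature grammar can emit (plus the terms needed
#' to tokenize a handful of literature names used in examples).
#' `full_schema_vocabulary()` returns a synthetic example of a full-size
#' vocabulary -- 199 terms of which 100 are attribute-flagged -- illustrating
#' the schema for dropping in a complete term list.
#'
#' @return a [term_vocabulary()].
#' @export
default_vocabulary <- function() {
  load_term_vocabulary(
    system.file("extdata", "vocabulary_reduced.tsv", package = "afmid",
                mustWork = TRUE)
  )
}

#' @rdname default_vocabulary
#' @export
full_schema_vocabulary <- function() {
  load_term_vocabulary(
    system.file("extdata", "vocabulary_full_synthetic.tsv", package = "afmid",
                mustWork = TRUE)
  )
}

#' Term sequences
#'
#' A `term_sequence` is the ordered term decomposition of one IUPAC name,
#' stored both as term strings and as the matching integer ids. Concatenating
#' `terms` reproduces the source name exactly.
#'
#' @param terms character vector of terms (may be empty).
#' @param vocab the `term_vocabulary` the terms belong to.
#' @return An object of class `term_sequence`: list with `terms` and `ids`.
#' @export
term_sequence <- function(terms, vocab) {
  terms <- as.character(terms)
  structure(
    list(terms = terms,
         ids = if (length(terms)) term_ids(vocab, terms) else integer()),
    class = "term_sequence"
  )
}

#' @export
print.term_sequence <- function(x, ...) {
  cat(sprintf("<term_sequence> %d terms: %s\n", length(x$terms),
              paste(x$terms, collapse = " | ")))
  invisible(x)
}

#' @export
length.term_sequence <- function(x) length(x$terms)

#' Tokenize an IUPAC name into vocabulary terms
#'
#' Segmentation is greedy longest-match from the left with backtracking: at
#' each position the longest vocabulary term matching the remaining string is
#' tried first and shorter matches are explored only when the greedy choice
#' leads to a dead end. This guarantees that a segmentation is found whenever
#' one exists, and is deterministic (equal-length candidates are impossible in
#' a duplicate-free vocabulary). Names are processed verbatim; no case folding
#' or whitespace handling is applied. The special tokens never participate.
#'
#' @param name non-empty character scalar.
#' @param vocab a [term_vocabulary()].
#' @return a [term_sequence()] whose terms concatenate to `name`.
#' @examples
#' v <- term_vocabulary(c("benz", "ene", "-", "1", "chlor", "o"))
#' tokenize_name("benzene", v)$terms
#' @export
tokenize_name <- function(name, vocab) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name))
    stop("'name' must be a non-empty string")
  base_terms <- vocab$terms[seq_len(vocab$n_base)]
  nc <- nchar(base_terms, type = "chars")
  n <- nchar(name, type = "chars")

  # candidate term ids at a position, longest first (vocab order on ties --
  # vacuous for duplicate-free vocabularies but kept for determinism)
  cands_at <- function(pos) {
    rem <- n - pos + 1L
    ok <- which(nc <= rem &
                  substring(name, pos, pos + nc - 1L) == base_terms)
    ok[order(-nc[ok], ok)]
  }

  pos_stack <- integer(0)     # position of each chosen term
  cand_stack <- list()        # remaining candidates at each depth
  chosen <- integer(0)
  pos <- 1L
  deepest <- 1L               # furthest position ever reached (for errors)

  cands <- cands_at(pos)
  repeat {
    if (length(cands) == 0L) {
      # dead end: backtrack
      if (length(chosen) == 0L)
        stop(sprintf(
          "name %s cannot be tokenized: no vocabulary term covers position %d",
          sQuote(name), deepest))
      pos <- pos_stack[length(pos_stack)]
      pos_stack <- pos_stack[-length(pos_stack)]
      cands <- cand_stack[[length(cand_stack)]]
      cand_stack[[length(cand_stack)]] <- NULL
      chosen <- chosen[-length(chosen)]
      next
    }
    id <- cands[[1L]]
    pos_stack <- c(pos_stack, pos)
    cand_stack[[length(cand_stack) + 1L]] <- cands[-1L]
    chosen <- c(chosen, id)
    pos <- pos + nc[[id]]
    if (pos > deepest) deepest <- pos
    if (pos > n)
      return(term_sequence(base_terms[chosen], vocab))
    cands <- cands_at(pos)
  }
}

#' Reassemble a name from its term decomposition
#'
#' Plain concatenation of the terms; no separators are inserted. This is the
#' exact inverse of [tokenize_name()] for any admitted name.
#'
#' @param seq a [term_sequence()] (or bare character vector of terms).
#' @return character scalar.
#' @export
detokenize <- function(seq) {
  terms <- if (inherits(seq, "term_sequence")) seq$terms else as.character(seq)
  paste(terms, collapse = "")
}

# canonical attribute order: length, then lexicographic byte order (C locale)
attribute_order <- function(terms, length_order = c("asc", "desc")) {
  length_order <- match.arg(length_order)
  len <- nchar(terms, type = "chars")
  if (length_order == "desc") len <- -len
  ord <- order(len, terms, method = "radix")
  terms[ord]
}

#' Extract the attribute set of a term sequence
#'
#' Attributes are the moiety-denoting subset of the vocabulary. The attribute
#' set of a name contains each attribute term once, however often it repeats
#' in the decomposition, sorted deterministically by term length and then
#' alphabetically (byte order). Sorting ascending by length is the package
#' default; descending is available behind the flag because the convention is
#' a declared choice.
#'
#' @param seq a [term_sequence()].
#' @param vocab the [term_vocabulary()] carrying the attribute flags.
#' @param length_order `"asc"` (default) or `"desc"`.
#' @return An object of class `attribute_set`: list with `attributes`
#'   (character) and `ids` (integer).
#' @export
extract_attributes <- function(seq, vocab, length_order = c("asc", "desc")) {
  stopifnot(inherits(seq, "term_sequence"))
  is_attr <- seq$ids > 0L & vocab$is_attribute[pmax(seq$ids, 1L)]
  terms <- unique(seq$terms[is_attr])
  terms <- attribute_order(terms, length_order)
  attribute_set(terms, vocab)
}

#' @rdname extract_attributes
#' @param attributes character vector of attribute terms (already ordered).
#' @export
attribute_set <- function(attributes, vocab) {
  attributes <- as.character(attributes)
  if (anyDuplicated(attributes))
    stop("attribute set contains duplicates")
  structure(
    list(attributes = attributes,
         ids = if (length(attributes)) term_ids(vocab, attributes)
               else integer()),
    class = "attribute_set"
  )
}

#' @export
print.attribute_set <- function(x, ...) {
  cat(sprintf("<attribute_set> {%s}\n", paste(x$attributes, collapse = ", ")))
  invisible(x)
}

#' @export
length.attribute_set <- function(x) length(x$attributes)

#' Dataset admission filters
#'
#' A name is admitted to training/evaluation when its term decomposition has
#' at most `max_terms` terms (57 by default, the longest decomposition kept in
#' the reference data set), its attribute set has at most `max_attributes`
#' distinct attributes (17 by default), and every term is in the vocabulary.
#'
#' @param seq a [term_sequence()].
#' @param vocab a [term_vocabulary()].
#' @param max_terms maximum admitted decomposition length.
#' @param max_attributes maximum admitted number of distinct attributes.
#' @return list with `pass` (logical) and `reason` (`""` when admitted,
#'   otherwise one of `"length"`, `"attributes"`, `"vocabulary"`).
#' @export
passes_filters <- function(seq, vocab, max_terms = 57L, max_attributes = 17L) {
  stopifnot(inherits(seq, "term_sequence"))
  in_vocab <- length(seq$terms) == 0L ||
    all(seq$terms %in% vocab$terms[seq_len(vocab$n_base)])
  if (!in_vocab)
    return(list(pass = FALSE, reason = "vocabulary"))
  if (length(seq) > max_terms)
    return(list(pass = FALSE, reason = "length"))
  n_attr <- length(extract_attributes(seq, vocab))
  if (n_attr > max_attributes)
    return(list(pass = FALSE, reason = "attributes"))
  list(pass = TRUE, reason = "")
}
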