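#' Modified n-gram precision between term sequences
#'
#' The clipped n-gram precision of BLEU with a single reference: each
#' candidate n-gram counts at most as often as it occurs in the reference.
#' A candidate shorter than `n` scores 0.
#'
#' @param candidate,reference [term_sequence()] objects or bare character
#'   vectors of terms.
#' @param n n-gram order (>= 1).
#' @return numeric scalar in \[0, 1\].
#' @export
modified_precision <- function(candidate, reference, n) {
  stopifnot(n >= 1)
  cand <- if (inherits(candidate, "term_sequence")) candidate$terms
          else as.character(candidate)
  ref <- if (inherits(reference, "term_sequence")) reference$terms
         else as.character(reference)
  if (length(cand) < n) return(0)
  cg <- .ngrams(cand, n)
  rg <- .ngrams(ref, n)
  ct <- table(cg)
  rt <- table(rg)
  shared <- intersect(names(ct), names(rt))
  clipped <- sum(pmin(as.numeric(ct[shared]), as.numeric(rt[shared])))
  clipped / length(cg)
}

.ngrams <- function(terms, n) {
  m <- length(terms) - n + 1L
  if (m <= 0L) return(character())
  vapply(seq_len(m), function(i)
    paste(terms[i:(i + n - 1L)], collapse = "\x1f"), character(1))
}

#' Cumulative BLEU score of a prediction against its reference
#'
#' Combines the clipped n-gram precisions for n = 1..N geometrically
#' (uniform weights) and multiplies by the brevity penalty
#' `BP = 1` if the candidate is at least as long as the reference, else
#' `exp(1 - |reference| / |candidate|)`. When any precision up to N has a
#' zero numerator the unsmoothed cumulative score is 0 -- short sequences
#' are therefore penalized harshly, which is a known property of the
#' metric. For candidates shorter than `N` the order is capped at the
#' candidate length (standard auto-reweighting), so an exact prediction
#' always scores 1 whatever its length. A smoothing variant (zero counts
#' replaced by 1 / (2 |candidate|)) is available behind `smooth = TRUE` for
#' diagnostics only.
#'
#' @param candidate,reference [term_sequence()] objects or character
#'   vectors of terms.
#' @param N maximum n-gram order (default 4).
#' @param smooth apply the diagnostic smoothing variant (default `FALSE`).
#' @return object of class `bleu_report`: list with `p` (modified precisions
#'   1..N), `bp`, `cumulative` (scores for orders 1..N), `n_candidate`,
#'   `n_reference`.
#' @export
cumulative_bleu <- function(candidate, reference, N = 4L, smooth = FALSE) {
  cand <- if (inherits(candidate, "term_sequence")) candidate$terms
          else as.character(candidate)
  ref <- if (inherits(reference, "term_sequence")) reference$terms
         else as.character(reference)
  nc <- length(cand); nr <- length(ref)
  p <- vapply(seq_len(N), function(n) modified_precision(cand, ref, n),
              numeric(1))
  bp <- if (nc == 0L) 0 else if (nc >= nr) 1 else exp(1 - nr / nc)
  n_eff <- max(1L, min(N, nc))
  cum <- vapply(seq_len(N), function(k) {
    pk <- p[seq_len(min(k, n_eff))]
    if (smooth) pk[pk == 0] <- 1 / (2 * max(nc, 1L))
    if (any(pk == 0)) return(0)
    bp * exp(mean(log(pk)))
  }, numeric(1))
  structure(
    list(p = p, bp = bp, cumulative = cum, n_candidate = nc,
         n_reference = nr),
    class = "bleu_report"
  )
}

#' @export
print.bleu_report <- function(x, ...) {
  cat(sprintf(
    "<bleu_report> p1..p%d = %s | BP = %.4f | cumulative-%d = %.4f\n",
    length(x$p), paste(sprintf("%.3f", x$p), collapse = " "),
    x$bp, length(x$cumulative), x$cumulative[length(x$cumulative)]))
  invisible(x)
}

#' Attribute-set 1-gram score
#'
#' 1.0 exactly when predicted and reference attribute sets are equal (every
#' reference attribute present, nothing extra); otherwise the clipped
#' 1-gram precision with brevity penalty over the canonically sorted
#' sequences.
#'
#' @param pred,ref `attribute_set` objects (or character vectors of
#'   attribute terms).
#' @return numeric scalar in \[0, 1\].
#' @export
attribute_score <- function(pred, ref) {
  pt <- if (inherits(pred, "attribute_set")) pred$attributes
        else attribute_order(as.character(pred))
  rt <- if (inherits(ref, "attribute_set")) ref$attributes
        else attribute_order(as.character(ref))
  if (setequal(pt, rt)) return(1)
  if (length(pt) == 0L) return(0)
  bp <- if (length(pt) >= length(rt)) 1 else exp(1 - length(rt) / length(pt))
  bp * modified_precision(pt, rt, 1L)
}

#' Character-level exact match
#'
#' `TRUE` when the detokenized prediction equals the detokenized reference
#' character by character; the token split itself is irrelevant.
#'
#' @param pred,ref [term_sequence()] objects or character vectors of terms.
#' @return logical scalar.
#' @export
exact_match <- function(pred, ref) {
  detokenize(pred) == detokenize(ref)
}

# term category for the error taxonomy
.term_category <- function(term) {
  if (grepl("^[0-9]+$", term)) "number"
  else if (term %in% c("-", "−")) "hyphen"
  else if (term %in% c("(", ")")) "parenthesis"
  else if (term == "yl") "yl"
  else if (term %in% c("[", "]")) "bracket"
  else "other"
}

# minimum-edit-distance alignment over terms; substitution preferred over
# insert+delete on cost ties. Returns the list of error operations.
.align_errors <- function(pred, ref) {
  np <- length(pred); nr <- length(ref)
  D <- matrix(0L, np + 1L, nr + 1L)
  D[, 1L] <- 0:np
  D[1L, ] <- 0:nr
  for (i in seq_len(np)) {
    for (j in seq_len(nr)) {
      sub_cost <- D[i, j] + (pred[i] != ref[j])
      del_cost <- D[i, j + 1L] + 1L      # drop predicted term (insertion
      ins_cost <- D[i + 1L, j] + 1L      # by the model) / missing term
      D[i + 1L, j + 1L] <- min(sub_cost, del_cost, ins_cost)
    }
  }
  ops <- list()
  i <- np; j <- nr
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        D[i + 1L, j + 1L] == D[i, j] + (pred[i] != ref[j])) {
      if (pred[i] != ref[j])
        ops[[length(ops) + 1L]] <- list(op = "substitution", term = ref[j])
      i <- i - 1L; j <- j - 1L
    } else if (j > 0L && D[i + 1L, j + 1L] == D[i + 1L, j] + 1L) {
      ops[[length(ops) + 1L]] <- list(op = "deletion", term = ref[j])
      j <- j - 1L
    } else {
      ops[[length(ops) + 1L]] <- list(op = "insertion", term = pred[i])
      i <- i - 1L
    }
  }
  ops
}

#' Term-level error taxonomy over prediction/reference pairs
#'
#' Aligns every pair by minimum edit distance over terms (unit costs,
#' substitution preferred on ties) and classifies each substitution,
#' insertion or deletion by the affected term: the reference term for
#' substitutions and deletions, the predicted term for insertions.
#' Categories: pure-digit `number` terms, `hyphen`, `parenthesis`, the
#' literal `yl` term, square `bracket`, and `other`.
#'
#' @param pairs list of `list(pred = , ref = )` entries; each element a
#'   [term_sequence()] or character vector of terms.
#' @return object of class `error_taxonomy`: list with `counts`,
#'   `fractions` (both named by category) and `n_errors`.
#' @export
classify_errors <- function(pairs) {
  cats <- c("number", "hyphen", "parenthesis", "yl", "bracket", "other")
  counts <- stats::setNames(numeric(length(cats)), cats)
  for (pr in pairs) {
    pred <- if (inherits(pr$pred, "term_sequence")) pr$pred$terms
            else as.character(pr$pred)
    ref <- if (inherits(pr$ref, "term_sequence")) pr$ref$terms
           else as.character(pr$ref)
    for (op in .align_errors(pred, ref)) {
      cat_ <- .term_category(op$term)
      counts[cat_] <- counts[cat_] + 1
    }
  }
  n <- sum(counts)
  structure(
    list(counts = counts,
         fractions = if (n > 0) counts / n else counts,
         n_errors = n),
    class = "error_taxonomy"
  )
}

#' @export
print.error_taxonomy <- function(x, ...) {
  cat(sprintf("<error_taxonomy> %d term errors\n", x$n_errors))
  for (nm in names(x$fractions))
    cat(sprintf("  %-12s %5.1f%%\n", nm, 100 * x$fractions[[nm]]))
  invisible(x)
}

#' Nearest terms in the learned embedding space
#'
#' Projects every vocabulary term into the embedding space of the (name)
#' network and returns the `k` terms closest to the query under the L2
#' norm, ties broken by vocabulary id; the query itself is excluded.
#'
#' @param model an [init_model()] result (typically the trained name
#'   network).
#' @param vocab the [term_vocabulary()].
#' @param term query term.
#' @param k number of neighbors.
#' @return data frame with columns `term` and `distance`, `k` rows.
#' @export
embedding_neighbors <- function(model, vocab, term, k = 5L) {
  if (!term %in% vocab$terms) stop("unknown term: ", sQuote(term))
  emb <- term_embedding_vectors(model, vocab)
  q <- emb[match(term, vocab$terms), ]
  d2 <- sqrt(rowSums(sweep(emb, 2L, q, `-`)^2))
  ord <- order(d2, seq_along(d2), method = "radix")
  ord <- ord[vocab$terms[ord] != term]
  take <- utils::head(ord, max(k, 0L))
  data.frame(term = vocab$terms[take], distance = d2[take],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Score a table of predictions against references
#'
#' Per-molecule evaluation report: exact match, modified precisions 1..4,
#' the cumulative 4-gram, and (when attribute columns are present) the
#' attribute 1-gram score; plus an aggregate summary. Both the mean
#' attribute 1-gram score and the exact-set-match rate are reported, since
#' either reading is a defensible summary of attribute accuracy.
#'
#' @param predictions data frame as returned by [predict_manifest()] (or
#'   with at least `reference` and `prediction` columns).
#' @param vocab the [term_vocabulary()].
#' @return list with `per_molecule` (data frame) and `summary` (named
#'   numeric vector).
#' @export
evaluate_predictions <- function(predictions, vocab) {
  stopifnot(all(c("reference", "prediction") %in% names(predictions)))
  n <- nrow(predictions)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ref <- tokenize_name(predictions$reference[i], vocab)
    pred <- tryCatch(tokenize_name(predictions$prediction[i], vocab),
                     error = function(e) term_sequence(character(), vocab))
    if (!nzchar(predictions$prediction[i]))
      pred <- term_sequence(character(), vocab)
    rep_ <- cumulative_bleu(pred, ref)
    a_sc <- NA_real_
    a_eq <- NA
    if (all(c("attr_reference", "attr_prediction") %in% names(predictions))) {
      split_attrs <- function(x) {
        x <- as.character(x)
        if (is.na(x) || !nzchar(x)) character()
        else strsplit(x, ",", fixed = TRUE)[[1]]
      }
      ra <- split_attrs(predictions$attr_reference[i])
      pa <- split_attrs(predictions$attr_prediction[i])
      a_sc <- attribute_score(pa, ra)
      a_eq <- setequal(pa, ra)
    }
    rows[[i]] <- data.frame(
      id = if ("id" %in% names(predictions)) predictions$id[i] else i,
      exact = exact_match(pred, ref),
      p1 = rep_$p[1], p2 = rep_$p[2], p3 = rep_$p[3], p4 = rep_$p[4],
      cumulative4 = rep_$cumulative[4],
      attr_score = a_sc, attr_exact = a_eq,
      stringsAsFactors = FALSE
    )
  }
  per <- do.call(rbind, rows)
  list(
    per_molecule = per,
    summary = c(
      exact_match_rate = mean(per$exact),
      mean_cumulative4 = mean(per$cumulative4),
      mean_p1 = mean(per$p1),
      mean_attr_score = mean(per$attr_score),
      attr_set_match_rate = mean(as.numeric(per$attr_exact))
    )
  )
}
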