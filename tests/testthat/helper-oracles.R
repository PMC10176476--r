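# Independent reference implementations used to cross-check the package.
# These deliberately use different algorithms (explicit loops, exhaustive
# enumeration) from the implementation under test.

# clipped n-gram counts by explicit greedy bipartite matching
oracle_ngram_counts <- function(cand, ref, n) {
  total <- length(cand) - n + 1L
  if (total <= 0L) return(c(clipped = 0, total = 0))
  nref <- length(ref) - n + 1L
  used <- rep(FALSE, max(nref, 0L))
  clipped <- 0L
  for (i in seq_len(total)) {
    g <- cand[i:(i + n - 1L)]
    for (j in seq_len(max(nref, 0L))) {
      if (!used[j] && all(ref[j:(j + n - 1L)] == g)) {
        used[j] <- TRUE
        clipped <- clipped + 1L
        break
      }
    }
  }
  c(clipped = clipped, total = total)
}

oracle_modified_precision <- function(cand, ref, n) {
  cc <- oracle_ngram_counts(cand, ref, n)
  if (cc[["total"]] == 0) 0 else cc[["clipped"]] / cc[["total"]]
}

oracle_cumulative_bleu <- function(cand, ref, N = 4L) {
  p <- vapply(seq_len(N), function(n) oracle_modified_precision(cand, ref, n),
              numeric(1))
  bp <- if (length(cand) == 0L) 0
        else if (length(cand) >= length(ref)) 1
        else exp(1 - length(ref) / length(cand))
  n_eff <- max(1L, min(N, length(cand)))
  vapply(seq_len(N), function(k) {
    pk <- p[seq_len(min(k, n_eff))]
    if (any(pk == 0)) 0 else bp * prod(pk)^(1 / length(pk))
  }, numeric(1))
}

# exhaustive segmentation enumeration; the greedy-longest-match-with-
# backtracking choice is the segmentation whose term-length sequence is
# lexicographically maximal
oracle_segmentations <- function(name, terms) {
  n <- nchar(name)
  recur <- function(pos) {
    if (pos > n) return(list(character()))
    out <- list()
    for (tm in terms) {
      L <- nchar(tm)
      if (pos + L - 1L <= n && substring(name, pos, pos + L - 1L) == tm) {
        for (tail in recur(pos + L))
          out[[length(out) + 1L]] <- c(tm, tail)
      }
    }
    out
  }
  recur(1L)
}

oracle_greedy_segmentation <- function(name, terms) {
  segs <- oracle_segmentations(name, terms)
  if (length(segs) == 0L) return(NULL)
  best <- segs[[1L]]
  for (s in segs[-1L]) {
    la <- nchar(s); lb <- nchar(best)
    k <- min(length(la), length(lb))
    d <- la[seq_len(k)] - lb[seq_len(k)]
    nz <- which(d != 0)
    if (length(nz) > 0L && d[nz[1L]] > 0) best <- s
  }
  best
}

# all 12 numberings of a benzene ring: start position x direction
oracle_benzene_numberings <- function() {
  out <- list()
  for (start in 0:5) {
    for (dir in c(1L, -1L)) {
      out[[length(out) + 1L]] <-
        vapply(0:5, function(site) ((site - start) * dir) %% 6L + 1L,
               integer(1))
    }
  }
  out
}

# brute-force attribute comparator: insertion sort with explicit pairwise
# comparison (length ascending, then byte-wise codepoint order)
oracle_attribute_sort <- function(terms) {
  lt <- function(a, b) {
    if (nchar(a) != nchar(b)) return(nchar(a) < nchar(b))
    ia <- utf8ToInt(a); ib <- utf8ToInt(b)
    k <- min(length(ia), length(ib))
    d <- ia[seq_len(k)] - ib[seq_len(k)]
    nz <- which(d != 0)
    if (length(nz) > 0L) return(d[nz[1L]] < 0)
    length(ia) < length(ib)
  }
  out <- character(0)
  for (t in terms) {
    pos <- length(out) + 1L
    for (i in seq_along(out)) if (lt(t, out[i])) { pos <- i; break }
    out <- append(out, t, after = pos - 1L)
  }
  out
}
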