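#' Constrained nomenclature grammar
#'
#' The grammar produces (layout, IUPAC name) pairs from a small family of
#' ring scaffolds with substituents, so that every downstream stage can be
#' trained and tested on fully synthetic data with exact ground truth. The
#' family is deliberately small -- single and fused double rings with up to
#' four substituents -- but rich enough to exercise locants, multiplying
#' prefixes, hyphens and commas, the very term classes that dominate the
#' error taxonomy of name-generating models.
#'
#' @param scaffolds character vector drawn from
#'   `c("benzene", "naphthalene", "pyridine")`.
#' @param substituents character vector drawn from
#'   `c("fluoro", "chloro", "bromo", "iodo", "methyl", "amino", "nitro",
#'   "hydroxy")`.
#' @param min_substituents,max_substituents bounds on the number of
#'   substituents per molecule (0 to 4).
#' @param nonplanar_range half-width (in Angstrom) of the uniform z-offset
#'   applied to substituent heavy atoms; 0 (the default) keeps the layout
#'   strictly quasiplanar.
#' @return an object of class `grammar_config`.
#' @export
grammar_config <- function(scaffolds = c("benzene", "naphthalene", "pyridine"),
                           substituents = c("fluoro", "chloro", "bromo",
                                            "iodo", "methyl", "amino",
                                            "nitro", "hydroxy"),
                           min_substituents = 1L,
                           max_substituents = 4L,
                           nonplanar_range = 0) {
  if (length(scaffolds) == 0L) stop("scaffold set must be non-empty")
  if (length(substituents) == 0L) stop("substituent set must be non-empty")
  scaffolds <- match.arg(scaffolds, names(.afm_scaffolds), several.ok = TRUE)
  substituents <- match.arg(substituents, names(.afm_substituents),
                            several.ok = TRUE)
  stopifnot(min_substituents >= 0L, max_substituents >= min_substituents,
            max_substituents <= 4L, nonplanar_range >= 0)
  structure(
    list(scaffolds = scaffolds, substituents = substituents,
         min_substituents = as.integer(min_substituents),
         max_substituents = as.integer(max_substituents),
         nonplanar_range = nonplanar_range),
    class = "grammar_config"
  )
}

# 2D rotation of a unit vector by `deg` degrees
.rot2 <- function(u, deg) {
  a <- deg * pi / 180
  c(cos(a) * u[1] - sin(a) * u[2], sin(a) * u[1] + cos(a) * u[2])
}

# ring scaffolds: coordinates (Angstrom), substitutable positions, symmetry
# group as locant permutations, and the parent name. Ring C-C bond 1.39-1.40 A.
.make_benzene <- function() {
  ang <- (90 - 60 * (0:5)) * pi / 180
  xy <- cbind(1.39 * cos(ang), 1.39 * sin(ang))
  rot <- lapply(0:5, function(k) ((0:5 + k) %% 6) + 1L)
  ref <- lapply(0:5, function(k) ((k - (0:5)) %% 6) + 1L)
  list(parent = "benzene",
       species = rep("C", 6), xy = xy,
       ring_bonds = cbind(1:6, c(2:6, 1L)),
       positions = 1:6,
       exo = xy / sqrt(rowSums(xy^2)),
       sym = c(rot, ref))
}

.make_naphthalene <- function() {
  a <- 1.4 * sqrt(3) / 2        # hexagon center to shared-edge midpoint
  ctr <- c(a, 0)
  vang <- c(90, 30, -30, -90) * pi / 180
  right <- t(vapply(vang, function(t) ctr + 1.4 * c(cos(t), sin(t)),
                    numeric(2)))                       # C1..C4
  left <- right[4:1, , drop = FALSE]; left[, 1] <- -left[, 1]  # C5..C8
  bridg <- rbind(c(0, -0.7), c(0, 0.7))                # C4a, C8a
  xy <- rbind(right, left, bridg)                      # 1..8, 9=C4a, 10=C8a
  ring_bonds <- rbind(
    cbind(1:3, 2:4), c(4, 9), c(9, 5), cbind(5:7, 6:8), c(8, 10), c(10, 1),
    c(9, 10))
  sym <- list(1:8,
              c(8L, 7L, 6L, 5L, 4L, 3L, 2L, 1L),
              c(4L, 3L, 2L, 1L, 8L, 7L, 6L, 5L),
              c(5L, 6L, 7L, 8L, 1L, 2L, 3L, 4L))
  ring_center <- function(i) if (i <= 4) c(a, 0) else c(-a, 0)
  exo <- t(vapply(1:8, function(i) {
    v <- xy[i, ] - ring_center(i); v / sqrt(sum(v^2))
  }, numeric(2)))
  list(parent = "naphthalene",
       species = rep("C", 10), xy = xy,
       ring_bonds = ring_bonds,
       positions = 1:8,
       exo = exo,
       sym = sym)
}

.make_pyridine <- function() {
  ang <- (90 - 60 * (0:5)) * pi / 180
  xy <- cbind(1.35 * cos(ang), 1.35 * sin(ang))
  list(parent = "pyridine",
       species = c("N", rep("C", 5)), xy = xy,
       ring_bonds = cbind(1:6, c(2:6, 1L)),
       positions = 2:6,                      # N (position 1) carries no H
       exo = xy / sqrt(rowSums(xy^2)),
       sym = list(2:6, c(6L, 5L, 4L, 3L, 2L)))
}

.afm_scaffolds <- list(
  benzene = .make_benzene(),
  naphthalene = .make_naphthalene(),
  pyridine = .make_pyridine()
)

# substituent builders: given attachment point r and outward unit vector u,
# return atoms (species, x, y) with the first atom bonded to the ring atom,
# plus bonds among the substituent atoms (1-based local indices)
.afm_substituents <- list(
  fluoro = function(r, u) list(atoms = rbind(data.frame(
    species = "F", x = r[1] + 1.35 * u[1], y = r[2] + 1.35 * u[2])),
    bonds = NULL),
  chloro = function(r, u) list(atoms = data.frame(
    species = "Cl", x = r[1] + 1.73 * u[1], y = r[2] + 1.73 * u[2]),
    bonds = NULL),
  bromo = function(r, u) list(atoms = data.frame(
    species = "Br", x = r[1] + 1.90 * u[1], y = r[2] + 1.90 * u[2]),
    bonds = NULL),
  iodo = function(r, u) list(atoms = data.frame(
    species = "I", x = r[1] + 2.10 * u[1], y = r[2] + 2.10 * u[2]),
    bonds = NULL),
  methyl = function(r, u) {
    c0 <- r + 1.50 * u
    hs <- lapply(c(0, 120, -120), function(d) c0 + 1.09 * .rot2(u, d))
    list(atoms = data.frame(
      species = c("C", "H", "H", "H"),
      x = c(c0[1], vapply(hs, `[`, numeric(1), 1)),
      y = c(c0[2], vapply(hs, `[`, numeric(1), 2))),
      bonds = cbind(1L, 2:4))
  },
  amino = function(r, u) {
    n0 <- r + 1.40 * u
    hs <- lapply(c(60, -60), function(d) n0 + 1.01 * .rot2(u, d))
    list(atoms = data.frame(
      species = c("N", "H", "H"),
      x = c(n0[1], vapply(hs, `[`, numeric(1), 1)),
      y = c(n0[2], vapply(hs, `[`, numeric(1), 2))),
      bonds = cbind(1L, 2:3))
  },
  nitro = function(r, u) {
    n0 <- r + 1.40 * u
    os <- lapply(c(60, -60), function(d) n0 + 1.21 * .rot2(u, d))
    list(atoms = data.frame(
      species = c("N", "O", "O"),
      x = c(n0[1], vapply(os, `[`, numeric(1), 1)),
      y = c(n0[2], vapply(os, `[`, numeric(1), 2))),
      bonds = cbind(1L, 2:3))
  },
  hydroxy = function(r, u) {
    o0 <- r + 1.36 * u
    h <- o0 + 0.97 * .rot2(u, 55)
    list(atoms = data.frame(
      species = c("O", "H"), x = c(o0[1], h[1]), y = c(o0[2], h[2])),
      bonds = cbind(1L, 2L))
  }
)

.multiplying_prefix <- c("", "di", "tri", "tetra")

#' Build a molecule layout from a substitution pattern
#'
#' @param scaffold scaffold name (`"benzene"`, `"naphthalene"`, `"pyridine"`).
#' @param substituents data frame with columns `position` (ring locant) and
#'   `sub` (substituent name), possibly empty.
#' @param nonplanar_range half-width of uniform z offsets (Angstrom) applied
#'   to substituent heavy atoms; drawn from the current RNG stream.
#' @return an object of class `molecule_layout`: atoms
#'   (`species`, `x`, `y`, `z`), `bonds` (two-column index matrix),
#'   the substitution metadata, and the systematic `name`.
#' @export
build_layout <- function(scaffold, substituents = NULL, nonplanar_range = 0) {
  sc <- .afm_scaffolds[[scaffold]]
  if (is.null(sc)) stop("unknown scaffold: ", sQuote(scaffold))
  if (is.null(substituents))
    substituents <- data.frame(position = integer(), sub = character())
  if (nrow(substituents) > 0) {
    if (anyDuplicated(substituents$position))
      stop("duplicate substituent position")
    if (!all(substituents$position %in% sc$positions))
      stop("position not substitutable on ", scaffold)
    if (!all(substituents$sub %in% names(.afm_substituents)))
      stop("unknown substituent: ",
           sQuote(setdiff(substituents$sub, names(.afm_substituents))[1]))
  }

  atoms <- data.frame(species = sc$species,
                      x = sc$xy[, 1], y = sc$xy[, 2], z = 0)
  bonds <- sc$ring_bonds
  # ring hydrogens on unsubstituted positions
  for (p in setdiff(sc$positions, substituents$position)) {
    h <- sc$xy[p, ] + 1.09 * sc$exo[p, ]
    atoms <- rbind(atoms, data.frame(species = "H", x = h[1], y = h[2], z = 0))
    bonds <- rbind(bonds, c(p, nrow(atoms)))
  }
  # substituents
  if (nrow(substituents) > 0) {
    for (k in seq_len(nrow(substituents))) {
      p <- substituents$position[k]
      piece <- .afm_substituents[[substituents$sub[k]]](sc$xy[p, ], sc$exo[p, ])
      zoff <- if (nonplanar_range > 0)
        stats::runif(1, -nonplanar_range, nonplanar_range) else 0
      base <- nrow(atoms)
      pa <- piece$atoms
      pa$z <- ifelse(pa$species == "H", 0, zoff)
      atoms <- rbind(atoms, pa[, c("species", "x", "y", "z")])
      bonds <- rbind(bonds, c(p, base + 1L))
      if (!is.null(piece$bonds))
        bonds <- rbind(bonds, piece$bonds + base)
    }
  }
  rownames(atoms) <- NULL
  layout <- structure(
    list(atoms = atoms, bonds = unname(as.matrix(bonds)),
         scaffold = scaffold,
         substituents = substituents[order(substituents$position), ,
                                     drop = FALSE],
         name = NA_character_),
    class = "molecule_layout"
  )
  layout$name <- name_molecule(layout)
  layout
}

#' @export
print.molecule_layout <- function(x, ...) {
  cat(sprintf("<molecule_layout> %s (%d atoms, scaffold %s)\n",
              x$name, nrow(x$atoms), x$scaffold))
  invisible(x)
}

#' Systematic substitutive name of a grammar layout
#'
#' Builds the name as `[locants]-[multiplying prefix][substituent]... parent`:
#' substituents are cited alphabetically (ignoring multiplying prefixes) and
#' locants are chosen by the lowest-locant rule, resolved by exhaustive
#' enumeration of the scaffold's ring symmetry operations -- first the sorted
#' set of all locants at the first point of difference, then lowest locants
#' for the first-cited substituent, and so on. A lone substituent on benzene
#' is cited without a locant.
#'
#' @param layout a [build_layout()] result (any layout carrying the grammar's
#'   scaffold/substituent metadata).
#' @return character scalar, the IUPAC name.
#' @export
name_molecule <- function(layout) {
  if (!inherits(layout, "molecule_layout") || is.null(layout$scaffold))
    stop("layout was not produced by the packaged grammar")
  sc <- .afm_scaffolds[[layout$scaffold]]
  subs <- layout$substituents
  if (is.null(subs) || nrow(subs) == 0L) return(sc$parent)

  cited <- sort(unique(subs$sub), method = "radix")
  pos_index <- match(subs$position, sc$positions)

  best_key <- NULL
  best_loc <- NULL
  for (perm in sc$sym) {
    loc <- perm[pos_index]               # locants under this numbering
    key <- c(sort(loc),
             unlist(lapply(cited, function(nm) sort(loc[subs$sub == nm]))))
    if (is.null(best_key) ||
        isTRUE((cmp <- .lex_cmp(key, best_key)) < 0)) {
      best_key <- key
      best_loc <- loc
    }
  }

  omit_locants <- identical(layout$scaffold, "benzene") && nrow(subs) == 1L
  segments <- vapply(cited, function(nm) {
    locs <- sort(best_loc[subs$sub == nm])
    mult <- .multiplying_prefix[length(locs)]
    if (omit_locants) nm
    else paste0(paste(locs, collapse = ","), "-", mult, nm)
  }, character(1))
  paste0(paste(segments, collapse = "-"), sc$parent)
}

# lexicographic comparison of equal-length integer keys: -1, 0, or 1
.lex_cmp <- function(a, b) {
  d <- a - b
  nz <- which(d != 0)
  if (length(nz) == 0L) 0L else sign(d[nz[1L]])
}

#' Sample one molecule from the grammar
#'
#' Draws a scaffold, a substituent count, positions and substituent types
#' uniformly from the current RNG stream (seed it with [set.seed()] for
#' reproducibility), builds the layout and names it.
#'
#' @param cfg a [grammar_config()].
#' @return a [build_layout()] result.
#' @export
sample_molecule <- function(cfg) {
  stopifnot(inherits(cfg, "grammar_config"))
  scaffold <- if (length(cfg$scaffolds) == 1L) cfg$scaffolds else
    sample(cfg$scaffolds, 1L)
  sc <- .afm_scaffolds[[scaffold]]
  kmax <- min(cfg$max_substituents, length(sc$positions))
  kmin <- min(cfg$min_substituents, kmax)
  k <- if (kmin == kmax) kmin else sample(kmin:kmax, 1L)
  subs <- if (k == 0L) NULL else data.frame(
    position = sort(sample(sc$positions, k)),
    sub = sample(cfg$substituents, k, replace = TRUE)
  )
  build_layout(scaffold, subs, nonplanar_range = cfg$nonplanar_range)
}

#' Number of distinct names the grammar can produce
#'
#' Counts substitution patterns up to ring symmetry with Burnside's lemma
#' (cycle-index polynomial per symmetry operation, truncated at the allowed
#' substituent counts), summed over the configured scaffolds. Distinct
#' patterns map to distinct names within this grammar.
#'
#' @param cfg a [grammar_config()].
#' @return integer count of distinct names.
#' @export
grammar_capacity <- function(cfg) {
  stopifnot(inherits(cfg, "grammar_config"))
  m <- length(cfg$substituents)
  total <- 0
  for (scname in cfg$scaffolds) {
    sc <- .afm_scaffolds[[scname]]
    kmax <- min(cfg$max_substituents, length(sc$positions))
    kmin <- min(cfg$min_substituents, kmax)
    acc <- 0
    for (perm in sc$sym) {
      # cycle lengths of the permutation on substitutable positions
      seen <- logical(length(perm))
      poly <- c(1, numeric(kmax))         # coefficients of x^0..x^kmax
      i <- 1L
      while (i <= length(perm)) {
        if (!seen[i]) {
          len <- 0L; j <- i
          repeat {
            seen[j] <- TRUE; len <- len + 1L
            j <- match(perm[j], sc$positions) # follow within local indexing
            if (j == i) break
          }
          # multiply poly by (1 + m * x^len), truncate at kmax
          upd <- poly
          if (len <= kmax)
            upd[(len + 1):(kmax + 1)] <- upd[(len + 1):(kmax + 1)] +
              m * poly[1:(kmax + 1 - len)]
          poly <- upd
        }
        i <- i + 1L
      }
      acc <- acc + sum(poly[(kmin + 1):(kmax + 1)])
    }
    total <- total + acc / length(sc$sym)
  }
  as.integer(round(total))
}

#' Generate a named, split synthetic dataset
#'
#' Rejection-samples molecules until `n` unique names are collected, verifies
#' every name against the vocabulary round trip and the admission filters,
#' and partitions the result into train/validation/test splits.
#'
#' @param n number of distinct molecules.
#' @param seed integer seed; fully determines the manifest.
#' @param cfg a [grammar_config()].
#' @param fractions named numeric vector summing to 1 with elements `train`,
#'   `val`, `test`.
#' @param vocab vocabulary used for admission checks
#'   (default [default_vocabulary()]).
#' @return an object of class `afm_manifest`: list with `records` (data frame
#'   `id`, `name`, `scaffold`, `split`), `layouts` (named list), `config`,
#'   `seed`.
#' @export
generate_dataset <- function(n, seed, cfg = grammar_config(),
                             fractions = c(train = 0.8, val = 0.1,
                                           test = 0.1),
                             vocab = default_vocabulary()) {
  stopifnot(n >= 1, abs(sum(fractions) - 1) < 1e-8,
            all(c("train", "val", "test") %in% names(fractions)))
  cap <- grammar_capacity(cfg)
  if (n > cap)
    stop(sprintf("requested %d molecules but the grammar capacity is %d",
                 n, cap))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)

  layouts <- list()
  names_seen <- character()
  guard <- 0L
  while (length(layouts) < n) {
    guard <- guard + 1L
    if (guard > 1000L * n + 10000L)
      stop("rejection sampling stalled; grammar capacity ", cap,
           " may be too close to n = ", n)
    lay <- sample_molecule(cfg)
    if (lay$name %in% names_seen) next
    seq <- tokenize_name(lay$name, vocab)
    if (detokenize(seq) != lay$name)
      stop("internal error: round trip failed for ", lay$name)
    if (!passes_filters(seq, vocab)$pass) next
    layouts[[length(layouts) + 1L]] <- lay
    names_seen <- c(names_seen, lay$name)
  }

  counts <- floor(fractions[c("train", "val", "test")] * n)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- fractions[c("train", "val", "test")] * n - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  split <- rep(c("train", "val", "test"), times = counts)

  ids <- sprintf("mol%04d", seq_len(n))
  names(layouts) <- ids
  records <- data.frame(
    id = ids,
    name = names_seen,
    scaffold = vapply(layouts, `[[`, character(1), "scaffold"),
    split = split,
    stringsAsFactors = FALSE
  )
  rownames(records) <- NULL
  structure(
    list(records = records, layouts = layouts, config = cfg,
         seed = as.integer(seed)),
    class = "afm_manifest"
  )
}

#' @export
print.afm_manifest <- function(x, ...) {
  cat(sprintf("<afm_manifest> %d molecules (train %d / val %d / test %d)\n",
              nrow(x$records), sum(x$records$split == "train"),
              sum(x$records$split == "val"), sum(x$records$split == "test")))
  invisible(x)
}

# save/restore the global RNG state so seeded helpers do not perturb callers
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# deterministic sub-seed derivation for named substreams
.derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483587)
}
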