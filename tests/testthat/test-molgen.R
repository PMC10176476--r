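test_that("layouts are connected, quasiplanar and carry their name", {
  l <- tiny_layout()
  expect_identical(l$name, "1-chloro-4-methylbenzene")
  expect_true(all(l$atoms$z == 0))
  # bonded graph is connected
  n <- nrow(l$atoms)
  adj <- matrix(FALSE, n, n)
  adj[l$bonds] <- TRUE
  adj[l$bonds[, 2:1]] <- TRUE
  reach <- logical(n); reach[1] <- TRUE
  repeat {
    new <- reach | apply(adj[, reach, drop = FALSE], 1, any)
    if (identical(new, reach)) break
    reach <- new
  }
  expect_true(all(reach))
})

test_that("systematic naming applies lowest locants and alphabetical citation", {
  expect_identical(build_layout("benzene")$name, "benzene")
  expect_identical(
    build_layout("benzene", data.frame(position = 3L, sub = "chloro"))$name,
    "chlorobenzene")
  expect_identical(
    build_layout("benzene", data.frame(position = c(3L, 4L),
                                       sub = c("chloro", "chloro")))$name,
    "1,2-dichlorobenzene")
  # pyridine nitrogen fixes the numbering origin
  expect_identical(
    build_layout("pyridine", data.frame(position = 6L, sub = "amino"))$name,
    "2-aminopyridine")

  # oracle: enumerate all 12 benzene numberings by hand and verify the
  # chosen locant set is minimal, with ties broken for the first-cited name
  set.seed(5)
  subs_pool <- c("chloro", "methyl", "bromo")
  for (rep in 1:25) {
    k <- sample(1:3, 1)
    pos <- sort(sample(1:6, k))
    subs <- data.frame(position = pos,
                       sub = sample(subs_pool, k, replace = TRUE))
    nm <- build_layout("benzene", subs)$name
    keys <- lapply(oracle_benzene_numberings(), function(numb) {
      loc <- numb[subs$position]
      cited <- sort(unique(subs$sub))
      c(sort(loc), unlist(lapply(cited, function(s) sort(loc[subs$sub == s]))))
    })
    best <- keys[[1]]
    for (kk in keys[-1]) {
      d <- kk - best
      nz <- which(d != 0)
      if (length(nz) && d[nz[1]] < 0) best <- kk
    }
    want_locs <- best[seq_len(k)]
    got_locs <- sort(as.integer(unlist(
      regmatches(nm, gregexpr("[0-9]+", nm)))))
    if (nrow(subs) == 1L) {
      expect_false(grepl("[0-9]", nm))  # lone benzene substituent: no locant
    } else {
      expect_identical(got_locs, as.integer(want_locs))
    }
  }
})

test_that("naming is injective on benzene patterns up to ring symmetry", {
  pool <- c("chloro", "methyl")
  pats <- list()
  for (k in 1:3) {
    pos_sets <- utils::combn(6, k, simplify = FALSE)
    subs_sets <- expand.grid(rep(list(pool), k), stringsAsFactors = FALSE)
    for (p in pos_sets) for (r in seq_len(nrow(subs_sets)))
      pats[[length(pats) + 1L]] <-
        data.frame(position = p, sub = unlist(subs_sets[r, ]))
  }
  canon <- vapply(pats, function(s) {
    reps <- vapply(oracle_benzene_numberings(), function(numb) {
      loc <- numb[s$position]
      paste(sort(paste0(loc, ":", s$sub)), collapse = "|")
    }, character(1))
    min(reps)
  }, character(1))
  names_ <- vapply(pats, function(s) build_layout("benzene", s)$name,
                   character(1))
  # same orbit <-> same name
  expect_identical(length(unique(canon)), length(unique(names_)))
  expect_true(all(tapply(names_, canon, function(x) length(unique(x)) == 1)))
})

test_that("sampling is deterministic and respects the config", {
  cfg <- grammar_config(scaffolds = "benzene", substituents = "chloro",
                        max_substituents = 1L)
  set.seed(1); l1 <- sample_molecule(cfg)
  set.seed(1); l2 <- sample_molecule(cfg)
  expect_identical(l1$name, "chlorobenzene")
  expect_identical(l1, l2)
  expect_error(grammar_config(scaffolds = character()), "non-empty|empty")

  # nonplanar knob: zero range keeps all z at 0; positive range moves
  # substituent heavy atoms
  cfgnp <- grammar_config(scaffolds = "benzene", substituents = "bromo",
                          nonplanar_range = 0.8)
  set.seed(4)
  lnp <- sample_molecule(cfgnp)
  expect_true(any(lnp$atoms$z != 0))
  expect_true(all(abs(lnp$atoms$z) <= 0.8))
})

test_that("generate_dataset yields unique, admitted, split molecules", {
  v <- default_vocabulary()
  man <- generate_dataset(100, seed = 9)
  expect_equal(nrow(man$records), 100L)
  expect_false(anyDuplicated(man$records$name) > 0)
  expect_equal(as.vector(table(man$records$split)[c("train", "val", "test")]),
               c(80L, 10L, 10L))
  for (nm in man$records$name) {
    s <- tokenize_name(nm, v)
    expect_identical(detokenize(s), nm)
    expect_true(passes_filters(s, v)$pass)
    # substituted molecules always carry at least one attribute
    expect_gt(length(extract_attributes(s, v)), 0L)
  }
  man2 <- generate_dataset(100, seed = 9)
  expect_identical(man$records, man2$records)

  cap_cfg <- grammar_config(scaffolds = "benzene", substituents = "chloro")
  expect_error(generate_dataset(1e5, seed = 1, cfg = cap_cfg),
               "capacity is [0-9]+")
})

test_that("grammar capacity matches exhaustive enumeration", {
  # benzene with 2 substituent types, up to 2 substituents: enumerate orbits
  cfg <- grammar_config(scaffolds = "benzene",
                        substituents = c("chloro", "methyl"),
                        min_substituents = 1L, max_substituents = 2L)
  pool <- c("chloro", "methyl")
  canon <- character()
  for (k in 1:2) {
    pos_sets <- utils::combn(6, k, simplify = FALSE)
    subs_sets <- expand.grid(rep(list(pool), k), stringsAsFactors = FALSE)
    for (p in pos_sets) for (r in seq_len(nrow(subs_sets))) {
      s <- data.frame(position = p, sub = unlist(subs_sets[r, ]))
      reps <- vapply(oracle_benzene_numberings(), function(numb)
        paste(sort(paste0(numb[s$position], ":", s$sub)), collapse = "|"),
        character(1))
      canon <- c(canon, min(reps))
    }
  }
  expect_equal(grammar_capacity(cfg), length(unique(canon)))
})
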