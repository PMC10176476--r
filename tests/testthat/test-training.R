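test_that("supervised pairs count one example per prefix plus endseq", {
  v <- default_vocabulary()
  man <- generate_dataset(5, seed = 3,
                          cfg = grammar_config(scaffolds = "benzene"),
                          fractions = c(train = 1, val = 0, test = 0))
  pairs <- make_supervised_pairs(man, v)
  for (i in seq_along(pairs$molecules)) {
    nm <- man$records$name[i]
    seq <- tokenize_name(nm, v)
    attrs <- extract_attributes(seq, v)
    expect_equal(sum(pairs$attr$mol == i), length(attrs) + 1L)
    expect_equal(sum(pairs$name$mol == i), length(seq) + 1L)

    # prefix targets reconstruct the full name in order
    tg <- pairs$name$target[pairs$name$mol == i]
    expect_identical(tg[length(tg)], endseq_id(v))
    expect_identical(detokenize(id_terms(v, tg[-length(tg)])), nm)
    # attribute targets reconstruct the sorted attribute set
    ta <- pairs$attr$target[pairs$attr$mol == i]
    expect_identical(id_terms(v, ta[-length(ta)]), attrs$attributes)
  }
  expect_identical(ncol(pairs$attr$input), 19L)
  expect_identical(ncol(pairs$name$input), 76L)
})

test_that("epoch stack sampling is uniform over combos and respects toggle", {
  expect_identical(sample_epoch_stacks(7, augment = FALSE), rep(1L, 7))
  set.seed(10)
  draws <- sample_epoch_stacks(3000, n_combos = 24L)
  expect_true(all(draws >= 1 & draws <= 24))
  chi <- stats::chisq.test(tabulate(draws, 24))
  expect_gt(chi$p.value, 1e-4)
  set.seed(99)
  a <- sample_epoch_stacks(50, 24L)
  set.seed(99)
  b <- sample_epoch_stacks(50, 24L)
  expect_identical(a, b)
  expect_error(sample_epoch_stacks(5, n_combos = 0L), "at least one")
})

test_that("analytic gradients agree with finite differences", {
  v <- term_vocabulary(c("a", "b", "c"), attributes = "a")
  cfg <- afmid:::model_config(v, "attribute", npix = 8L, channels = 3L,
                              conv_channels = c(2L, 3L), d_feature = 5L,
                              d_embed = 4L, d_hidden = 6L, d_fuse = 7L)
  m <- afmid:::init_model(cfg, seed = 3)
  set.seed(9)
  X <- matrix(rnorm(2 * 8 * 8 * 3), 2)
  mol_of <- c(1L, 1L, 2L)
  dense <- rbind(c(4L, 1L, 2L, 0L), c(4L, 0L, 0L, 0L), c(4L, 2L, 3L, 1L))
  target <- c(1L, 2L, 5L)
  res <- afmid:::.captioning_batch(m, X, mol_of, dense, target,
                                   train = FALSE)
  f <- function(params) {
    mm <- m; mm$params <- params
    afmid:::.captioning_batch(mm, X, mol_of, dense, target,
                              train = FALSE)$loss
  }
  eps <- 1e-6
  for (nm in names(m$params)) {
    idx <- sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))
    for (i in idx) {
      p1 <- m$params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- m$params; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (f(p1) - f(p2)) / (2 * eps)
      expect_equal(res$grads[[nm]][i], num, tolerance = 1e-4,
                   label = paste("grad", nm))
    }
  }
})

test_that("training runs are deterministic and logs are well formed", {
  v <- default_vocabulary()
  man <- generate_dataset(4, seed = 6,
                          cfg = grammar_config(scaffolds = "benzene",
                                               max_substituents = 1L),
                          fractions = c(train = 0.75, val = 0.25, test = 0))
  cfg <- train_config(epochs_attr = 3L, epochs_name = 3L, seed = 5L,
                      npix = 16L, d_hidden = 16L, d_fuse = 16L,
                      d_feature = 16L, conv_channels = c(2L, 4L),
                      augment_grid = FALSE)
  f1 <- train_two_stage(man, cfg, v)
  f2 <- train_two_stage(man, cfg, v)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$name_model$params, f2$name_model$params)
  expect_setequal(unique(f1$log$stage), c("attribute", "name", "validation"))
  expect_true(all(is.finite(f1$log$loss[f1$log$stage != "validation"])))

  # with grid augmentation on, the same seed still reproduces the log
  cfg_aug <- train_config(epochs_attr = 2L, epochs_name = 2L, seed = 5L,
                          npix = 16L, d_hidden = 16L, d_fuse = 16L,
                          d_feature = 16L, conv_channels = c(2L, 4L),
                          augment_grid = TRUE, idg = TRUE)
  g1 <- train_two_stage(man, cfg_aug, v)
  g2 <- train_two_stage(man, cfg_aug, v)
  expect_identical(g1$log, g2$log)

  # zero epochs: untrained but valid models
  cfg0 <- train_config(epochs_attr = 0L, epochs_name = 0L, seed = 5L,
                       npix = 16L, conv_channels = c(2L, 4L))
  f0 <- train_two_stage(man, cfg0, v)
  expect_s3_class(f0$attr_model, "mrnn_model")
  st <- small_stack(npix = 16L)
  expect_length(encode_stack(st, f0$attr_model),
                f0$attr_model$config$d_feature)
})

test_that("loss decreases and the attribute signal is informative", {
  mf <- micro_fit()
  log <- mf$fit$log
  nl <- log$loss[log$stage == "name"]
  expect_lt(mean(utils::tail(nl, 10)), 0.25 * mean(utils::head(nl, 10)))
  al <- log$loss[log$stage == "attribute"]
  expect_lt(mean(utils::tail(al, 10)), 0.5 * mean(utils::head(al, 10)))

  # teacher-forced loss with true attributes beats permuted attributes
  v <- mf$vocab
  pairs <- make_supervised_pairs(mf$man, v)
  dense <- afmid:::.densify(pairs$name$input)
  grid <- parameter_grid()
  X <- t(vapply(pairs$molecules, function(id)
    as.vector(render_stack(mf$man$layouts[[id]], params = grid[1, ],
                           npix = 24L, fov = 12.8)$planes),
    numeric(24 * 24 * 10)))
  mol_of <- pairs$name$mol
  true_loss <- afmid:::.captioning_batch(
    mf$fit$name_model, X, mol_of, dense, pairs$name$target,
    train = FALSE)$loss
  # permute the attribute slots (first 18 entries) across molecules
  set.seed(31)
  perm <- c(2, 3, 4, 5, 6, 1)
  shuf_in <- pairs$name$input
  for (i in seq_len(nrow(shuf_in))) {
    donor <- which(pairs$name$mol == perm[pairs$name$mol[i]])[1]
    shuf_in[i, 1:18] <- pairs$name$input[donor, 1:18]
  }
  shuf_loss <- afmid:::.captioning_batch(
    mf$fit$name_model, X, mol_of, afmid:::.densify(shuf_in),
    pairs$name$target, train = FALSE)$loss
  expect_lt(true_loss, shuf_loss)
})
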