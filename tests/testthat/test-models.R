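test_that("semantic inputs have the contracted shapes and padding", {
  v <- default_vocabulary()
  s0 <- assemble_attr_input(integer(), v)
  expect_length(s0, 19L)
  expect_identical(s0, c(startseq_id(v), integer(18)))

  a2 <- assemble_attr_input(c(3L, 5L), v)
  expect_identical(a2[1:3], c(startseq_id(v), 3L, 5L))
  expect_identical(a2[4:19], integer(16))

  a17 <- assemble_attr_input(1:17, v)
  expect_length(a17, 19L)
  expect_identical(sum(a17 == 0L), 1L)   # only the final slot is free
  expect_error(assemble_attr_input(1:18, v), "longer")

  n0 <- assemble_name_input(c(3L, 5L), integer(), v)
  expect_length(n0, 76L)
  expect_identical(n0[1:2], c(3L, 5L))
  expect_identical(n0[3:18], integer(16))
  expect_identical(n0[19], startseq_id(v))
  expect_identical(n0[20:76], integer(57))

  full <- assemble_name_input(1:18, rep(2L, 57), v)
  expect_identical(sum(full == 0L), 0L)  # zero-free at the boundary
  expect_error(assemble_name_input(1:19, integer(), v), "attributes")
  expect_error(assemble_name_input(1:3, rep(1L, 58), v), "history")

  # length is 76 whatever the inputs
  set.seed(4)
  for (i in 1:20) {
    na <- sample(0:18, 1); nh <- sample(0:57, 1)
    expect_length(
      assemble_name_input(rep(2L, na), rep(3L, nh), v), 76L)
  }
})

test_that("stack encoding is deterministic, finite and shape-checked", {
  v <- default_vocabulary()
  m <- stub_model("attribute", v, npix = 16L)
  st <- small_stack(npix = 16L)
  v1 <- encode_stack(st, m)
  v2 <- encode_stack(st, m)
  expect_identical(v1, v2)
  expect_length(v1, 8L)

  zero <- image_stack(array(0, c(16, 16, 10)), seq(2.8, 3.7, by = 0.1))
  expect_true(all(is.finite(encode_stack(zero, m))))

  big <- small_stack(npix = 32L)
  expect_length(encode_stack(big, m), 8L)          # resized on the fly
  expect_error(encode_stack(big, m, resize = FALSE), "expects")
  bad <- image_stack(array(0, c(16, 16, 3)), c(2.8, 2.9, 3.0))
  expect_error(encode_stack(bad, m), "planes")

  # different molecules produce different feature vectors
  other <- render_stack(build_layout("pyridine"), npix = 16L)
  expect_gt(max(abs(encode_stack(other, m) - v1)), 1e-8)
})

test_that("fusion output is a probability distribution of the right width", {
  v <- default_vocabulary()
  m <- stub_model("attribute", v)
  set.seed(6)
  for (i in 1:10) {
    p <- multimodal_fuse(m, rnorm(8), rnorm(8))
    expect_length(p, vocab_size(v))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-6)
  }
  expect_error(multimodal_fuse(m, rnorm(3), rnorm(8)), "feature")
  expect_error(multimodal_fuse(m, rnorm(8), rnorm(3)), "context")
  # deterministic for fixed weights and inputs
  expect_identical(multimodal_fuse(m, rep(1, 8), rep(0.5, 8)),
                   multimodal_fuse(m, rep(1, 8), rep(0.5, 8)))
})

test_that("decoding loops terminate under adversarial fusion heads", {
  v <- default_vocabulary()
  st <- small_stack(npix = 16L)

  always_end <- force_constant_output(stub_model("attribute", v), endseq_id(v))
  expect_length(predict_attributes(st, always_end, v), 0L)

  # a head that never emits endseq is stopped by the cap
  never_end <- force_constant_output(stub_model("attribute", v),
                                     term_ids(v, "chlor"))
  got <- predict_attributes(st, never_end, v)
  expect_lte(length(got), 17L)
  expect_identical(got$attributes, "chlor")  # deduplicated

  name_end <- force_constant_output(stub_model("name", v), endseq_id(v))
  expect_length(predict_name(st, integer(), name_end, v), 0L)
  name_loop <- force_constant_output(stub_model("name", v),
                                     term_ids(v, "benz"))
  seq_out <- predict_name(st, integer(), name_loop, v)
  expect_length(seq_out, 57L)   # cap respected, endseq excluded
  expect_true(all(seq_out$terms == "benz"))
})

test_that("term embeddings have one row per term and train away from init", {
  v <- default_vocabulary()
  m <- stub_model("name", v)
  emb <- term_embedding_vectors(m, v)
  expect_identical(nrow(emb), vocab_size(v))
  expect_identical(ncol(emb), m$config$d_embed)
  expect_identical(rownames(emb)[1:2], v$terms[1:2])

  mf <- micro_fit()
  emb0 <- term_embedding_vectors(
    afmid:::init_model(mf$fit$name_model$config,
                       seed = afmid:::.derive_seed(2L, "name-init")))
  emb1 <- term_embedding_vectors(mf$fit$name_model)
  expect_gt(max(abs(emb1 - emb0)), 1e-3)
})

test_that("a micro overfit run reproduces its training names end to end", {
  mf <- micro_fit()
  preds <- predict_manifest(mf$fit, mf$man, mf$vocab, split = "train")
  expect_identical(mean(preds$exact), 1)
  expect_identical(preds$attr_prediction, preds$attr_reference)
})

test_that("checkpoints round-trip and refuse mismatched weights", {
  v <- default_vocabulary()
  m <- stub_model("name", v)
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  expect_identical(m2$params, m$params)
  expect_identical(m2$config, m$config)
  st <- small_stack(npix = 16L)
  expect_identical(encode_stack(st, m), encode_stack(st, m2))

  bad <- m; bad$params$out_W <- bad$params$out_W[, 1:3]
  f2 <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(bad, f2)
  expect_error(load_checkpoint(f2), "do not match")
  saveRDS(list(a = 1), f2)
  expect_error(load_checkpoint(f2), "not a model checkpoint")
})
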