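# Shared fixtures: tiny vocabularies, layouts, stub models, and one cached
# micro training run reused by the model-level tests.

toy_vocab <- function() {
  term_vocabulary(c("benz", "ene", "-", "1", "2", ",", "chlor", "o", "di"),
                  attributes = c("benz", "chlor"))
}

tiny_layout <- function() {
  build_layout("benzene", data.frame(position = c(1L, 4L),
                                     sub = c("chloro", "methyl")))
}

small_stack <- function(layout = tiny_layout(), npix = 24L, ...) {
  render_stack(layout, npix = npix, fov = 12.8, ...)
}

# a real (untrained) model at miniature dimensions, cheap to build
stub_model <- function(kind = "attribute", vocab = default_vocabulary(),
                       npix = 16L, seed = 1L) {
  cfg <- afmid:::model_config(vocab, kind, npix = npix,
                              conv_channels = c(2L, 4L), d_feature = 8L,
                              d_embed = 6L, d_hidden = 8L, d_fuse = 12L)
  afmid:::init_model(cfg, seed = seed)
}

# force the fusion head to always emit one fixed token id
force_constant_output <- function(model, id) {
  model$params$out_W[] <- 0
  model$params$out_b[] <- 0
  model$params$out_b[id] <- 50
  model
}

# micro overfitting run (6 molecules) cached for the whole test session
.micro_cache <- new.env(parent = emptyenv())
micro_fit <- function() {
  if (!is.null(.micro_cache$fit)) return(.micro_cache$fit)
  vocab <- default_vocabulary()
  man <- generate_dataset(6, seed = 21,
                          cfg = grammar_config(scaffolds = "benzene",
                                               max_substituents = 2L),
                          fractions = c(train = 1, val = 0, test = 0))
  cfg <- train_config(epochs_attr = 120L, epochs_name = 250L, seed = 2L,
                      npix = 24L, d_hidden = 48L, d_fuse = 96L)
  fit <- train_two_stage(man, cfg, vocab)
  .micro_cache$fit <- list(fit = fit, man = man, vocab = vocab)
  .micro_cache$fit
}

# the mini benchmark of the end-to-end sanity check: 50 training and 20
# held-out molecules from the default grammar
mini_benchmark_manifest <- function(seed = 11L) {
  generate_dataset(70, seed = seed,
                   fractions = c(train = 50 / 70, val = 0, test = 20 / 70))
}

mini_benchmark_config <- function(seed = 1L) {
  train_config(epochs_attr = 300L, epochs_name = 400L, seed = seed)
}
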