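#' Captioning model configuration
#'
#' Both networks share one architecture family: a small convolutional tower
#' that treats the 10 constant-height planes as input channels and encodes
#' the stack into a feature vector `v`; an embedding + LSTM branch that
#' summarizes the padded semantic input; and a multimodal fusion head that
#' concatenates `v` with the recurrent summary and maps it through fully
#' connected layers to a probability distribution over the vocabulary. The
#' attribute network (`kind = "attribute"`) consumes semantic inputs of fixed
#' length 19 (up to 17 attributes plus the `startseq`/`endseq` bookkeeping);
#' the name network (`kind = "name"`) consumes semantic inputs of length 76
#' (18 attribute slots, `startseq`, and up to 57 term-prediction slots).
#'
#' @param vocab a [term_vocabulary()].
#' @param kind `"attribute"` (first stage) or `"name"` (second stage).
#' @param npix input image size per plane (planes are resized if needed).
#' @param channels number of planes per stack.
#' @param conv_channels integer vector of channel counts for the
#'   convolutional tower (stride-2, 3x3, 'same' padding each).
#' @param d_feature dimension of the CNN output `v`.
#' @param d_embed term-embedding dimension (default 32).
#' @param d_hidden LSTM width.
#' @param d_fuse width of the fusion hidden layer.
#' @param dropout dropout rate applied to `v` and the fusion hidden layer
#'   during training (0 disables).
#' @param max_attributes,max_terms admission bounds mirrored by the decoder
#'   caps.
#' @return object of class `mrnn_config`.
#' @export
model_config <- function(vocab, kind = c("attribute", "name"),
                         npix = 32L, channels = 10L,
                         conv_channels = c(8L, 16L),
                         d_feature = 64L, d_embed = 32L, d_hidden = 64L,
                         d_fuse = 128L, dropout = 0,
                         max_attributes = 17L, max_terms = 57L) {
  kind <- match.arg(kind)
  v_size <- vocab_size(vocab)
  sem_len <- if (kind == "attribute") max_attributes + 2L
             else (max_attributes + 1L) + 1L + max_terms
  structure(
    list(kind = kind, npix = as.integer(npix), channels = as.integer(channels),
         conv_channels = as.integer(conv_channels),
         d_feature = as.integer(d_feature), d_embed = as.integer(d_embed),
         d_hidden = as.integer(d_hidden), d_fuse = as.integer(d_fuse),
         dropout = dropout, vocab_size = v_size,
         max_attributes = as.integer(max_attributes),
         max_terms = as.integer(max_terms),
         semantic_length = as.integer(sem_len)),
    class = "mrnn_config"
  )
}

# conv geometries for the tower (computed once per model)
.tower_geoms <- function(cfg) {
  geoms <- list()
  size <- cfg$npix
  c_in <- cfg$channels
  for (i in seq_along(cfg$conv_channels)) {
    geoms[[i]] <- .conv_geom(size, c_in, k = 3L, stride = 2L)
    size <- geoms[[i]]$out
    c_in <- cfg$conv_channels[i]
  }
  geoms
}

#' Initialize a multimodal recurrent captioning model
#'
#' Glorot-uniform weights drawn from a seeded stream; biases zero (LSTM
#' forget-gate bias 1).
#'
#' @param cfg a [model_config()].
#' @param seed integer seed for the weight draw.
#' @return object of class `mrnn_model`: list with `config` and `params`.
#' @export
init_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "mrnn_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  geoms <- .tower_geoms(cfg)
  p <- list()
  c_in <- cfg$channels
  for (i in seq_along(cfg$conv_channels)) {
    kk <- 9L * c_in
    p[[paste0("conv", i, "_W")]] <- .glorot(kk, cfg$conv_channels[i])
    p[[paste0("conv", i, "_b")]] <- numeric(cfg$conv_channels[i])
    c_in <- cfg$conv_channels[i]
  }
  flat <- utils::tail(geoms, 1)[[1]]$out^2 * c_in
  p$fc_W <- .glorot(flat, cfg$d_feature)
  p$fc_b <- numeric(cfg$d_feature)
  p$emb <- .glorot(cfg$vocab_size, cfg$d_embed) # one row per id 1..V
  H <- cfg$d_hidden
  p$lstm_W <- .glorot(cfg$d_embed, 4L * H, cfg$d_embed, 4L * H)
  p$lstm_U <- .glorot(H, 4L * H, H, 4L * H)
  p$lstm_b <- rep(c(0, 1, 0, 0), each = H)   # forget-gate bias 1
  p$fuse1_W <- .glorot(cfg$d_feature + H, cfg$d_fuse)
  p$fuse1_b <- numeric(cfg$d_fuse)
  p$out_W <- .glorot(cfg$d_fuse, cfg$vocab_size)
  p$out_b <- numeric(cfg$vocab_size)
  structure(list(config = cfg, params = p, geoms = geoms),
            class = "mrnn_model")
}

#' @export
print.mrnn_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<mrnn_model> %s network, %d parameters (emb %d, lstm %d, v %d)\n",
              x$config$kind, np, x$config$d_embed, x$config$d_hidden,
              x$config$d_feature))
  invisible(x)
}

# stack -> flat CNN input row vector (resizing planes when configured size
# differs from the rendered size)
.stack_to_input <- function(stack, cfg, resize = TRUE) {
  d <- dim(stack$planes)
  if (d[3] != cfg$channels)
    stop(sprintf("stack has %d planes; the model expects %d", d[3],
                 cfg$channels))
  planes <- stack$planes
  if (d[1] != cfg$npix || d[2] != cfg$npix) {
    if (!resize)
      stop(sprintf("stack is %dx%d px; the model expects %dx%d",
                   d[1], d[2], cfg$npix, cfg$npix))
    planes <- vapply(seq_len(d[3]), function(p)
      EBImage::resize(stack$planes[, , p], w = cfg$npix, h = cfg$npix),
      matrix(0, cfg$npix, cfg$npix))
  }
  as.vector(planes)
}

# CNN forward on a batch (rows = flattened stacks); returns v and caches
.encode_forward <- function(model, X, train = FALSE, dropmask = NULL) {
  caches <- list()
  a <- X
  for (i in seq_along(model$config$conv_channels)) {
    fw <- .conv_forward(a, model$params[[paste0("conv", i, "_W")]],
                        model$params[[paste0("conv", i, "_b")]],
                        model$geoms[[i]])
    caches[[i]] <- fw$cache
    a <- fw$out
  }
  z <- sweep(a %*% model$params$fc_W, 2L, model$params$fc_b, `+`)
  v <- .relu(z)
  if (train && !is.null(dropmask)) v <- v * dropmask
  list(v = v, conv_caches = caches, flat = a, fc_z = z)
}

.encode_backward <- function(model, enc, dv) {
  dz <- dv * (enc$fc_z > 0)
  g <- list(fc_W = crossprod(enc$flat, dz), fc_b = colSums(dz))
  da <- tcrossprod(dz, model$params$fc_W)
  for (i in rev(seq_along(model$config$conv_channels))) {
    bw <- .conv_backward(da, enc$conv_caches[[i]])
    g[[paste0("conv", i, "_W")]] <- bw$dW
    g[[paste0("conv", i, "_b")]] <- bw$db
    da <- bw$dX
  }
  g
}

#' Encode an image stack into the CNN feature vector
#'
#' Deterministic in inference mode (dropout disabled). Planes are bilinearly
#' resized to the configured input size when necessary; the plane count must
#' match the model.
#'
#' @param stack an [image_stack()].
#' @param model an [init_model()] result (either network).
#' @param resize resize planes to the configured size (default `TRUE`; with
#'   `FALSE` a size mismatch is an error).
#' @return numeric vector `v` of length `d_feature`.
#' @export
encode_stack <- function(stack, model, resize = TRUE) {
  stopifnot(inherits(model, "mrnn_model"))
  x <- matrix(.stack_to_input(stack, model$config, resize = resize), 1L)
  as.vector(.encode_forward(model, x)$v)
}

#' Assemble the attribute-network semantic input
#'
#' The fixed-length-19 integer vector `(startseq, Y^A_1, ..., Y^A_{t-1},
#' 0, ..., 0)`: the `startseq` token followed by the attributes predicted so
#' far, zero-padded.
#'
#' @param history integer ids of previously predicted attributes (possibly
#'   empty), or an `attribute_set`.
#' @param vocab the [term_vocabulary()].
#' @param max_attributes attribute cap (17).
#' @return integer vector of length `max_attributes + 2`.
#' @export
assemble_attr_input <- function(history, vocab, max_attributes = 17L) {
  ids <- if (inherits(history, "attribute_set")) history$ids
         else as.integer(history)
  if (length(ids) > max_attributes)
    stop("attribute history longer than ", max_attributes)
  out <- integer(max_attributes + 2L)
  out[seq_len(length(ids) + 1L)] <- c(startseq_id(vocab), ids)
  out
}

#' Assemble the name-network semantic input
#'
#' The fixed-length-76 integer vector `(Y^A_1, ..., Y^A_18, startseq, Y_1,
#' ..., Y_{t-1}, 0, ..., 0)`: 18 attribute slots (zero-padded), the
#' `startseq` token, and 57 term-history slots (zero-padded).
#'
#' @param attrs attribute ids (or an `attribute_set`), at most 18.
#' @param history integer ids of previously predicted terms, at most 57.
#' @param vocab the [term_vocabulary()].
#' @param max_attributes attribute slot count minus one (17; slots = 18).
#' @param max_terms term-history slot count (57).
#' @return integer vector of length `max_attributes + 1 + 1 + max_terms`.
#' @export
assemble_name_input <- function(attrs, history, vocab,
                                max_attributes = 17L, max_terms = 57L) {
  a_ids <- if (inherits(attrs, "attribute_set")) attrs$ids
           else as.integer(attrs)
  h_ids <- as.integer(history)
  n_slots <- max_attributes + 1L
  if (length(a_ids) > n_slots)
    stop("more than ", n_slots, " attributes")
  if (length(h_ids) > max_terms)
    stop("term history longer than ", max_terms)
  out <- integer(n_slots + 1L + max_terms)
  out[seq_along(a_ids)] <- a_ids
  out[n_slots + 1L] <- startseq_id(vocab)
  out[n_slots + 1L + seq_along(h_ids)] <- h_ids
  out
}

# run the LSTM over the dense (non-zero) tokens of one semantic input
.semantic_summary <- function(model, sem) {
  dense <- sem[sem > 0L]
  ids <- matrix(dense, 1L, max(length(dense), 1L))
  fwd <- .lstm_forward(ids, model$params$emb, model$params$lstm_W,
                       model$params$lstm_U, model$params$lstm_b,
                       keep_cache = FALSE)
  as.vector(fwd$h_final)
}

#' Multimodal fusion head
#'
#' Concatenates the CNN feature vector with the recurrent context summary
#' and maps the result through the fully connected fusion layers to a
#' probability vector over the vocabulary (softmax output).
#'
#' @param model an [init_model()] result.
#' @param v CNN feature vector (`d_feature`).
#' @param context recurrent summary vector (`d_hidden`).
#' @return numeric probability vector of length `vocab_size` (non-negative,
#'   sums to 1).
#' @export
multimodal_fuse <- function(model, v, context) {
  cfg <- model$config
  if (length(v) != cfg$d_feature)
    stop("feature vector has length ", length(v), "; expected ",
         cfg$d_feature)
  if (length(context) != cfg$d_hidden)
    stop("context vector has length ", length(context), "; expected ",
         cfg$d_hidden)
  z <- matrix(c(v, context), 1L)
  h1 <- .relu(sweep(z %*% model$params$fuse1_W, 2L, model$params$fuse1_b,
                    `+`))
  logits <- sweep(h1 %*% model$params$out_W, 2L, model$params$out_b, `+`)
  p <- as.vector(.softmax_rows(logits))
  names(p) <- NULL
  p
}

# greedy argmax with lowest-id tie break
.argmax_id <- function(p) which.max(p)

#' Predict the attribute set of an image stack
#'
#' Greedy decoding loop of the first-stage network: at each step the padded
#' semantic input is assembled from the prediction history, the fusion head
#' scores the vocabulary, and the most likely token (lowest id on ties) is
#' appended. The loop stops at the `endseq` token or after the attribute cap.
#' Raw loop history may contain duplicates; the returned set is deduplicated
#' and re-sorted by the canonical attribute comparator.
#'
#' @param stack an [image_stack()].
#' @param model the attribute-stage [init_model()] result.
#' @param vocab the [term_vocabulary()].
#' @return an `attribute_set`.
#' @export
predict_attributes <- function(stack, model, vocab) {
  stopifnot(model$config$kind == "attribute")
  v <- encode_stack(stack, model)
  hist <- integer()
  cap <- model$config$max_attributes
  repeat {
    sem <- assemble_attr_input(hist, vocab, cap)
    h <- .semantic_summary(model, sem)
    p <- multimodal_fuse(model, v, h)
    id <- .argmax_id(p)
    if (id == endseq_id(vocab) || id == startseq_id(vocab)) break
    hist <- c(hist, id)
    if (length(hist) >= cap) break
  }
  terms <- unique(id_terms(vocab, hist))
  terms <- terms[vocab$is_attribute[match(terms, vocab$terms)]]
  attribute_set(attribute_order(terms), vocab)
}

#' Predict the term sequence of an image stack given its attributes
#'
#' Greedy decoding loop of the second-stage network, conditioned on the
#' attribute set (predicted, or ground truth for teacher-forced evaluation).
#' Stops at `endseq` or after the term cap; `endseq` is excluded from the
#' returned sequence.
#'
#' @param stack an [image_stack()].
#' @param attrs an `attribute_set` (or integer ids).
#' @param model the name-stage [init_model()] result.
#' @param vocab the [term_vocabulary()].
#' @return a [term_sequence()].
#' @export
predict_name <- function(stack, attrs, model, vocab) {
  stopifnot(model$config$kind == "name")
  v <- encode_stack(stack, model)
  a_ids <- if (inherits(attrs, "attribute_set")) attrs$ids
           else as.integer(attrs)
  hist <- integer()
  cap <- model$config$max_terms
  repeat {
    sem <- assemble_name_input(a_ids, hist, vocab,
                               model$config$max_attributes, cap)
    h <- .semantic_summary(model, sem)
    p <- multimodal_fuse(model, v, h)
    id <- .argmax_id(p)
    if (id == endseq_id(vocab) || id == startseq_id(vocab)) break
    hist <- c(hist, id)
    if (length(hist) >= cap) break
  }
  term_sequence(id_terms(vocab, hist), vocab)
}

#' Term-embedding vectors of a trained model
#'
#' One row per vocabulary term (specials included, padding excluded by
#' construction), taken from the model's embedding layer.
#'
#' @param model an [init_model()] result (typically the name network).
#' @param vocab optional [term_vocabulary()] used to name the rows.
#' @return numeric matrix, rows named by term.
#' @export
term_embedding_vectors <- function(model, vocab = NULL) {
  emb <- model$params$emb
  if (!is.null(vocab)) rownames(emb) <- vocab$terms
  emb
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single serialized file holding the configuration
#' snapshot, the weights and the package version. The loader refuses
#' checkpoints whose weights do not match their configuration.
#'
#' @param model an [init_model()] result.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mrnn_model"))
  obj <- list(config = model$config, params = model$params,
              package_version = as.character(utils::packageVersion("afmid")))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!all(c("config", "params") %in% names(obj)))
    stop("not a model checkpoint: ", path)
  model <- structure(list(config = obj$config, params = obj$params,
                          geoms = .tower_geoms(obj$config)),
                     class = "mrnn_model")
  # consistency: output layer width must equal the configured vocabulary size
  if (ncol(model$params$out_W) != model$config$vocab_size ||
      nrow(model$params$emb) != model$config$vocab_size)
    stop("checkpoint weights do not match their configuration: ", path)
  model
}
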