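#' Training configuration
#'
#' All hyperparameters of the two-stage training live here; the seed fully
#' determines weight initialization, epoch-wise augmentation draws and hence
#' the metric log. Training is full-batch Adam with teacher forcing: each
#' molecule contributes one example per prefix of its attribute set (first
#' stage) and of its term decomposition (second stage), and the per-step loss
#' is categorical cross-entropy on the next token (padding positions are
#' never scored because examples are built per prefix).
#'
#' @param epochs_attr,epochs_name Adam steps for the attribute and name
#'   stages.
#' @param lr learning rate.
#' @param seed master seed; named substreams are derived from it.
#' @param npix rendered/model image size used for training.
#' @param fov field of view in Angstrom.
#' @param augment_grid draw a fresh operational-parameter combo per molecule
#'   per epoch (the rendering-parameter augmentation protocol); with `FALSE`
#'   combo 1 is always used.
#' @param n_amplitude,n_stiffness augmentation grid shape (6 x 4 = 24).
#' @param idg apply stack-coherent image deformations on the fly each epoch.
#' @param idg_cfg an [idg_config()].
#' @param d_feature,d_embed,d_hidden,d_fuse,conv_channels,dropout model
#'   dimensions, passed to [model_config()].
#' @param val_every compute the validation exact-match rate every this many
#'   name-stage epochs (0 = only after training, and only when a validation
#'   split exists).
#' @param verbose print per-epoch losses.
#' @return object of class `train_config`.
#' @export
train_config <- function(epochs_attr = 150L, epochs_name = 400L, lr = 2e-3,
                         seed = 1L, npix = 32L, fov = 12.8,
                         augment_grid = TRUE, n_amplitude = 6L,
                         n_stiffness = 4L, idg = FALSE,
                         idg_cfg = idg_config(),
                         d_feature = 64L, d_embed = 32L, d_hidden = 64L,
                         d_fuse = 128L, conv_channels = c(8L, 16L),
                         dropout = 0, val_every = 0L, verbose = FALSE) {
  structure(
    list(epochs_attr = as.integer(epochs_attr),
         epochs_name = as.integer(epochs_name),
         lr = lr, seed = as.integer(seed), npix = as.integer(npix),
         fov = fov, augment_grid = isTRUE(augment_grid),
         n_amplitude = as.integer(n_amplitude),
         n_stiffness = as.integer(n_stiffness),
         idg = isTRUE(idg), idg_cfg = idg_cfg,
         d_feature = as.integer(d_feature), d_embed = as.integer(d_embed),
         d_hidden = as.integer(d_hidden), d_fuse = as.integer(d_fuse),
         conv_channels = as.integer(conv_channels), dropout = dropout,
         val_every = as.integer(val_every), verbose = isTRUE(verbose)),
    class = "train_config"
  )
}

#' Build per-time-step supervised examples for both networks
#'
#' For every molecule: the attribute network gets one example per prefix of
#' its sorted attribute set (targets: each attribute in order, then
#' `endseq`); the name network gets one example per prefix of its term
#' decomposition (targets: each term in order, then `endseq`), with the full
#' attribute set in the conditioning slots. Semantic inputs are the padded
#' vectors of [assemble_attr_input()] / [assemble_name_input()].
#'
#' @param manifest an [generate_dataset()] manifest (or a subset of one).
#' @param vocab the [term_vocabulary()].
#' @param split optional split name to restrict to (`"train"`, ...).
#' @return list with `molecules` (ids) and two example sets `attr` and
#'   `name`, each a list of `mol` (molecule index), `input` (padded semantic
#'   matrix), `target` (next-token id).
#' @export
make_supervised_pairs <- function(manifest, vocab, split = NULL) {
  rec <- manifest$records
  if (!is.null(split)) rec <- rec[rec$split %in% split, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no molecules in the requested split")
  end_id <- endseq_id(vocab)

  attr_mol <- integer(); attr_in <- list(); attr_tg <- integer()
  name_mol <- integer(); name_in <- list(); name_tg <- integer()
  for (i in seq_len(nrow(rec))) {
    seq <- tokenize_name(rec$name[i], vocab)
    flt <- passes_filters(seq, vocab)
    if (!flt$pass)
      stop("name fails admission filters (", flt$reason, "): ", rec$name[i])
    attrs <- extract_attributes(seq, vocab)
    n_a <- length(attrs$ids)
    for (t in seq_len(n_a + 1L)) {
      attr_mol <- c(attr_mol, i)
      attr_in[[length(attr_in) + 1L]] <-
        assemble_attr_input(attrs$ids[seq_len(t - 1L)], vocab)
      attr_tg <- c(attr_tg, if (t <= n_a) attrs$ids[t] else end_id)
    }
    n_t <- length(seq$ids)
    for (t in seq_len(n_t + 1L)) {
      name_mol <- c(name_mol, i)
      name_in[[length(name_in) + 1L]] <-
        assemble_name_input(attrs$ids, seq$ids[seq_len(t - 1L)], vocab)
      name_tg <- c(name_tg, if (t <= n_t) seq$ids[t] else end_id)
    }
  }
  list(
    molecules = rec$id,
    attr = list(mol = attr_mol, input = do.call(rbind, attr_in),
                target = attr_tg),
    name = list(mol = name_mol, input = do.call(rbind, name_in),
                target = name_tg)
  )
}

# left-align the non-zero tokens of each padded semantic row (the masked
# LSTM consumes dense prefixes; interior padding carries no information)
.densify <- function(input) {
  t(apply(input, 1L, function(r) {
    d <- r[r > 0L]
    c(d, integer(ncol(input) - length(d)))
  }))
}

#' Draw one operational-parameter combo per molecule for an epoch
#'
#' Under the augmentation protocol each molecule is fed through a different,
#' uniformly drawn rendering-parameter combination in each epoch; with
#' augmentation disabled every molecule uses combo 1. Draws come from the
#' current RNG stream.
#'
#' @param n_molecules number of molecules.
#' @param n_combos number of parameter combinations (24 for the default
#'   grid).
#' @param augment logical toggle.
#' @return integer vector of combo indices, one per molecule.
#' @export
sample_epoch_stacks <- function(n_molecules, n_combos = 24L, augment = TRUE) {
  if (n_combos < 1L) stop("need at least one rendered parameter combo")
  if (!augment) return(rep(1L, n_molecules))
  sample.int(n_combos, n_molecules, replace = TRUE)
}

# full joint forward/backward for one batch of (stack, semantic, target)
# examples. X: unique-stack inputs (M x D); mol_of maps examples to rows of
# X. Returns loss and the full gradient list.
.captioning_batch <- function(model, X, mol_of, dense_ids, target,
                              train = TRUE, dropout = 0) {
  p <- model$params
  n <- length(target)
  m <- nrow(X)
  mask_v <- if (train && dropout > 0)
    matrix(stats::rbinom(m * model$config$d_feature, 1L, 1 - dropout) /
             (1 - dropout), m) else NULL
  enc <- .encode_forward(model, X, train = train, dropmask = mask_v)
  v_ex <- enc$v[mol_of, , drop = FALSE]

  fwd <- .lstm_forward(dense_ids, p$emb, p$lstm_W, p$lstm_U, p$lstm_b)
  h <- fwd$h_final

  z <- cbind(v_ex, h)
  pre1 <- sweep(z %*% p$fuse1_W, 2L, p$fuse1_b, `+`)
  h1 <- .relu(pre1)
  mask_h1 <- if (train && dropout > 0)
    matrix(stats::rbinom(length(h1), 1L, 1 - dropout) / (1 - dropout),
           nrow(h1)) else NULL
  if (!is.null(mask_h1)) h1 <- h1 * mask_h1
  logits <- sweep(h1 %*% p$out_W, 2L, p$out_b, `+`)
  prob <- .softmax_rows(logits)
  picked <- prob[cbind(seq_len(n), target)]
  loss <- -mean(log(pmax(picked, 1e-300)))

  dlogit <- prob
  dlogit[cbind(seq_len(n), target)] <- dlogit[cbind(seq_len(n), target)] - 1
  dlogit <- dlogit / n
  g <- list(out_W = crossprod(h1, dlogit), out_b = colSums(dlogit))
  dh1 <- tcrossprod(dlogit, p$out_W)
  if (!is.null(mask_h1)) dh1 <- dh1 * mask_h1
  dpre1 <- dh1 * (pre1 > 0)
  g$fuse1_W <- crossprod(z, dpre1)
  g$fuse1_b <- colSums(dpre1)
  dz <- tcrossprod(dpre1, p$fuse1_W)
  d_v <- model$config$d_feature
  dv_ex <- dz[, seq_len(d_v), drop = FALSE]
  dh <- dz[, d_v + seq_len(model$config$d_hidden), drop = FALSE]

  lb <- .lstm_backward(dh, fwd, p$emb, p$lstm_W, p$lstm_U)
  g$lstm_W <- lb$dW; g$lstm_U <- lb$dU; g$lstm_b <- lb$db; g$emb <- lb$demb

  dv <- matrix(0, m, d_v)
  agg <- rowsum(dv_ex, group = mol_of)
  dv[as.integer(rownames(agg)), ] <- agg
  if (!is.null(mask_v)) dv <- dv * mask_v
  g <- c(g, .encode_backward(model, enc, dv))
  list(loss = loss, grads = g)
}

# train one stage (full-batch Adam over the supervised examples)
.train_stage <- function(model, pairs_stage, get_input, epochs, cfg,
                         stage_label, log_env) {
  dense_ids <- .densify(pairs_stage$input)
  mols <- sort(unique(pairs_stage$mol))
  mol_of <- match(pairs_stage$mol, mols)
  state <- .adam_init(model$params)
  for (ep in seq_len(max(epochs, 0L))) {
    X <- get_input(mols, ep, stage_label)
    res <- .captioning_batch(model, X, mol_of, dense_ids,
                             pairs_stage$target, train = TRUE,
                             dropout = model$config$dropout)
    if (!is.finite(res$loss))
      stop("training diverged at ", stage_label, " epoch ", ep,
           " (non-finite loss); lower the learning rate")
    upd <- .adam_step(model$params, res$grads, state, lr = cfg$lr)
    model$params <- upd$params
    state <- upd$state
    log_env$rows[[length(log_env$rows) + 1L]] <-
      data.frame(stage = stage_label, epoch = ep, loss = res$loss,
                 val_exact = NA_real_)
    if (cfg$verbose && (ep %% 25L == 0L || ep == 1L))
      message(sprintf("[%s] epoch %d loss %.5f", stage_label, ep, res$loss))
  }
  model
}

#' Two-stage supervised training
#'
#' Trains the attribute network, then the attribute-conditioned name network
#' (teacher forcing: ground-truth prefixes and ground-truth attribute sets;
#' free-running greedy decoding is used at inference). Each epoch every
#' molecule is rendered under one operational-parameter combo drawn for that
#' epoch (augmentation protocol), optionally followed by an image
#' deformation. Fixed seeds give bitwise-reproducible metric logs on one
#' platform.
#'
#' @param manifest a [generate_dataset()] manifest.
#' @param cfg a [train_config()].
#' @param vocab the [term_vocabulary()].
#' @return list with `attr_model`, `name_model`, `log` (data frame: stage,
#'   epoch, loss, val_exact), `grid`, `config`.
#' @export
train_two_stage <- function(manifest, cfg = train_config(),
                            vocab = default_vocabulary()) {
  stopifnot(inherits(manifest, "afm_manifest"), inherits(cfg, "train_config"))
  old <- .save_rng(); on.exit(.restore_rng(old))

  pairs <- make_supervised_pairs(manifest, vocab, split = "train")
  grid <- parameter_grid(cfg$n_amplitude, cfg$n_stiffness)
  n_combos <- nrow(grid)

  mc_attr <- model_config(vocab, "attribute", npix = cfg$npix,
                          conv_channels = cfg$conv_channels,
                          d_feature = cfg$d_feature, d_embed = cfg$d_embed,
                          d_hidden = cfg$d_hidden, d_fuse = cfg$d_fuse,
                          dropout = cfg$dropout)
  mc_name <- model_config(vocab, "name", npix = cfg$npix,
                          conv_channels = cfg$conv_channels,
                          d_feature = cfg$d_feature, d_embed = cfg$d_embed,
                          d_hidden = cfg$d_hidden, d_fuse = cfg$d_fuse,
                          dropout = cfg$dropout)
  attr_model <- init_model(mc_attr, seed = .derive_seed(cfg$seed, "attr-init"))
  name_model <- init_model(mc_name, seed = .derive_seed(cfg$seed, "name-init"))

  # stack cache: molecule x combo, rendered at the model input size
  cache <- new.env(parent = emptyenv())
  render_one <- function(id, combo) {
    key <- paste0(id, "#", combo)
    if (exists(key, envir = cache, inherits = FALSE)) return(cache[[key]])
    st <- render_stack(manifest$layouts[[id]], params = grid[combo, ],
                       npix = cfg$npix, fov = cfg$fov, molecule_id = id)
    cache[[key]] <- as.vector(st$planes)
    cache[[key]]
  }
  get_input <- function(mol_idx, epoch, stage_label) {
    ids <- pairs$molecules[mol_idx]
    combos <- sample_epoch_stacks(length(ids), n_combos, cfg$augment_grid)
    X <- t(vapply(seq_along(ids), function(j) render_one(ids[j], combos[j]),
                  numeric(cfg$npix^2 * 10L)))
    if (cfg$idg) {
      for (j in seq_len(nrow(X))) {
        st <- image_stack(array(X[j, ], c(cfg$npix, cfg$npix, 10L)),
                          seq(2.8, 3.7, by = 0.1))
        X[j, ] <- as.vector(apply_idg(st, cfg$idg_cfg)$planes)
      }
    }
    X
  }

  log_env <- new.env(parent = emptyenv()); log_env$rows <- list()

  set.seed(.derive_seed(cfg$seed, "attr-epochs"))
  attr_model <- .train_stage(attr_model, pairs$attr, get_input,
                             cfg$epochs_attr, cfg, "attribute", log_env)
  set.seed(.derive_seed(cfg$seed, "name-epochs"))
  name_model <- .train_stage(name_model, pairs$name, get_input,
                             cfg$epochs_name, cfg, "name", log_env)

  log <- do.call(rbind, log_env$rows)
  if (is.null(log))
    log <- data.frame(stage = character(), epoch = integer(),
                      loss = numeric(), val_exact = numeric())

  # validation exact match (free-running, predicted attributes)
  has_val <- any(manifest$records$split == "val")
  if (has_val) {
    preds <- predict_manifest(list(attr_model = attr_model,
                                   name_model = name_model),
                              manifest, vocab, split = "val")
    log <- rbind(log, data.frame(stage = "validation", epoch = NA_integer_,
                                 loss = NA_real_,
                                 val_exact = mean(preds$exact)))
  }
  list(attr_model = attr_model, name_model = name_model, log = log,
       grid = grid, config = cfg)
}

#' Free-running prediction over a manifest
#'
#' Renders each molecule's stack (combo 1 of the parameter grid, no
#' deformation), predicts its attribute set and name, and reports them next
#' to the ground truth. The attribute conditioning of the name network can
#' be switched between the predicted sets, the ground-truth sets, or
#' ground-truth sets shuffled between molecules (ablation baseline).
#'
#' @param models list with `attr_model` and `name_model`.
#' @param manifest an [generate_dataset()] manifest.
#' @param vocab the [term_vocabulary()].
#' @param split optional split restriction.
#' @param attrs_mode `"predicted"`, `"truth"`, or `"shuffled"`.
#' @param shuffle_seed seed for the shuffled-attribute permutation.
#' @return data frame: `id`, `reference`, `prediction`, `exact`,
#'   `attr_reference`, `attr_prediction` (comma-joined attribute terms).
#' @export
predict_manifest <- function(models, manifest, vocab, split = NULL,
                             attrs_mode = c("predicted", "truth", "shuffled"),
                             shuffle_seed = 1L) {
  attrs_mode <- match.arg(attrs_mode)
  rec <- manifest$records
  if (!is.null(split)) rec <- rec[rec$split %in% split, , drop = FALSE]
  if (nrow(rec) == 0L) stop("no molecules in the requested split")
  npix <- models$name_model$config$npix
  grid <- parameter_grid()

  truth_attrs <- lapply(rec$name, function(nm)
    extract_attributes(tokenize_name(nm, vocab), vocab))
  perm <- seq_len(nrow(rec))
  if (attrs_mode == "shuffled" && nrow(rec) > 1L) {
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(shuffle_seed) %% .Machine$integer.max)
    repeat {   # permutation without fixed points where possible
      perm <- sample.int(nrow(rec))
      if (!any(perm == seq_along(perm))) break
    }
  }

  out <- vector("list", nrow(rec))
  for (i in seq_len(nrow(rec))) {
    st <- render_stack(manifest$layouts[[rec$id[i]]], params = grid[1L, ],
                       npix = npix, fov = 12.8, molecule_id = rec$id[i])
    pred_attrs <- switch(attrs_mode,
      predicted = predict_attributes(st, models$attr_model, vocab),
      truth = truth_attrs[[i]],
      shuffled = truth_attrs[[perm[i]]])
    pred_seq <- predict_name(st, pred_attrs, models$name_model, vocab)
    out[[i]] <- data.frame(
      id = rec$id[i],
      reference = rec$name[i],
      prediction = detokenize(pred_seq),
      exact = detokenize(pred_seq) == rec$name[i],
      attr_reference = paste(truth_attrs[[i]]$attributes, collapse = ","),
      attr_prediction = paste(pred_attrs$attributes, collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
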