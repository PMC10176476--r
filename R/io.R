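# Workbench: on-disk formats, config snapshots, and the command surface the
# CLI script wraps. Every artifact a run produces is accompanied by a JSON
# config snapshot sufficient to regenerate it.

#' Write / read a dataset manifest directory
#'
#' The manifest directory contains `manifest.tsv` (id, IUPAC name, scaffold,
#' split), and `config.json` (grammar configuration, seed, split fractions).
#' Layout geometry is not serialized: the generator is deterministic, so
#' `read_manifest()` regenerates the layouts from the snapshot and verifies
#' the names against the table.
#'
#' @param manifest an [generate_dataset()] result.
#' @param dir output directory.
#' @param force overwrite an existing directory.
#' @export
write_manifest <- function(manifest, dir, force = FALSE) {
  stopifnot(inherits(manifest, "afm_manifest"))
  if (dir.exists(dir) && length(list.files(dir)) > 0L && !force)
    stop("output directory exists (use force = TRUE): ", dir)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(manifest$records, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  snap <- list(
    n = nrow(manifest$records),
    seed = manifest$seed,
    fractions = as.list(table(manifest$records$split) /
                          nrow(manifest$records)),
    grammar = unclass(manifest$config)
  )
  jsonlite::write_json(snap, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(dir) {
  tsv <- file.path(dir, "manifest.tsv")
  cfgf <- file.path(dir, "config.json")
  if (!file.exists(tsv) || !file.exists(cfgf))
    stop("not a manifest directory (need manifest.tsv + config.json): ", dir)
  rec <- utils::read.table(tsv, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  snap <- jsonlite::read_json(cfgf, simplifyVector = TRUE)
  g <- snap$grammar
  cfg <- grammar_config(scaffolds = g$scaffolds,
                        substituents = g$substituents,
                        min_substituents = g$min_substituents,
                        max_substituents = g$max_substituents,
                        nonplanar_range = g$nonplanar_range)
  frac <- c(train = snap$fractions$train %||% 0,
            val = snap$fractions$val %||% 0,
            test = snap$fractions$test %||% 0)
  man <- generate_dataset(snap$n, snap$seed, cfg, fractions = frac)
  if (!identical(man$records$name, rec$name))
    stop("manifest does not match its config snapshot: ", dir)
  man
}

#' Lossless stack container
#'
#' One serialized file per stack (array of planes + height vector +
#' parameters); written and read back bitwise-identically.
#'
#' @param stack an [image_stack()].
#' @param path file path (`.rds`).
#' @export
save_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  saveRDS(unclass(stack), path)
  invisible(path)
}

#' @rdname save_stack
#' @export
load_stack <- function(path) {
  obj <- readRDS(path)
  image_stack(obj$planes, obj$heights, obj$params, obj$molecule_id)
}

#' Export the planes of a stack as 16-bit TIFF images
#'
#' One image per plane, named by height; 16-bit depth avoids quantizing the
#' contrast. Pixel values are clipped to \[0, 1\].
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if missing).
#' @return the written file paths, invisibly.
#' @export
export_stack_tiff <- function(stack, dir) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(stack$heights))
  for (p in seq_along(stack$heights)) {
    img <- pmin(pmax(stack$planes[, , p], 0), 1)
    paths[p] <- file.path(dir, sprintf("plane_%04.1fA.tif",
                                       stack$heights[p]))
    tiff::writeTIFF(img, paths[p], bits.per.sample = 16L)
  }
  invisible(paths)
}

.log_msg <- function(...) message(sprintf(...))

#' Simulate a dataset to disk
#'
#' Generates a named molecule set, writes the manifest and config snapshot,
#' and renders one stack file per molecule and requested parameter combo
#' (default: combo 1 only; training re-renders other combos on the fly).
#' Deterministic under a fixed seed; an existing non-empty output directory
#' is refused without `force`.
#'
#' @param out_dir output directory.
#' @param n number of molecules.
#' @param seed integer seed.
#' @param cfg a [grammar_config()].
#' @param combos integer vector of parameter-grid rows to render.
#' @param npix,fov rendering geometry.
#' @param force overwrite existing output.
#' @return the manifest, invisibly.
#' @export
run_simulate <- function(out_dir, n = 50L, seed = 1L,
                         cfg = grammar_config(), combos = 1L,
                         npix = 128L, fov = 12.8, force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force)
    stop("output directory exists (use --force): ", out_dir)
  .log_msg("simulate: n=%d seed=%d npix=%d", n, seed, npix)
  man <- generate_dataset(n, seed, cfg)
  write_manifest(man, out_dir, force = TRUE)
  grid <- parameter_grid()
  stack_dir <- file.path(out_dir, "stacks")
  dir.create(stack_dir, showWarnings = FALSE)
  for (id in man$records$id) {
    for (cb in combos) {
      st <- render_stack(man$layouts[[id]], params = grid[cb, ],
                         npix = npix, fov = fov, molecule_id = id)
      save_stack(st, file.path(stack_dir, sprintf("%s_c%02d.rds", id, cb)))
    }
  }
  invisible(man)
}

#' Train both networks from a manifest directory
#'
#' @param data_dir a [run_simulate()] output directory.
#' @param out_dir directory for checkpoints, metric log and config snapshot.
#' @param cfg a [train_config()].
#' @param force overwrite existing output.
#' @return the [train_two_stage()] result, invisibly.
#' @export
run_train <- function(data_dir, out_dir, cfg = train_config(),
                      force = FALSE) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0L && !force)
    stop("output directory exists (use --force): ", out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  man <- read_manifest(data_dir)
  vocab <- default_vocabulary()
  .log_msg("train: %d molecules, seed=%d", nrow(man$records), cfg$seed)
  fit <- train_two_stage(man, cfg, vocab)
  save_checkpoint(fit$attr_model, file.path(out_dir, "attr_model.rds"))
  save_checkpoint(fit$name_model, file.path(out_dir, "name_model.rds"))
  utils::write.table(fit$log, file.path(out_dir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(cfg)[!vapply(unclass(cfg), is.list,
                                            logical(1))],
                       file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}

#' Predict names for a manifest with trained checkpoints
#'
#' @param model_dir a [run_train()] output directory.
#' @param data_dir a [run_simulate()] output directory.
#' @param out_file TSV file for the per-molecule predictions.
#' @param split split to predict (`"test"` by default).
#' @param attrs_mode attribute conditioning, see [predict_manifest()].
#' @return the prediction data frame, invisibly.
#' @export
run_predict <- function(model_dir, data_dir, out_file, split = "test",
                        attrs_mode = "predicted") {
  models <- list(
    attr_model = load_checkpoint(file.path(model_dir, "attr_model.rds")),
    name_model = load_checkpoint(file.path(model_dir, "name_model.rds")))
  man <- read_manifest(data_dir)
  vocab <- default_vocabulary()
  preds <- predict_manifest(models, man, vocab, split = split,
                            attrs_mode = attrs_mode)
  utils::write.table(preds, out_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(preds)
}

#' Score a prediction table
#'
#' @param pred_file TSV written by [run_predict()].
#' @param out_file TSV for the per-molecule report; a summary block is
#'   printed to the console.
#' @return the [evaluate_predictions()] result, invisibly.
#' @export
run_evaluate <- function(pred_file, out_file = NULL) {
  preds <- utils::read.table(pred_file, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  vocab <- default_vocabulary()
  ev <- evaluate_predictions(preds, vocab)
  if (!is.null(out_file))
    utils::write.table(ev$per_molecule, out_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  print(round(ev$summary, 4))
  invisible(ev)
}

#' Nearest embedding neighbors of a term, from a checkpoint
#'
#' @param model_path a name-network checkpoint file.
#' @param term query term.
#' @param k number of neighbors.
#' @return data frame of neighbors, invisibly (also printed).
#' @export
run_embed_neighbors <- function(model_path, term, k = 5L) {
  model <- load_checkpoint(model_path)
  vocab <- default_vocabulary()
  nb <- embedding_neighbors(model, vocab, term, k)
  print(nb)
  invisible(nb)
}
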