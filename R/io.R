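#' Read and write 8-bit grayscale PNG images
#'
#' Images are stored as single-channel 8-bit PNGs with background exactly 0;
#' in memory they are numeric matrices of integers in \[0, 255\]
#' (rows = y, columns = x).
#'
#' @param image Numeric matrix with values in \[0, 255\].
#' @param path File path.
#' @return `read_gray_png()` returns the intensity matrix;
#'   `write_gray_png()` returns `path` invisibly.
#' @export
write_gray_png <- function(image, path) {
  stopifnot(is.matrix(image))
  png::writePNG(round(image) / 255, target = path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_png <- function(path) {
  if (!file.exists(path)) abort(sprintf("image file not found: %s", path))
  p <- png::readPNG(path)
  if (length(dim(p)) == 3L) p <- p[, , 1L]
  round(p * 255)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with header `path,label`: one image file (relative to
#' the manifest's directory unless absolute) and one of the four cluster
#' labels per row.  Unknown label strings and, optionally, missing files are
#' reported with their row number.
#'
#' @param path Manifest CSV path.
#' @param check_files Verify that every referenced image exists.
#' @return A tibble with columns `path` and `label`; attribute `base_dir`
#'   holds the directory paths are resolved against.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  if (!identical(names(df), c("path", "label"))) {
    abort(sprintf("manifest must have header `path,label`; got `%s`",
                  paste(names(df), collapse = ",")))
  }
  base_dir <- dirname(path)
  bad <- which(!df$label %in% cluster_labels())
  if (length(bad)) {
    abort(sprintf("unknown label \"%s\" in manifest row %d", df$label[bad[1]], bad[1]))
  }
  if (check_files && nrow(df)) {
    full <- ifelse(startsWith(df$path, "/"), df$path, file.path(base_dir, df$path))
    missing <- which(!file.exists(full))
    if (length(missing)) {
      abort(sprintf("missing image file \"%s\" in manifest row %d",
                    df$path[missing[1]], missing[1]))
    }
  }
  out <- tibble::as_tibble(df)
  attr(out, "base_dir") <- base_dir
  out
}

#' Load the images referenced by a manifest
#'
#' @param manifest Tibble from [read_manifest()] or [make_dataset()].
#' @param base_dir Directory image paths are resolved against; defaults to
#'   the manifest's own `base_dir` attribute.
#' @return List of [labeled_sample()] objects.
#' @export
load_samples <- function(manifest, base_dir = attr(manifest, "base_dir")) {
  if (is.null(base_dir)) base_dir <- "."
  purrr::map2(manifest$path, manifest$label, function(p, l) {
    full <- if (startsWith(p, "/")) p else file.path(base_dir, p)
    labeled_sample(read_gray_png(full), l)
  })
}

#' Save and load training checkpoints
#'
#' A checkpoint bundles an architecture tag, the parameter list, the run
#' configuration and the seed; the save/load round trip restores all weights
#' bit-exactly.  Loading verifies the architecture tag when one is expected.
#'
#' @param state Named list with at least `architecture` and `params`.
#' @param path Checkpoint file path (RDS).
#' @param expect_architecture Optional architecture tag that the checkpoint
#'   must match.
#' @return `load_checkpoint()` returns the state list; `save_checkpoint()`
#'   returns `path` invisibly.
#' @export
save_checkpoint <- function(state, path) {
  stopifnot(is.list(state), !is.null(state$architecture))
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path, expect_architecture = NULL) {
  if (!file.exists(path)) abort(sprintf("checkpoint not found: %s", path))
  state <- tryCatch(readRDS(path), error = function(e) {
    abort(sprintf("corrupt checkpoint %s: %s", path, conditionMessage(e)))
  })
  if (!is.list(state) || is.null(state$architecture)) {
    abort(sprintf("corrupt checkpoint %s: missing architecture tag", path))
  }
  if (!is.null(expect_architecture) && !identical(state$architecture, expect_architecture)) {
    abort(sprintf("checkpoint architecture \"%s\" does not match expected \"%s\"",
                  state$architecture, expect_architecture))
  }
  state
}

#' Full run configuration
#'
#' Nested configuration covering synthesis, composition, pretraining and
#' fine-tuning, plus a global seed and output directory.  Round-trips
#' losslessly through YAML via [write_run_config()] / [read_run_config()].
#' The shipped defaults encode the reference training recipe.
#'
#' @param synth,composition,pretrain,finetune Component configurations.
#' @param seed Global seed.
#' @param out_dir Output directory for artifacts.
#' @return A nested `supcam_run_config` list.
#' @export
run_config <- function(synth = synth_config(),
                       composition = composition_config(),
                       pretrain = pretrain_config(),
                       finetune = finetune_config(),
                       seed = 1L,
                       out_dir = ".") {
  structure(list(synth = synth, composition = composition,
                 pretrain = pretrain, finetune = finetune,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "supcam_run_config")
}

#' @rdname run_config
#' @param config A `supcam_run_config`.
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  merge_into <- function(defaults, given) {
    for (nm in names(given)) {
      if (is.list(defaults[[nm]]) && is.list(given[[nm]])) {
        defaults[[nm]] <- merge_into(defaults[[nm]], given[[nm]])
      } else {
        defaults[[nm]] <- given[[nm]]
      }
    }
    defaults
  }
  base <- run_config()
  cfg <- merge_into(rapply(unclass(base), unclass, how = "replace"), raw)
  structure(list(
    synth = do.call(synth_config, cfg$synth[setdiff(names(cfg$synth), character())]),
    composition = do.call(composition_config, cfg$composition),
    pretrain = do.call(pretrain_config, cfg$pretrain),
    finetune = do.call(finetune_config, cfg$finetune),
    seed = as.integer(cfg$seed), out_dir = cfg$out_dir
  ), class = "supcam_run_config")
}
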