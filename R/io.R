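# Readers/writers and the pipeline driver: NIfTI and serialized-archive
# image IO, dataset archives, model checkpoints, YAML configuration with
# schema validation, and the staged generate -> train -> evaluate runner.

#' Read a 2-D image
#'
#' Accepts NIfTI (`.nii` / `.nii.gz`) or a serialized archive (`.rds`)
#' holding a matrix or a named list with a matrix under `key`. 3-D NIfTI
#' volumes require an explicit `slice` (axial plane index).
#'
#' @param path file path.
#' @param slice slice index for 3-D volumes.
#' @param key list key for archive files (default `"t1w"`).
#' @return a numeric matrix.
#' @export
read_image <- function(path, slice = NULL, key = "t1w") {
  stop_if(!file.exists(path), paste("file not found:", path))
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                    error = function(e) stop(sprintf(
                      "malformed NIfTI file: %s (%s)", path, conditionMessage(e)),
                      call. = FALSE))
    a <- as.array(img)
    if (length(dim(a)) == 2) return(unclass(a)[, , drop = TRUE])
    if (length(dim(a)) == 3) {
      stop_if(is.null(slice), "3-D volume: a `slice` index is required")
      stop_if(slice < 1 || slice > dim(a)[3], "slice index out of range")
      return(matrix(a[, , slice], dim(a)[1], dim(a)[2]))
    }
    stop(sprintf("unsupported NIfTI dimensionality in %s", path), call. = FALSE)
  }
  if (grepl("\\.rds$", path)) {
    obj <- tryCatch(readRDS(path), error = function(e) stop(sprintf(
      "malformed archive: %s (%s)", path, conditionMessage(e)), call. = FALSE))
    if (is.matrix(obj)) return(obj)
    if (is.list(obj) && is.matrix(obj[[key]])) return(obj[[key]])
    stop(sprintf("archive %s holds no matrix under key '%s'", path, key),
         call. = FALSE)
  }
  stop(sprintf("unknown image format: %s", path), call. = FALSE)
}

#' Write a 2-D image
#'
#' @param img numeric matrix.
#' @param path output path; `.nii`/`.nii.gz` writes NIfTI, `.rds` a
#'   serialized archive.
#' @return invisibly, `path`.
#' @export
write_image <- function(img, path) {
  if (grepl("\\.nii(\\.gz)?$", path)) RNifti::writeNifti(img, path)
  else if (grepl("\\.rds$", path)) saveRDS(img, path, compress = "gzip")
  else stop(sprintf("unknown image format: %s", path), call. = FALSE)
  invisible(path)
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the architecture spec, build seed, parameters and
#' the training manifest (config + loss history), so a model is fully
#' reconstructable and auditable from one file.
#'
#' @param model a [dunet].
#' @param path checkpoint path (`.rds`).
#' @return `save_dunet` returns `path` invisibly; `load_dunet` the model.
#' @export
save_dunet <- function(model, path) {
  saveRDS(model, path, compress = "gzip")
  invisible(path)
}

#' @rdname save_dunet
#' @export
load_dunet <- function(path) {
  m <- readRDS(path)
  stop_if(!inherits(m, "dunet"), "checkpoint does not hold a dunet model")
  m
}

#' Write a generated dataset to an archive
#'
#' Stores the triples under keys `at1w`, `lrsi`, `hrsi` (lists of matrices)
#' with a JSON sidecar of the generation parameters.
#'
#' @param cases list of cases from [generate_dataset()].
#' @param path archive path (`.rds`); the sidecar is `<path>.json`.
#' @param params list recorded in the sidecar.
#' @return invisibly, `path`.
#' @export
write_dataset <- function(cases, path, params = list()) {
  obj <- list(at1w = lapply(cases, `[[`, "at1w"),
              lrsi = lapply(cases, `[[`, "lrsi"),
              hrsi = lapply(cases, `[[`, "hrsi"),
              case_seed = vapply(cases, `[[`, 0L, "case_seed"))
  saveRDS(obj, path, compress = "gzip")
  jsonlite::write_json(c(params, list(n_cases = length(cases))),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

pipeline_schema <- list(
  seed = "integer", out_dir = "character", stages = "character",
  phantom = list(size = "integer", n_gyri = "integer"),
  generator = list(n_cases = "integer", lr_size = "integer",
                   noise = "numeric"),
  model = list(input_size = "integer", growth_maps = "integer",
               n_pool = "integer"),
  train = list(n_epochs = "integer", samples_per_epoch = "integer",
               learning_rate = "numeric"),
  eval = list(n_cases = "integer")
)

validate_config_block <- function(block, schema, path = "") {
  for (nm in names(block)) {
    full <- if (nzchar(path)) paste0(path, ".", nm) else nm
    stop_if(is.null(schema[[nm]]), paste("unknown config key:", full))
    if (is.list(schema[[nm]]))
      validate_config_block(block[[nm]], schema[[nm]], full)
  }
  if (!is.null(block$lr_size))
    stop_if(!(block$lr_size %in% c(16L, 24L, 32L)),
            sprintf("generator.lr_size must be 16, 24 or 32 (got %s)",
                    block$lr_size))
  invisible(TRUE)
}

#' Read and validate a pipeline configuration
#'
#' YAML with nested blocks `phantom`, `generator`, `model`, `train`,
#' `eval` plus a global `seed`, `out_dir` and `stages`. Unknown keys and
#' out-of-range values are rejected before any stage runs.
#'
#' @param path YAML file path.
#' @return validated config list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config_block(cfg, pipeline_schema)
  stop_if(is.null(cfg$seed), "config needs a global `seed`")
  stop_if(is.null(cfg$out_dir), "config needs `out_dir`")
  structure(cfg, class = "pipeline_config")
}

#' Run the staged pipeline
#'
#' Executes the requested stages (`generate`, `train`, `evaluate`) with
#' per-stage seeds derived from the global seed. Every artifact gets a JSON
#' manifest (stage, seeds, parameters); completed stages are skipped on
#' re-runs unless `force = TRUE`.
#'
#' @param config a `pipeline_config` (or path to one).
#' @param force re-run stages whose artifacts already exist.
#' @return invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stages <- config$stages %||% c("generate")
  seed <- as.integer(config$seed)
  gen <- config$generator %||% list()
  n_cases <- gen$n_cases %||% 20L
  lr_size <- gen$lr_size %||% 32L
  noise <- gen$noise %||% c(0.02, 0.05)
  msz <- (config$model %||% list())$input_size %||% 128L
  artifacts <- list()

  manifest <- function(path, stage, extra = list()) {
    jsonlite::write_json(c(list(stage = stage, seed = seed,
                                created = as.character(Sys.time())), extra),
                         paste0(path, ".manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  if ("generate" %in% stages) {
    p <- file.path(config$out_dir, "dataset.rds")
    if (force || !file.exists(p)) {
      cases <- generate_dataset(n_cases, hr_size = msz, lr_size = lr_size,
                                noise_range = noise,
                                seed = derive_seed(seed, 1L))
      write_dataset(cases, p, list(lr_size = lr_size, hr_size = msz))
      manifest(p, "generate", list(n_cases = n_cases, lr_size = lr_size))
    } else message("generate: artifact exists, skipping (use force = TRUE)")
    artifacts$dataset <- p
  }
  if ("train" %in% stages) {
    p <- file.path(config$out_dir, "model.rds")
    if (force || !file.exists(p)) {
      tc <- config$train %||% list()
      spec <- dunet_spec(input_size = msz,
                         growth_maps = (config$model %||% list())$growth_maps %||% 32L)
      model <- dunet(spec, seed = derive_seed(seed, 2L))
      ne <- tc$n_epochs %||% 10L
      sched <- if (ne > 2)
        list(list(epochs = c(1, 2), size = 1L),
             list(epochs = c(3, ne), size = 10L))
      else list(list(epochs = c(1, ne), size = 1L))
      cfg <- train_config(n_epochs = ne,
                          samples_per_epoch = tc$samples_per_epoch %||% 200L,
                          learning_rate = tc$learning_rate %||% 1e-3,
                          batch_schedule = sched,
                          lr_size = lr_size, noise_range = noise,
                          seed = derive_seed(seed, 3L))
      model <- train_dunet(model, cfg)
      save_dunet(model, p)
      utils::write.csv(model$history[c("epoch", "mean_loss")],
                       file.path(config$out_dir, "loss_history.csv"),
                       row.names = FALSE)
      manifest(p, "train", list(n_epochs = cfg$n_epochs))
    } else message("train: artifact exists, skipping (use force = TRUE)")
    artifacts$model <- p
  }
  if ("evaluate" %in% stages) {
    p <- file.path(config$out_dir, "eval_report.csv")
    if (force || !file.exists(p)) {
      methods <- list(
        zero_fill = function(case, lr) zero_fill_upsample(lr$native, msz),
        bicubic   = function(case, lr) bicubic_upsample(lr$native, msz))
      if (!is.null(artifacts$model) && file.exists(artifacts$model)) {
        model <- load_dunet(artifacts$model)
        methods$dunet <- dunet_method(model)
      }
      rep <- noise_sweep(methods,
                         n_cases = (config$eval %||% list())$n_cases %||% 20L,
                         lr_size = lr_size, hr_size = msz,
                         seed = derive_seed(seed, 4L))
      utils::write.csv(rep$mse, p)
      manifest(p, "evaluate", list(n_cases = rep$n_cases))
    } else message("evaluate: artifact exists, skipping (use force = TRUE)")
    artifacts$report <- p
  }
  invisible(artifacts)
}

#' Wrap a trained model as a reconstruction method
#'
#' Returns a `(case, lowres) -> matrix` closure for [noise_sweep()]: inputs
#' are max-normalized, the network is applied, and the prediction is
#' rescaled by the low-resolution map's max (the carried scale), so the
#' method competes with the interpolation baselines on the raw scale.
#'
#' @param model a trained [dunet].
#' @return a function usable as a `noise_sweep` method.
#' @export
dunet_method <- function(model) {
  function(case, lr) {
    mx <- max(lr$upscaled)
    lrn <- if (mx > 0) lr$upscaled / mx else lr$upscaled
    pmax(predict(model, case$at1w, lrn), 0) * mx
  }
}
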