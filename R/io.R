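#' Read / write NIfTI volumes
#'
#' Thin wrappers over RNifti preserving affine/header metadata. Both
#' `.nii` and `.nii.gz` are accepted.
#'
#' @param path File path.
#' @return `read_volume()` returns a numeric array with RNifti image
#'   attributes attached; `write_volume()` returns `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume: ", path, call. = FALSE)
  RNifti::readNifti(path)
}

#' @rdname read_volume
#' @param vol Numeric array (3D or 4D); float32 on disk.
#' @param template Optional RNifti image supplying the affine/header.
#' @export
write_volume <- function(vol, path, template = NULL) {
  img <- if (is.null(template)) {
    RNifti::asNifti(vol, datatype = "float")
  } else {
    RNifti::asNifti(vol, reference = template, datatype = "float")
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Validate and normalize a pipeline run configuration
#'
#' A run config is a JSON object (or equivalent list) with fields:
#' `outdir`; optional `seed` (default 1), `grid` (default 32,32,4),
#' `target_snr` (default 10), `noise_sd` (overrides `target_snr`),
#' `models` (default all four), `protocol` (default the bundled
#' multi-delay protocol), `constants`, `calibration`
#' (`partition_lambda`, `tr_calib`, `saturation_correction`),
#' `thresholds` (`gm_pve`, `abv`, `cvr_floor`), and `fit`
#' (`tol_F`, `max_iter`, `n_restarts`). Unknown top-level fields are
#' an error so typos do not silently change a run.
#'
#' @param config Path to a JSON file or a named list.
#' @return A normalized config list of class `asl_run_config`.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  known <- c("outdir", "seed", "grid", "target_snr", "noise_sd", "models",
             "protocol", "constants", "calibration", "thresholds", "fit",
             "petco2")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(config$outdir)) stop("config needs `outdir`", call. = FALSE)

  proto <- config$protocol
  protocol <- if (is.null(proto)) asl_protocol() else {
    asl_protocol(
      tau = proto$tau_s %||% 1.4,
      plds = proto$plds_s %||% seq(0.25, 1.5, 0.25),
      n_repeats = proto$repeats %||% 8L,
      slice_dt = proto$slice_dt_s %||% 0.046,
      n_slices = proto$n_slices %||% 24L,
      tr = proto$tr_s %||% 4.1
    )
  }
  cs <- config$constants
  consts <- asl_constants(
    t1_blood = cs$t1_blood %||% 1.65,
    t1_tissue = cs$t1_tissue %||% 1.3,
    partition_lambda = cs$partition_lambda %||% 0.9,
    label_efficiency_alpha = cs$label_efficiency_alpha %||% 0.85
  )
  cal <- config$calibration
  calib <- calib_config(
    partition_lambda = cal$partition_lambda %||% consts$partition_lambda,
    label_efficiency_alpha = consts$label_efficiency_alpha,
    tr_calib = cal$tr_calib %||% protocol$tr,
    saturation_correction = cal$saturation_correction %||% TRUE,
    t1_tissue_for_sat = cal$t1_tissue_for_sat %||% consts$t1_tissue
  )
  models <- config$models %||% asl_model_codes()
  bad <- setdiff(models, asl_model_codes())
  if (length(bad) > 0) {
    stop("unknown model code(s): ", paste(bad, collapse = ", "),
         "; valid: ", paste(asl_model_codes(), collapse = ", "),
         call. = FALSE)
  }
  th <- config$thresholds
  fit <- config$fit
  petco2 <- config$petco2 %||% c(normo = 38.8, hyper = 46.6)
  petco2 <- stats::setNames(as.numeric(petco2), c("normo", "hyper"))

  structure(
    list(
      outdir = config$outdir,
      seed = as.integer(config$seed %||% 1L),
      grid = as.integer(config$grid %||% c(32L, 32L, 4L)),
      target_snr = config$target_snr %||% 10,
      noise_sd = config$noise_sd,
      models = models,
      protocol = protocol, consts = consts, calib = calib,
      thresholds = list(
        gm_pve = th$gm_pve %||% 0.3,
        abv = th$abv %||% 0.7,
        cvr_floor = th$cvr_floor %||% 1
      ),
      fit = vb_opts(
        tol_F = fit$tol_F %||% 0.01,
        max_iter = fit$max_iter %||% 30L,
        seed = as.integer(config$seed %||% 1L)
      ),
      n_restarts = fit$n_restarts %||% 1L,
      petco2 = petco2
    ),
    class = "asl_run_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
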