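#' Write / read parameter maps as one NIfTI per parameter
#'
#' @param maps An `asl_param_maps` tibble.
#' @param dir Output directory.
#' @param prefix File-name prefix, e.g. `"normo_art_disp"`.
#' @return `write_maps()` returns the written paths invisibly;
#'   `read_maps()` reconstructs the tibble from the volumes.
#' @export
write_maps <- function(maps, dir, prefix) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vars <- intersect(
    c("ftiss", "att", "abv", "att_art", "s", "p", "free_energy",
      "converged", "cbf", "abv_cal"),
    names(maps)
  )
  paths <- character(0)
  for (v in vars) {
    vol <- maps_to_volume(maps, v)
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, v))
    write_volume(vol, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname write_maps
#' @param model Model code recorded in the returned tibble.
#' @export
read_maps <- function(dir, prefix, model) {
  fe_path <- file.path(dir, sprintf("%s_free_energy.nii.gz", prefix))
  if (!file.exists(fe_path)) {
    stop("no maps with prefix ", prefix, " in ", dir, call. = FALSE)
  }
  fe <- read_volume(fe_path)
  dm <- dim(fe)
  idx <- which(is.finite(fe), arr.ind = TRUE)
  out <- tibble::tibble(x = idx[, 1L], y = idx[, 2L], z = idx[, 3L])
  for (v in c("ftiss", "att", "abv", "att_art", "s", "p",
              "free_energy", "converged", "cbf", "abv_cal")) {
    p <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, v))
    if (file.exists(p)) {
      vol <- read_volume(p)
      out[[v]] <- vol[cbind(out$x, out$y, out$z)]
    }
  }
  if ("converged" %in% names(out)) out$converged <- out$converged > 0
  tibble::new_tibble(out, vol_dim = dm, model = model,
                     class = "asl_param_maps")
}

roi_codes <- function(roi) {
  labs <- sort(setdiff(unique(as.vector(roi)), NA))
  code <- array(0L, dim(roi))
  for (i in seq_along(labs)) code[which(roi == labs[i])] <- i
  list(code = code, legend = labs)
}

#' Run the phantom-to-report analysis pipeline
#'
#' Executes the full workflow from a single run configuration:
#' simulate the two-condition phantom acquisition, subtract and
#' average control/label pairs, fit the requested kinetic models per
#' voxel under each condition, calibrate CBF/aBV against the M0 image,
#' form CVR / transit-time / arterial-volume change maps, and write
#' regional and model-comparison reports. All outputs land under
#' `config$outdir`: NIfTI volumes, ground-truth and protocol JSON, a
#' PETCO2 TSV, per-parameter map NIfTIs, and the report TSVs
#' (`regional_report.tsv`, `model_comparison.tsv`,
#' `condition_changes.tsv`).
#'
#' @param config Path to a run-config JSON or a list
#'   (see [read_run_config()]).
#' @param stages Subset of
#'   `c("simulate", "fit", "calibrate", "cvr", "report")`; later
#'   stages read the files earlier stages wrote, so they can be run
#'   across separate calls.
#' @param quiet Suppress progress messages?
#' @return The config, invisibly.
#' @export
run_pipeline <- function(config,
                         stages = c("simulate", "fit", "calibrate",
                                    "cvr", "report"),
                         quiet = FALSE) {
  cfg <- if (inherits(config, "asl_run_config")) config else read_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  out <- cfg$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  protocol <- cfg$protocol
  consts <- cfg$consts
  conditions <- c("normo", "hyper")

  if ("simulate" %in% stages) {
    say("[simulate] %s grid, seed %d", paste(cfg$grid, collapse = "x"),
        cfg$seed)
    spec <- phantom_spec(dim = cfg$grid, noise_sd = cfg$noise_sd,
                         target_snr = cfg$target_snr,
                         petco2 = cfg$petco2, seed = cfg$seed)
    ph <- make_phantom(spec)
    write_volume(ph$gm_pve, file.path(out, "gm_pve.nii.gz"))
    rc <- roi_codes(ph$roi)
    write_volume(rc$code, file.path(out, "roi.nii.gz"))
    jsonlite::write_json(rc$legend, file.path(out, "roi_legend.json"))
    write_protocol(protocol, file.path(out, "protocol.json"))
    readr::write_tsv(
      tibble::tibble(subject = "phantom01",
                     petco2_normo = cfg$petco2[["normo"]],
                     petco2_hyper = cfg$petco2[["hyper"]]),
      file.path(out, "petco2.tsv")
    )
    for (cond in conditions) {
      ds <- simulate_acquisition(ph, protocol, consts, cond,
                                 calib = cfg$calib)
      write_volume(interleave_series(ds),
                   file.path(out, sprintf("asl_%s.nii.gz", cond)))
      write_volume(ds$m0, file.path(out, sprintf("m0_%s.nii.gz", cond)))
      jsonlite::write_json(ds$truth,
                           file.path(out, sprintf("truth_%s.json", cond)),
                           digits = NA)
      say("[simulate] %s: %d volumes, noise sd %.3e", cond,
          dim(ds$control)[4L] * 2L, ds$noise_sd)
    }
  }

  if ("fit" %in% stages) {
    for (cond in conditions) {
      series <- read_volume(file.path(out, sprintf("asl_%s.nii.gz", cond)))
      m0 <- read_volume(file.path(out, sprintf("m0_%s.nii.gz", cond)))
      deltam <- subtract_pairs(series, protocol)
      mask <- m0 > 0.2 * stats::quantile(m0[m0 > 0], 0.99, names = FALSE)
      for (code in cfg$models) {
        say("[fit] %s / %s (%d voxels)", cond, code, sum(mask))
        maps <- fit_volume(deltam, mask, code, protocol, consts,
                           opts = cfg$fit, n_restarts = cfg$n_restarts,
                           quiet = quiet)
        write_maps(maps, out, sprintf("%s_%s", cond, code))
      }
    }
  }

  if ("calibrate" %in% stages) {
    for (cond in conditions) {
      m0 <- read_volume(file.path(out, sprintf("m0_%s.nii.gz", cond)))
      for (code in cfg$models) {
        maps <- read_maps(out, sprintf("%s_%s", cond, code), code)
        maps <- calibrate_cbf(maps, as.array(m0), cfg$calib)
        write_maps(maps, out, sprintf("%s_%s", cond, code))
        say("[calibrate] %s / %s", cond, code)
      }
    }
  }

  if ("cvr" %in% stages) {
    pet <- read_petco2(file.path(out, "petco2.tsv"))
    dpet <- mean(pet$petco2_hyper - pet$petco2_normo)
    for (code in cfg$models) {
      mn <- read_maps(out, sprintf("normo_%s", code), code)
      mh <- read_maps(out, sprintf("hyper_%s", code), code)
      cvr <- cvr_map(mn, mh, dpet, floor = cfg$thresholds$cvr_floor)
      write_volume(maps_to_volume(cvr, "cvr"),
                   file.path(out, sprintf("cvr_%s.nii.gz", code)))
      deltas <- condition_deltas(mn, mh)
      write_volume(maps_to_volume(deltas, "datt"),
                   file.path(out, sprintf("datt_%s.nii.gz", code)))
      write_volume(maps_to_volume(deltas, "dabv"),
                   file.path(out, sprintf("dabv_%s.nii.gz", code)))
      say("[cvr] %s: dPETCO2 = %.1f mmHg", code, dpet)
    }
  }

  if ("report" %in% stages) {
    gm_pve <- read_volume(file.path(out, "gm_pve.nii.gz"))
    gm <- gm_mask(as.array(gm_pve), cfg$thresholds$gm_pve)
    rc_code <- as.array(read_volume(file.path(out, "roi.nii.gz")))
    legend <- unlist(jsonlite::read_json(file.path(out, "roi_legend.json"),
                                         simplifyVector = TRUE))
    roi <- array(NA_character_, dim(rc_code))
    for (i in seq_along(legend)) roi[round(rc_code) == i] <- legend[i]

    # arterial mask from the full (dispersion + arterial) model if run
    art <- NULL
    art_src <- intersect("art_disp", cfg$models)
    if (length(art_src) == 1L) {
      mn <- read_maps(out, sprintf("normo_%s", art_src), art_src)
      abv_val <- if ("abv_cal" %in% names(mn)) mn$abv_cal else mn$abv
      abv_vol <- maps_to_volume(
        dplyr::mutate(mn, .abv = abv_val), ".abv", fill = 0
      )
      abv_vol[!is.finite(abv_vol)] <- 0
      art <- arterial_mask(abv_vol, cfg$thresholds$abv)
    }
    membership <- region_membership(roi, gm, art)

    pet <- read_petco2(file.path(out, "petco2.tsv"))
    dpet <- mean(pet$petco2_hyper - pet$petco2_normo)

    param_rows <- list(); cmp_rows <- list(); chg_rows <- list()
    for (cond in conditions) {
      fits <- list()
      for (code in cfg$models) {
        maps <- read_maps(out, sprintf("%s_%s", cond, code), code)
        fits[[code]] <- maps
        vals <- dplyr::mutate(maps, model = code, condition = cond)
        vars <- intersect(c("cbf", "att", "abv_cal", "free_energy"),
                          names(vals))
        param_rows[[paste(cond, code)]] <-
          regional_summary(vals, membership, vars)
      }
      cmp <- compare_models(fits, membership)
      cmp_rows[[cond]] <- dplyr::mutate(cmp$region_summary,
                                        condition = cond)
    }
    for (code in cfg$models) {
      mn <- read_maps(out, sprintf("normo_%s", code), code)
      mh <- read_maps(out, sprintf("hyper_%s", code), code)
      cvr <- cvr_map(mn, mh, dpet, floor = cfg$thresholds$cvr_floor)
      deltas <- condition_deltas(mn, mh)
      both <- dplyr::inner_join(cvr, deltas, by = c("x", "y", "z"))
      both <- dplyr::mutate(both, model = code)
      chg_rows[[code]] <- regional_summary(
        both, membership, c("cvr", "datt", "datt_pct", "dabv", "dabv_pct")
      )
    }
    report <- dplyr::bind_rows(param_rows)
    report <- dplyr::mutate(report,
                            mean_report = round(.data$mean, 1),
                            sd_report = round(.data$sd, 1))
    readr::write_tsv(report, file.path(out, "regional_report.tsv"))
    readr::write_tsv(dplyr::bind_rows(cmp_rows),
                     file.path(out, "model_comparison.tsv"))
    readr::write_tsv(dplyr::bind_rows(chg_rows),
                     file.path(out, "condition_changes.tsv"))
    say("[report] wrote regional_report.tsv, model_comparison.tsv, condition_changes.tsv")
  }

  invisible(cfg)
}
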