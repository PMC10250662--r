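#' Calibration configuration
#'
#' Settings for voxelwise M0 calibration of relative perfusion to
#' absolute CBF. The arterial equilibrium magnetization is derived per
#' voxel from the (unsuppressed) M0 image via the blood-brain partition
#' coefficient, with an optional saturation-recovery correction for a
#' short calibration TR:
#' `M0a = m0 / lambda / (1 - exp(-TR/T1_tissue))`.
#'
#' @param partition_lambda Blood-brain partition coefficient, ml/g.
#' @param label_efficiency_alpha Labelling efficiency (already applied
#'   inside the forward model; recorded here for provenance).
#' @param tr_calib TR of the calibration image, seconds.
#' @param saturation_correction Apply the short-TR correction?
#' @param t1_tissue_for_sat Tissue T1 used in the correction, seconds.
#' @return A list of class `calib_config`.
#' @export
calib_config <- function(partition_lambda = 0.9,
                         label_efficiency_alpha = 0.85,
                         tr_calib = 4.1,
                         saturation_correction = TRUE,
                         t1_tissue_for_sat = 1.3) {
  stopifnot(partition_lambda > 0, tr_calib > 0, t1_tissue_for_sat > 0,
            label_efficiency_alpha > 0, label_efficiency_alpha <= 1)
  structure(
    list(partition_lambda = partition_lambda,
         label_efficiency_alpha = label_efficiency_alpha,
         tr_calib = tr_calib,
         saturation_correction = isTRUE(saturation_correction),
         t1_tissue_for_sat = t1_tissue_for_sat),
    class = "calib_config"
  )
}

# per-voxel arterial equilibrium magnetization from the M0 image
m0a_from_m0 <- function(m0, cfg) {
  out <- m0 / cfg$partition_lambda
  if (cfg$saturation_correction) {
    out <- out / (1 - exp(-cfg$tr_calib / cfg$t1_tissue_for_sat))
  }
  out
}

#' Calibrate relative perfusion to absolute CBF
#'
#' Divides the fitted relative perfusion by the voxelwise arterial
#' equilibrium magnetization M0a; the labelling efficiency is already
#' part of the forward model. Voxels whose M0 falls below a small
#' fraction of the robust M0 maximum are excluded (set to `NA`) and
#' counted in the `n_excluded` attribute.
#'
#' @param maps An `asl_param_maps` tibble from [fit_volume()] (column
#'   `ftiss`, relative perfusion on the ml/100g/min scale in data
#'   units).
#' @param m0 3D array: the M0 calibration image on the same grid.
#' @param cfg A [calib_config()].
#' @param m0_floor_frac Exclusion threshold as a fraction of the 99th
#'   percentile of positive M0 values.
#' @return `maps` with added columns `cbf` (ml/100g/min) and
#'   `cbf_floored` (negative estimates floored at zero for display).
#' @export
calibrate_cbf <- function(maps, m0, cfg = calib_config(),
                          m0_floor_frac = 1e-6) {
  dm <- attr(maps, "vol_dim")
  if (is.null(dm) || !identical(dim(m0), dm)) {
    stop("M0 grid does not match the parameter-map grid", call. = FALSE)
  }
  m0_vox <- m0[cbind(maps$x, maps$y, maps$z)]
  robust_max <- stats::quantile(m0[m0 > 0], 0.99, names = FALSE)
  bad <- !is.finite(m0_vox) | m0_vox <= m0_floor_frac * robust_max
  m0a <- m0a_from_m0(m0_vox, cfg)
  cbf <- maps$ftiss / m0a
  cbf[bad] <- NA_real_
  out <- maps
  out$cbf <- cbf
  out$cbf_floored <- pmax(cbf, 0)
  out$abv_cal <- maps$abv / m0a
  out$abv_cal[bad] <- NA_real_
  attr(out, "n_excluded") <- sum(bad)
  if (sum(bad) > 0) {
    message(sprintf("calibrate_cbf: %d voxel(s) excluded (low M0)", sum(bad)))
  }
  out
}

#' Grey-matter mask from a partial-volume map
#'
#' @param pve 3D array of GM partial-volume estimates in `[0, 1]`.
#' @param threshold Strict threshold; voxels with `pve > threshold`
#'   are kept (default 0.3).
#' @return Logical 3D array.
#' @export
gm_mask <- function(pve, threshold = 0.3) {
  if (any(pve < 0 | pve > 1, na.rm = TRUE)) {
    stop("PVE values must lie in [0, 1]", call. = FALSE)
  }
  pve > threshold
}

#' Arterial mask from an aBV map
#'
#' Thresholds the fitted arterial-blood-volume map (percent units,
#' strict `>`); the default of 0.7% follows visual optimisation of
#' macrovascular maps from the dispersion + arterial model.
#'
#' @param abv Numeric vector or array of aBV values (%).
#' @param threshold Strict threshold, default 0.7.
#' @return Logical of the same shape.
#' @export
arterial_mask <- function(abv, threshold = 0.7) {
  if (any(!is.finite(abv))) stop("abv must be finite", call. = FALSE)
  abv > threshold
}

#' Cerebrovascular reactivity map
#'
#' CVR is the CBF change due to hypercapnia, expressed as a percentage
#' of the normocapnic CBF and normalized by the change in end-tidal
#' CO2: `CVR = 100 * (CBF_hyper - CBF_normo) / CBF_normo / dPETCO2`
#' in %/mmHg. Voxels whose normocapnic CBF falls below `floor`
#' (default 1 ml/100g/min) produce unrealistically large ratios and
#' are set to `NA`; their count is kept in the `n_floored` attribute.
#'
#' @param cbf_normo,cbf_hyper Calibrated map tibbles (from
#'   [calibrate_cbf()]) for the two conditions, same voxel set.
#' @param delta_petco2 PETCO2 change in mmHg, > 0.
#' @param floor Denominator floor in ml/100g/min.
#' @return A tibble with `x`, `y`, `z`, `cbf_normo`, `cbf_hyper`,
#'   `cvr` (%/mmHg).
#' @export
cvr_map <- function(cbf_normo, cbf_hyper, delta_petco2, floor = 1) {
  if (delta_petco2 <= 0) stop("delta_petco2 must be > 0", call. = FALSE)
  joined <- dplyr::inner_join(
    tibble::tibble(x = cbf_normo$x, y = cbf_normo$y, z = cbf_normo$z,
                   cbf_normo = cbf_normo$cbf),
    tibble::tibble(x = cbf_hyper$x, y = cbf_hyper$y, z = cbf_hyper$z,
                   cbf_hyper = cbf_hyper$cbf),
    by = c("x", "y", "z")
  )
  low <- !is.finite(joined$cbf_normo) | joined$cbf_normo < floor
  cvr <- 100 * (joined$cbf_hyper - joined$cbf_normo) /
    joined$cbf_normo / delta_petco2
  cvr[low] <- NA_real_
  out <- dplyr::mutate(joined, cvr = cvr)
  attr(out, "n_floored") <- sum(low)
  attr(out, "vol_dim") <- attr(cbf_normo, "vol_dim")
  out
}

#' Between-condition transit-time and arterial-volume changes
#'
#' Per-voxel hypercapnia-minus-normocapnia differences: `datt` (s) and
#' `dabv` (percentage points), plus percentage variants normalized by
#' the normocapnic value with the same denominator floor rule as
#' [cvr_map()].
#'
#' @param maps_normo,maps_hyper `asl_param_maps` for the two
#'   conditions, same voxel set.
#' @param att_floor,abv_floor Denominator floors for the percentage
#'   variants (s and %, respectively).
#' @return A tibble with the difference columns.
#' @export
condition_deltas <- function(maps_normo, maps_hyper,
                             att_floor = 0.05, abv_floor = 0.05) {
  abv_of <- function(m) if ("abv_cal" %in% names(m)) m$abv_cal else m$abv
  joined <- dplyr::inner_join(
    tibble::tibble(x = maps_normo$x, y = maps_normo$y, z = maps_normo$z,
                   att_n = maps_normo$att, abv_n = abv_of(maps_normo)),
    tibble::tibble(x = maps_hyper$x, y = maps_hyper$y, z = maps_hyper$z,
                   att_h = maps_hyper$att, abv_h = abv_of(maps_hyper)),
    by = c("x", "y", "z")
  )
  datt <- joined$att_h - joined$att_n
  dabv <- joined$abv_h - joined$abv_n
  datt_pct <- 100 * datt / joined$att_n
  datt_pct[!is.finite(joined$att_n) | joined$att_n < att_floor] <- NA_real_
  dabv_pct <- 100 * dabv / joined$abv_n
  dabv_pct[!is.finite(joined$abv_n) | joined$abv_n < abv_floor] <- NA_real_
  out <- dplyr::mutate(joined,
                       datt = datt, datt_pct = datt_pct,
                       dabv = dabv, dabv_pct = dabv_pct)
  attr(out, "n_floored_att") <- sum(!is.finite(joined$att_n) |
                                      joined$att_n < att_floor)
  attr(out, "n_floored_abv") <- sum(!is.finite(joined$abv_n) |
                                      joined$abv_n < abv_floor)
  attr(out, "vol_dim") <- attr(maps_normo, "vol_dim")
  out
}

#' Region membership table
#'
#' Builds a long voxel-to-region table from ROI labels intersected
#' with the GM mask, plus a whole-GM region and (optionally) an
#' arterial region. A voxel may belong to several regions.
#'
#' @param roi 3D array of region labels (character or factor; `""` or
#'   `NA` = no region).
#' @param gm Logical 3D GM mask.
#' @param arterial Optional logical 3D arterial mask (not intersected
#'   with GM).
#' @return A tibble with `x`, `y`, `z`, `region`.
#' @export
region_membership <- function(roi, gm, arterial = NULL) {
  stopifnot(identical(dim(roi), dim(gm)))
  gm_idx <- which(gm, arr.ind = TRUE)
  dimnames(gm_idx) <- NULL
  out <- list(tibble::tibble(x = gm_idx[, 1L], y = gm_idx[, 2L],
                             z = gm_idx[, 3L], region = "GM"))
  labs <- setdiff(unique(as.vector(roi)), c(NA, ""))
  for (lab in labs) {
    idx <- which(roi == lab & gm, arr.ind = TRUE)
    dimnames(idx) <- NULL
    if (nrow(idx) > 0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        x = idx[, 1L], y = idx[, 2L], z = idx[, 3L], region = lab
      )
    }
  }
  if (!is.null(arterial)) {
    stopifnot(identical(dim(arterial), dim(gm)))
    idx <- which(arterial, arr.ind = TRUE)
    dimnames(idx) <- NULL
    if (nrow(idx) > 0) {
      out[[length(out) + 1L]] <- tibble::tibble(
        x = idx[, 1L], y = idx[, 2L], z = idx[, 3L], region = "arterial"
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Regional summary of parameter maps
#'
#' Mean, sample SD (n-1) and voxel count of the requested columns per
#' region. `NA` voxels (floored or excluded upstream) are dropped from
#' each column's summary and reported via `n_used`.
#'
#' @param values A tibble with voxel coordinates and value columns
#'   (e.g. a calibrated map or [cvr_map()] output), optionally with
#'   `model` / `condition` columns to group by.
#' @param membership A [region_membership()] tibble.
#' @param vars Character vector of value columns to summarise.
#' @param by Extra grouping columns present in `values`.
#' @return A tibble with one row per region (x grouping) x variable:
#'   `mean`, `sd`, `n_region`, `n_used`.
#' @export
regional_summary <- function(values, membership, vars,
                             by = intersect(c("model", "condition"),
                                            names(values))) {
  stopifnot(all(vars %in% names(values)))
  joined <- dplyr::inner_join(membership, values, by = c("x", "y", "z"),
                              relationship = "many-to-many")
  long <- tidyr::pivot_longer(
    joined, dplyr::all_of(vars),
    names_to = "variable", values_to = "value"
  )
  long |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("region", by, "variable")
    ))) |>
    dplyr::summarise(
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      n_region = dplyr::n(),
      n_used = sum(is.finite(.data$value)),
      .groups = "drop"
    )
}

#' Group summary of end-tidal CO2 values
#'
#' Per-subject hypercapnia-minus-normocapnia change and group
#' mean +/- sample SD (n-1) of the normocapnic, hypercapnic and delta
#' values, rounded to one decimal for the report columns (full
#' precision is retained in the unrounded columns).
#'
#' @param records A data frame with columns `subject`, `petco2_normo`
#'   and `petco2_hyper` (mmHg).
#' @return A list of class `petco2_summary` with `subjects` (per
#'   subject, including `delta`) and `group` (one row per quantity:
#'   mean, sd, and their 1-decimal report values).
#' @export
petco2_summary <- function(records) {
  stopifnot(all(c("subject", "petco2_normo", "petco2_hyper") %in%
                  names(records)))
  subjects <- tibble::as_tibble(records) |>
    dplyr::mutate(delta = .data$petco2_hyper - .data$petco2_normo)
  if (nrow(subjects) < 2L) {
    warning("fewer than 2 subjects: group SD undefined", call. = FALSE)
  }
  group <- tibble::tibble(
    quantity = c("petco2_normo", "petco2_hyper", "delta"),
    mean = c(mean(subjects$petco2_normo), mean(subjects$petco2_hyper),
             mean(subjects$delta)),
    sd = c(stats::sd(subjects$petco2_normo),
           stats::sd(subjects$petco2_hyper),
           stats::sd(subjects$delta)),
    n = nrow(subjects)
  )
  group$mean_report <- round(group$mean, 1)
  group$sd_report <- round(group$sd, 1)
  structure(list(subjects = subjects, group = group),
            class = "petco2_summary")
}

#' @export
print.petco2_summary <- function(x, ...) {
  cat(sprintf("<petco2_summary> %d subject(s)\n", nrow(x$subjects)))
  g <- x$group
  for (i in seq_len(nrow(g))) {
    cat(sprintf("  %-13s %.1f +/- %.1f mmHg\n",
                g$quantity[i], g$mean_report[i], g$sd_report[i]))
  }
  invisible(x)
}

#' Read a per-subject PETCO2 table
#'
#' Tab-separated with columns `subject`, `petco2_normo`,
#' `petco2_hyper` (mmHg).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_petco2 <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE)
  need <- c("subject", "petco2_normo", "petco2_hyper")
  miss <- setdiff(need, names(out))
  if (length(miss) > 0) {
    stop("PETCO2 TSV missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out
}
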