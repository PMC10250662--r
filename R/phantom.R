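#' Default per-tissue haemodynamic parameters for each gas condition
#'
#' Normocapnic defaults: GM perfusion 60 ml/100g/min with a 1.0 s
#' transit time and mild bolus dispersion (s = e^2 /s, p = e^-0.3/e^2 s,
#' the dispersion-prior means); WM 20 ml/100g/min at 1.3 s; arteries
#' carry a 1.0% arterial blood volume arriving at 0.5 s on top of
#' GM-like tissue; CSF and background are signal-free. Hypercapnia is a
#' vasodilatory stress: CBF scales by 1.33, transit times shorten by
#' 15% and aBV drops to 0.7 of baseline (labelled blood clears the
#' macrovasculature faster).
#'
#' @param condition `"normo"` or `"hyper"`.
#' @param cbf_scale,att_scale,abv_scale Hypercapnia effect sizes
#'   (multiplicative on the normocapnic values).
#' @return A tibble with one row per tissue label: `label`, `f`,
#'   `att`, `abv`, `att_art`, `s`, `p`.
#' @export
default_condition_params <- function(condition = c("normo", "hyper"),
                                     cbf_scale = 1.33,
                                     att_scale = 0.85,
                                     abv_scale = 0.7) {
  condition <- match.arg(condition)
  s0 <- exp(2); p0 <- 0.1
  normo <- tibble::tribble(
    ~label,       ~f, ~att, ~abv, ~att_art, ~s, ~p,
    "GM",         60,  1.0,    0,      0.5, s0, p0,
    "WM",         20,  1.3,    0,      0.5, s0, p0,
    "artery",     60,  1.0,  1.0,      0.5, s0, p0,
    "CSF",         0,  1.0,    0,      0.5, s0, p0,
    "background",  0,  1.0,    0,      0.5, s0, p0
  )
  if (condition == "normo") return(normo)
  dplyr::mutate(normo,
                f = .data$f * cbf_scale,
                att = .data$att * att_scale,
                abv = .data$abv * abv_scale,
                att_art = .data$att_art * att_scale)
}

#' Digital-phantom specification
#'
#' A desk-scale cylindrical head phantom on a `32 x 32 x 4` grid:
#' concentric CSF core, WM annulus and GM rim, a one-voxel-wide
#' arterial line crossing the grid, and background outside the head.
#' Per-condition tissue parameters default to
#' [default_condition_params()]; `noise_sd = NULL` asks the simulator
#' to set the white-noise SD so that the per-PLD-averaged peak GM SNR
#' equals `target_snr`.
#'
#' @param dim Grid dimensions (x, y, slices).
#' @param params_normo,params_hyper Per-label parameter tibbles.
#' @param m0_scale Named vector of baseline (M0 image) intensities per
#'   label, arbitrary units.
#' @param noise_sd Per-volume Gaussian noise SD in M0 units, or `NULL`
#'   for SNR-targeted.
#' @param target_snr Per-PLD-averaged peak-GM SNR used when
#'   `noise_sd` is `NULL`.
#' @param petco2 Named pair `c(normo=, hyper=)` in mmHg for the
#'   synthetic subject.
#' @param seed Integer seed controlling all simulated noise.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(32L, 32L, 4L),
                         params_normo = default_condition_params("normo"),
                         params_hyper = default_condition_params("hyper"),
                         m0_scale = c(GM = 1.0, WM = 0.82, artery = 1.0,
                                      CSF = 1.35, background = 0),
                         noise_sd = NULL, target_snr = 10,
                         petco2 = c(normo = 38.8, hyper = 46.6),
                         seed = 1L) {
  stopifnot(length(dim) == 3L, dim[1L] >= 12L, dim[2L] >= 12L,
            dim[3L] >= 1L)
  if (!is.null(noise_sd)) stopifnot(noise_sd >= 0)
  structure(
    list(dim = as.integer(dim),
         params = list(normo = params_normo, hyper = params_hyper),
         m0_scale = m0_scale, noise_sd = noise_sd,
         target_snr = target_snr, petco2 = petco2,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Build the phantom's label, truth and mask volumes
#'
#' Deterministic given the spec: tissue labels partition the grid; the
#' GM partial-volume map is 1 inside GM and 0 elsewhere; four
#' pseudo-lobe ROI labels (anterior/posterior x left/right quadrants)
#' partition the GM rim.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `asl_phantom` with `labels` (character 3D
#'   array), `gm_pve`, `roi` (quadrant labels), per-condition ground
#'   truth tibbles, and the spec.
#' @export
make_phantom <- function(spec = phantom_spec()) {
  dm <- spec$dim
  cx <- (dm[1L] + 1) / 2; cy <- (dm[2L] + 1) / 2
  xs <- seq_len(dm[1L]); ys <- seq_len(dm[2L])
  r2d <- outer(xs, ys, function(x, y) sqrt((x - cx)^2 + (y - cy)^2))
  rmax <- min(cx, cy) - 3.5          # head radius, leaves a border
  slice_lab <- matrix("background", dm[1L], dm[2L])
  slice_lab[r2d <= rmax] <- "GM"
  slice_lab[r2d <= rmax - 3] <- "WM"
  slice_lab[r2d <= rmax - 9] <- "CSF"
  art_y <- round(cy - 0.5)
  art_x <- xs[r2d[, art_y] <= rmax]
  slice_lab[art_x, art_y] <- "artery"

  labels <- array(slice_lab, dim = dm)
  gm_pve <- array(as.numeric(labels == "GM"), dim = dm)

  roi_slice <- matrix(NA_character_, dm[1L], dm[2L])
  gm2d <- slice_lab == "GM"
  roi_slice[gm2d] <- paste0(
    ifelse(outer(xs, ys, function(x, y) x <= cx), "ant", "post"),
    "_",
    ifelse(outer(xs, ys, function(x, y) y <= cy), "l", "r")
  )[gm2d]
  roi <- array(roi_slice, dim = dm)

  vox <- expand.grid(x = xs, y = ys, z = seq_len(dm[3L]))
  vox$label <- as.vector(labels)
  truth <- lapply(spec$params, function(par) {
    dplyr::inner_join(tibble::as_tibble(vox), par, by = "label") |>
      dplyr::mutate(m0 = unname(spec$m0_scale[.data$label])) |>
      dplyr::arrange(.data$z, .data$y, .data$x)
  })

  structure(
    list(labels = labels, gm_pve = gm_pve, roi = roi,
         truth = truth, spec = spec),
    class = "asl_phantom"
  )
}

#' @export
print.asl_phantom <- function(x, ...) {
  cat(sprintf("<asl_phantom> %s grid\n", paste(dim(x$labels), collapse = " x ")))
  print(table(x$labels))
  invisible(x)
}

# Noise SD per volume such that the per-PLD repeat-averaged difference
# signal has the target peak-GM SNR: sd(avg dM) = sqrt(2)*sd/sqrt(R).
auto_noise_sd <- function(spec, phantom, protocol, consts,
                          calib = calib_config(tr_calib = protocol$tr)) {
  gm <- spec$params$normo[spec$params$normo$label == "GM", ]
  m0a <- m0a_from_m0(unname(spec$m0_scale["GM"]), calib)
  sig <- model_signal(
    "art_disp",
    hemo_params(f = gm$f, att = gm$att, abv = gm$abv,
                att_art = gm$att_art, s = gm$s, p = gm$p, check = FALSE),
    protocol, consts, slice_index = 0L
  )$value * m0a
  peak <- max(sig)
  (peak / spec$target_snr) * sqrt(protocol$n_repeats) / sqrt(2)
}

#' Simulate a multi-delay pCASL acquisition of the phantom
#'
#' For every voxel the difference signal is evaluated at the
#' slice-corrected sampling times with the dispersion + macrovascular
#' forward model (arterial voxels carry an aBV component; other
#' tissues are tissue-only), scaled by the voxel's arterial
#' equilibrium magnetization. Control and label volumes are the static
#' baseline plus/minus half the difference signal, each with
#' independent white Gaussian noise per volume, so the control-label
#' subtraction has noise SD `sqrt(2) * noise_sd`. The M0 image is the
#' baseline with its own noise draw. Everything is reproducible from
#' the seed; the global RNG state is left untouched.
#'
#' @param phantom An [make_phantom()] result.
#' @param protocol An [asl_protocol()].
#' @param consts An [asl_constants()].
#' @param condition `"normo"` or `"hyper"`.
#' @param calib A [calib_config()]; defines the M0-to-M0a relation the
#'   simulator and [calibrate_cbf()] share.
#' @param seed Overrides the spec seed (the hypercapnic run is offset
#'   automatically so conditions get independent noise).
#' @return A list of class `asl_dataset`: `control` and `label` 4D
#'   arrays (`x, y, z, n_pld * repeats`, PLD-major control/label pairs),
#'   `m0`, the ground-truth tibble, protocol, condition, PETCO2 pair,
#'   `noise_sd` and seed.
#' @export
simulate_acquisition <- function(phantom, protocol, consts,
                                 condition = c("normo", "hyper"),
                                 calib = calib_config(tr_calib = protocol$tr),
                                 seed = NULL) {
  condition <- match.arg(condition)
  spec <- phantom$spec
  dm <- spec$dim
  if (protocol$n_slices < dm[3L]) {
    stop("protocol has fewer slices than the phantom grid", call. = FALSE)
  }
  truth <- phantom$truth[[condition]]
  if (is.null(truth)) stop("phantom lacks condition ", condition, call. = FALSE)
  if (is.null(seed)) {
    seed <- spec$seed + if (condition == "hyper") 104729L else 0L
  }
  noise_sd <- spec$noise_sd
  if (is.null(noise_sd)) {
    noise_sd <- auto_noise_sd(spec, phantom, protocol, consts, calib)
  }

  n_pld <- length(protocol$plds)
  R <- protocol$n_repeats
  par_tbl <- dplyr::distinct(truth, .data$label, .data$f, .data$att,
                             .data$abv, .data$att_art, .data$s, .data$p)

  # noiseless dM (in M0a units) per (label, slice): everything else is
  # broadcast, so simulation cost is independent of grid size
  dm_sig <- array(0, c(dm, n_pld))
  for (z in seq_len(dm[3L])) {
    for (i in seq_len(nrow(par_tbl))) {
      pr <- par_tbl[i, ]
      if (pr$f == 0 && pr$abv == 0) next
      sig <- model_signal(
        "art_disp",
        hemo_params(f = pr$f, att = pr$att, abv = pr$abv,
                    att_art = pr$att_art, s = pr$s, p = pr$p,
                    check = FALSE),
        protocol, consts, slice_index = z - 1L
      )$value
      sel <- phantom$labels[, , z] == pr$label
      for (k in seq_len(n_pld)) {
        plane <- dm_sig[, , z, k]
        plane[sel] <- sig[k]
        dm_sig[, , z, k] <- plane
      }
    }
  }

  baseline <- array(unname(spec$m0_scale[as.vector(phantom$labels)]), dm)
  m0a <- m0a_from_m0(baseline, calib)
  for (k in seq_len(n_pld)) {
    dm_sig[, , , k] <- dm_sig[, , , k] * m0a
  }

  rng <- local_rng(seed)
  nvol <- n_pld * R
  control <- array(0, c(dm, nvol))
  label <- array(0, c(dm, nvol))
  nv <- prod(dm)
  for (k in seq_len(n_pld)) {
    half <- dm_sig[, , , k] / 2
    for (r in seq_len(R)) {
      v <- (k - 1L) * R + r
      control[, , , v] <- baseline + half +
        array(rng$rnorm(nv, 0, noise_sd), dm)
      label[, , , v] <- baseline - half +
        array(rng$rnorm(nv, 0, noise_sd), dm)
    }
  }
  m0 <- baseline + array(rng$rnorm(nv, 0, noise_sd), dm)

  structure(
    list(control = control, label = label, m0 = m0,
         truth = truth, protocol = protocol, condition = condition,
         petco2 = spec$petco2, noise_sd = noise_sd, seed = seed,
         calib = calib),
    class = "asl_dataset"
  )
}

#' @export
print.asl_dataset <- function(x, ...) {
  dm <- dim(x$control)
  cat(sprintf("<asl_dataset> %s, %s grid, %d control/label pairs, noise sd %.2e\n",
              x$condition, paste(dm[1:3], collapse = " x "), dm[4L],
              x$noise_sd))
  invisible(x)
}

#' Average control-label pairs into per-PLD difference volumes
#'
#' Perfusion-weighted imaging: pairwise subtraction of control and
#' label volumes, then averaging the repeats of each PLD. Volumes must
#' be ordered PLD-major, repeat-minor, with control/label alternating
#' within each pair.
#'
#' @param series 4D array `x * y * z * (2 * n_pld * repeats)` of
#'   interleaved control/label pairs, or an `asl_dataset` (whose
#'   `control`/`label` arrays are used directly).
#' @param protocol An [asl_protocol()].
#' @param ordering `"control_first"` (default) or `"label_first"`
#'   within each pair.
#' @return 4D array `x * y * z * n_pld` of repeat-averaged difference
#'   signals.
#' @export
subtract_pairs <- function(series, protocol,
                           ordering = c("control_first", "label_first")) {
  ordering <- match.arg(ordering)
  n_pld <- length(protocol$plds)
  R <- protocol$n_repeats
  if (inherits(series, "asl_dataset")) {
    ctl <- series$control
    lab <- series$label
  } else {
    expected <- 2L * n_pld * R
    if (length(dim(series)) != 4L || dim(series)[4L] != expected) {
      stop(sprintf("expected %d volumes (2 x %d PLDs x %d repeats), got %d",
                   expected, n_pld, R,
                   if (length(dim(series)) == 4L) dim(series)[4L] else -1L),
           call. = FALSE)
    }
    first <- seq(1L, expected, by = 2L)
    if (ordering == "control_first") {
      ctl <- series[, , , first, drop = FALSE]
      lab <- series[, , , first + 1L, drop = FALSE]
    } else {
      lab <- series[, , , first, drop = FALSE]
      ctl <- series[, , , first + 1L, drop = FALSE]
    }
  }
  dmv <- dim(ctl)
  if (dmv[4L] != n_pld * R) {
    stop(sprintf("expected %d control/label pairs, got %d",
                 n_pld * R, dmv[4L]), call. = FALSE)
  }
  diffs <- ctl - lab
  out <- array(0, c(dmv[1:3], n_pld))
  for (k in seq_len(n_pld)) {
    idx <- (k - 1L) * R + seq_len(R)
    out[, , , k] <- apply(diffs[, , , idx, drop = FALSE], 1:3, mean)
  }
  out
}

#' Interleave an asl_dataset into a single acquisition series
#'
#' Produces the volume ordering [subtract_pairs()] expects
#' (PLD-major, repeat-minor, control/label alternating), which is also
#' the on-disk layout of the simulated 4D NIfTI.
#'
#' @param dataset An `asl_dataset`.
#' @param ordering Pair ordering.
#' @return A 4D array with `2 * n_pld * repeats` volumes.
#' @export
interleave_series <- function(dataset,
                              ordering = c("control_first",
                                           "label_first")) {
  ordering <- match.arg(ordering)
  dmv <- dim(dataset$control)
  out <- array(0, c(dmv[1:3], 2L * dmv[4L]))
  first <- seq(1L, 2L * dmv[4L], by = 2L)
  if (ordering == "control_first") {
    out[, , , first] <- dataset$control
    out[, , , first + 1L] <- dataset$label
  } else {
    out[, , , first] <- dataset$label
    out[, , , first + 1L] <- dataset$control
  }
  out
}
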