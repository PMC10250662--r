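#' Fit a kinetic model to every voxel in a mask
#'
#' Runs [vb_fit()] voxel-by-voxel over a repeat-averaged difference
#' volume with slice-correct sampling times (the 3rd array dimension is
#' the ascending slice direction). Optional jittered restarts re-run
#' the fit from perturbed initial transit times and keep the highest
#' free energy; restarts draw from a generator seeded by `opts$seed`,
#' so results are deterministic for a given seed.
#'
#' @param deltam 4D numeric array `x * y * z * n_pld` of per-PLD
#'   repeat-averaged difference signals.
#' @param mask 3D logical (or 0/1) array selecting voxels to fit.
#' @param model An [asl_model()] or model code.
#' @param protocol An [asl_protocol()].
#' @param consts An [asl_constants()].
#' @param priors Optional `asl_priors`; defaults per model.
#' @param opts A [vb_opts()].
#' @param n_restarts Number of fits per voxel (1 = no restarts).
#' @param quiet Suppress the convergence-fraction message?
#' @return A tibble of class `asl_param_maps`: one row per fitted voxel
#'   with coordinates (`x`, `y`, `z`), natural-scale parameter
#'   estimates (`ftiss` relative perfusion, `att`, `abv`, `att_art`,
#'   `s`, `p`), `free_energy`, `n_iter` and `converged`. The grid
#'   dimensions and model code are kept in attributes `vol_dim` and
#'   `model`.
#' @export
fit_volume <- function(deltam, mask, model, protocol, consts,
                       priors = NULL, opts = vb_opts(),
                       n_restarts = 1L, quiet = FALSE) {
  if (!inherits(model, "asl_model")) model <- asl_model(model)
  dm <- dim(deltam)
  if (length(dm) != 4L || dm[4L] != length(protocol$plds)) {
    stop("deltam must be a 4D array with one volume per PLD", call. = FALSE)
  }
  if (!identical(dim(mask), dm[1:3])) {
    stop("mask dimensions do not match the volume grid", call. = FALSE)
  }
  vox <- which(mask != 0, arr.ind = TRUE)
  dimnames(vox) <- NULL
  if (nrow(vox) == 0L) stop("mask is empty", call. = FALSE)
  if (is.null(priors)) priors <- default_priors(model)
  priors <- validate_priors(priors, model)

  jitters <- NULL
  if (n_restarts > 1L) {
    rng <- local_rng(opts$seed)
    jitters <- matrix(rng$rnorm((n_restarts - 1L) * 2L, 0, 0.25),
                      ncol = 2L)
  }

  rows <- vector("list", nrow(vox))
  for (i in seq_len(nrow(vox))) {
    x <- vox[i, 1L]; y <- vox[i, 2L]; z <- vox[i, 3L]
    sig <- deltam[x, y, z, ]
    fit <- vb_fit(sig, model, protocol, consts, priors = priors,
                  slice_index = z - 1L, opts = opts)
    if (n_restarts > 1L) {
      for (r in seq_len(n_restarts - 1L)) {
        pr2 <- priors
        pr2$mean[pr2$param == "att"] <-
          pr2$mean[pr2$param == "att"] + jitters[r, 1L]
        if ("att_art" %in% pr2$param) {
          pr2$mean[pr2$param == "att_art"] <-
            pr2$mean[pr2$param == "att_art"] + jitters[r, 2L]
        }
        alt <- vb_fit(sig, model, protocol, consts, priors = pr2,
                      slice_index = z - 1L, opts = opts)
        if (is.finite(alt$free_energy) &&
            (!is.finite(fit$free_energy) ||
             alt$free_energy > fit$free_energy)) {
          fit <- alt
        }
      }
    }
    np <- natural_params(fit$means)
    rows[[i]] <- c(x = x, y = y, z = z,
                   ftiss = np$f, att = np$att, abv = np$abv,
                   att_art = np$att_art, s = np$s, p = np$p,
                   free_energy = fit$free_energy,
                   n_iter = fit$n_iter,
                   converged = as.numeric(fit$converged))
  }
  out <- tibble::as_tibble(do.call(rbind, rows))
  out$converged <- out$converged > 0
  if (!quiet) {
    message(sprintf("fit_volume [%s]: %d voxels, %.1f%% converged",
                    model$code, nrow(out), 100 * mean(out$converged)))
  }
  tibble::new_tibble(out, vol_dim = dm[1:3], model = model$code,
                     class = "asl_param_maps")
}

# isolated RNG stream that does not disturb the global .Random.seed
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  draw <- function(fn, ...) {
    old2 <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old2)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old2, globalenv())
    }
    out
  }
  list(
    rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max)
  )
}

#' Convert a parameter-map tibble column to a 3D volume
#'
#' @param maps An `asl_param_maps` tibble (or any tibble with `x`,
#'   `y`, `z` and a `vol_dim` attribute).
#' @param var Column name to rasterize.
#' @param fill Value outside the fitted mask.
#' @return A 3D array.
#' @export
maps_to_volume <- function(maps, var, fill = NA_real_) {
  dm <- attr(maps, "vol_dim")
  if (is.null(dm)) stop("maps has no `vol_dim` attribute", call. = FALSE)
  vol <- array(fill, dm)
  vol[cbind(maps$x, maps$y, maps$z)] <- maps[[var]]
  vol
}

#' Compare fitted models by free energy
#'
#' The variational free energy approximates the log evidence for a
#' model, combining goodness of fit with a complexity penalty; values
#' closer to zero indicate a better model. For each voxel the model
#' with the highest free energy wins; exact ties go to the model with
#' fewer parameters.
#'
#' @param fits Named list of `asl_param_maps`, one per model code,
#'   fitted on the same voxel set.
#' @param membership Optional region membership tibble
#'   (see [region_membership()]) for a per-region mean-FE table.
#' @return A list of class `asl_model_comparison`:
#'   `voxel` (per-voxel winner tibble), `summary` (per-model mean FE
#'   and winner fraction), and `region_summary` when `membership` is
#'   supplied.
#' @export
compare_models <- function(fits, membership = NULL) {
  stopifnot(is.list(fits), length(fits) >= 1L, !is.null(names(fits)))
  codes <- names(fits)
  ref <- tibble::tibble(x = fits[[1L]]$x, y = fits[[1L]]$y,
                        z = fits[[1L]]$z)
  for (code in codes) {
    f <- fits[[code]]
    if (!identical(attr(f, "vol_dim"), attr(fits[[1L]], "vol_dim")) ||
        nrow(f) != nrow(ref) ||
        !all(f$x == ref$x & f$y == ref$y & f$z == ref$z)) {
      stop("all fits must share the same grid and voxel set", call. = FALSE)
    }
  }
  n_par <- vapply(codes, function(code) {
    length(asl_model(code)$parameter_names)
  }, numeric(1))

  fe <- vapply(codes, function(code) fits[[code]]$free_energy,
               numeric(nrow(ref)))
  fe <- matrix(fe, nrow = nrow(ref),
               dimnames = list(NULL, codes))
  # winner: max FE; exact ties to the model with fewest parameters
  # (columns scanned in increasing parameter count)
  ord <- order(n_par)
  win_idx <- ord[max.col(fe[, ord, drop = FALSE], ties.method = "first")]
  voxel <- dplyr::bind_cols(
    ref,
    tibble::tibble(winner = codes[win_idx])
  )
  for (code in codes) voxel[[paste0("fe_", code)]] <- fe[, code]

  summary <- tibble::tibble(
    model = codes,
    n_params = as.integer(n_par),
    mean_fe = unname(colMeans(fe)),
    winner_fraction = unname(vapply(codes, function(code) {
      mean(voxel$winner == code)
    }, numeric(1)))
  )
  summary <- dplyr::arrange(summary, dplyr::desc(.data$mean_fe))

  out <- list(voxel = voxel, summary = summary)
  if (!is.null(membership)) {
    long <- tidyr::pivot_longer(
      voxel, dplyr::starts_with("fe_"),
      names_to = "model", names_prefix = "fe_", values_to = "fe"
    )
    out$region_summary <- long |>
      dplyr::inner_join(membership, by = c("x", "y", "z"),
                        relationship = "many-to-many") |>
      dplyr::group_by(.data$region, .data$model) |>
      dplyr::summarise(mean_fe = mean(.data$fe), n = dplyr::n(),
                       .groups = "drop")
  }
  structure(out, class = "asl_model_comparison")
}

#' @export
print.asl_model_comparison <- function(x, ...) {
  cat("<asl_model_comparison>\n")
  print(x$summary)
  invisible(x)
}
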