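# Shared fixtures. Everything is generated in code; the only file-based
# fixture is the per-subject PETCO2 table under inst/extdata.

default_protocol <- function() asl_protocol()
default_consts <- function() asl_constants()

petco2_path <- function() {
  system.file("extdata", "petco2_subjects.tsv", package = "aslcvr")
}

# small noiseless phantom + one-condition dataset, shared by several files
small_noiseless <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(dim = c(16L, 16L, 2L), noise_sd = 0, seed = 7L)
      ph <- make_phantom(spec)
      dsn <- simulate_acquisition(ph, default_protocol(), default_consts(),
                                  "normo")
      cache <<- list(spec = spec, phantom = ph, dataset = dsn,
                     deltam = subtract_pairs(dsn, default_protocol()))
    }
    cache
  }
})

# The study-scale fixture behind the acceptance tests: 32x32x4 phantom at
# per-PLD-averaged peak-GM SNR 10, all four models fitted under
# normocapnia plus the generating model under hypercapnia. Computed once
# per test run and reused across acceptance blocks.
acceptance_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    pr <- default_protocol(); co <- default_consts()
    spec <- phantom_spec(seed = 1L)
    ph <- make_phantom(spec)
    mask <- ph$labels == "GM" | ph$labels == "artery"
    dsn <- simulate_acquisition(ph, pr, co, "normo")
    dsh <- simulate_acquisition(ph, pr, co, "hyper")
    dMn <- subtract_pairs(dsn, pr)
    dMh <- subtract_pairs(dsh, pr)
    fits <- lapply(
      stats::setNames(asl_model_codes(), asl_model_codes()),
      function(code) fit_volume(dMn, mask, code, pr, co, quiet = TRUE)
    )
    fit_h <- fit_volume(dMh, mask, "art_disp", pr, co, quiet = TRUE)
    calib <- calib_config(tr_calib = pr$tr)
    cal_n <- suppressMessages(calibrate_cbf(fits[["art_disp"]], dsn$m0, calib))
    cal_h <- suppressMessages(calibrate_cbf(fit_h, dsh$m0, calib))
    truth <- ph$truth$normo
    gm_ids <- with(truth[truth$label == "GM", ], paste(x, y, z))
    subset_gm <- function(m) {
      keep <- paste(m$x, m$y, m$z) %in% gm_ids
      out <- m[keep, ]
      attr(out, "vol_dim") <- attr(m, "vol_dim")
      class(out) <- class(m)
      out
    }
    cache <<- list(
      phantom = ph, spec = spec, protocol = pr, consts = co,
      fits = fits, fit_h = fit_h, cal_n = cal_n, cal_h = cal_h,
      fits_gm = lapply(fits, subset_gm),
      cal_n_gm = subset_gm(cal_n), cal_h_gm = subset_gm(cal_h),
      truth = truth, gm_ids = gm_ids
    )
    cache
  }
})
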