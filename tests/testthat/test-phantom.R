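pr <- asl_protocol()
co <- asl_constants()

test_that("condition defaults encode the hypercapnic parameter shifts", {
  n <- default_condition_params("normo")
  h <- default_condition_params("hyper")
  gm_n <- n[n$label == "GM", ]; gm_h <- h[h$label == "GM", ]
  expect_equal(gm_n$f, 60); expect_equal(gm_n$att, 1.0)
  expect_equal(gm_h$f, 60 * 1.33)        # 79.8
  expect_equal(gm_h$att, 0.85)
  expect_equal(h$abv[h$label == "artery"], 0.7)
  expect_equal(n$f[n$label == "CSF"], 0)
  expect_equal(n$f[n$label == "WM"], 20)
})

test_that("phantom construction is deterministic and label-consistent", {
  ph1 <- make_phantom(phantom_spec(seed = 3L))
  ph2 <- make_phantom(phantom_spec(seed = 3L))
  expect_identical(ph1$labels, ph2$labels)
  expect_identical(ph1$truth, ph2$truth)
  # labels partition the grid
  expect_equal(sum(table(ph1$labels)), prod(dim(ph1$labels)))
  expect_true(all(ph1$gm_pve %in% c(0, 1)))
  expect_identical(ph1$gm_pve == 1, ph1$labels == "GM")
  # GM mask from the PVE map recovers exactly the GM label set
  expect_identical(gm_mask(ph1$gm_pve, 0.3), ph1$labels == "GM")
  # ROI quadrants partition GM into four non-empty pseudo-lobes
  rois <- table(ph1$roi[ph1$labels == "GM"])
  expect_equal(length(rois), 4L)
  expect_true(all(rois > 0))
})

test_that("noiseless acquisition reproduces the forward model exactly", {
  fx <- small_noiseless()
  ph <- fx$phantom
  for (lab in c("GM", "WM", "artery")) {
    idx <- which(ph$labels == lab, arr.ind = TRUE)[1, ]
    tru <- ph$truth$normo
    tru <- tru[tru$x == idx[1] & tru$y == idx[2] & tru$z == idx[3], ]
    sig <- model_signal(
      "art_disp",
      hemo_params(f = tru$f, att = tru$att, abv = tru$abv,
                  att_art = tru$att_art, s = tru$s, p = tru$p,
                  check = FALSE),
      pr, co, slice_index = idx[3] - 1L
    )$value
    m0a <- aslcvr:::m0a_from_m0(tru$m0, calib_config(tr_calib = pr$tr))
    expect_equal(fx$deltam[idx[1], idx[2], idx[3], ], sig * m0a,
                 tolerance = 1e-12)
  }
  # background voxels carry no signal
  bg <- which(ph$labels == "background", arr.ind = TRUE)[1, ]
  expect_equal(fx$deltam[bg[1], bg[2], bg[3], ], rep(0, 6))
})

test_that("simulated noise has the configured subtraction SD", {
  spec <- phantom_spec(dim = c(16L, 16L, 2L), noise_sd = 0.002, seed = 21L)
  ph <- make_phantom(spec)
  ds <- simulate_acquisition(ph, pr, co, "normo")
  diffs <- ds$control - ds$label
  # remove the deterministic dM part by differencing repeats of one PLD
  d1 <- diffs[, , , 1] - diffs[, , , 2]
  expect_lt(abs(sd(d1) - 2 * 0.002) / (2 * 0.002), 0.1)
  # per-PLD averaged subtraction noise: sqrt(2)*sd/sqrt(R)
  dM <- subtract_pairs(ds, pr)
  bg <- ph$labels == "background"
  resid <- dM[, , , 1][bg]
  expect_lt(abs(sd(resid) - sqrt(2) * 0.002 / sqrt(8)) /
              (sqrt(2) * 0.002 / sqrt(8)), 0.1)
})

test_that("the default noise level hits the target peak-GM SNR", {
  spec <- phantom_spec(dim = c(16L, 16L, 2L), seed = 5L)  # SNR target 10
  ph <- make_phantom(spec)
  ds <- simulate_acquisition(ph, pr, co, "normo")
  gm <- ph$truth$normo[ph$truth$normo$label == "GM", ][1, ]
  m0a <- aslcvr:::m0a_from_m0(gm$m0, calib_config(tr_calib = pr$tr))
  peak <- max(model_signal(
    "art_disp",
    hemo_params(f = gm$f, att = gm$att, abv = gm$abv,
                att_art = gm$att_art, s = gm$s, p = gm$p, check = FALSE),
    pr, co, slice_index = 0L
  )$value) * m0a
  sd_avg <- sqrt(2) * ds$noise_sd / sqrt(pr$n_repeats)
  expect_equal(peak / sd_avg, 10, tolerance = 1e-10)
})

test_that("same seed gives identical data; different seeds decorrelate", {
  spec <- phantom_spec(dim = c(16L, 16L, 2L), seed = 9L)
  ph <- make_phantom(spec)
  d1 <- simulate_acquisition(ph, pr, co, "normo")
  d2 <- simulate_acquisition(ph, pr, co, "normo")
  expect_identical(d1$control, d2$control)
  d3 <- simulate_acquisition(ph, pr, co, "normo", seed = 10L)
  # background voxels carry pure noise: distinct seeds must decorrelate
  bg <- which(array(ph$labels == "background", dim(d1$control)))
  expect_lt(abs(cor(d1$control[bg], d3$control[bg])), 0.05)
  # conditions draw independent noise automatically
  dh <- simulate_acquisition(ph, pr, co, "hyper")
  expect_false(identical(dh$seed, d1$seed))
})

test_that("hypercapnic grey matter peaks earlier and higher", {
  tg <- seq(0, 4.5, by = 0.005)
  n <- default_condition_params("normo"); n <- n[n$label == "GM", ]
  h <- default_condition_params("hyper"); h <- h[h$label == "GM", ]
  sn <- tissue_curve_numeric(
    hemo_params(f = n$f, att = n$att, s = n$s, p = n$p), co, tg,
    dispersed = TRUE
  )
  sh <- tissue_curve_numeric(
    hemo_params(f = h$f, att = h$att, s = h$s, p = h$p), co, tg,
    dispersed = TRUE
  )
  expect_gt(max(sh$value), max(sn$value))
  expect_lt(tg[which.max(sh$value)], tg[which.max(sn$value)])
})

test_that("ground truth survives a JSON round trip and a noiseless refit", {
  fx <- small_noiseless()
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(fx$phantom$truth$normo, path, digits = NA)
  back <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  expect_equal(back$f, fx$phantom$truth$normo$f)
  expect_equal(back$att, fx$phantom$truth$normo$att)

  gm_idx <- which(fx$phantom$labels == "GM", arr.ind = TRUE)
  mask <- array(FALSE, dim(fx$phantom$labels))
  mask[gm_idx[seq(1, nrow(gm_idx), by = 6), , drop = FALSE]] <- TRUE
  maps <- fit_volume(fx$deltam, mask, "art_disp", pr, co, quiet = TRUE)
  cal <- suppressMessages(
    calibrate_cbf(maps, fx$dataset$m0, calib_config(tr_calib = pr$tr))
  )
  j <- dplyr::inner_join(cal, back, by = c("x", "y", "z"))
  expect_lt(max(abs(j$cbf - j$f) / j$f), 0.01)
  expect_lt(max(abs(j$att.x - j$att.y)), 0.02)
})

test_that("protocol/phantom mismatches are caught", {
  ph <- make_phantom(phantom_spec(dim = c(16L, 16L, 2L), seed = 1L))
  small_proto <- asl_protocol(n_slices = 1L)
  expect_error(simulate_acquisition(ph, small_proto, co, "normo"),
               "fewer slices")
})
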