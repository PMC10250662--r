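fake_maps <- function(ftiss, dm = c(3L, 1L, 1L), att = 1, abv = 0) {
  n <- length(ftiss)
  tibble::new_tibble(
    tibble::tibble(x = seq_len(n), y = rep(1L, n), z = rep(1L, n),
                   ftiss = ftiss, att = att, abv = abv,
                   free_energy = -1),
    vol_dim = dm, model = "noart_nodisp", class = "asl_param_maps"
  )
}

test_that("CBF calibration is linear in the fitted amplitude", {
  m0 <- array(1, c(3, 1, 1))
  cfg <- calib_config(saturation_correction = FALSE)
  c1 <- calibrate_cbf(fake_maps(c(30, 60, 90)), m0, cfg)
  c2 <- calibrate_cbf(fake_maps(2 * c(30, 60, 90)), m0, cfg)
  expect_equal(c2$cbf, 2 * c1$cbf)
  # M0a = m0 / lambda without saturation correction
  expect_equal(c1$cbf, c(30, 60, 90) / (1 / 0.9))
})

test_that("saturation correction raises M0a by the recovery factor", {
  m0 <- array(1, c(3, 1, 1))
  base <- calibrate_cbf(fake_maps(c(60, 60, 60)), m0,
                        calib_config(saturation_correction = FALSE))
  corr <- calibrate_cbf(fake_maps(c(60, 60, 60)), m0,
                        calib_config(tr_calib = 4.1,
                                     saturation_correction = TRUE,
                                     t1_tissue_for_sat = 1.3))
  expect_equal(corr$cbf, base$cbf * (1 - exp(-4.1 / 1.3)))
})

test_that("zero-M0 voxels are excluded and counted", {
  m0 <- array(c(0, 1, 1), c(3, 1, 1))
  expect_message(
    cal <- calibrate_cbf(fake_maps(c(60, 60, 60)), m0, calib_config()),
    "1 voxel"
  )
  expect_true(is.na(cal$cbf[1]))
  expect_equal(attr(cal, "n_excluded"), 1L)
  expect_error(
    calibrate_cbf(fake_maps(c(60, 60, 60)), array(1, c(2, 1, 1)),
                  calib_config()),
    "grid"
  )
})

test_that("tissue masks threshold strictly", {
  pve <- array(c(0.29, 0.3, 0.31, 1), c(4, 1, 1))
  m <- gm_mask(pve)
  expect_equal(as.vector(m), c(FALSE, FALSE, TRUE, TRUE))
  expect_error(gm_mask(array(1.2, c(1, 1, 1))), "\\[0, 1\\]")
  expect_equal(as.vector(arterial_mask(c(0.69, 0.7, 0.71))),
               c(FALSE, FALSE, TRUE))
  expect_false(any(arterial_mask(rep(0, 10))))
  expect_error(arterial_mask(c(1, NA)), "finite")
})

test_that("CVR follows its defining ratio and the denominator floor", {
  n <- fake_maps(c(60, 60, 0.5)); n$cbf <- c(60, 60, 0.5)
  h <- fake_maps(c(80, 60, 5)); h$cbf <- c(80, 60, 5)
  cv <- cvr_map(n, h, delta_petco2 = 8)
  expect_equal(cv$cvr[1], 100 * (20 / 60) / 8, tolerance = 1e-12)
  expect_equal(cv$cvr[2], 0)
  expect_true(is.na(cv$cvr[3]))          # below the 1 ml/100g/min floor
  expect_equal(attr(cv, "n_floored"), 1L)
  expect_error(cvr_map(n, h, 0), "> 0")
  # invariant under common rescaling of both CBF maps
  n2 <- n; n2$cbf <- n$cbf * 3.7
  h2 <- h; h2$cbf <- h$cbf * 3.7
  cv2 <- cvr_map(n2, h2, delta_petco2 = 8, floor = 1e-9)
  cv1 <- cvr_map(n, h, delta_petco2 = 8, floor = 1e-9)
  expect_equal(cv2$cvr, cv1$cvr)
})

test_that("condition deltas subtract hyper minus normo with floors", {
  n <- fake_maps(c(60, 60), dm = c(2L, 1L, 1L), att = c(1, 0.01),
                 abv = c(1, 0))
  h <- fake_maps(c(80, 80), dm = c(2L, 1L, 1L), att = c(0.85, 0.02),
                 abv = c(0.7, 0))
  d0 <- condition_deltas(n, n)
  expect_equal(d0$datt, c(0, 0))
  expect_equal(d0$dabv, c(0, 0))
  d <- condition_deltas(n, h)
  expect_equal(d$datt, c(-0.15, 0.01))
  expect_equal(d$datt_pct[1], 100 * (-0.15) / 1)
  expect_true(is.na(d$datt_pct[2]))  # att below floor
  expect_equal(d$dabv[1], -0.3)
  expect_true(is.na(d$dabv_pct[2]))  # abv below floor
  expect_equal(attr(d, "n_floored_att"), 1L)
})

test_that("regional summaries use sample SD and skip undefined voxels", {
  vals <- tibble::tibble(x = 1:4, y = 1L, z = 1L,
                         cbf = c(50, 60, 70, NA))
  membership <- tibble::tibble(x = c(1:4, 2L), y = 1L, z = 1L,
                               region = c(rep("GM", 4), "single"))
  rs <- regional_summary(vals, membership, "cbf")
  gm <- rs[rs$region == "GM", ]
  expect_equal(gm$mean, 60)
  expect_equal(gm$sd, sd(c(50, 60, 70)))
  expect_equal(gm$n_region, 4L)
  expect_equal(gm$n_used, 3L)
  single <- rs[rs$region == "single", ]
  expect_equal(single$mean, 60)   # single-voxel ROI mean = voxel value
  expect_equal(single$n_used, 1L)
})

test_that("region membership intersects ROIs with GM and adds arterial", {
  roi <- array(c("a", "a", "b", "b"), c(4, 1, 1))
  gm <- array(c(TRUE, FALSE, TRUE, TRUE), c(4, 1, 1))
  art <- array(c(FALSE, TRUE, FALSE, FALSE), c(4, 1, 1))
  mem <- region_membership(roi, gm, art)
  expect_equal(sum(mem$region == "GM"), 3L)
  expect_equal(sum(mem$region == "a"), 1L)   # voxel 2 dropped (not GM)
  expect_equal(sum(mem$region == "b"), 2L)
  expect_equal(mem$x[mem$region == "arterial"], 2L)  # not GM-intersected
})

test_that("group PETCO2 statistics reproduce the printed subject table", {
  rec <- read_petco2(petco2_path())
  expect_equal(nrow(rec), 10L)
  ps <- petco2_summary(rec)
  expect_equal(ps$subjects$delta[1], 8.2)
  g <- ps$group
  expect_equal(g$mean_report[g$quantity == "petco2_normo"], 38.8)
  expect_equal(g$sd_report[g$quantity == "petco2_normo"], 2.6)
  expect_equal(g$mean_report[g$quantity == "petco2_hyper"], 46.6)
  expect_equal(g$sd_report[g$quantity == "petco2_hyper"], 2.6)
  expect_equal(g$mean_report[g$quantity == "delta"], 7.8)
  expect_equal(g$sd_report[g$quantity == "delta"], 0.8)
  expect_warning(petco2_summary(rec[1, ]), "SD undefined")
  one <- suppressWarnings(petco2_summary(rec[1, ]))
  expect_equal(one$subjects$delta, 8.2)
})
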