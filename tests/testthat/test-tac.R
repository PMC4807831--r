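test_that("ROI selection implements the first-frame threshold rule", {
  proto <- acquisition_protocol(c(30, 30))
  sc <- scanner_model(voxel_size = 1, grid_shape = c(16, 16, 16))

  # single nonzero voxel: mask is exactly that voxel
  s <- render_frames(c(1e5, 1e5), sc,
                     injection_spec(activity = 1e6, source_sigma = 0),
                     proto)
  # collapse the spot to one voxel by zeroing everything but the max
  vol <- s$values[, , , 1]
  keep <- which.max(vol)
  s$values[] <- 0
  for (f in 1:2) {
    v <- array(0, dim = dim(vol))
    v[keep] <- 100
    s$values[, , , f] <- v
  }
  roi <- select_roi(s)
  expect_equal(roi$voxel_count, 1L)
  expect_true(roi$mask[keep])

  # smooth peak: mask equals the brute-force scan of the lattice
  s2 <- small_series(lambda = 0, A0 = 1e6)
  roi2 <- select_roi(s2, threshold_fraction = 0.5)
  ref <- s2$values[, , , 1]
  brute <- array(FALSE, dim = dim(ref))
  mx <- max(ref)
  for (i in seq_len(dim(ref)[1])) {
    for (j in seq_len(dim(ref)[2])) {
      for (k in seq_len(dim(ref)[3])) {
        brute[i, j, k] <- ref[i, j, k] > 0.5 * mx
      }
    }
  }
  brute[which.max(ref)] <- TRUE
  expect_identical(roi2$mask, brute)
  expect_equal(roi2$voxel_count, sum(brute))

  # near-unity threshold keeps only the peak voxel (source placed at a
  # voxel centre so the peak is unique)
  s3 <- small_series(lambda = 0, A0 = 1e6,
                     injection = injection_spec(activity = 1e6,
                                                position = rep(6.25, 3)))
  roi3 <- select_roi(s3, threshold_fraction = 0.999)
  expect_equal(roi3$voxel_count, 1L)

  # all-zero reference frame has no source
  s$values[] <- 0
  expect_error(select_roi(s), "no source")
})

test_that("raising the threshold never grows the mask", {
  s <- small_series(lambda = 0, A0 = 1e6,
                    scanner = scanner_model(voxel_size = 1,
                                            grid_shape = c(16, 16, 16)))
  prev <- NULL
  for (thr in seq(0.05, 0.95, by = 0.05)) {
    m <- select_roi(s, threshold_fraction = thr)$mask
    if (!is.null(prev)) expect_true(all(prev | !m)) # m subset of prev
    prev <- m
  }
})

test_that("extracted TACs reproduce the generative kinetics", {
  proto <- acquisition_protocol()

  # constant biology under physical decay, decay-corrected: flat TAC at
  # A0 x ROI mass fraction
  s <- small_series(lambda = 0, A0 = 1e6, include_physical_decay = TRUE)
  roi <- select_roi(s)
  spot <- s$values[, , , 1] / sum(s$values[, , , 1])
  frac <- sum(spot[roi$mask])
  tac <- extract_tac(s, roi, decay_correct = TRUE)
  expect_equal(tac$value, rep(1e6 * frac, 25), tolerance = 1e-9)
  expect_true(is_decay_corrected(tac))

  # dead-condition series: TAC proportional to the frame-averaged
  # tissular exponential (central pipeline oracle), < 1e-6 relative
  lam <- halflife_to_lambda(2878)
  sd_ <- small_series(lambda = lam, A0 = 1e6)
  roid <- select_roi(sd_)
  tacd <- extract_tac(sd_, roid, decay_correct = FALSE)
  p <- two_component_params(lam, 0, A0 = 1e6)
  model <- frame_average_activity(p, "dead", proto,
                                  include_physical_decay = FALSE)
  ratio <- tacd$value / model
  expect_lt(max(abs(ratio / ratio[1] - 1)), 1e-6)

  # decay correction inverts pure physical decay exactly
  su <- small_series(lambda = 0, A0 = 1e6, include_physical_decay = TRUE)
  tacu <- extract_tac(su, select_roi(su), decay_correct = TRUE)
  expect_lt(max(abs(tacu$value / tacu$value[1] - 1)), 1e-9)

  # full noiseless chain after decay correction matches the biological
  # frame average to 1e-6 relative
  pfull <- two_component_params(lam, halflife_to_lambda(330), A0 = 0.9e6)
  act <- frame_average_activity(pfull, "alive", proto,
                                include_physical_decay = FALSE)
  sfull <- render_frames(act, small_scanner(),
                         injection_spec(activity = 0.9e6), proto)
  tfull <- extract_tac(sfull, select_roi(sfull), decay_correct = FALSE)
  r <- tfull$value / act
  expect_lt(max(abs(r / r[1] - 1)), 1e-6)
})

test_that("TAC extraction is linear in the series under a fixed mask", {
  s1 <- small_series(lambda = halflife_to_lambda(2000), A0 = 1e6)
  s2 <- small_series(lambda = halflife_to_lambda(400), A0 = 5e5)
  roi <- select_roi(s1)
  ssum <- s1
  ssum$values <- s1$values + s2$values
  t1 <- extract_tac(s1, roi, decay_correct = FALSE)
  t2 <- extract_tac(s2, roi, decay_correct = FALSE)
  ts <- extract_tac(ssum, roi, decay_correct = FALSE)
  expect_equal(ts$value, t1$value + t2$value, tolerance = 1e-12)
})

test_that("mismatched ROI and series geometries are rejected", {
  s <- small_series(lambda = 0)
  s16 <- small_series(lambda = 0,
                      scanner = scanner_model(voxel_size = 1,
                                              grid_shape = c(16, 16, 16)))
  roi <- select_roi(s16)
  expect_error(extract_tac(s, roi), "does not match")
})

test_that("FWHM measurement recovers the Gaussian width", {
  proto1 <- acquisition_protocol(30)

  # sigma = 1 mm on a fine grid: FWHM = 2.3548 mm within 2%
  sc_fine <- scanner_model(psf_fwhm = 2.3548, sensitivity = 0.1,
                           voxel_size = 0.25, grid_shape = c(64, 64, 64))
  s <- render_frames(1e6, sc_fine,
                     injection_spec(activity = 1e6, source_sigma = 0),
                     proto1)
  expect_equal(as.numeric(measure_fwhm(s)), 2.3548, tolerance = 0.02)

  # default scanner + 0.5 mm deposit: quadrature-sum oracle
  # sqrt(1.5^2 + (2.3548 * 0.5)^2) = 1.9069 mm, within 10%
  s05 <- render_frames(1e6, scanner_model(),
                       injection_spec(activity = 1e6, source_sigma = 0.5),
                       proto1)
  expect_equal(as.numeric(measure_fwhm(s05)), 1.906907, tolerance = 0.10)

  # default deposit (0.6 mm): sqrt(1.5^2 + (2.3548 * 0.6)^2) = 2.0606 mm
  s06 <- render_frames(1e6, scanner_model(), injection_spec(activity = 1e6),
                       proto1)
  expect_equal(as.numeric(measure_fwhm(s06)), 2.060646, tolerance = 0.10)

  # doubling the voxel size leaves the FWHM unchanged within
  # interpolation error
  sc2 <- scanner_model(voxel_size = 1.0, grid_shape = c(16, 16, 16))
  s06b <- render_frames(1e6, sc2, injection_spec(activity = 1e6), proto1)
  expect_equal(as.numeric(measure_fwhm(s06b)),
               as.numeric(measure_fwhm(s06)), tolerance = 0.15)

  # per-axis attribute present and isotropic here
  pa <- attr(measure_fwhm(s06), "per_axis")
  expect_named(pa, c("x", "y", "z"))
  expect_lt(diff(range(pa)), 1e-6)
})

test_that("TAC tables round-trip through as_tac with validation", {
  d <- data.frame(t_start = c(0, 30, 60), duration = 30,
                  value = c(100, 90, 81))
  tac <- as_tac(d)
  expect_s3_class(tac, "tac")
  expect_equal(tac$t_mid, c(15, 45, 75))
  bad <- data.frame(t_start = c(60, 30, 0), duration = 30, value = 1:3)
  expect_error(as_tac(bad), "increasing")
  expect_error(as_tac(data.frame(t_start = 0, duration = 30, value = -1)),
               ">= 0")
})
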