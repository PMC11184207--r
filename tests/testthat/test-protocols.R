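test_that("sodium-current scaling shifts conduction velocity around the calibrated bulk", {
  pr <- tissue_properties(cv_strip(), sigma_cal())
  cv_lo <- as.numeric(measure_cv(cv_strip(), pr, ionic_profile(INa = 0.5)))
  cv_mid <- calib()$cv_cm_s
  cv_hi <- as.numeric(measure_cv(cv_strip(), pr, ionic_profile(INa = 1.5)))
  expect_lt(cv_lo, cv_mid)
  expect_gt(cv_hi, cv_mid)
})

test_that("inexcitable tissue reports a block, not a number", {
  pr <- tissue_properties(cv_strip(), sigma_cal())
  cv <- measure_cv(cv_strip(), pr, ionic_profile(INa = 0.02), max_ms = 120)
  expect_true(is.na(cv))
  expect_equal(attr(cv, "status"), "block")
})

test_that("tissue ERP sits near the cellular APD and responds to IKr block", {
  strip <- make_sheet(50, 3, 400)
  pr <- tissue_properties(strip, sigma_cal())
  erp <- measure_erp(strip, pr)
  expect_true(is.finite(erp))
  apd <- measure_biomarkers(run_ap(pacing_cl = 600, n_beats = 4L))$apd90_ms
  expect_gte(as.numeric(erp), apd - 30)
  erp_blk <- measure_erp(strip, pr, ionic_profile(IKr = 0.3))
  expect_gt(as.numeric(erp_blk), as.numeric(erp))
  # class-III drug effect: amiodarone lengthens the tissue ERP
  erp_amio <- measure_erp(strip, pr, drug = drug_preset("amiodarone_3.0"))
  expect_gte(as.numeric(erp_amio), as.numeric(erp))
  # deterministic to the grid resolution
  erp2 <- measure_erp(strip, pr)
  expect_lte(abs(as.numeric(erp2) - as.numeric(erp)), 5)
})

test_that("pulmonary vein isolation is minimal, complete and idempotent", {
  m <- demo_atria()
  m2 <- apply_pvi(m)
  la_body <- which(m2$region == "la_body" & m2$active & !m2$removed)
  xy <- atriasim:::node_xy(m2)
  rings <- attr(m2, "pvi_rings")
  for (k in 1:4) {
    pv <- landmark(m2, paste0("pv", k))
    cx <- mean(xy$x[pv]); cy <- mean(xy$y[pv])
    d <- sqrt((xy$x - cx)^2 + (xy$y - cy)^2)
    far <- la_body[d[la_body] > max(d[rings[[paste0("pv", k)]]]) + m2$h_mm]
    expect_false(is_connected(m2, pv, far))
    # minimality: the next annulus inward would overlap the vein itself
    r_used <- stats::median(d[rings[[paste0("pv", k)]]])
    expect_gt(max(d[pv]), r_used - 1.75 * m2$h_mm)
  }
  m3 <- apply_pvi(m2)
  expect_identical(m2$removed, m3$removed)
  expect_error(apply_pvi(make_sheet(10, 10, 1000)), "pv1")
})

test_that("a stimulus inside an isolated vein cannot excite the atrial body", {
  m <- apply_pvi(demo_atria())
  pr <- tissue_properties(m, sigma_cal())
  pv <- landmark(m, "pv1")
  pw <- landmark(m, "posterior_wall")
  cfg <- solver_config(record_ms = 0)
  traj <- run_monodomain(m, pr, duration_ms = 150, config = cfg,
                         stims = list(stimulus(pv, 0, 3, 60)),
                         probes = pw[1])
  expect_lt(max(traj$probe_vm), -60)
})

test_that("re-entry induction is deterministic and degenerates to rest", {
  m <- make_sheet(30, 30, 600)
  none <- induce_reentry(m, tibble::tibble(x = numeric(), y = numeric()))
  expect_equal(none, atriasim:::resting_state_matrix(m))
  cores <- tibble::tibble(x = 9, y = 9)
  a <- induce_reentry(m, cores)
  b <- induce_reentry(m, cores)
  expect_identical(a, b)
  m2 <- remove_elements(m, which.min((atriasim:::node_xy(m)$x - 9)^2 +
                                       (atriasim:::node_xy(m)$y - 9)^2))
  expect_error(induce_reentry(m2, cores), "removed")
})

test_that("sustainment verdicts follow activity in the final window and are threshold-robust", {
  m <- make_sheet(4, 4, 1000)
  times <- seq(0, 3000, by = 5)
  quiet <- matrix(-80, length(times), 16)
  quiet[times <= 400, ] <- rep(c(-80, 20), length.out = sum(times <= 400) * 16)
  tq <- fake_trajectory(m, times, quiet)
  vq <- assess_sustainment(tq, window_ms = 3000)
  expect_false(vq$sustained)
  expect_lte(vq$termination_ms, 500)
  active <- matrix(-80 + 120 * (sin(2 * pi * times / 150) > 0),
                   length(times), 16)
  ta <- fake_trajectory(m, times, active)
  expect_true(assess_sustainment(ta, window_ms = 3000)$sustained)
  for (thr in c(8, 12)) {
    expect_false(assess_sustainment(tq, window_ms = 3000,
                                    dvdt_thresh_v_s = thr)$sustained)
    expect_true(assess_sustainment(ta, window_ms = 3000,
                                   dvdt_thresh_v_s = thr)$sustained)
  }
  expect_error(assess_sustainment(ta, window_ms = 9000), "shorter")
})
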