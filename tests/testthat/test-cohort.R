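test_that("profile sampling respects bounds, seed and the small-spread limit", {
  p <- sample_profiles(40, spread = 0.5, seed = 1)
  expect_equal(nrow(p), 40)
  sc <- as.matrix(p[, paste0("scale_", current_names())])
  expect_true(all(sc >= 0.5 & sc <= 1.5))
  expect_identical(p, sample_profiles(40, spread = 0.5, seed = 1))
  tiny <- sample_profiles(5, spread = 1e-9, seed = 2)
  expect_equal(as.numeric(as.matrix(tiny[, -1])), rep(1, 45),
               tolerance = 1e-6)
  expect_error(sample_profiles(3, spread = 0), "spread")
})

test_that("cohort cardinality follows profiles x anatomies x LVA states", {
  pr <- sample_profiles(40, seed = 1)
  an <- sample_anatomy_scales(10, seed = 2)
  expect_equal(nrow(build_cohort(pr, an, TRUE)), 800)
  expect_equal(nrow(build_cohort(pr, an, FALSE)), 400)
  expect_equal(nrow(build_cohort(pr[1, ], an[1, ], FALSE)), 1)
  # LVA twins share profile and anatomy
  co <- build_cohort(pr, an, TRUE)
  twins <- dplyr::count(co, profile_id, anatomy_id)
  expect_true(all(twins$n == 2))
  dup <- dplyr::bind_rows(pr[1, ], pr[1, ])
  expect_error(build_cohort(dup, an), "duplicate")
})

test_that("anatomy sampling matches its distribution and truncation", {
  a <- sample_anatomy_scales(4000, seed = 7)
  expect_gt(min(a$ra_volume_ml, a$la_volume_ml), 20)
  # sample means within 3 standard errors of the truncated-normal means
  # (truncation at 20 mL shifts the mean up slightly; allow that shift)
  expect_lt(abs(mean(a$ra_volume_ml) - 127), 3 * 51 / sqrt(4000) + 3)
  expect_lt(abs(mean(a$la_volume_ml) - 105), 3 * 39 / sqrt(4000) + 2)
  expect_identical(a, sample_anatomy_scales(4000, seed = 7))
})

test_that("profile calibration keeps exactly the in-range profiles", {
  pr <- dplyr::bind_rows(baseline_profile(), sample_profiles(7, seed = 3))
  wide <- calibration_ranges(apd90_ms = c(1e-6, 1e6),
                             resting_vm_mv = c(-1e6, 1e6),
                             peak_vm_mv = c(-1e6, 1e6),
                             dvdt_max_v_s = c(-1e6, 1e6))
  kept <- calibrate_profiles(pr, wide, n_beats = 2L)
  expect_setequal(kept$profile_id, pr$profile_id)

  # a window that excludes the baseline APD90 rejects it, naming the reason
  bm0 <- measure_biomarkers(run_ap(n_beats = 2L))
  narrow <- calibration_ranges(apd90_ms = bm0$apd90_ms + c(50, 100))
  res <- calibrate_profiles(baseline_profile(), narrow, n_beats = 2L)
  expect_equal(nrow(res), 0)
  rej <- attr(res, "rejections")
  expect_match(rej$reason, "apd90")

  # brute-force per-profile oracle gives the same accepted set
  rng <- calibration_ranges()
  kept2 <- calibrate_profiles(pr, rng, n_beats = 2L)
  oracle_keep <- vapply(seq_len(nrow(pr)), function(i) {
    bm <- tryCatch(measure_biomarkers(run_ap(pr[i, ], n_beats = 2L)),
                   error = function(e) NULL)
    !is.null(bm) &&
      bm$apd90_ms >= rng$apd90_ms[1] && bm$apd90_ms <= rng$apd90_ms[2] &&
      bm$resting_vm_mv >= rng$resting_vm_mv[1] &&
      bm$resting_vm_mv <= rng$resting_vm_mv[2] &&
      bm$peak_vm_mv >= rng$peak_vm_mv[1] &&
      bm$peak_vm_mv <= rng$peak_vm_mv[2] &&
      bm$dvdt_max_v_s >= rng$dvdt_max_v_s[1] &&
      bm$dvdt_max_v_s <= rng$dvdt_max_v_s[2]
  }, logical(1))
  expect_setequal(kept2$profile_id, pr$profile_id[oracle_keep])

  # widening every interval never removes an accepted profile
  wider <- calibration_ranges(apd90_ms = rng$apd90_ms + c(-30, 30),
                              resting_vm_mv = rng$resting_vm_mv + c(-5, 5),
                              peak_vm_mv = rng$peak_vm_mv + c(-5, 5),
                              dvdt_max_v_s = rng$dvdt_max_v_s + c(-20, 20))
  kept3 <- calibrate_profiles(pr, wider, n_beats = 2L)
  expect_true(all(kept2$profile_id %in% kept3$profile_id))
})
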