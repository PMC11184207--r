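test_that("an unstimulated cell stays at rest", {
  st <- cell_initial_state()
  st2 <- step_cell(st, n_steps = 1000L)
  expect_lt(abs(st2[["V"]] - st[["V"]]), 1)
})

test_that("a drug with all-zero block equals no drug exactly", {
  null_drug <- drug_spec("placebo", 1,
                         c(IKr = 0, INa = 0, ICaL = 0, IK1 = 0))
  st <- cell_initial_state()
  a <- step_cell(st, drug = NULL, I_stim = 25, n_steps = 500L)
  b <- step_cell(st, drug = null_drug, I_stim = 25, n_steps = 500L)
  expect_identical(a, b)
})

test_that("scaling composition is multiplicative and order-independent", {
  pr <- ionic_profile(INa = 0.7, IKr = 1.3)
  dr <- drug_preset("amiodarone_3.0")
  sc <- effective_scales(pr, "pv_sleeve", dr)
  manual <- atriasim:::profile_scales(pr) *
    atriasim:::region_scales("pv_sleeve") * atriasim:::drug_scales(dr)
  expect_equal(sc, manual)
  # reordering the factor product changes nothing
  manual2 <- atriasim:::drug_scales(dr) *
    atriasim:::profile_scales(pr) * atriasim:::region_scales("pv_sleeve")
  expect_equal(sc, manual2)
})

test_that("pore-block presets reduce clamp peak currents by the preset fraction", {
  ikr <- clamp_block_assay("IKr", drug_preset("amiodarone_3.0"))
  expect_equal(ikr$reduction_pct, 70, tolerance = 0.01)
  ina <- clamp_block_assay("INa", drug_preset("vernakalant_30"))
  expect_equal(ina$reduction_pct, 70, tolerance = 0.01)
})

test_that("baseline paced action potential is physiological", {
  bm <- measure_biomarkers(run_ap())
  expect_gt(bm$peak_vm_mv, 0)
  rng <- calibration_ranges()
  expect_gt(bm$apd90_ms, rng$apd90_ms[1])
  expect_lt(bm$apd90_ms, rng$apd90_ms[2])
})

test_that("blocking the rapid delayed rectifier prolongs the action potential", {
  base <- measure_biomarkers(run_ap())
  slow <- measure_biomarkers(run_ap(ionic_profile(IKr = 0.3)))
  expect_gt(slow$apd90_ms, base$apd90_ms)
})

test_that("pacing is deterministic and causal across beat counts", {
  a <- run_ap(n_beats = 1L)
  b <- run_ap(n_beats = 1L)
  expect_identical(a$vm_mv, b$vm_mv)
  # the first beat of a longer run is unaffected by later stimuli
  two <- run_ap(n_beats = 2L, pacing_cl = 600)
  one <- run_ap(n_beats = 1L, pacing_cl = 600)
  st1 <- attr(one, "final_state")
  # continuing the 1-beat run one more beat reproduces the 2-beat last beat
  cont <- run_ap(n_beats = 1L, pacing_cl = 600, init = st1)
  expect_equal(cont$vm_mv, two$vm_mv, tolerance = 1e-10)
})

test_that("rate dependence: APD90 at CL 400 does not exceed APD90 at CL 1000", {
  a400 <- measure_biomarkers(run_ap(pacing_cl = 400, n_beats = 6L))
  a1000 <- measure_biomarkers(run_ap(pacing_cl = 1000, n_beats = 6L))
  expect_lte(a400$apd90_ms, a1000$apd90_ms)
})

test_that("biomarker measurement handles constructed waveforms and errors", {
  t <- seq(0, 400, by = 0.5)
  v <- ifelse(t > 10 & t <= 210, 20, -80)
  bm <- measure_biomarkers(tibble::tibble(time_ms = t, vm_mv = v))
  expect_equal(bm$apd90_ms, 200, tolerance = 0.6)
  flat <- tibble::tibble(time_ms = t, vm_mv = rep(-80, length(t)))
  expect_error(measure_biomarkers(flat), "no upstroke")
})

test_that("APD90 agrees with an independent threshold-crossing detector", {
  tr <- run_ap()
  a <- measure_biomarkers(tr)$apd90_ms
  b <- oracle_apd90(tr)
  expect_equal(a, b, tolerance = 0.05)
})

test_that("tabulated kinetics track the exact integrator", {
  st_lut <- cell_initial_state()
  st_ex <- cell_initial_state()
  sc <- effective_scales()
  p <- cell_params()
  # 60 ms including a stimulated upstroke
  st_lut <- step_cell(st_lut, I_stim = 30, n_steps = 100L)
  st_lut <- step_cell(st_lut, n_steps = 2900L)
  for (k in seq_len(3000))
    st_ex <- atriasim:::cpp_react_exact(st_ex, sc, p,
                                        0.02, if (k <= 100) 30 else 0)
  expect_lt(max(abs(st_lut - st_ex)), 1e-3)
})

test_that("non-finite states are rejected with the offending variable named", {
  st <- cell_initial_state()
  st[["Cai"]] <- NaN
  expect_error(step_cell(st), "Cai")
})

test_that("the original (non-remodelled) parameter set reproduces published biomarkers", {
  tr <- run_ap(params = cell_params(af_remodelled = FALSE),
               init = cell_initial_state(af_remodelled = FALSE))
  bm <- measure_biomarkers(tr)
  expect_gt(bm$apd90_ms, 250)
  expect_lt(bm$apd90_ms, 330)
  expect_gt(bm$resting_vm_mv, -85)
  expect_lt(bm$resting_vm_mv, -75)
  expect_gt(bm$dvdt_max_v_s, 80)
})

test_that("drug presets match their catalogued block tables", {
  am <- drug_preset("amiodarone_3.0")
  expect_equal(am$block[["IKr"]], 0.70)
  expect_equal(am$block[["INa"]], 0.50)
  vk <- drug_preset("vernakalant_30")
  expect_equal(vk$block[["IKur"]], 0.70)
  expect_equal(vk$block[["ICaL"]], 0.20)
  lo <- drug_preset("amiodarone_1.5")
  expect_equal(lo$block[["IKr"]], 0.40)
  expect_error(drug_spec("bad", 1, c(IKr = 1.2)), "0, 1")
})
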