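test_that("the therapy catalog separates ablation and drug arms", {
  expect_length(therapy_names(), 11)
  am <- therapy("amiodarone3.0")
  expect_length(am$components, 0)
  expect_equal(am$drug$block[["IKr"]], 0.70)
  combo <- therapy("LVA_LA+CTI", adjunct_amiodarone = TRUE)
  expect_equal(combo$drug$concentration, 1.5)
  expect_match(combo$name, "amio1.5")
  expect_error(therapy("amiodarone3.0", adjunct_amiodarone = TRUE),
               "ablation therapies only")
  expect_error(therapy("nope"), "unknown therapy")
})

test_that("lesion sets isolate their targets and compose by union", {
  m <- demo_atria()
  pwi <- build_lesion_set(m, therapy("PWI"))
  m2 <- remove_elements(m, pwi)
  pw_inner <- setdiff(landmark(m, "posterior_wall"), pwi)
  la_out <- setdiff(which(m$region == "la_body" & m$active),
                    c(landmark(m, "posterior_wall"), pwi))
  expect_false(is_connected(m2, pw_inner, la_out))
  # composite = exact union of the parts
  cti <- intersect(landmark(m, "cti_line"), which(m$active))
  expect_setequal(build_lesion_set(m, therapy("MiLine+CTI")),
                  union(build_lesion_set(m, therapy("MiLine")), cti))
  expect_setequal(build_lesion_set(m, therapy("PWI+MI")),
                  union(pwi, intersect(landmark(m, "mitral_line"),
                                       which(m$active))))
  # LVA therapy without any LVA labels warns and returns an empty set
  expect_warning(
    empty <- build_lesion_set(m, therapy("LVA_LA"),
                              lva_map = threshold_lva(rep(0, atriasim:::mesh_n(m)), m, 0)),
    "no LVA elements")
  expect_length(empty, 0)
  expect_error(build_lesion_set(make_sheet(10, 10, 1000), therapy("PWI")),
               "posterior_wall")
})

test_that("the stratification cascade reproduces the decision rules", {
  f <- function(lva, ra, la, erp)
    stratify(tibble::tibble(has_lva = lva, ra_volume_ml = ra,
                            la_volume_ml = la, erp_ms = erp))
  expect_equal(f(TRUE, 55, 100, 200)$therapy, "LVA_LA")
  expect_equal(f(TRUE, 100, 100, 160)$therapy, "LVA_LA-RA+CTI")
  expect_equal(f(TRUE, 100, 100, 200)$therapy, "LVA_LA+CTI")
  expect_equal(f(FALSE, 80, 85, 200)$therapy, "Marshall-PLAN")
  expect_equal(f(FALSE, 80, 120, 200)$therapy, "MiLine+CTI")
  expect_equal(f(FALSE, 50, 120, 200)$therapy, "MiLine")
  expect_equal(f(FALSE, 50, 80, 200)$therapy, "flutter-circuit")
  # short ERP adds the low-dose amiodarone adjunct in the LVA-absent arm
  expect_equal(f(FALSE, 80, 85, 160)$adjunct, "amiodarone_1.5")
  expect_true(is.na(f(FALSE, 80, 85, 171)$adjunct))
  # boundary convention: thresholds go to the big/long branch
  expect_equal(f(TRUE, 60, 100, 170)$therapy, "LVA_LA+CTI")
  expect_equal(f(FALSE, 60, 90, 170)$therapy, "MiLine+CTI")
  expect_error(f(TRUE, 60, 100, NA), "missing")
  expect_error(stratify(tibble::tibble(has_lva = TRUE)), "missing feature")
})

test_that("efficacy tables match a hand tally and ignore record order", {
  rec <- tibble::tibble(
    patient_id = rep(sprintf("vp%02d", 1:6), each = 2),
    therapy = rep(c("PWI", "PWI+MI+CTI"), 6),
    outcome = c("terminated", "terminated", "sustained", "terminated",
                "terminated", "terminated", "sustained", "sustained",
                "terminated", "terminated", "sustained", "terminated"),
    has_lva = rep(c(FALSE, TRUE), each = 6))
  et <- efficacy_table(rec)
  all_pwi <- et[et$therapy == "PWI" & et$stratum == "all", ]
  expect_equal(all_pwi$n_treated, 6)
  expect_equal(all_pwi$n_terminated, 3)
  expect_equal(all_pwi$pct_free, 100 * 3 / 6)
  # strata add up to the totals
  by_s <- et[et$therapy == "PWI" & et$stratum != "all", ]
  expect_equal(sum(by_s$n_treated), all_pwi$n_treated)
  expect_equal(sum(by_s$n_terminated), all_pwi$n_terminated)
  set.seed(1)
  et2 <- efficacy_table(rec[sample(nrow(rec)), ])
  expect_equal(dplyr::arrange(as.data.frame(et2), therapy, stratum),
               dplyr::arrange(as.data.frame(et), therapy, stratum))
  # all-terminated edge case
  all_term <- dplyr::mutate(rec, outcome = "terminated")
  expect_true(all(efficacy_table(all_term)$pct_free == 100))
})

test_that("planned-run accounting matches the trial design arithmetic", {
  expect_equal(planned_runs(800, 522, 12), 7064)
  expect_equal(planned_runs(4, 0, 12), 4)
})

test_that("a full sodium block terminates any propagating activity", {
  m <- make_sheet(40, 12, 600)
  m$chamber[] <- "LA"
  pr <- tissue_properties(m, sigma_cal())
  cfg <- solver_config(record_ms = 5)
  edge <- which(((seq_len(480) - 1L) %% 40L) < 3L)
  traj <- run_monodomain(m, pr, duration_ms = 40, config = cfg,
                         stims = list(stimulus(edge, 0)))
  block_all <- drug_spec("na-blocker", 1, c(INa = 1))
  th <- structure(list(name = "full-INa-block", components = character(),
                       drug = block_all), class = "therapy")
  rec <- run_treatment(m, pr, baseline_profile(), traj$final_state, th,
                       config = cfg, window_ms = 1100, t0 = 40)
  expect_equal(rec$outcome, "terminated")
})

test_that("an empty therapy reproduces the untreated continuation", {
  m <- make_sheet(30, 10, 600)
  m$chamber[] <- "LA"
  pr <- tissue_properties(m, sigma_cal())
  cfg <- solver_config(record_ms = 5)
  edge <- which(((seq_len(300) - 1L) %% 30L) < 3L)
  traj <- run_monodomain(m, pr, duration_ms = 30, config = cfg,
                         stims = list(stimulus(edge, 0)))
  nothing <- structure(list(name = "sham", components = character(),
                            drug = NULL), class = "therapy")
  rec <- run_treatment(m, pr, baseline_profile(), traj$final_state, nothing,
                       config = cfg, window_ms = 1100, t0 = 30)
  plain <- run_monodomain(m, pr, duration_ms = 1100, config = cfg,
                          init = traj$final_state, t0 = 30)
  verdict <- assess_sustainment(plain, window_ms = 1100)
  expect_equal(rec$outcome,
               if (verdict$sustained) "sustained" else "terminated")
})

test_that("the reduced trial is reproducible and accounts for its runs", {
  tp <- tiny_trial_pair()
  res1 <- tp$res1
  expect_equal(res1$records, tp$res2$records)
  n_sus <- length(res1$sustained_ids)
  expect_equal(res1$planned_runs, nrow(tp$cohort) + 2 * n_sus)
  expect_equal(sum(res1$records$therapy == "induction"), nrow(tp$cohort))
  expect_true(all(res1$records$outcome %in%
                    c("terminated", "sustained", "failed-run")))
  expect_equal(glance(res1)$n_patients, 2)
  # therapies with CTI block terminate at least as many cases as their
  # CTI-free counterparts on the reduced cohort
  et <- efficacy_table(res1$records)
  n_term <- function(th) {
    r <- et[et$therapy == th & et$stratum == "all", ]
    if (nrow(r)) r$n_terminated else 0L
  }
  if (length(res1$sustained_ids) > 0)
    expect_gte(n_term("LVA_LA+CTI") + n_term("PWI+MI+CTI"),
               n_term("LVA_LA") + n_term("PWI+MI"))
})
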