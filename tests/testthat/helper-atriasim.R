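# Shared fixtures. Expensive objects (conductivity calibration, standard
# strips) are computed once per test run and memoized here.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, force(expr), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# standard longitudinal calibration strip (30 mm x 1.2 mm, h = 400 um)
cv_strip <- function() memo("cv_strip", make_sheet(75, 3, 400))

# transversal strip: propagate along y
cv_strip_t <- function() memo("cv_strip_t", make_sheet(3, 150, 400))

# baseline conductivity calibrated to 80 cm/s on the standard strip
calib <- function() memo("calib", calibrate_baseline_conductivity(cv_strip()))

sigma_cal <- function() calib()$sigma_l

# whole-mesh LVA map (for applying LVA remodelling to an entire sheet)
all_lva <- function(mesh) {
  n <- mesh$nx * mesh$ny
  structure(list(prob = rep(1, n), label = rep(TRUE, n), fraction = 1,
                 coverage = NULL),
            class = "lva_map")
}

# coarse idealized atria shared across geometry/trial tests
demo_atria <- function() memo("demo_atria",
                              make_idealized_atria(127, 105, h_um = 2000))

# independent connected-components oracle: repeated neighbour expansion on
# an adjacency list (distinct from the package BFS implementation)
oracle_components <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny
  ok <- mesh$active & !mesh$removed
  lab <- ifelse(ok, seq_len(nx * ny), NA_integer_)
  repeat {
    changed <- FALSE
    for (idx in which(ok)) {
      i <- (idx - 1L) %% nx; j <- (idx - 1L) %/% nx
      nbs <- c(if (i > 0) idx - 1L, if (i < nx - 1) idx + 1L,
               if (j > 0) idx - nx, if (j < ny - 1) idx + nx)
      nbs <- nbs[ok[nbs]]
      if (length(nbs)) {
        m <- min(lab[idx], lab[nbs])
        if (m < lab[idx]) { lab[idx] <- m; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  lab
}

# independent APD90 detector: fixed-threshold crossing, no upstroke-velocity
# marker (oracle for measure_biomarkers)
oracle_apd90 <- function(trace) {
  t <- trace$time_ms; v <- trace$vm_mv
  rest <- min(v); peak <- max(v)
  v90 <- rest + 0.1 * (peak - rest)
  up <- which(diff(v > (rest + 0.5 * (peak - rest))) == 1)[1] + 1L
  dn <- which(t > t[up] & v <= v90)[1]
  t[dn] - t[up]
}

# synthetic trajectory construction (for sustainment / pseudo-ECG tests)
fake_trajectory <- function(mesh, times, vm) {
  structure(list(times = times, vm = vm, probe_times = numeric(),
                 probe_vm = NULL, final_state = NULL, mesh = mesh,
                 config = solver_config(), t0 = 0,
                 duration_ms = max(times) - min(times), status = "ok"),
            class = "tissue_trajectory")
}

# ideal spiral phase field about (cx, cy) in element units
spiral_phase <- function(mesh, cx_mm, cy_mm, chirality = 1) {
  xy <- atriasim:::node_xy(mesh)
  atan2(xy$y - cy_mm, xy$x - cx_mm) * chirality
}

# sustained re-entry demonstration: 42 x 42 mm sheet at h = 600 um, bulk
# conductivity at a quarter of the calibrated value and a short-APD demo
# profile so the re-entrant wavelength fits the sheet; one imposed core.
demo_profile <- function() ionic_profile(IKr = 2.2, ICaL = 0.4,
                                         profile_id = "demo_short_apd")

demo_reentry <- function() memo("demo_reentry", {
  sheet <- make_sheet(70, 70, 600)
  sheet$chamber[] <- "LA"
  pr <- tissue_properties(sheet, sigma_cal() / 4, anisotropy = 1)
  init <- induce_reentry(sheet, tibble::tibble(x = 21, y = 21),
                         profile = demo_profile())
  traj <- run_monodomain(sheet, pr, demo_profile(), duration_ms = 4200,
                         config = solver_config(record_ms = 5),
                         init = init)
  list(sheet = sheet, props = pr, traj = traj)
})

# a tiny two-patient trial executed twice with the same seed (shared by the
# trial unit tests and the determinism acceptance check)
tiny_trial_pair <- function() memo("tiny_trial_pair", {
  pr <- dplyr::bind_rows(baseline_profile(),
                         ionic_profile(INa = 1.2, profile_id = "p2"))
  an <- tibble::tibble(anatomy_id = "a01", ra_volume_ml = 30,
                       la_volume_ml = 28)
  co <- build_cohort(pr, an, with_and_without_lva = TRUE)[1:2, ]
  cfg <- trial_config(h_um = 1300, induction_window_ms = 400,
                      treatment_window_ms = 400, sigma_l = sigma_cal(),
                      seed = 4L)
  ths <- list("PWI", "LVA_LA+CTI")
  list(cohort = co, profiles = pr, therapies = ths,
       res1 = run_trial(co, pr, ths, cfg),
       res2 = run_trial(co, pr, ths, cfg))
})
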