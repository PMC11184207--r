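test_that("analytic-signal phase rotates uniformly for a sinusoid and flags quiet nodes", {
  m <- make_sheet(3, 3, 1000)
  times <- seq(0, 2000, by = 5)
  f <- 4 / 1000   # 4 Hz in 1/ms
  vm <- matrix(rep(-70 + 30 * sin(2 * pi * f * times), 9), ncol = 9)
  vm[, 5] <- -80  # quiescent element
  traj <- fake_trajectory(m, times, vm)
  pm <- compute_phase(traj)
  expect_false(pm$defined[5])
  expect_true(all(is.na(pm$phase[, 5])))
  ph <- pm$phase[, 1]
  core <- 40:360  # away from Hilbert edge effects
  dph <- atriasim:::wrap_pi(diff(ph))[core]
  expect_equal(mean(dph), 2 * pi * f * 5, tolerance = 0.02)
  expect_lt(stats::sd(dph), 0.02)
  # time reversal negates the phase: phase_rev(t) = -phase(T - t) (mod 2pi)
  nfr <- nrow(vm)
  pm_rev <- compute_phase(fake_trajectory(m, times, vm[rev(seq_len(nfr)), ]))
  mism <- atriasim:::wrap_pi(pm_rev$phase[core, 1] +
                               pm$phase[nfr + 1 - core, 1])
  expect_lt(max(abs(mism)), 0.05)
})

test_that("topological charge finds constructed spirals and figure-of-eight pairs", {
  m <- make_sheet(40, 40, 1000)
  # planar wave: constant phase gradient, no singularity
  xy <- atriasim:::node_xy(m)
  planar <- atriasim:::wrap_pi(0.4 * xy$x)
  expect_equal(nrow(detect_singularities(planar, m)), 0)
  # ideal spiral about (20.5, 20.5)
  sp <- spiral_phase(m, 20, 20)
  hits <- detect_singularities(sp, m)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$charge, 1L)
  expect_lt(abs(hits$x - 20) + abs(hits$y - 20), 2.1)
  # opposite chirality flips the charge
  expect_equal(detect_singularities(spiral_phase(m, 20, 20, -1), m)$charge,
               -1L)
  # figure of eight: two cores of opposite charge, net zero
  f8 <- atriasim:::wrap_pi(spiral_phase(m, 12, 20) -
                             spiral_phase(m, 28, 20))
  hits8 <- detect_singularities(f8, m)
  expect_equal(nrow(hits8), 2)
  expect_equal(sum(hits8$charge), 0)
})

test_that("net charge equals the boundary winding and survives phase offsets", {
  m <- make_sheet(30, 30, 1000)
  ph <- atriasim:::wrap_pi(spiral_phase(m, 10, 15) +
                             spiral_phase(m, 20, 12) + 0.3 * 15)
  hits <- detect_singularities(ph, m)
  # brute-force winding along the domain boundary (counter-clockwise loop)
  nx <- 30L
  bot <- seq.int(1L, nx)
  rgt <- seq.int(2L * nx, nx * nx, by = nx)
  top <- seq.int(nx * nx - 1L, nx * (nx - 1L) + 1L, by = -1L)
  lft <- seq.int(nx * (nx - 2L) + 1L, nx + 1L, by = -nx)
  loop <- c(bot, rgt, top, lft, 1L)
  wind <- sum(atriasim:::wrap_pi(diff(ph[loop]))) / (2 * pi)
  expect_equal(sum(hits$charge), round(wind))
  # a global offset changes no detection
  ph2 <- atriasim:::wrap_pi(ph + 1.2)
  expect_equal(detect_singularities(ph2, m)$element, hits$element)
})

test_that("tracking separates stationary from meandering tips", {
  m <- make_sheet(50, 50, 1000)
  times <- seq(0, 1900, by = 100)
  mk <- function(xfun, yfun) {
    purrr::map_dfr(seq_along(times), function(i)
      tibble::tibble(time_ms = times[i], x = xfun(i), y = yfun(i),
                     charge = 1L,
                     element = 1L + round(xfun(i)) + round(yfun(i)) * 50L))
  }
  stat <- mk(function(i) 25 + 0.4 * sin(i), function(i) 25)
  cl <- track_and_classify(stat, m)
  expect_equal(nrow(cl$tracks), 1)
  expect_equal(cl$tracks$label, "stationary")
  expect_equal(cl$regime, "stationary-only")
  expect_equal(cl$rotor_count, 1, tolerance = 1e-9)
  drift <- mk(function(i) 5 + 1.8 * i, function(i) 25)
  cl2 <- track_and_classify(drift, m)
  expect_equal(cl2$tracks$label, "meandering")
  expect_equal(cl2$regime, "one-meandering")
  none <- track_and_classify(stat[0, ], m)
  expect_equal(none$regime, "none")
  expect_equal(none$rotor_count, 0)
})

test_that("anchoring requires sustained residence near LVA elements", {
  m <- make_sheet(50, 50, 1000)
  m$chamber[] <- "LA"
  lab <- rep(FALSE, 2500)
  lab[which(abs(((seq_len(2500) - 1L) %% 50L) - 25L) <= 3 &
              abs(((seq_len(2500) - 1L) %/% 50L) - 25L) <= 3)] <- TRUE
  lva <- structure(list(prob = as.numeric(lab), label = lab, fraction = NA),
                   class = "lva_map")
  times <- seq(0, 1900, by = 100)
  near <- purrr::map_dfr(seq_along(times), function(i)
    tibble::tibble(time_ms = times[i], x = 25.5 + 0.3 * cos(i), y = 25.5,
                   charge = 1L, element = 26L + 25L * 50L))
  cl <- track_and_classify(near, m, lva_map = lva)
  expect_true(cl$tracks$anchored)
  far <- dplyr::mutate(near, x = x - 15, element = 11L + 25L * 50L)
  cl2 <- track_and_classify(far, m, lva_map = lva)
  expect_false(cl2$tracks$anchored)
})

test_that("pseudo-ECG obeys the dipole-sum limits", {
  m <- make_sheet(30, 10, 500)
  pr <- tissue_properties(m, sigma_cal())
  times <- seq(0, 45, by = 5)
  # uniform field -> zero signal
  vm_u <- matrix(-20, length(times), 300)
  e1 <- tibble::tibble(x = 7.5, y = 2.5, z = 10)
  ecg_u <- pseudo_ecg(fake_trajectory(m, times, vm_u), pr, e1)
  expect_equal(max(abs(ecg_u$ecg_1)), 0)
  # travelling step depolarization -> biphasic deflection, decaying with distance
  vm <- matrix(-80, length(times), 300)
  for (i in seq_along(times)) {
    front <- 3 * i
    sel <- which(((seq_len(300) - 1L) %% 30L) < front)
    vm[i, sel] <- 20
  }
  traj <- fake_trajectory(m, times, vm)
  els <- tibble::tibble(x = c(7.5, 7.5), y = c(2.5, 2.5), z = c(10, 20))
  ecg <- pseudo_ecg(traj, pr, els)
  expect_gt(max(ecg$ecg_1), 0)
  expect_lt(min(ecg$ecg_1), 0)
  expect_gt(max(abs(ecg$ecg_1)), max(abs(ecg$ecg_2)))
  expect_error(pseudo_ecg(traj, pr, tibble::tibble(x = 7.25, y = 2.25, z = 0)),
               "electrode lies on the tissue")
})

test_that("dominant frequency recovers known spectra", {
  dt <- 5
  t <- seq(0, 5000, by = dt)
  expect_equal(dominant_frequency(sin(2 * pi * 6 * t / 1000), dt), 6,
               tolerance = 0.25)
  silent <- dominant_frequency(rep(0.5, length(t)), dt)
  expect_true(is.na(silent))
  expect_equal(attr(silent, "status"), "silent")
  expect_error(dominant_frequency(sin(t[1:100]), dt), "4 s")
  # paced cell at 500 ms cycle length -> 2 Hz
  tr <- run_ap(pacing_cl = 500, n_beats = 11L, sample_ms = 5)
  st <- attr(tr, "final_state")
  # build a 5 s paced voltage signal from successive beats
  long <- atriasim:::cpp_monodomain_run(
    state = matrix(cell_initial_state(), ncol = 1),
    scales = matrix(effective_scales(), ncol = 1),
    pars = cell_params(), active = TRUE, nx = 1L, ny = 1L, h = 1,
    Dxx = 0, Dyy = 0, Dxy = 0, dt = 0.02,
    n_steps = 250000L, t0 = 0,
    stims = lapply(0:9, function(b) list(nodes = 0L, t_start = b * 500,
                                         duration = 2, amplitude = 30)),
    record_stride = 0L, probe_idx = 0L, probe_stride = 250L,
    reaction_on = TRUE, diffusion_on = FALSE)
  sig <- long$probes[seq_len(long$n_probe_t), 1]
  expect_equal(dominant_frequency(sig, 5), 2, tolerance = 0.25)
})

test_that("loop winding identifies macro-re-entry around an obstacle", {
  m <- make_sheet(40, 40, 1000)
  xy <- atriasim:::node_xy(m)
  hole <- which((xy$x - 20)^2 + (xy$y - 20)^2 <= 25)
  m <- remove_elements(m, hole)
  times <- seq(0, 1000, by = 50)
  theta <- atan2(xy$y - 20, xy$x - 20)
  rot <- t(vapply(times, function(tt)
    atriasim:::wrap_pi(theta - 2 * pi * tt / 200), numeric(1600)))
  pm <- structure(list(times = times, phase = rot,
                       defined = m$active & !m$removed, mesh = m),
                  class = "phase_map")
  res <- detect_macro_reentry(pm, c(20, 20), 9)
  expect_true(res$macro_reentry)
  expect_equal(res$winding, 1)
  # a translating planar wave has zero loop winding
  plane <- t(vapply(times, function(tt)
    atriasim:::wrap_pi(0.3 * xy$x - 2 * pi * tt / 200), numeric(1600)))
  pm2 <- structure(list(times = times, phase = plane,
                        defined = m$active & !m$removed, mesh = m),
                   class = "phase_map")
  expect_false(detect_macro_reentry(pm2, c(20, 20), 9)$macro_reentry)
  # loops through the obstacle are rejected
  expect_error(detect_macro_reentry(pm, c(20, 20), 3), "non-conducting")
})
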