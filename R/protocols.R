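# Measurement and induction protocols: plane-wave conduction velocity,
# tissue effective refractory period (S1-S2), pulmonary-vein isolation, and
# spiral-wave initial conditions via the phase-distribution method.

activation_time <- function(times, vm, after = -Inf, v_thresh = -40) {
  # time of maximum upstroke velocity at the first upward threshold
  # crossing after `after`; NA when no genuine upstroke occurs there
  sel <- times >= after
  t <- times[sel]; v <- vm[sel]
  if (length(t) < 3) return(NA_real_)
  cross <- which(v[-length(v)] < v_thresh & v[-1] >= v_thresh)
  if (!length(cross)) return(NA_real_)
  k <- cross[1]
  win <- which(t >= t[k] - 2 & t <= t[k] + 2)
  if (length(win) < 2) return(t[k])
  dv <- diff(v[win]) / diff(t[win])
  if (max(dv) < 1) return(NA_real_)   # drift, not an upstroke
  t[win][which.max(dv)]
}

# stimulated edge width (elements): scales with the electrotonic space
# constant so capture survives strong coupling
stim_edge_width <- function(mesh, props) {
  Dmax <- max(props$sigma_l) / props$constants[["beta"]]
  w_mm <- max(0.8, 2.6 * sqrt(Dmax))
  max(2L, as.integer(ceiling(w_mm / mesh$h_mm)))
}

#' Measure plane-wave conduction velocity
#'
#' Stimulates one edge of a planar mesh and reports the wavefront speed from
#' the activation-time difference (maximum-upstroke-velocity marker) between
#' two recording sites at least 10 mm apart along the propagation direction.
#'
#' @param mesh A sheet/cable `tissue_mesh` (fibers along +x).
#' @param props A `tissue_props`.
#' @param profile Ionic profile.
#' @param direction `"longitudinal"` (along x/fibers) or `"transversal"`
#'   (along y).
#' @param drug Optional [drug_spec()].
#' @param config Solver configuration.
#' @param max_ms Simulation cap (ms).
#' @return CV in cm/s, or `NA` with attribute `status = "block"` when the
#'   far site is never captured.
#' @export
measure_cv <- function(mesh, props, profile = baseline_profile(),
                       direction = c("longitudinal", "transversal"),
                       drug = NULL, config = solver_config(), max_ms = 400) {
  direction <- match.arg(direction)
  nx <- mesh$nx; ny <- mesh$ny; h <- mesh$h_mm
  along_x <- direction == "longitudinal"
  len_mm <- (if (along_x) nx else ny) * h
  if (len_mm < 16)
    abort("mesh too short for CV measurement: need >= 16 mm along the direction.")
  # probe rows/columns at 30% and 30% + >=10 mm of the length
  p1_mm <- 0.25 * len_mm
  p2_mm <- p1_mm + max(10, 0.4 * len_mm)
  at <- function(d_mm) min(max(1L, as.integer(round(d_mm / h))),
                           (if (along_x) nx else ny) - 1L)
  i1 <- at(p1_mm); i2 <- at(p2_mm)
  mid <- if (along_x) ny %/% 2L else nx %/% 2L
  node_at <- function(i) if (along_x) i + 1L + mid * nx else mid + 1L + i * nx
  ew <- stim_edge_width(mesh, props)
  edge <- if (along_x) which((seq_len(nx * ny) - 1L) %% nx < ew)
          else which((seq_len(nx * ny) - 1L) %/% nx < ew)
  edge <- edge[mesh$active[edge] & !mesh$removed[edge]]
  probes <- c(node_at(i1), node_at(i2))
  cfg <- config; cfg$record_ms <- 0
  traj <- run_monodomain(mesh, props, profile, drug, duration_ms = max_ms,
                         config = cfg,
                         stims = list(stimulus(edge, 0, config$stim_dur,
                                               config$stim_amp)),
                         probes = probes)
  t1 <- activation_time(traj$probe_times, traj$probe_vm[, 1])
  t2 <- activation_time(traj$probe_times, traj$probe_vm[, 2])
  if (is.na(t1) || is.na(t2) || t2 <= t1)
    return(structure(NA_real_, status = "block"))
  d_mm <- (i2 - i1) * h
  structure(100 * d_mm / (t2 - t1), status = "ok")  # mm/ms -> cm/s
}

#' Measure tissue effective refractory period (S1-S2)
#'
#' S1 train of 4 beats at 600 ms cycle length from one edge of the strip,
#' then a premature S2 from the same site; the ERP is the shortest S1-S2
#' coupling interval whose S2 propagates at least 10 mm, refined by binary
#' search to the grid resolution.
#'
#' @param mesh A strip mesh (>= 16 mm long).
#' @param props,profile,drug,config As in [measure_cv()].
#' @param s1_cl S1 cycle length (ms, default 600).
#' @param n_s1 Number of S1 beats (default 4).
#' @param s2_grid Coupling-interval resolution in ms (<= 5, default 5).
#' @param s2_range Initial coupling-interval search range (ms).
#' @return ERP in ms; `Inf` with attribute `status = "no-capture"` when no
#'   coupling interval in the range captures.
#' @export
measure_erp <- function(mesh, props, profile = baseline_profile(),
                        drug = NULL, config = solver_config(),
                        s1_cl = 600, n_s1 = 4, s2_grid = 5,
                        s2_range = c(60, 500)) {
  if (s2_grid > 5) abort("`s2_grid` must be <= 5 ms.")
  nx <- mesh$nx; ny <- mesh$ny; h <- mesh$h_mm
  if (nx * h < 16) abort("strip too short for the 10 mm propagation criterion.")
  ew <- stim_edge_width(mesh, props)
  edge <- which((seq_len(nx * ny) - 1L) %% nx < ew)
  edge <- edge[mesh$active[edge] & !mesh$removed[edge]]
  mid <- ny %/% 2L
  far <- min(nx - 1L, as.integer(ceiling(12 / h))) + 1L + mid * nx
  cfg <- config; cfg$record_ms <- 0
  # condition with the S1 train once, checkpoint at the last S1 onset
  t_last_s1 <- (n_s1 - 1) * s1_cl
  stims <- lapply(seq_len(n_s1 - 1) - 1L, function(b)
    stimulus(edge, b * s1_cl, config$stim_dur, config$stim_amp))
  base <- run_monodomain(mesh, props, profile, drug,
                         duration_ms = t_last_s1, config = cfg,
                         stims = stims, probes = far)
  s2_captures <- function(ci) {
    tr <- run_monodomain(mesh, props, profile, drug,
                         duration_ms = ci + 250, config = cfg,
                         init = base$final_state, t0 = t_last_s1,
                         stims = list(
                           stimulus(edge, t_last_s1, config$stim_dur,
                                    config$stim_amp),
                           stimulus(edge, t_last_s1 + ci, config$stim_dur,
                                    config$stim_amp)),
                         probes = far)
    !is.na(activation_time(tr$probe_times, tr$probe_vm[, 1],
                           after = t_last_s1 + ci + 2))
  }
  lo <- s2_range[1]; hi <- s2_range[2]
  if (s2_captures(lo)) return(structure(lo, status = "ok"))
  if (!s2_captures(hi))
    return(structure(Inf, status = "no-capture"))
  while (hi - lo > s2_grid) {
    mid_ci <- 0.5 * (lo + hi)
    if (s2_captures(mid_ci)) hi <- mid_ci else lo <- mid_ci
  }
  structure(hi, status = "ok")
}

#' Pulmonary vein isolation
#'
#' For each pulmonary vein, searches outward from the vein boundary for the
#' smallest circumferential ring of elements lying wholly outside the vein
#' whose removal disconnects the vein interior from the left-atrial body,
#' and ablates it. Veins that are already isolated are left untouched, so
#' re-application is a no-op.
#'
#' @param mesh An idealized atrial mesh with landmarks `pv1`..`pv4`.
#' @return The ablated mesh; attribute `pvi_rings` holds the lesion indices
#'   per vein.
#' @export
apply_pvi <- function(mesh) {
  pvs <- paste0("pv", 1:4)
  if (!all(pvs %in% names(mesh$landmarks)))
    abort("mesh lacks the four pulmonary-vein landmarks pv1..pv4.")
  la_body <- which(mesh$active & !mesh$removed & !is.na(mesh$region) &
                     mesh$region == "la_body")
  xy <- node_xy(mesh)
  rings <- list()
  for (pv in pvs) {
    interior <- intersect(landmark(mesh, pv), conducting(mesh))
    if (!length(interior)) next
    cx <- mean(xy$x[interior]); cy <- mean(xy$y[interior])
    r_pv <- max(sqrt((xy$x[interior] - cx)^2 + (xy$y[interior] - cy)^2))
    d <- sqrt((xy$x - cx)^2 + (xy$y - cy)^2)
    far <- la_body[d[la_body] > r_pv + 8.75 * mesh$h_mm]
    if (!is_connected(mesh, interior, far)) { rings[[pv]] <- integer(); next }
    done <- FALSE
    for (r in seq(r_pv + mesh$h_mm, r_pv + 8 * mesh$h_mm, by = mesh$h_mm)) {
      # annulus of width 1.5 h: a 4-connected path cannot step across it
      ring <- which(d > r - 0.75 * mesh$h_mm & d <= r + 0.75 * mesh$h_mm &
                      mesh$active & !mesh$removed)
      ring <- setdiff(ring, landmark(mesh, pv))
      if (any(d[landmark(mesh, pv)] >= r - 0.75 * mesh$h_mm)) next
      if (!length(ring)) next
      trial <- remove_elements(mesh, ring)
      outside <- la_body[d[la_body] > r + 0.75 * mesh$h_mm]
      if (!is_connected(trial, interior, outside)) {
        mesh <- trial
        rings[[pv]] <- ring
        done <- TRUE
        break
      }
    }
    if (!done) abort(paste0("could not isolate ", pv,
                            " within the ring search range."))
  }
  attr(mesh, "pvi_rings") <- rings
  mesh
}

#' Single-cell limit cycle for the phase-distribution method
#'
#' Paces a cell to quasi-steady state, then records the full 21-variable
#' state at 1 ms resolution over one final cycle.
#'
#' @param profile,region,drug,params As in [run_ap()].
#' @param cycle_ms Cycle length of the recorded loop (ms, default 250).
#' @param n_cond Conditioning beats before recording (default 3).
#' @return 21 x `cycle_ms` state matrix (column k = state at phase k ms).
#' @export
limit_cycle_states <- function(profile = baseline_profile(),
                               region = "ra_baseline", drug = NULL,
                               cycle_ms = 250, n_cond = 3,
                               params = cell_params()) {
  sc <- effective_scales(profile, region, drug)
  st <- cell_initial_state()
  one <- function(st, ms, stim) {
    res <- cpp_monodomain_run(
      state = matrix(st, ncol = 1), scales = matrix(sc, ncol = 1),
      pars = params, active = TRUE, nx = 1L, ny = 1L, h = 1,
      Dxx = 0, Dyy = 0, Dxy = 0, dt = 0.02,
      n_steps = as.integer(round(ms / 0.02)), t0 = 0,
      stims = if (stim) list(list(nodes = 0L, t_start = 0, duration = 2,
                                  amplitude = 30)) else list(),
      record_stride = 0L, probe_idx = integer(), probe_stride = 0L,
      reaction_on = TRUE, diffusion_on = FALSE)
    as.numeric(res$state)
  }
  for (b in seq_len(n_cond)) st <- one(st, cycle_ms, TRUE)
  out <- matrix(0, 21, cycle_ms)
  for (k in seq_len(cycle_ms)) {
    st <- one(st, 1, k == 1)
    out[, k] <- st
  }
  out
}

#' Spiral-wave initial conditions (phase-distribution method)
#'
#' Builds a tissue state in which each element takes the single-cell
#' limit-cycle state at a phase given by the polar angle about each rotor
#' core (summed over cores, modulo one cycle). Evolving this state under the
#' monodomain model produces re-entrant spiral waves at the requested cores.
#'
#' @param mesh A `tissue_mesh`.
#' @param cores Tibble/data frame with columns `x`, `y` (mm) and optionally
#'   `chirality` (+1/-1); must lie on conducting tissue.
#' @param profile,drug As elsewhere.
#' @param cycle_ms Limit-cycle length used for the phase mapping.
#' @return 21 x N state matrix usable as `init` in [run_monodomain()].
#' @export
induce_reentry <- function(mesh, cores, profile = baseline_profile(),
                           drug = NULL, cycle_ms = 250) {
  n <- mesh_n(mesh)
  if (!nrow(cores)) return(resting_state_matrix(mesh))
  if (!all(c("x", "y") %in% names(cores)))
    abort("`cores` needs columns x and y (mm).")
  chir <- if ("chirality" %in% names(cores)) cores$chirality
          else rep(1, nrow(cores))
  xy <- node_xy(mesh)
  ok <- mesh$active & !mesh$removed
  for (k in seq_len(nrow(cores))) {
    ni <- which.min((xy$x - cores$x[k])^2 + (xy$y - cores$y[k])^2)
    if (!ok[ni]) abort(sprintf("core %d lies on removed/inactive tissue.", k))
  }
  lc <- limit_cycle_states(profile = profile, drug = drug,
                           cycle_ms = cycle_ms)
  phase <- rep(0, n)
  for (k in seq_len(nrow(cores)))
    phase <- phase + chir[k] * atan2(xy$y - cores$y[k], xy$x - cores$x[k])
  frac <- (phase / (2 * pi)) %% 1
  col <- pmin(cycle_ms, 1L + as.integer(floor(frac * cycle_ms)))
  state <- resting_state_matrix(mesh)
  state[, ok] <- lc[, col[ok]]
  state
}

#' Assess arrhythmia sustainment over an analysis window
#'
#' The trajectory is sustained if any element still activates (upstroke
#' faster than the threshold) during the final 500 ms of the window;
#' otherwise it is terminated at the start of the first fully silent 500 ms.
#'
#' @param traj A `tissue_trajectory` with snapshots covering the window.
#' @param window_ms Analysis window length (default 7000 ms).
#' @param quiet_ms Silent-stretch length defining termination (500 ms).
#' @param dvdt_thresh_v_s Upstroke-velocity threshold (V/s, default 10).
#' @return One-row tibble: `sustained` (logical), `termination_ms` (NA when
#'   sustained).
#' @export
assess_sustainment <- function(traj, window_ms = 7000, quiet_ms = 500,
                               dvdt_thresh_v_s = 10) {
  if (is.null(traj$vm)) abort("trajectory has no snapshots; record them.")
  times <- traj$times
  if (max(times) - min(times) < window_ms - 1e-6)
    abort("trajectory shorter than the analysis window.")
  sel <- times <= min(times) + window_ms + 1e-9
  times <- times[sel]
  vm <- traj$vm[sel, , drop = FALSE]
  ok <- traj$mesh$active & !traj$mesh$removed
  dt <- diff(times)
  dv <- diff(vm[, ok, drop = FALSE]) / dt
  active_frame <- c(FALSE, apply(dv, 1, function(r) any(r > dvdt_thresh_v_s)))
  t_end <- min(times) + window_ms
  in_last <- times >= t_end - quiet_ms
  sustained <- any(active_frame[in_last])
  term <- NA_real_
  if (!sustained) {
    # first frame after which a full quiet window elapses with no activation
    last_act <- if (any(active_frame)) max(times[active_frame]) else min(times)
    term <- last_act
  }
  tibble(sustained = sustained, termination_ms = term)
}
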