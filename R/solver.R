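# Monodomain reaction-diffusion driver: operator splitting with a
# conservative anisotropic flux stencil for diffusion and Rush-Larsen /
# forward-Euler reaction steps (compiled kernel).

#' Solver configuration
#'
#' @param dt_ms Shared reaction/diffusion time step in ms (default 0.02).
#' @param record_ms Snapshot interval for the full voltage field (ms).
#' @param probe_ms Sampling interval for probe traces (ms).
#' @param stim_amp Default stimulus amplitude (pA/pF).
#' @param stim_dur Default stimulus duration (ms).
#' @param seed Integer seed carried in provenance.
#' @return A `solver_config` list.
#' @export
solver_config <- function(dt_ms = 0.02, record_ms = 5, probe_ms = 0.1,
                          stim_amp = 30, stim_dur = 2, seed = 1L) {
  if (dt_ms <= 0 || dt_ms > 0.05) abort("`dt_ms` must lie in (0, 0.05] ms.")
  structure(list(dt_ms = dt_ms, record_ms = record_ms, probe_ms = probe_ms,
                 stim_amp = stim_amp, stim_dur = stim_dur,
                 seed = as.integer(seed)),
            class = "solver_config")
}

#' Explicit-diffusion stability check
#'
#' Verifies `dt <= h^2 / (2 * max(Dxx + Dyy))` for the explicit stencil.
#'
#' @param config A [solver_config()].
#' @param mesh,props Tissue geometry and properties.
#' @return TRUE invisibly, or an error naming the violated bound.
#' @export
stability_check <- function(config, mesh, props) {
  D <- diffusion_tensors(mesh, props)
  dmax <- max(D$Dxx + D$Dyy)
  if (dmax <= 0) return(invisible(TRUE))
  dt_max <- mesh$h_mm^2 / (2 * dmax)
  if (config$dt_ms > dt_max)
    abort(sprintf(paste0(
      "explicit diffusion unstable: dt = %g ms exceeds the bound ",
      "h^2 / (2 max(Dxx + Dyy)) = %.4g ms (h = %g mm, max D = %.4g mm^2/ms)."),
      config$dt_ms, dt_max, mesh$h_mm, dmax))
  invisible(TRUE)
}

#' Build a stimulus entry
#'
#' @param nodes Element indices to stimulate.
#' @param t_start Onset (ms).
#' @param duration Duration (ms).
#' @param amplitude Amplitude (pA/pF, depolarizing positive).
#' @return Stimulus list understood by [run_monodomain()].
#' @export
stimulus <- function(nodes, t_start, duration = 2, amplitude = 30) {
  list(nodes = as.integer(nodes) - 1L, t_start = t_start,
       duration = duration, amplitude = amplitude)
}

# per-node 9 x N scale matrix from profile, regions, drug and LVA ionic edits
node_scales <- function(mesh, props, profile, drug = NULL) {
  n <- mesh_n(mesh)
  base <- profile_scales(profile) * drug_scales(drug)
  adj <- region_adjustments()
  regs <- adj$region
  sc <- matrix(base, nrow = 9, ncol = n)
  reg_tab <- t(as.matrix(adj[, current_names()]))
  ridx <- match(mesh$region, regs)
  okr <- which(!is.na(ridx))
  sc[, okr] <- sc[, okr] * reg_tab[, ridx[okr]]
  cur <- current_names()
  for (nm in names(props$ionic))
    sc[match(nm, cur), ] <- sc[match(nm, cur), ] * props$ionic[[nm]]
  sc
}

# resting full-state matrix for a mesh
resting_state_matrix <- function(mesh) {
  matrix(cell_initial_state(), nrow = 21, ncol = mesh_n(mesh))
}

#' Run the monodomain model on a tissue mesh
#'
#' @param mesh A `tissue_mesh`.
#' @param props A `tissue_props`.
#' @param profile Ionic-current profile ([ionic_profile()]).
#' @param drug Optional [drug_spec()].
#' @param duration_ms Simulated time (ms).
#' @param config A [solver_config()].
#' @param init Initial state: a 21 x N matrix (e.g. from a previous run's
#'   `final_state` or [induce_reentry()]), or NULL for rest.
#' @param stims List of [stimulus()] entries.
#' @param probes Element indices whose voltage is sampled at `probe_ms`.
#' @param t0 Simulation clock at entry (ms).
#' @param reaction,diffusion Toggles for operator-splitting sub-steps
#'   (both TRUE for physiology; `reaction = FALSE` isolates the diffusion
#'   operator).
#' @param check_stability Run [stability_check()] first (default TRUE).
#' @return A `tissue_trajectory`: snapshot times/voltages, probe traces,
#'   final full state, and solver status. Aborts with diagnostics if the
#'   integration leaves the physiological voltage range.
#' @export
run_monodomain <- function(mesh, props, profile = baseline_profile(),
                           drug = NULL, duration_ms = 100,
                           config = solver_config(), init = NULL,
                           stims = list(), probes = integer(), t0 = 0,
                           reaction = TRUE, diffusion = TRUE,
                           check_stability = TRUE) {
  if (check_stability && diffusion) stability_check(config, mesh, props)
  n <- mesh_n(mesh)
  if (is.null(init)) init <- resting_state_matrix(mesh)
  stopifnot(is.matrix(init), nrow(init) == 21L, ncol(init) == n)
  D <- diffusion_tensors(mesh, props)
  sc <- node_scales(mesh, props, profile, drug)
  dt <- config$dt_ms
  n_steps <- as.integer(round(duration_ms / dt))
  rec_stride <- if (is.finite(config$record_ms) && config$record_ms > 0)
    max(1L, as.integer(round(config$record_ms / dt))) else 0L
  probe_stride <- max(1L, as.integer(round(config$probe_ms / dt)))
  ok <- mesh$active & !mesh$removed
  res <- cpp_monodomain_run(
    state = init, scales = sc, pars = cell_params(), active = ok,
    nx = mesh$nx, ny = mesh$ny, h = mesh$h_mm,
    Dxx = D$Dxx, Dyy = D$Dyy, Dxy = D$Dxy,
    dt = dt, n_steps = n_steps, t0 = t0, stims = stims,
    record_stride = rec_stride,
    probe_idx = as.integer(probes) - 1L, probe_stride = probe_stride,
    reaction_on = reaction, diffusion_on = diffusion)
  if (res$status != "ok")
    abort(sprintf(
      "monodomain integration unstable at t = %.2f ms (element %d): |Vm| left the physiological range.",
      res$bad_time, res$bad_node))
  snaps <- NULL; snap_t <- numeric()
  if (rec_stride > 0L && res$n_snap > 0) {
    snaps <- res$snapshots[seq_len(res$n_snap), , drop = FALSE]
    snap_t <- res$snap_times[seq_len(res$n_snap)]
  }
  probe_vm <- NULL; probe_t <- numeric()
  if (length(probes) && res$n_probe_t > 0) {
    probe_vm <- res$probes[seq_len(res$n_probe_t), , drop = FALSE]
    colnames(probe_vm) <- as.character(probes)
    probe_t <- res$probe_times[seq_len(res$n_probe_t)]
  }
  structure(list(times = snap_t, vm = snaps,
                 probe_times = probe_t, probe_vm = probe_vm,
                 final_state = res$state, mesh = mesh, config = config,
                 t0 = t0, duration_ms = duration_ms, status = res$status),
            class = "tissue_trajectory")
}

#' @export
print.tissue_trajectory <- function(x, ...) {
  cat(sprintf("<tissue_trajectory> t = %g..%g ms, %d snapshots, %d probes\n",
              x$t0, x$t0 + x$duration_ms, length(x$times),
              if (is.null(x$probe_vm)) 0L else ncol(x$probe_vm)))
  invisible(x)
}

#' Probe traces as a tidy tibble
#'
#' @param x A `tissue_trajectory`.
#' @param ... Unused.
#' @return Tibble `time_ms`, `element`, `vm_mv` (probe traces if present,
#'   otherwise snapshots in long form).
#' @exportS3Method tibble::as_tibble
as_tibble.tissue_trajectory <- function(x, ...) {
  if (!is.null(x$probe_vm)) {
    tidyr::pivot_longer(
      dplyr::bind_cols(tibble(time_ms = x$probe_times),
                       as_tibble(as.data.frame(x$probe_vm))),
      -"time_ms", names_to = "element", values_to = "vm_mv") |>
      mutate(element = as.integer(.data$element))
  } else {
    stopifnot(!is.null(x$vm))
    df <- as.data.frame(x$vm)
    names(df) <- as.character(seq_len(ncol(df)))
    tidyr::pivot_longer(dplyr::bind_cols(tibble(time_ms = x$times), df),
                        -"time_ms", names_to = "element",
                        values_to = "vm_mv") |>
      mutate(element = as.integer(.data$element))
  }
}

#' Export snapshot voltages as CSV
#'
#' Wide CSV: first column `time_ms`, one column per active element.
#'
#' @param traj A `tissue_trajectory`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(!is.null(traj$vm))
  keep <- which(traj$mesh$active)
  df <- data.frame(time_ms = traj$times, traj$vm[, keep, drop = FALSE])
  names(df) <- c("time_ms", paste0("el", keep))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Calibrate baseline longitudinal conductivity against a target velocity
#'
#' Bisection over the longitudinal conductivity of a planar sheet until the
#' measured plane-wave conduction velocity matches the target (80 cm/s bulk
#' default) within tolerance.
#'
#' @param mesh A planar sheet/cable mesh (see [make_sheet()]).
#' @param profile Ionic profile used during calibration.
#' @param target_cv_cm_s Target plane-wave velocity (default 80).
#' @param tol_cm_s Acceptance half-width (default 1).
#' @param bracket Initial conductivity bracket in mS/mm.
#' @param anisotropy Passed to [tissue_properties()].
#' @param config Solver configuration.
#' @param max_iter Bisection iteration cap.
#' @return A `cv_calibration`: `sigma_l` (mS/mm), achieved `cv_cm_s`,
#'   iteration count and the search history; supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
calibrate_baseline_conductivity <- function(mesh, profile = baseline_profile(),
                                            target_cv_cm_s = 80, tol_cm_s = 1,
                                            bracket = c(0.02, 3),
                                            anisotropy = 4,
                                            config = solver_config(),
                                            max_iter = 30) {
  cv_at <- function(sig) {
    pr <- tissue_properties(mesh, sig, anisotropy = anisotropy)
    measure_cv(mesh, pr, profile, direction = "longitudinal", config = config)
  }
  lo <- bracket[1]; hi <- bracket[2]
  cv_lo <- cv_at(lo); cv_hi <- cv_at(hi)
  if (is.na(cv_lo)) cv_lo <- 0
  if (is.na(cv_hi) || !(cv_lo < target_cv_cm_s && target_cv_cm_s < cv_hi))
    abort(sprintf(
      "conductivity bracket [%g, %g] mS/mm does not bracket %g cm/s (CV %g..%g).",
      lo, hi, target_cv_cm_s, cv_lo, cv_hi))
  hist <- list()
  cv_mid <- NA_real_; mid <- NA_real_
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)      # geometric mid: CV ~ sqrt(sigma)
    cv_mid <- cv_at(mid)
    if (is.na(cv_mid)) cv_mid <- 0
    hist[[it]] <- tibble(iter = it, sigma_l = mid, cv_cm_s = cv_mid)
    if (abs(cv_mid - target_cv_cm_s) <= 0.5 * tol_cm_s) break
    if (cv_mid < target_cv_cm_s) lo <- mid else hi <- mid
  }
  structure(list(sigma_l = mid, cv_cm_s = cv_mid,
                 target_cv_cm_s = target_cv_cm_s, iterations = it,
                 history = dplyr::bind_rows(hist), anisotropy = anisotropy),
            class = "cv_calibration")
}

#' @export
print.cv_calibration <- function(x, ...) {
  cat(sprintf(
    "<cv_calibration> sigma_l = %.4g mS/mm -> CV %.2f cm/s (target %g, %d iterations)\n",
    x$sigma_l, x$cv_cm_s, x$target_cv_cm_s, x$iterations))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.cv_calibration <- function(x, ...) x$history

#' @exportS3Method generics::glance
glance.cv_calibration <- function(x, ...) {
  tibble(sigma_l_ms_mm = x$sigma_l, cv_cm_s = x$cv_cm_s,
         target_cv_cm_s = x$target_cv_cm_s, iterations = x$iterations,
         anisotropy = x$anisotropy)
}
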