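# Human atrial action-potential layer: Courtemanche-Ramirez-Nattel (CRN)
# baseline with a persistent-AF remodelling set, per-current scaling
# (profile x region x drug, multiplicative), and biomarker measurement.

#' Names of the scalable ionic currents
#'
#' The nine sarcolemmal currents/fluxes whose maximal conductances (or maximal
#' pump/exchanger rates) can be scaled per virtual patient, per region, and by
#' pore-block drug action.
#'
#' @return Character vector of length 9.
#' @export
current_names <- function() {
  c("INa", "ICaL", "IK1", "IKr", "IKs", "Ito", "IKur", "INaK", "INCX")
}

#' Baseline cell-model parameters
#'
#' Maximal conductances of the CRN human atrial model, optionally with the
#' persistent-AF electrical remodelling set applied (L-type calcium current
#' reduced to 35%, transient outward to 35%, ultrarapid delayed rectifier to
#' 50%, and inward rectifier doubled). The remodelled variant is the package
#' default baseline for all tissue work.
#'
#' @param af_remodelled Apply the persistent-AF remodelling set (default TRUE).
#' @return Named numeric vector of model parameters (conductances in nS/pF,
#'   maximal pump current in pA/pF, maximal exchanger rate in pA/pF).
#' @export
cell_params <- function(af_remodelled = TRUE) {
  p <- c(gNa = 7.8, gCaL = 0.12375, gK1 = 0.09, gKr = 0.029411765,
         gKs = 0.12941176, gto = 0.1652, gKur_sf = 1.0,
         gNaK = 0.59933874, gNCX = 1600)
  if (af_remodelled) {
    p["gCaL"] <- p["gCaL"] * 0.35
    p["gto"] <- p["gto"] * 0.35
    p["gKur_sf"] <- p["gKur_sf"] * 0.5
    p["gK1"] <- p["gK1"] * 2.0
  }
  p
}

#' Resting initial state of the cell model
#'
#' For the persistent-AF remodelled baseline the state has been settled to
#' quiescence (4 s without stimulation), so an unstimulated cell stays at rest
#' to numerical precision; for the original parameter set the published
#' initial conditions are returned.
#'
#' @param af_remodelled Match the default of [cell_params()].
#' @return Named numeric vector of length 21 (membrane potential in mV, 15
#'   gating variables, intracellular Na+/K+/Ca2+ and SR Ca2+ in mM).
#' @export
cell_initial_state <- function(af_remodelled = TRUE) {
  if (af_remodelled) {
    c(V = -84.0424, m = 0.00181227, h = 0.981322, j = 0.988312,
      oa = 0.0259719, oi = 0.999559, ua = 0.00369098, ui = 0.998679,
      xr = 2.12252e-05, xs = 0.0167, d = 9.55945e-05, f = 0.999703,
      fca = 0.779768, u = 0, v = 1, w = 0.999323,
      Nai = 11.1827, Ki = 138.991, Cai = 9.88513e-05,
      Caup = 1.46997, Carel = 1.47186)
  } else {
    c(V = -81.18, m = 0.002908, h = 0.9649, j = 0.9775,
      oa = 0.03043, oi = 0.9992, ua = 0.004966, ui = 0.9986,
      xr = 3.296e-5, xs = 0.01869, d = 1.367e-4, f = 0.9996, fca = 0.7755,
      u = 0, v = 1, w = 0.9992,
      Nai = 11.17, Ki = 139.0, Cai = 1.013e-4, Caup = 1.488, Carel = 1.488)
  }
}

state_names <- function() names(cell_initial_state())

validate_state <- function(state) {
  if (!is.numeric(state) || length(state) != 21L)
    abort("`state` must be a numeric vector of length 21 (see cell_initial_state()).")
  if (any(!is.finite(state))) {
    bad <- state_names()[which(!is.finite(state))[1]]
    abort(paste0("integration failure: state variable `", bad, "` is non-finite."))
  }
  invisible(state)
}

#' Construct an ionic-current profile
#'
#' A profile is one virtual patient's electrophysiology: a strictly positive
#' multiplier on each of the nine scalable currents, applied to the baseline
#' maximal conductances.
#'
#' @param ... Named multipliers among [current_names()], e.g. `INa = 0.5`.
#'   Unnamed currents default to 1.
#' @param profile_id Identifier (default "baseline" when all multipliers are 1).
#' @return One-row tibble with columns `profile_id` and `scale_<current>`.
#' @examples
#' ionic_profile(INa = 0.5, profile_id = "slow_na")
#' @export
ionic_profile <- function(..., profile_id = NULL) {
  m <- list(...)
  cur <- current_names()
  if (length(m) && (is.null(names(m)) || any(!names(m) %in% cur)))
    abort("multipliers must be named after one of current_names().")
  sc <- stats::setNames(rep(1, 9), cur)
  sc[names(m)] <- unlist(m)
  if (any(sc <= 0)) abort("all current multipliers must be strictly positive.")
  if (is.null(profile_id))
    profile_id <- if (all(sc == 1)) "baseline" else
      paste0("profile_", substr(digest_scales(sc), 1, 8))
  out <- as_tibble(as.list(stats::setNames(sc, paste0("scale_", cur))))
  tibble(profile_id = profile_id) |> dplyr::bind_cols(out)
}

digest_scales <- function(sc) {
  s <- paste(format(sc, digits = 10), collapse = "_")
  u <- utf8ToInt(s)
  sprintf("%08x", sum(u * seq_along(u)) %% .Machine$integer.max)
}

#' @rdname ionic_profile
#' @export
baseline_profile <- function() ionic_profile()

profile_scales <- function(profile) {
  cur <- current_names()
  cols <- paste0("scale_", cur)
  if (!all(cols %in% names(profile)))
    abort("`profile` must contain columns scale_INa ... scale_INCX (see ionic_profile()).")
  sc <- as.numeric(profile[1, cols])
  stats::setNames(sc, cur)
}

#' Electrophysiological region classes
#'
#' Seven region classes: the right-atrial baseline plus six heterogeneous
#' regions. Each maps to a set of per-current multiplicative adjustments
#' applied on top of a patient's ionic profile; the right-atrial baseline
#' adjustment is the identity.
#'
#' @return `region_kinds()`: character vector of the 7 class names.
#' @export
region_kinds <- function() {
  c("ra_baseline", "la_body", "pv_sleeve", "crista_terminalis",
    "pectinate_appendage", "av_ring", "cs_septal")
}

#' @rdname region_kinds
#' @return `region_adjustments()`: tibble with one row per region and one
#'   column per scalable current. Values are package defaults emulating
#'   shorter pulmonary-vein/left-atrial action potentials and longer
#'   crista-terminalis ones; they are assumptions, editable by the user.
#' @export
region_adjustments <- function() {
  adj <- tibble(region = region_kinds(),
                INa = 1, ICaL = 1, IK1 = 1, IKr = 1, IKs = 1,
                Ito = 1, IKur = 1, INaK = 1, INCX = 1)
  set <- function(adj, reg, ...) {
    v <- list(...)
    for (nm in names(v)) adj[adj$region == reg, nm] <- v[[nm]]
    adj
  }
  adj |>
    set("la_body", IKr = 1.6) |>
    set("pv_sleeve", IKr = 2.2, ICaL = 0.7, IK1 = 0.87) |>
    set("crista_terminalis", ICaL = 1.6, Ito = 1.35) |>
    set("pectinate_appendage", Ito = 1.2, IKr = 1.4) |>
    set("av_ring", ICaL = 0.67, Ito = 0.6) |>
    set("cs_septal", ICaL = 0.8, Ito = 0.8, IKr = 1.3)
}

region_scales <- function(region) {
  adj <- region_adjustments()
  if (!region %in% adj$region)
    abort(paste0("unknown region `", region, "`; see region_kinds()."))
  row <- adj[adj$region == region, current_names()]
  stats::setNames(as.numeric(row), current_names())
}

#' Pore-block drug specification
#'
#' A drug is a named set of fractional conductance blocks: current X keeps
#' `1 - block[X]` of its conductance. Unlisted currents are unblocked.
#'
#' @param name Drug name.
#' @param concentration Concentration in micromolar (bookkeeping only; no
#'   dose-response model).
#' @param block Named numeric vector of block fractions in \[0, 1\], names in
#'   [current_names()].
#' @return Object of class `drug_spec`.
#' @export
drug_spec <- function(name, concentration, block = numeric()) {
  if (length(block)) {
    if (is.null(names(block)) || any(!names(block) %in% current_names()))
      abort("`block` must be named after current_names().")
    if (any(block < 0 | block > 1)) abort("block fractions must lie in [0, 1].")
  }
  structure(list(name = name, concentration = concentration, block = block),
            class = "drug_spec")
}

#' @export
print.drug_spec <- function(x, ...) {
  cat(sprintf("<drug_spec> %s (%.1f uM)\n", x$name, x$concentration))
  if (length(x$block))
    cat(paste(sprintf("  %s: %d%%", names(x$block), round(100 * x$block)),
              collapse = "\n"), "\n")
  invisible(x)
}

#' Shipped pore-block presets
#'
#' The three antiarrhythmic presets used in the virtual trial: amiodarone at
#' 1.5 and 3.0 micromolar and vernakalant at 30 micromolar, as fractional
#' blocks of the nine scalable currents.
#'
#' @param name One of `"amiodarone_1.5"`, `"amiodarone_3.0"`,
#'   `"vernakalant_30"`.
#' @return A [drug_spec()].
#' @export
drug_preset <- function(name = c("amiodarone_1.5", "amiodarone_3.0",
                                 "vernakalant_30")) {
  name <- match.arg(name)
  switch(name,
    "amiodarone_1.5" = drug_spec("amiodarone", 1.5,
      c(IKr = 0.40, IKs = 0.30, INCX = 0.30, INa = 0.20)),
    "amiodarone_3.0" = drug_spec("amiodarone", 3.0,
      c(IKr = 0.70, Ito = 0.30, IK1 = 0.20, IKs = 0.50, INaK = 0.40,
        INCX = 0.50, INa = 0.50)),
    "vernakalant_30" = drug_spec("vernakalant", 30,
      c(IKur = 0.70, IKr = 0.60, Ito = 0.70, ICaL = 0.20, INa = 0.70)))
}

drug_scales <- function(drug) {
  sc <- stats::setNames(rep(1, 9), current_names())
  if (is.null(drug)) return(sc)
  if (!inherits(drug, "drug_spec")) abort("`drug` must be a drug_spec or NULL.")
  if (length(drug$block)) sc[names(drug$block)] <- 1 - drug$block
  sc
}

#' Compose effective per-current scalings
#'
#' Effective conductance of current X is baseline x profile x region
#' adjustment x (1 - drug block) x any extra multiplier (e.g. low-voltage-area
#' ionic remodelling). Composition is multiplicative, hence order-independent.
#'
#' @param profile An [ionic_profile()] row.
#' @param region One of [region_kinds()].
#' @param drug A [drug_spec()] or NULL.
#' @param extra Optional named multiplier vector (names in [current_names()]).
#' @return Named numeric vector of 9 multipliers.
#' @export
effective_scales <- function(profile = baseline_profile(),
                             region = "ra_baseline", drug = NULL,
                             extra = NULL) {
  sc <- profile_scales(profile) * region_scales(region) * drug_scales(drug)
  if (!is.null(extra)) sc[names(extra)] <- sc[names(extra)] * extra
  sc
}

#' Advance a single cell by one or more fixed time steps
#'
#' @param state Numeric state vector (see [cell_initial_state()]).
#' @param profile,region,drug Scaling sources, see [effective_scales()].
#' @param I_stim Stimulus current density in pA/pF (depolarizing positive).
#' @param dt Time step in ms, in (0, 0.05].
#' @param n_steps Number of steps to take (default 1).
#' @param params Baseline parameters, see [cell_params()].
#' @return Advanced state vector.
#' @export
step_cell <- function(state, profile = baseline_profile(),
                      region = "ra_baseline", drug = NULL,
                      I_stim = 0, dt = 0.02, n_steps = 1L,
                      params = cell_params()) {
  if (dt <= 0 || dt > 0.05) abort("`dt` must lie in (0, 0.05] ms.")
  validate_state(state)
  sc <- effective_scales(profile, region, drug)
  res <- cpp_monodomain_run(
    state = matrix(state, ncol = 1), scales = matrix(sc, ncol = 1),
    pars = params, active = TRUE, nx = 1L, ny = 1L, h = 1,
    Dxx = 0, Dyy = 0, Dxy = 0, dt = dt, n_steps = as.integer(n_steps), t0 = 0,
    stims = list(list(nodes = 0L, t_start = 0, duration = n_steps * dt,
                      amplitude = I_stim)),
    record_stride = 0L, probe_idx = integer(), probe_stride = 0L,
    reaction_on = TRUE, diffusion_on = FALSE)
  out <- stats::setNames(as.numeric(res$state), state_names())
  validate_state(out)
  out
}

#' Run a paced action potential to quasi-steady state
#'
#' Paces the cell for `n_beats` beats at the given cycle length and returns
#' the membrane-potential trace of the last beat (earlier beats are discarded
#' as conditioning).
#'
#' @inheritParams step_cell
#' @param pacing_cl Pacing cycle length in ms (>= 200).
#' @param n_beats Number of beats (>= 1).
#' @param stim_amp,stim_dur Stimulus amplitude (pA/pF) and duration (ms).
#' @param sample_ms Output sampling interval in ms.
#' @param init Initial state (default [cell_initial_state()]).
#' @return Tibble with columns `time_ms` (0 at the last stimulus onset) and
#'   `vm_mv`; attribute `final_state` carries the end state. Fails with an
#'   error if the last beat shows no upstroke (loss of capture).
#' @export
run_ap <- function(profile = baseline_profile(), region = "ra_baseline",
                   drug = NULL, pacing_cl = 1000, n_beats = 4L,
                   dt = 0.02, stim_amp = 30, stim_dur = 2,
                   sample_ms = 0.5, init = cell_initial_state(),
                   params = cell_params()) {
  if (pacing_cl < 200) abort("`pacing_cl` must be >= 200 ms.")
  if (n_beats < 1) abort("`n_beats` must be >= 1.")
  sc <- effective_scales(profile, region, drug)
  stims <- lapply(seq_len(n_beats) - 1L, function(b)
    list(nodes = 0L, t_start = b * pacing_cl, duration = stim_dur,
         amplitude = stim_amp))
  n_steps <- as.integer(round(n_beats * pacing_cl / dt))
  probe_stride <- max(1L, as.integer(round(sample_ms / dt)))
  res <- cpp_monodomain_run(
    state = matrix(init, ncol = 1), scales = matrix(sc, ncol = 1),
    pars = params, active = TRUE, nx = 1L, ny = 1L, h = 1,
    Dxx = 0, Dyy = 0, Dxy = 0, dt = dt, n_steps = n_steps, t0 = 0,
    stims = stims, record_stride = 0L, probe_idx = 0L,
    probe_stride = probe_stride, reaction_on = TRUE, diffusion_on = FALSE)
  if (res$status != "ok")
    abort(sprintf("cell integration unstable at t = %.2f ms.", res$bad_time))
  keep <- seq_len(res$n_probe_t)
  t_all <- res$probe_times[keep]
  v_all <- res$probes[keep, 1]
  last <- t_all >= (n_beats - 1L) * pacing_cl
  trace <- tibble(time_ms = t_all[last] - (n_beats - 1L) * pacing_cl,
                  vm_mv = v_all[last])
  if (max(trace$vm_mv) < -40)
    abort("failure to capture: no upstroke in the final paced beat.")
  attr(trace, "final_state") <- stats::setNames(as.numeric(res$state),
                                                state_names())
  attr(trace, "pacing_cl") <- pacing_cl
  trace
}

#' Measure single-cell action-potential biomarkers
#'
#' APD90 is measured from the time of maximum upstroke velocity to 90%
#' repolarization toward the resting potential.
#'
#' @param trace Tibble with `time_ms`, `vm_mv` (one beat, stimulus near t = 0).
#' @return One-row tibble: `apd90_ms`, `resting_vm_mv`, `peak_vm_mv`,
#'   `dvdt_max_v_s`, `erp_cell_ms` (NA; tissue ERP is measured by the pacing
#'   protocols).
#' @export
measure_biomarkers <- function(trace) {
  stopifnot(all(c("time_ms", "vm_mv") %in% names(trace)))
  t <- trace$time_ms; v <- trace$vm_mv
  if (length(t) < 5) abort("trace too short.")
  dvdt <- diff(v) / diff(t)              # mV/ms == V/s
  if (max(v) < -40 || max(dvdt) < 1)
    abort("no upstroke detected in trace.")
  iup <- which.max(dvdt)
  rest <- min(v[seq_len(max(iup - 1, 1))])
  if (iup <= 2) rest <- v[1]
  peak <- max(v[iup:length(v)])
  v90 <- rest + 0.1 * (peak - rest)
  after_peak <- which.max(v[iup:length(v)]) + iup - 1L
  below <- which(v[after_peak:length(v)] <= v90)
  if (!length(below)) {
    apd90 <- NA_real_
  } else {
    k <- below[1] + after_peak - 1L
    # linear interpolation of the crossing
    if (k > 1 && v[k - 1] > v90) {
      frac <- (v[k - 1] - v90) / (v[k - 1] - v[k])
      t90 <- t[k - 1] + frac * (t[k] - t[k - 1])
    } else t90 <- t[k]
    apd90 <- t90 - t[iup]
  }
  tibble(apd90_ms = apd90, resting_vm_mv = rest, peak_vm_mv = peak,
         dvdt_max_v_s = max(dvdt), erp_cell_ms = NA_real_)
}

#' Peak current under a voltage-clamp step, with and without a drug
#'
#' Runs a fixed two-step clamp protocol eliciting the named current and
#' reports the peak magnitude with and without the pore-block drug, plus the
#' percentage reduction. Used for the drug worked examples (e.g. the 70%
#' rapid-delayed-rectifier block by amiodarone 3.0 uM).
#'
#' @param current One of [current_names()].
#' @param drug A [drug_spec()].
#' @param profile,region,params As in [step_cell()].
#' @param dt Time step (ms).
#' @return One-row tibble: `current`, `peak_control`, `peak_drug`,
#'   `reduction_pct`.
#' @export
clamp_block_assay <- function(current, drug, profile = baseline_profile(),
                              region = "ra_baseline", params = cell_params(),
                              dt = 0.02) {
  stopifnot(current %in% current_names())
  # holding at -80 mV then a depolarizing step; tail at -40 for IKr-like tails
  hold <- -80; step_v <- if (current == "INa") -20 else 20
  t_hold <- 100; t_step <- 300; t_tail <- 100
  v_prot <- c(rep(hold, round(t_hold / dt)),
              rep(step_v, round(t_step / dt)),
              rep(-40, round(t_tail / dt)))
  run1 <- function(d) {
    sc <- effective_scales(profile, region, d)
    out <- cpp_voltage_clamp(cell_initial_state(), sc, params, v_prot, dt)
    max(abs(out$currents[, current]))
  }
  pc <- run1(NULL); pd <- run1(drug)
  tibble(current = current, peak_control = pc, peak_drug = pd,
         reduction_pct = 100 * (1 - pd / pc))
}
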