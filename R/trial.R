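# In-silico trial orchestration: named therapy catalog (lesion sets and/or
# pore-block drugs), treatment application to re-entrant tissue states,
# efficacy tabulation by LVA stratum, the feature-based stratification rule,
# and the reduced cohort trial driver.

#' Therapy catalog and constructor
#'
#' The trial's treatment arms: posterior-wall isolation (PWI), mitral
#' isthmus line (MI), cavo-tricuspid isthmus line (CTI), anterior mitral
#' line (MiLine), Marshall-PLAN (Marshall-bundle surrogate + MI + CTI on top
#' of PVI), staged LVA ablation, and the two drug arms. An amiodarone 1.5 uM
#' adjunct can be added to any ablation therapy (synergistic therapy).
#'
#' @param name Therapy name, one of `therapy_names()`.
#' @param adjunct_amiodarone Add low-dose amiodarone on top of an ablation
#'   therapy.
#' @return A `therapy` object: `name`, `components` (lesion building
#'   blocks), `drug` ([drug_spec()] or NULL).
#' @export
therapy <- function(name, adjunct_amiodarone = FALSE) {
  cat_tbl <- list(
    "PWI"            = list(comp = "pwi", drug = NULL),
    "PWI+MI"         = list(comp = c("pwi", "mi"), drug = NULL),
    "PWI+MI+CTI"     = list(comp = c("pwi", "mi", "cti"), drug = NULL),
    "MiLine"         = list(comp = "miline", drug = NULL),
    "MiLine+CTI"     = list(comp = c("miline", "cti"), drug = NULL),
    "Marshall-PLAN"  = list(comp = c("marshall", "mi", "cti"), drug = NULL),
    "LVA_LA"         = list(comp = "lva_la", drug = NULL),
    "LVA_LA+CTI"     = list(comp = c("lva_la", "cti"), drug = NULL),
    "LVA_LA-RA+CTI"  = list(comp = c("lva_la", "lva_ra", "cti"), drug = NULL),
    "amiodarone3.0"  = list(comp = character(),
                            drug = drug_preset("amiodarone_3.0")),
    "vernakalant30"  = list(comp = character(),
                            drug = drug_preset("vernakalant_30")))
  if (!name %in% names(cat_tbl))
    abort(paste0("unknown therapy `", name, "`; see therapy_names()."))
  spec <- cat_tbl[[name]]
  drug <- spec$drug
  if (adjunct_amiodarone) {
    if (!is.null(drug)) abort("adjunct applies to ablation therapies only.")
    drug <- drug_preset("amiodarone_1.5")
    name <- paste0(name, "+amio1.5")
  }
  structure(list(name = name, components = spec$comp, drug = drug),
            class = "therapy")
}

#' @rdname therapy
#' @export
therapy_names <- function() {
  c("PWI", "PWI+MI", "PWI+MI+CTI", "MiLine", "MiLine+CTI", "Marshall-PLAN",
    "LVA_LA", "LVA_LA+CTI", "LVA_LA-RA+CTI", "amiodarone3.0",
    "vernakalant30")
}

#' @export
print.therapy <- function(x, ...) {
  cat(sprintf("<therapy> %s: lesions [%s]%s\n", x$name,
              paste(x$components, collapse = ", "),
              if (!is.null(x$drug)) paste0(" + ", x$drug$name) else ""))
  invisible(x)
}

# perimeter of an element set: members adjacent to conducting non-members
boundary_ring <- function(mesh, set) {
  nb <- neighbour_matrix(mesh)
  ok <- mesh$active & !mesh$removed
  inset <- rep(FALSE, mesh_n(mesh)); inset[set] <- TRUE
  out <- vapply(set, function(e) {
    nbs <- nb[e, ]; nbs <- nbs[!is.na(nbs)]
    any(ok[nbs] & !inset[nbs])
  }, logical(1))
  set[out]
}

#' Build the lesion element set for a therapy
#'
#' PWI is a box isolation (perimeter ring) of the posterior wall; MI, CTI
#' and MiLine are transmural lines across their corridors; the Marshall
#' component is an extra lesion along the mitral-isthmus corridor standing
#' in for the ethanol-infused bundle; LVA components ablate every
#' LVA-labelled element of the named chamber. Composite therapies union
#' their parts.
#'
#' @param mesh An idealized atrial mesh.
#' @param therapy A [therapy()].
#' @param lva_map An `lva_map` (required by LVA components).
#' @return Integer element indices (possibly empty, with a warning for LVA
#'   components on LVA-free tissue).
#' @export
build_lesion_set <- function(mesh, therapy, lva_map = NULL) {
  need <- function(nm) {
    if (!nm %in% names(mesh$landmarks))
      abort(paste0("therapy `", therapy$name, "` needs missing landmark `",
                   nm, "`."))
    intersect(landmark(mesh, nm), which(mesh$active))
  }
  lva_in <- function(chamber) {
    if (is.null(lva_map)) {
      warn(paste0("LVA ablation requested without an LVA map; empty lesion."))
      return(integer())
    }
    sel <- which(lva_map$label & !is.na(mesh$chamber) &
                   mesh$chamber == chamber & mesh$active)
    if (!length(sel))
      warn(paste0("no LVA elements in the ", chamber, "; empty lesion."))
    sel
  }
  parts <- lapply(therapy$components, function(cp) {
    switch(cp,
      pwi = boundary_ring(mesh, need("posterior_wall")),
      mi = need("mitral_line"),
      cti = need("cti_line"),
      miline = need("anterior_line"),
      marshall = need("mitral_isthmus"),
      lva_la = lva_in("LA"),
      lva_ra = lva_in("RA"),
      abort(paste0("unknown lesion component `", cp, "`.")))
  })
  sort(unique(unlist(parts)))
}

majority_driver_class <- function(ps_kept, mesh, lva_map) {
  if (is.null(ps_kept) || !nrow(ps_kept)) return("none")
  ch <- mesh$chamber[ps_kept$element]
  lab <- rep("none", nrow(ps_kept))
  lab[!is.na(ch) & ch == "LA"] <- "LA"
  ra <- which(!is.na(ch) & ch == "RA")
  lab[ra] <- "RA-healthy"
  if (!is.null(lva_map) && length(ra))
    lab[ra[lva_map$label[ps_kept$element[ra]]]] <- "RA-LVA"
  names(which.max(table(lab)))
}

#' Apply one treatment to a re-entrant tissue state and record the outcome
#'
#' Applies the therapy's lesions (element removal) and/or drug to the
#' running state, simulates the analysis window, and records the
#' sustainment verdict plus rotor metrics and the driver-location class.
#'
#' @param mesh Mesh carrying the arrhythmia (post-PVI).
#' @param props Tissue properties (LVA remodelling already applied if any).
#' @param profile Patient profile.
#' @param state 21 x N state matrix at treatment time.
#' @param therapy A [therapy()].
#' @param config [solver_config()].
#' @param window_ms Post-treatment analysis window (ms).
#' @param lva_map Optional `lva_map`.
#' @param patient_id Identifier copied into the record.
#' @param t0 Simulation clock at treatment (ms).
#' @return One-row TrialRecord tibble: `patient_id`, `therapy`, `outcome`
#'   (`terminated`/`sustained`/`failed-run`), `termination_ms`,
#'   `rotor_count`, `regime`, `driver_class`.
#' @export
run_treatment <- function(mesh, props, profile, state, therapy,
                          config = solver_config(), window_ms = 2000,
                          lva_map = NULL, patient_id = "vp", t0 = 0) {
  lesion <- if (length(therapy$components))
    build_lesion_set(mesh, therapy, lva_map) else integer()
  mesh2 <- if (length(lesion)) apply_ablation(mesh, lesion) else mesh
  state2 <- state
  if (length(lesion)) state2[1, lesion] <- cell_initial_state()[["V"]]
  rec <- function(outcome, term = NA_real_, rot = NA_real_,
                  regime = NA_character_, drv = NA_character_) {
    tibble(patient_id = patient_id, therapy = therapy$name,
           outcome = outcome, termination_ms = term, rotor_count = rot,
           regime = regime, driver_class = drv)
  }
  traj <- tryCatch(
    run_monodomain(mesh2, props, profile, drug = therapy$drug,
                   duration_ms = window_ms, config = config, init = state2,
                   t0 = t0),
    error = function(e) NULL)
  if (is.null(traj)) return(rec("failed-run"))
  sus <- assess_sustainment(traj, window_ms = window_ms)
  drv <- "none"; rot <- 0; regime <- "none"
  cls <- tryCatch({
    pm <- compute_phase(traj)
    ps <- singularity_series(pm)
    list(cl = track_and_classify(ps, mesh2, lva_map = lva_map,
                                 min_life_ms = min(100, window_ms / 10)),
         ps = ps)
  }, error = function(e) NULL)
  if (!is.null(cls)) {
    rot <- cls$cl$rotor_count; regime <- cls$cl$regime
    if (nrow(cls$cl$tracks)) {
      drv <- majority_driver_class(cls$cl$samples, mesh2, lva_map)
    }
  }
  rec(if (sus$sustained) "sustained" else "terminated",
      term = sus$termination_ms, rot = rot, regime = regime, drv = drv)
}

#' Trial configuration
#'
#' Desk-scale defaults: coarse mesh and a shortened analysis window so a
#' reduced cohort runs in minutes. The full-scale settings of the emulated
#' protocol (h = 400 um, 7 s windows) are reachable by overriding the
#' fields.
#'
#' @param h_um Mesh edge length for patient anatomies.
#' @param induction_window_ms Post-induction analysis window.
#' @param treatment_window_ms Post-treatment analysis window.
#' @param n_cores Number of imposed spiral-wave cores.
#' @param lva_fraction Target LVA coverage per chamber.
#' @param sigma_l Baseline longitudinal conductivity (mS/mm); NULL means
#'   calibrate on a sheet at `h_um` to `target_cv_cm_s`.
#' @param target_cv_cm_s Bulk plane-wave calibration target (cm/s).
#' @param seed Master seed; all per-patient randomness derives from it.
#' @param solver A [solver_config()].
#' @return A `trial_config` list.
#' @export
trial_config <- function(h_um = 2000, induction_window_ms = 2000,
                         treatment_window_ms = 2000, n_cores = 3,
                         lva_fraction = 0.15, sigma_l = NULL,
                         target_cv_cm_s = 80, seed = 1L,
                         solver = solver_config(record_ms = 5)) {
  structure(list(h_um = h_um, induction_window_ms = induction_window_ms,
                 treatment_window_ms = treatment_window_ms,
                 n_cores = n_cores, lva_fraction = lva_fraction,
                 sigma_l = sigma_l, target_cv_cm_s = target_cv_cm_s,
                 seed = as.integer(seed), solver = solver),
            class = "trial_config")
}

default_cores <- function(mesh, n_cores, seed) {
  xy <- node_xy(mesh)
  pick <- function(lmk) {
    el <- landmark(mesh, lmk)
    c(mean(xy$x[el]), mean(xy$y[el]))
  }
  sites <- list(pick("posterior_wall"), pick("crista"), pick("anterior_wall"),
                pick("ra_appendage"), pick("la_appendage"))
  set.seed(as.integer(seed))
  jit <- matrix(rnorm(2 * n_cores, 0, 1.5), ncol = 2)
  ok <- mesh$active & !mesh$removed
  rows <- purrr::map_dfr(seq_len(n_cores), function(k) {
    p <- sites[[(k - 1L) %% length(sites) + 1L]] + jit[k, ]
    ni <- which.min((xy$x - p[1])^2 + (xy$y - p[2])^2 + 1e6 * !ok)
    tibble(x = xy$x[ni], y = xy$y[ni], chirality = ifelse(k %% 2 == 0, -1, 1))
  })
  rows
}

#' Run the reduced in-silico trial over a cohort
#'
#' Per patient: build the idealized anatomy at the configured resolution,
#' apply LVA remodelling for LVA-present patients, isolate the pulmonary
#' veins, impose spiral-wave re-entry, and assess sustainment over the
#' induction window. Patients with sustained arrhythmia then receive each
#' therapy independently from the same post-induction state.
#'
#' @param cohort Cohort tibble from [build_cohort()].
#' @param profiles Profile tibble holding every `profile_id` in the cohort.
#' @param therapies List of [therapy()] objects (or names).
#' @param config A [trial_config()].
#' @return A `trial_result`: `records` (all induction + treatment records),
#'   `sustained_ids`, `planned_runs`, `config`, plus the input cohort.
#' @export
run_trial <- function(cohort, profiles, therapies, config = trial_config()) {
  therapies <- lapply(therapies, function(th)
    if (inherits(th, "therapy")) th else therapy(th))
  sigma_l <- config$sigma_l
  if (is.null(sigma_l)) {
    sheet <- make_sheet(max(40L, as.integer(16000 / config$h_um)), 3,
                        config$h_um)
    sigma_l <- calibrate_baseline_conductivity(
      sheet, target_cv_cm_s = config$target_cv_cm_s,
      config = config$solver)$sigma_l
  }
  recs <- list(); sustained <- character()
  for (i in seq_len(nrow(cohort))) {
    pat <- cohort[i, ]
    prof <- profiles[profiles$profile_id == pat$profile_id, ]
    if (!nrow(prof)) abort(paste0("profile ", pat$profile_id, " not found."))
    pseed <- (config$seed + 7L * i) %% .Machine$integer.max
    mesh <- make_idealized_atria(pat$ra_volume_ml, pat$la_volume_ml,
                                 h_um = config$h_um)
    props <- tissue_properties(mesh, sigma_l)
    lva <- NULL
    if (pat$has_lva) {
      fld <- make_lva_probability_field(mesh, seed = pseed)
      lva <- threshold_lva(fld, mesh, config$lva_fraction)
      props <- apply_lva_remodelling(props, lva)
    }
    mesh <- apply_pvi(mesh)
    cores <- default_cores(mesh, config$n_cores, pseed)
    init <- induce_reentry(mesh, cores, profile = prof)
    traj <- tryCatch(
      run_monodomain(mesh, props, prof,
                     duration_ms = config$induction_window_ms,
                     config = config$solver, init = init),
      error = function(e) NULL)
    if (is.null(traj)) {
      recs[[length(recs) + 1]] <-
        tibble(patient_id = pat$patient_id, therapy = "induction",
               outcome = "failed-run", termination_ms = NA_real_,
               rotor_count = NA_real_, regime = NA_character_,
               driver_class = NA_character_, has_lva = pat$has_lva)
      next
    }
    sus <- assess_sustainment(traj, window_ms = config$induction_window_ms)
    recs[[length(recs) + 1]] <-
      tibble(patient_id = pat$patient_id, therapy = "induction",
             outcome = if (sus$sustained) "sustained" else "terminated",
             termination_ms = sus$termination_ms, rotor_count = NA_real_,
             regime = NA_character_, driver_class = NA_character_,
             has_lva = pat$has_lva)
    if (!sus$sustained) next
    sustained <- c(sustained, pat$patient_id)
    for (th in therapies) {
      recs[[length(recs) + 1]] <-
        run_treatment(mesh, props, prof, traj$final_state, th,
                      config = config$solver,
                      window_ms = config$treatment_window_ms,
                      lva_map = lva, patient_id = pat$patient_id,
                      t0 = config$induction_window_ms) |>
        mutate(has_lva = pat$has_lva)
    }
  }
  records <- dplyr::bind_rows(recs)
  structure(list(records = records, cohort = cohort,
                 sustained_ids = sustained,
                 planned_runs = planned_runs(nrow(cohort), length(sustained),
                                             length(therapies)),
                 config = config),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf("<trial_result> %d patients, %d sustained post-PVI, %d planned runs\n",
              nrow(x$cohort), length(x$sustained_ids), x$planned_runs))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.trial_result <- function(x, ...) x$records

#' @exportS3Method generics::glance
glance.trial_result <- function(x, ...) {
  tibble(n_patients = nrow(x$cohort),
         n_sustained = length(x$sustained_ids),
         planned_runs = x$planned_runs,
         n_failed = sum(x$records$outcome == "failed-run"))
}

#' Planned-run accounting
#'
#' One induction run per cohort member plus one treatment run per sustained
#' patient and therapy.
#'
#' @param n_cohort,n_sustained,n_therapies Counts.
#' @return Total planned simulation count.
#' @export
planned_runs <- function(n_cohort, n_sustained, n_therapies) {
  n_cohort + n_sustained * n_therapies
}

#' Treatment efficacy table by LVA stratum
#'
#' Freedom-from-arrhythmia (terminated / treated) per therapy, split by the
#' presence of LVAs, with totals. Failed runs are excluded from the
#' denominators.
#'
#' @param records TrialRecord tibble (therapy rows; induction rows are
#'   dropped automatically).
#' @return An `efficacy_table` tibble: `therapy`, `stratum`, `n_treated`,
#'   `n_terminated`, `pct_free`.
#' @export
efficacy_table <- function(records) {
  if (!nrow(records)) abort("no records.")
  tr <- records |> filter(.data$therapy != "induction",
                          .data$outcome != "failed-run")
  one <- function(df, label) {
    df |>
      group_by(.data$therapy) |>
      summarise(n_treated = dplyr::n(),
                n_terminated = sum(.data$outcome == "terminated"),
                .groups = "drop") |>
      mutate(stratum = label,
             pct_free = 100 * .data$n_terminated / .data$n_treated)
  }
  out <- dplyr::bind_rows(
    if ("has_lva" %in% names(tr))
      dplyr::bind_rows(one(tr |> filter(!.data$has_lva), "no_lva"),
                       one(tr |> filter(.data$has_lva), "lva")),
    one(tr, "all")) |>
    select("therapy", "stratum", "n_treated", "n_terminated", "pct_free")
  class(out) <- c("efficacy_table", class(out))
  out
}

#' Stratify a patient to a recommended therapy
#'
#' Decision cascade on the measured features. With LVAs: small right atria
#' (< 60 mL) get left-atrial LVA ablation alone; larger right atria get LVA
#' ablation with CTI block, extended to the right atrium when the ERP is
#' short (< 170 ms). Without LVAs: Marshall-PLAN for big right/small left
#' atria; anterior-line or posterior-wall strategies as the left atrium
#' grows (with CTI when the right atrium is big); small right and left
#' atria point to flutter-specific circuit ablation, which has no single
#' lesion set and is reported as a placeholder. In the LVA-absent arm a
#' short ERP adds the low-dose amiodarone adjunct. Boundary convention:
#' values exactly at a threshold take the "big/long" branch.
#'
#' @param features Tibble with `has_lva`, `ra_volume_ml`, `la_volume_ml`,
#'   `erp_ms` (one or more rows).
#' @return Tibble: input features plus `therapy` and `adjunct`.
#' @export
stratify <- function(features) {
  need <- c("has_lva", "ra_volume_ml", "la_volume_ml", "erp_ms")
  miss <- setdiff(need, names(features))
  if (length(miss))
    abort(paste0("missing feature(s): ", paste(miss, collapse = ", "), "."))
  if (any(is.na(features[need])))
    abort("stratification features contain missing values.")
  pick <- function(lva, ra, la, erp) {
    if (lva) {
      if (ra < 60) return(c("LVA_LA", NA))
      if (erp < 170) return(c("LVA_LA-RA+CTI", NA))
      return(c("LVA_LA+CTI", NA))
    }
    adj <- if (erp < 170) "amiodarone_1.5" else NA
    if (ra >= 60 && la < 90) return(c("Marshall-PLAN", adj))
    if (ra >= 60) return(c("MiLine+CTI", adj))
    if (la >= 90) return(c("MiLine", adj))
    c("flutter-circuit", adj)
  }
  res <- purrr::map(seq_len(nrow(features)), function(i)
    pick(features$has_lva[i], features$ra_volume_ml[i],
         features$la_volume_ml[i], features$erp_ms[i]))
  features |>
    mutate(therapy = purrr::map_chr(res, 1),
           adjunct = purrr::map_chr(res, 2))
}
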