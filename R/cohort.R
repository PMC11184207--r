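# Virtual-patient cohort assembly: sampled ionic-current profiles,
# biomarker-based calibration (population-of-models rejection sampling),
# anatomy-size sampling, and the profiles x anatomies x LVA-status cross.

#' Sample ionic-current profiles
#'
#' Each of the nine scalable currents receives an independent multiplier
#' drawn uniformly from `[1 - spread, 1 + spread]` (default +/- 50%).
#'
#' @param n Number of profiles (>= 1).
#' @param spread Half-width of the uniform sampling interval, in (0, 1].
#' @param seed Integer seed (reproducible).
#' @return Tibble of `n` profiles: `profile_id`, `scale_<current>`.
#' @export
sample_profiles <- function(n, spread = 0.5, seed = 1) {
  if (n < 1) abort("`n` must be >= 1.")
  if (spread <= 0 || spread > 1) abort("`spread` must lie in (0, 1].")
  set.seed(as.integer(seed))
  cur <- current_names()
  m <- matrix(runif(n * 9, 1 - spread, 1 + spread), nrow = n)
  colnames(m) <- paste0("scale_", cur)
  dplyr::bind_cols(tibble(profile_id = sprintf("p%03d", seq_len(n))),
                   as_tibble(as.data.frame(m)))
}

#' Biomarker acceptance intervals for profile calibration
#'
#' Default single-cell acceptance windows for persistent-AF human atrial
#' action potentials: APD90, resting and peak membrane potential, and
#' maximum upstroke velocity. Broad literature-informed package defaults;
#' override any bound as needed.
#'
#' @param apd90_ms,resting_vm_mv,peak_vm_mv,dvdt_max_v_s Two-element
#'   `c(lower, upper)` intervals.
#' @return A `calibration_ranges` list.
#' @export
calibration_ranges <- function(apd90_ms = c(70, 330),
                               resting_vm_mv = c(-90, -70),
                               peak_vm_mv = c(0, 50),
                               dvdt_max_v_s = c(50, 400)) {
  rng <- list(apd90_ms = apd90_ms, resting_vm_mv = resting_vm_mv,
              peak_vm_mv = peak_vm_mv, dvdt_max_v_s = dvdt_max_v_s)
  for (nm in names(rng))
    if (length(rng[[nm]]) != 2 || diff(rng[[nm]]) <= 0)
      abort(paste0("range `", nm, "` must be c(lower, upper) with lower < upper."))
  structure(rng, class = "calibration_ranges")
}

#' Single-cell biomarkers for a table of profiles
#'
#' @param profiles Tibble from [sample_profiles()] / [ionic_profile()].
#' @param pacing_cl,n_beats Pacing protocol for [run_ap()].
#' @return `profiles` with biomarker columns appended; `capture` is FALSE
#'   (biomarkers NA) for profiles that fail to elicit an upstroke.
#' @export
profile_biomarkers <- function(profiles, pacing_cl = 1000, n_beats = 3L) {
  bm <- purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
    tr <- tryCatch(run_ap(profiles[i, ], pacing_cl = pacing_cl,
                          n_beats = n_beats),
                   error = function(e) NULL)
    if (is.null(tr))
      return(tibble(apd90_ms = NA_real_, resting_vm_mv = NA_real_,
                    peak_vm_mv = NA_real_, dvdt_max_v_s = NA_real_,
                    erp_cell_ms = NA_real_, capture = FALSE))
    measure_biomarkers(tr) |> mutate(capture = TRUE)
  })
  dplyr::bind_cols(profiles, bm)
}

#' Calibrate a population of profiles against biomarker ranges
#'
#' Population-of-models rejection step: keeps exactly those profiles whose
#' single-cell biomarkers fall inside every acceptance interval. Rejection
#' reasons are recorded per profile in the `rejections` attribute.
#'
#' @param profiles Profile tibble.
#' @param ranges A [calibration_ranges()].
#' @param ... Passed to [profile_biomarkers()].
#' @return Accepted subset (biomarker columns retained); attribute
#'   `rejections` is a tibble `profile_id`, `reason`. Warns when nothing is
#'   accepted.
#' @export
calibrate_profiles <- function(profiles, ranges = calibration_ranges(), ...) {
  bm <- profile_biomarkers(profiles, ...)
  inside <- function(v, rng) !is.na(v) & v >= rng[1] & v <= rng[2]
  reasons <- purrr::map_chr(seq_len(nrow(bm)), function(i) {
    if (!bm$capture[i]) return("no-capture")
    bad <- names(ranges)[!purrr::map_lgl(names(ranges), function(nm)
      inside(bm[[nm]][i], ranges[[nm]]))]
    if (!length(bad)) "" else paste(sub("_ms$|_mv$|_v_s$", "", bad),
                                    collapse = ";")
  })
  keep <- reasons == ""
  out <- bm[keep, , drop = FALSE]
  attr(out, "rejections") <- tibble(profile_id = bm$profile_id[!keep],
                                    reason = reasons[!keep])
  if (!nrow(out))
    warn("calibration rejected every profile; inspect attr(, 'rejections').")
  out
}

#' Sample anatomy size scales
#'
#' Right/left atrial volumes drawn from truncated normal distributions
#' (means 127 and 105 mL, SDs 51 and 39 mL, truncated above 20 mL),
#' matching the population statistics the cohort is meant to span.
#'
#' @param n Number of anatomies (>= 1).
#' @param seed Integer seed.
#' @param ra_mean,ra_sd,la_mean,la_sd Distribution parameters (mL).
#' @param lower Truncation bound (mL, default 20).
#' @return Tibble: `anatomy_id`, `ra_volume_ml`, `la_volume_ml`.
#' @export
sample_anatomy_scales <- function(n, seed = 1, ra_mean = 127, ra_sd = 51,
                                  la_mean = 105, la_sd = 39, lower = 20) {
  if (n < 1) abort("`n` must be >= 1.")
  set.seed(as.integer(seed))
  draw <- function(mean, sd) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- rnorm(n, mean, sd)
      out <- c(out, x[x > lower])
    }
    out[seq_len(n)]
  }
  tibble(anatomy_id = sprintf("a%02d", seq_len(n)),
         ra_volume_ml = draw(ra_mean, ra_sd),
         la_volume_ml = draw(la_mean, la_sd))
}

#' Assemble the virtual-patient cohort
#'
#' Full cross of profiles and anatomies; when `with_and_without_lva` each
#' combination appears twice, as an LVA-absent patient and its LVA-present
#' twin sharing profile and anatomy. Pure function of its inputs.
#'
#' @param profiles Profile tibble (unique `profile_id`s).
#' @param anatomies Anatomy tibble from [sample_anatomy_scales()].
#' @param with_and_without_lva Duplicate each patient into LVA-absent and
#'   LVA-present versions (default TRUE).
#' @return Cohort tibble: `patient_id`, `profile_id`, `anatomy_id`,
#'   `ra_volume_ml`, `la_volume_ml`, `has_lva`, `erp_ms` (NA until measured).
#' @export
build_cohort <- function(profiles, anatomies, with_and_without_lva = TRUE) {
  if (!nrow(profiles) || !nrow(anatomies))
    abort("need at least one profile and one anatomy.")
  if (anyDuplicated(profiles$profile_id))
    abort("duplicate profile_id in `profiles`.")
  if (anyDuplicated(anatomies$anatomy_id))
    abort("duplicate anatomy_id in `anatomies`.")
  lva_states <- if (with_and_without_lva) c(FALSE, TRUE) else FALSE
  out <- tidyr::expand_grid(profile_id = profiles$profile_id,
                            anatomy_id = anatomies$anatomy_id,
                            has_lva = lva_states) |>
    left_join(anatomies, by = "anatomy_id") |>
    mutate(patient_id = sprintf("vp%04d", dplyr::row_number()),
           erp_ms = NA_real_) |>
    select("patient_id", "profile_id", "anatomy_id", "ra_volume_ml",
           "la_volume_ml", "has_lva", "erp_ms")
  out
}

#' Write cohort and profiles to disk
#'
#' @param cohort Cohort tibble.
#' @param profiles Profile tibble.
#' @param dir Output directory (created if absent).
#' @return Paths written, invisibly.
#' @export
write_cohort <- function(cohort, profiles, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p1 <- file.path(dir, "cohort.csv")
  p2 <- file.path(dir, "profiles.json")
  write.csv(cohort, p1, row.names = FALSE)
  jsonlite::write_json(profiles, p2, digits = NA)
  invisible(c(p1, p2))
}
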