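# Arrhythmia quantification: analytic-signal phase maps, phase-singularity
# detection by topological charge, frame-to-frame rotor tracking and
# classification, infinite-volume-conductor pseudo-ECG, and dominant
# frequency of fibrillatory signals.

# analytic signal x + i*H(x) via the frequency-domain construction
analytic_signal <- function(x) {
  n <- length(x)
  X <- fft(x)
  w <- rep(0, n)
  w[1] <- 1
  if (n %% 2 == 0) {
    w[n / 2 + 1] <- 1
    if (n > 2) w[2:(n / 2)] <- 2
  } else {
    w[2:((n + 1) / 2)] <- 2
  }
  fft(X * w, inverse = TRUE) / n
}

#' Phase map of a voltage trajectory
#'
#' Per-element instantaneous phase via the analytic-signal (Hilbert) method
#' on the mean-subtracted voltage. Elements whose voltage barely varies are
#' flagged undefined.
#'
#' @param traj A `tissue_trajectory` with snapshots (>= 1 s at <= 5 ms
#'   stride).
#' @param min_sd_mv Variability floor (mV) below which phase is undefined.
#' @return A `phase_map`: list with `times`, `phase` (frames x elements, in
#'   (-pi, pi], NA where undefined), `defined` (logical per element), `mesh`.
#' @export
compute_phase <- function(traj, min_sd_mv = 1) {
  if (is.null(traj$vm)) abort("trajectory has no snapshots.")
  times <- traj$times
  if (length(times) < 8) abort("need at least 8 snapshot frames.")
  stride <- stats::median(diff(times))
  if (stride > 5 + 1e-9) abort("snapshot stride must be <= 5 ms for phase mapping.")
  if (max(times) - min(times) < 1000 - 1e-9)
    warn("phase map computed from less than 1 s of data.")
  vm <- traj$vm
  n <- ncol(vm)
  ph <- matrix(NA_real_, nrow(vm), n)
  sds <- apply(vm, 2, stats::sd)
  defined <- sds >= min_sd_mv
  idx <- which(defined)
  if (length(idx)) {
    centred <- sweep(vm[, idx, drop = FALSE], 2,
                     colMeans(vm[, idx, drop = FALSE]))
    an <- apply(centred, 2, analytic_signal)
    ph[, idx] <- atan2(Im(an), Re(an))
  }
  structure(list(times = times, phase = ph, defined = defined,
                 mesh = traj$mesh),
            class = "phase_map")
}

wrap_pi <- function(x) ((x + pi) %% (2 * pi)) - pi

#' Detect phase singularities at one frame
#'
#' Topological charge of every 2 x 2 plaquette of conducting elements:
#' the closed-loop sum of wrapped phase differences divided by 2*pi.
#' Plaquettes with |charge| = 1 are reported as singularities (rotor tips)
#' at the plaquette center.
#'
#' @param phase Either a `phase_map` or a numeric phase vector (one frame).
#' @param mesh Required when `phase` is a vector.
#' @param frame Frame index when `phase` is a `phase_map` (default last).
#' @return Tibble: `x`, `y` (mm), `charge` (+1/-1), `element` (lower-left
#'   element of the plaquette).
#' @export
detect_singularities <- function(phase, mesh = NULL, frame = NULL) {
  if (inherits(phase, "phase_map")) {
    mesh <- phase$mesh
    if (is.null(frame)) frame <- nrow(phase$phase)
    ph <- phase$phase[frame, ]
  } else ph <- phase
  stopifnot(!is.null(mesh))
  nx <- mesh$nx; ny <- mesh$ny
  ok <- mesh$active & !mesh$removed & !is.na(ph)
  n <- nx * ny
  i <- (seq_len(n) - 1L) %% nx
  j <- (seq_len(n) - 1L) %/% nx
  base <- which(i < nx - 1L & j < ny - 1L)
  a <- base; b <- base + 1L; cc <- base + 1L + nx; d <- base + nx
  good <- ok[a] & ok[b] & ok[cc] & ok[d]
  a <- a[good]; b <- b[good]; cc <- cc[good]; d <- d[good]
  wind <- wrap_pi(ph[b] - ph[a]) + wrap_pi(ph[cc] - ph[b]) +
    wrap_pi(ph[d] - ph[cc]) + wrap_pi(ph[a] - ph[d])
  q <- round(wind / (2 * pi))
  hit <- which(abs(q) == 1L)
  h <- mesh$h_mm
  tibble(x = (i[a[hit]] + 1) * h, y = (j[a[hit]] + 1) * h,
         charge = as.integer(q[hit]), element = a[hit])
}

#' Detect and track singularities across all frames
#'
#' @param pm A `phase_map`.
#' @return Tibble with `time_ms`, `x`, `y`, `charge`, `element` stacked over
#'   frames.
#' @export
singularity_series <- function(pm) {
  stopifnot(inherits(pm, "phase_map"))
  purrr::map_dfr(seq_along(pm$times), function(f) {
    s <- detect_singularities(pm, frame = f)
    if (nrow(s)) s$time_ms <- pm$times[f]
    s
  })
}

#' Track singularities over time and classify rotor dynamics
#'
#' Nearest-neighbour frame-to-frame linking with a gating radius; a track is
#' `stationary` when its tip excursion stays under `stationary_mm`, else
#' `meandering`. The trajectory-level regime follows the track census:
#' `none`, `stationary-only`, `one-meandering` (one meandering, any number
#' stationary), `two-plus-unstable` (two or more meandering), or `break-up`
#' (mean simultaneous tip count above `breakup_count`). When an LVA map is
#' supplied, a track is anchored if at least `anchor_frac` of its tip
#' samples lie within `halo_mm` of LVA elements.
#'
#' @param ps Singularity series from [singularity_series()] (or a tibble
#'   with `time_ms`, `x`, `y`, `charge`).
#' @param mesh The mesh (for LVA distance lookups).
#' @param lva_map Optional `lva_map`.
#' @param gate_mm Linking radius between consecutive frames (default 4 mm).
#' @param stationary_mm Excursion threshold (default 5 mm).
#' @param anchor_frac,halo_mm Anchoring rule parameters (defaults 0.8, 2 mm).
#' @param breakup_count Mean simultaneous-tip count defining break-up
#'   (default 4).
#' @param min_life_ms Tracks shorter than this are ignored as detection
#'   noise (default 100 ms).
#' @return A `rotor_classification`: list with `tracks` (per-track tibble:
#'   id, life span, excursion, label, anchored), `rotor_count` (mean
#'   simultaneous tracked tips), `regime`.
#' @export
track_and_classify <- function(ps, mesh, lva_map = NULL, gate_mm = 4,
                               stationary_mm = 5, anchor_frac = 0.8,
                               halo_mm = 2, breakup_count = 4,
                               min_life_ms = 100) {
  if (!nrow(ps)) {
    return(structure(list(tracks = tibble(), rotor_count = 0,
                          regime = "none", samples = tibble()),
                     class = "rotor_classification"))
  }
  frames <- sort(unique(ps$time_ms))
  ps <- ps |> arrange(.data$time_ms)
  ps$track <- NA_integer_
  next_id <- 0L
  prev <- NULL
  for (ft in frames) {
    cur <- which(ps$time_ms == ft)
    if (!is.null(prev) && length(prev)) {
      for (k in cur) {
        d <- sqrt((ps$x[prev] - ps$x[k])^2 + (ps$y[prev] - ps$y[k])^2)
        d[ps$charge[prev] != ps$charge[k]] <- Inf
        if (length(d) && min(d) <= gate_mm) {
          j <- prev[which.min(d)]
          ps$track[k] <- ps$track[j]
          prev <- setdiff(prev, j)
        }
      }
    }
    new <- cur[is.na(ps$track[cur])]
    if (length(new)) {
      ps$track[new] <- next_id + seq_along(new)
      next_id <- next_id + length(new)
    }
    prev <- cur
  }
  # LVA halo distance
  in_halo <- function(x, y) {
    if (is.null(lva_map)) return(rep(FALSE, length(x)))
    sel <- which(lva_map$label)
    if (!length(sel)) return(rep(FALSE, length(x)))
    xy <- node_xy(mesh)
    vapply(seq_along(x), function(k)
      min(sqrt((xy$x[sel] - x[k])^2 + (xy$y[sel] - y[k])^2)) <= halo_mm,
      logical(1))
  }
  tracks <- ps |>
    group_by(track_id = .data$track) |>
    summarise(t_start = min(.data$time_ms), t_end = max(.data$time_ms),
              life_ms = .data$t_end - .data$t_start,
              excursion_mm = max(sqrt((.data$x - .data$x[1])^2 +
                                        (.data$y - .data$y[1])^2)),
              charge = .data$charge[1],
              anchored = mean(in_halo(.data$x, .data$y)) >= anchor_frac,
              n_samples = dplyr::n(), .groups = "drop") |>
    filter(.data$life_ms >= min_life_ms) |>
    mutate(label = ifelse(.data$excursion_mm < stationary_mm,
                          "stationary", "meandering"))
  kept <- ps |> filter(.data$track %in% tracks$track_id)
  rotor_count <- if (nrow(kept))
    mean(table(factor(kept$time_ms, levels = frames))) else 0
  n_meander <- sum(tracks$label == "meandering")
  regime <- if (!nrow(tracks)) "none"
    else if (rotor_count >= breakup_count) "break-up"
    else if (n_meander == 0) "stationary-only"
    else if (n_meander == 1) "one-meandering"
    else "two-plus-unstable"
  structure(list(tracks = tracks, rotor_count = rotor_count,
                 regime = regime, samples = kept),
            class = "rotor_classification")
}

#' @export
print.rotor_classification <- function(x, ...) {
  cat(sprintf("<rotor_classification> %s; mean simultaneous rotors %.2f; %d tracks\n",
              x$regime, x$rotor_count, nrow(x$tracks)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.rotor_classification <- function(x, ...) x$tracks

#' @exportS3Method generics::glance
glance.rotor_classification <- function(x, ...)
  tibble(regime = x$regime, rotor_count = x$rotor_count,
         n_tracks = nrow(x$tracks))

#' Detect macro-re-entry around an obstacle
#'
#' Structural identification of macro-re-entrant circuits (e.g.
#' peri-annular flutter): the phase winding along a closed loop of
#' conducting elements encircling an obstacle (an annulus landmark or any
#' inactive/ablated island) is +-1 consistently across frames, even though
#' no phase singularity lies on tissue.
#'
#' @param pm A `phase_map`.
#' @param centre_xy Numeric `c(x, y)` (mm): a point inside the obstacle.
#' @param radius_mm Loop radius; must clear the obstacle and stay on
#'   conducting tissue.
#' @param min_frac Fraction of frames that must agree on a nonzero winding
#'   (default 0.8).
#' @return One-row tibble: `macro_reentry` (logical), `winding` (modal
#'   winding number), `frac_frames` (agreement fraction).
#' @export
detect_macro_reentry <- function(pm, centre_xy, radius_mm, min_frac = 0.8) {
  stopifnot(inherits(pm, "phase_map"))
  mesh <- pm$mesh
  xy <- node_xy(mesh)
  ang <- seq(0, 2 * pi, length.out = 73)[-73]
  px <- centre_xy[1] + radius_mm * cos(ang)
  py <- centre_xy[2] + radius_mm * sin(ang)
  loop <- vapply(seq_along(ang), function(k)
    which.min((xy$x - px[k])^2 + (xy$y - py[k])^2), integer(1))
  loop <- loop[c(TRUE, diff(loop) != 0)]
  ok <- mesh$active & !mesh$removed
  if (any(!ok[loop]))
    abort("loop crosses non-conducting tissue; adjust centre or radius.")
  loop <- c(loop, loop[1])
  winds <- vapply(seq_along(pm$times), function(f) {
    ph <- pm$phase[f, loop]
    if (any(is.na(ph))) return(NA_real_)
    round(sum(wrap_pi(diff(ph))) / (2 * pi))
  }, numeric(1))
  winds <- winds[!is.na(winds)]
  if (!length(winds))
    return(tibble(macro_reentry = FALSE, winding = 0, frac_frames = 0))
  tab <- table(winds)
  modal <- as.numeric(names(tab)[which.max(tab)])
  frac <- max(tab) / length(winds)
  tibble(macro_reentry = modal != 0 && frac >= min_frac,
         winding = modal, frac_frames = frac)
}

#' Infinite-volume-conductor pseudo-ECG
#'
#' The dipole-source sum `phi(t) = sum_elements sigma * grad(Vm) . grad(1/r)`
#' evaluated at each electrode, with r the distance from element to
#' electrode. Electrodes must lie off the tissue plane or outside the tissue.
#'
#' @param traj A `tissue_trajectory` with snapshots.
#' @param props A `tissue_props` (per-element conductivity).
#' @param electrodes Tibble with `x`, `y`, `z` (mm).
#' @return Tibble: `time_ms`, one column `ecg_<k>` per electrode
#'   (arbitrary units).
#' @export
pseudo_ecg <- function(traj, props, electrodes) {
  if (is.null(traj$vm)) abort("trajectory has no snapshots.")
  mesh <- traj$mesh
  stopifnot(all(c("x", "y", "z") %in% names(electrodes)))
  xy <- node_xy(mesh)
  ok <- mesh$active & !mesh$removed
  h <- mesh$h_mm
  nx <- mesh$nx; ny <- mesh$ny
  nfr <- nrow(traj$vm)
  ne <- nrow(electrodes)
  out <- matrix(0, nfr, ne)
  # gradient kernels of 1/r at each element, per electrode
  GX <- matrix(0, nx * ny, ne); GY <- matrix(0, nx * ny, ne)
  for (e in seq_len(ne)) {
    dx <- xy$x - electrodes$x[e]
    dy <- xy$y - electrodes$y[e]
    dz <- -electrodes$z[e]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    if (any(r[ok] < 0.5 * h))
      abort("electrode lies on the tissue; move it off the plane.")
    GX[, e] <- -dx / r^3
    GY[, e] <- -dy / r^3
  }
  okm <- matrix(ok, nx, ny)
  badx <- matrix(TRUE, nx, ny)
  badx[2:(nx - 1), ] <- !okm[3:nx, ] | !okm[1:(nx - 2), ]
  bady <- matrix(TRUE, nx, ny)
  bady[, 2:(ny - 1)] <- !okm[, 3:ny] | !okm[, 1:(ny - 2)]
  sig <- props$sigma_l
  for (f in seq_len(nfr)) {
    vmat <- matrix(traj$vm[f, ], nx, ny)
    gvx <- matrix(0, nx, ny); gvy <- matrix(0, nx, ny)
    gvx[2:(nx - 1), ] <- (vmat[3:nx, ] - vmat[1:(nx - 2), ]) / (2 * h)
    gvy[, 2:(ny - 1)] <- (vmat[, 3:ny] - vmat[, 1:(ny - 2)]) / (2 * h)
    gvx[!okm | badx] <- 0
    gvy[!okm | bady] <- 0
    wx <- sig * as.numeric(gvx); wy <- sig * as.numeric(gvy)
    out[f, ] <- (crossprod(GX, wx) + crossprod(GY, wy)) * h^2
  }
  res <- as_tibble(as.data.frame(out))
  names(res) <- paste0("ecg_", seq_len(ncol(out)))
  dplyr::bind_cols(tibble(time_ms = traj$times), res)
}

#' Dominant frequency of a fibrillatory signal
#'
#' Argmax of the Welch-averaged periodogram inside a physiological band
#' (default 1-15 Hz).
#'
#' @param signal Numeric signal values (uniformly sampled).
#' @param dt_ms Sampling interval in ms.
#' @param band Search band in Hz.
#' @param n_segments Welch segments (50% overlap, Hann window; default 4).
#' @return Dominant frequency in Hz, or `NA` with attribute
#'   `status = "silent"` for (near-)constant signals.
#' @export
dominant_frequency <- function(signal, dt_ms, band = c(1, 15),
                               n_segments = 4) {
  n <- length(signal)
  if (n * dt_ms < 4000 - 1e-9)
    abort("need at least 4 s of signal for dominant-frequency analysis.")
  if (stats::sd(signal) < 1e-9)
    return(structure(NA_real_, status = "silent"))
  x <- signal - mean(signal)
  seg_len <- floor(n / (n_segments / 2 + 0.5))
  seg_len <- max(16, seg_len)
  hop <- floor(seg_len / 2)
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))
  nfft <- 2^ceiling(log2(seg_len))
  acc <- numeric(nfft)
  k <- 0
  start <- 1
  while (start + seg_len - 1 <= n) {
    seg <- x[start:(start + seg_len - 1)] * win
    acc <- acc + Mod(fft(c(seg, rep(0, nfft - seg_len))))^2
    k <- k + 1
    start <- start + hop
  }
  if (k == 0) abort("signal too short for the Welch estimator.")
  fs <- 1000 / dt_ms
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  sel <- which(freqs >= band[1] & freqs <= band[2])
  freqs[sel[which.max(acc[sel])]]
}
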