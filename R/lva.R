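# Probabilistic low-voltage-area (LVA) maps: a smooth random field over the
# mesh standing in for the multi-patient bipolar-voltage superposition the
# pipeline would otherwise take from electro-anatomical mapping, and a greedy
# per-chamber thresholding that labels the most probable elements until the
# target coverage is reached.

gauss_smooth_grid <- function(z, nx, ny, sigma_nodes, mask) {
  # separable Gaussian smoothing on the full grid with mask renormalization
  if (sigma_nodes <= 0) return(z)
  half <- max(1L, ceiling(3 * sigma_nodes))
  k <- exp(-0.5 * ((-half:half) / sigma_nodes)^2)
  k <- k / sum(k)
  zm <- matrix(z * mask, nx, ny)
  mm <- matrix(as.numeric(mask), nx, ny)
  conv1 <- function(m, along) {
    out <- matrix(0, nrow(m), ncol(m))
    for (d in -half:half) {
      w <- k[d + half + 1]
      if (along == 1) {
        src <- pmin(pmax(seq_len(nrow(m)) + d, 1L), nrow(m))
        out <- out + w * m[src, , drop = FALSE]
      } else {
        src <- pmin(pmax(seq_len(ncol(m)) + d, 1L), ncol(m))
        out <- out + w * m[, src, drop = FALSE]
      }
    }
    out
  }
  num <- conv1(conv1(zm, 1), 2)
  den <- conv1(conv1(mm, 1), 2)
  res <- as.numeric(num) / pmax(as.numeric(den), 1e-12)
  res[!mask] <- 0
  res
}

#' Synthetic LVA probability field
#'
#' A Gaussian-smoothed random field over the conducting elements, rescaled to
#' \[0, 1\], with a configurable bias toward the anterior- and posterior-wall
#' landmarks (where such mapping data typically concentrate low voltage).
#' Reproducible under `seed`.
#'
#' @param mesh A `tissue_mesh`.
#' @param smoothness_mm Smoothing length in mm (correlation length grows with
#'   it). Default 4.
#' @param seed Integer seed.
#' @param wall_bias Additive bias weight on anterior/posterior-wall elements
#'   (0 disables; default 0.5).
#' @return Numeric vector (length = number of elements) of probabilities in
#'   \[0, 1\]; 0 on non-conducting elements.
#' @export
make_lva_probability_field <- function(mesh, smoothness_mm = 4, seed = 1,
                                       wall_bias = 0.5) {
  n <- mesh_n(mesh)
  ok <- mesh$active & !mesh$removed
  set.seed(as.integer(seed))
  z <- rnorm(n)
  sig <- smoothness_mm / mesh$h_mm
  f <- gauss_smooth_grid(z, mesh$nx, mesh$ny, sig, ok)
  if (wall_bias > 0) {
    ind <- rep(0, n)
    for (nm in intersect(c("anterior_wall", "posterior_wall"),
                         names(mesh$landmarks)))
      ind[mesh$landmarks[[nm]]] <- 1
    f <- f + wall_bias * gauss_smooth_grid(ind, mesh$nx, mesh$ny, sig, ok) *
      stats::sd(f[ok]) / max(1e-12, stats::sd(ind[ok]))
  }
  rng <- range(f[ok])
  p <- rep(0, n)
  p[ok] <- (f[ok] - rng[1]) / max(rng[2] - rng[1], 1e-12)
  p
}

#' Threshold a probability field into an LVA map
#'
#' Greedy selection per chamber: elements are labelled in order of decreasing
#' probability (ties broken by element index) until the labelled fraction of
#' that chamber's conducting elements reaches `fraction`. Deterministic given
#' the field.
#'
#' @param field Probability vector from [make_lva_probability_field()].
#' @param mesh A `tissue_mesh`.
#' @param fraction Target coverage per chamber in \[0, 1\] (default 0.15).
#' @return An `lva_map`: list with `prob`, logical `label`, `fraction`, and a
#'   tibble `coverage` of achieved per-chamber fractions.
#' @export
threshold_lva <- function(field, mesh, fraction = 0.15) {
  if (fraction < 0 || fraction > 1) abort("`fraction` must lie in [0, 1].")
  n <- mesh_n(mesh)
  ok <- mesh$active & !mesh$removed
  label <- rep(FALSE, n)
  chams <- unique(mesh$chamber[ok])
  chams <- chams[!is.na(chams)]
  if (!length(chams)) chams <- NA
  cov <- list()
  for (ch in chams) {
    in_ch <- ok & (if (is.na(ch)) TRUE else !is.na(mesh$chamber) &
                     mesh$chamber == ch)
    idx <- which(in_ch)
    if (!length(idx)) next
    ord <- idx[order(-field[idx], idx)]
    need <- ceiling(fraction * length(idx))
    if (need > 0) label[ord[seq_len(need)]] <- TRUE
    cov[[length(cov) + 1]] <- tibble(chamber = as.character(ch),
                                     n_elements = length(idx),
                                     n_lva = sum(label[idx]),
                                     achieved = sum(label[idx]) / length(idx))
  }
  structure(list(prob = field, label = label, fraction = fraction,
                 coverage = dplyr::bind_rows(cov)),
            class = "lva_map")
}

#' @export
print.lva_map <- function(x, ...) {
  cat(sprintf("<lva_map> target fraction %.2f\n", x$fraction))
  print(x$coverage)
  invisible(x)
}

# ---- legacy VTK and CSV export ----

region_codes <- function() stats::setNames(seq_along(region_kinds()),
                                           region_kinds())

#' Write a mesh (and optional element data) as legacy ASCII VTK
#'
#' Elements are emitted as vertex cells at their centers with CELL_DATA
#' arrays `region`, `removed`, `fiber_angle` and any extra arrays supplied;
#' grid metadata is stored as field data so [read_mesh_vtk()] can rebuild the
#' structured mesh.
#'
#' @param mesh A `tissue_mesh`.
#' @param path Output file.
#' @param cell_data Named list of numeric per-element vectors (e.g. the LVA
#'   label or conductivities).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, cell_data = list()) {
  xy <- node_xy(mesh)
  keep <- which(mesh$active)
  np <- length(keep)
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("atriasim tissue_mesh nx=%d ny=%d h_mm=%g", mesh$nx, mesh$ny, mesh$h_mm)
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  w("POINTS %d float", np)
  writeLines(sprintf("%g %g 0", xy$x[keep], xy$y[keep]), con)
  w("CELLS %d %d", np, 2L * np)
  writeLines(sprintf("1 %d", seq_len(np) - 1L), con)
  w("CELL_TYPES %d", np)
  writeLines(rep("1", np), con)
  w("CELL_DATA %d", np)
  arrays <- c(list(region = as.numeric(region_codes()[mesh$region[keep]]),
                   removed = as.numeric(mesh$removed[keep]),
                   fiber_angle = mesh$fiber_angle[keep],
                   grid_index = as.numeric(keep)),
              lapply(cell_data, function(v) as.numeric(v[keep])))
  for (nm in names(arrays)) {
    w("SCALARS %s float 1", nm)
    w("LOOKUP_TABLE default")
    writeLines(sprintf("%g", arrays[[nm]]), con)
  }
  invisible(path)
}

#' Read a mesh written by [write_mesh_vtk()]
#'
#' @param path VTK file produced by [write_mesh_vtk()].
#' @return A `tissue_mesh` (landmarks are not round-tripped); extra cell-data
#'   arrays are attached as attribute `cell_data`.
#' @export
read_mesh_vtk <- function(path) {
  ln <- readLines(path)
  hdr <- ln[2]
  gv <- function(key) as.numeric(sub(paste0(".*", key, "="), "",
                                     regmatches(hdr, regexpr(paste0(key, "=[0-9.]+"), hdr))))
  nx <- as.integer(gv("nx")); ny <- as.integer(gv("ny")); h_mm <- gv("h_mm")
  np <- as.integer(strsplit(ln[grep("^POINTS", ln)], " ")[[1]][2])
  di <- grep("^CELL_DATA", ln)
  arrays <- list()
  i <- di + 1
  while (i <= length(ln) && grepl("^SCALARS", ln[i])) {
    nm <- strsplit(ln[i], " ")[[1]][2]
    vals <- as.numeric(ln[(i + 2):(i + 1 + np)])
    arrays[[nm]] <- vals
    i <- i + 2 + np
  }
  keep <- as.integer(arrays$grid_index)
  n <- nx * ny
  active <- rep(FALSE, n); active[keep] <- TRUE
  region <- rep(NA_character_, n)
  region[keep] <- names(region_codes())[as.integer(arrays$region)]
  removed <- rep(FALSE, n); removed[keep] <- arrays$removed > 0
  fiber <- rep(0, n); fiber[keep] <- arrays$fiber_angle
  mesh <- new_tissue_mesh(nx, ny, h_mm, active, region, fiber,
                          rep(NA_character_, n), list())
  mesh$removed <- removed
  extra <- arrays[setdiff(names(arrays),
                          c("region", "removed", "fiber_angle", "grid_index"))]
  attr(mesh, "cell_data") <- lapply(extra, function(v) {
    full <- rep(NA_real_, n); full[keep] <- v; full
  })
  mesh
}

#' Export an LVA map as CSV
#'
#' @param lva An `lva_map`.
#' @param mesh The mesh it belongs to.
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_lva_csv <- function(lva, mesh, path) {
  df <- as_tibble(mesh) |>
    mutate(lva_prob = lva$prob, lva = lva$label) |>
    filter(.data$active)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
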