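# Synthetic labelled tissue geometries on a masked structured grid:
# calibration cables/sheets and an idealized two-chamber atrial template
# standing in for imaging-derived anatomy. Elements are grid cells of edge
# length h; each carries a region class, optional landmark tags, a fiber
# angle and an active/removed flag.

new_tissue_mesh <- function(nx, ny, h_mm, active, region, fiber_angle,
                            chamber, landmarks) {
  structure(list(nx = as.integer(nx), ny = as.integer(ny), h_mm = h_mm,
                 active = active, removed = rep(FALSE, nx * ny),
                 region = region, fiber_angle = fiber_angle,
                 chamber = chamber, landmarks = landmarks),
            class = "tissue_mesh")
}

mesh_n <- function(mesh) mesh$nx * mesh$ny

#' Conducting elements of a mesh
#'
#' @param mesh A `tissue_mesh`.
#' @return Integer indices of elements that are active and not ablated.
#' @export
conducting <- function(mesh) which(mesh$active & !mesh$removed)

node_xy <- function(mesh) {
  idx <- seq_len(mesh_n(mesh)) - 1L
  tibble(x = (idx %% mesh$nx + 0.5) * mesh$h_mm,
         y = (idx %/% mesh$nx + 0.5) * mesh$h_mm)
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat(sprintf("<tissue_mesh> %d x %d grid, h = %g mm, %d active (%d removed)\n",
              x$nx, x$ny, x$h_mm, sum(x$active), sum(x$removed)))
  if (length(x$landmarks))
    cat("  landmarks:", paste(names(x$landmarks), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.tissue_mesh <- function(x, ...) {
  xy <- node_xy(x)
  tibble(element = seq_len(mesh_n(x)), x = xy$x, y = xy$y,
         active = x$active, removed = x$removed, region = x$region,
         chamber = x$chamber, fiber_angle = x$fiber_angle)
}

#' Landmark element indices
#'
#' @param mesh A `tissue_mesh`.
#' @param name Landmark tag, e.g. `"posterior_wall"`, `"pv1"`, `"cti"`.
#' @return Integer element indices; errors if the tag is unknown.
#' @export
landmark <- function(mesh, name) {
  if (!name %in% names(mesh$landmarks))
    abort(paste0("landmark `", name, "` absent from this mesh."))
  mesh$landmarks[[name]]
}

#' Make a one-dimensional cable mesh
#'
#' @param n_nodes Number of elements (>= 3).
#' @param h_um Edge length in micrometres (default 400).
#' @return A `tissue_mesh` of size `n_nodes` x 1 with fibers along x.
#' @export
make_cable <- function(n_nodes, h_um = 400) {
  if (n_nodes < 3) abort("`n_nodes` must be >= 3.")
  if (h_um <= 0) abort("`h_um` must be positive.")
  n <- as.integer(n_nodes)
  new_tissue_mesh(n, 1L, h_um / 1000, rep(TRUE, n),
                  rep("ra_baseline", n), rep(0, n),
                  rep(NA_character_, n), list())
}

#' Make a rectangular sheet mesh
#'
#' @param nx,ny Grid size.
#' @param h_um Edge length in micrometres.
#' @param fiber_angle_deg Uniform fiber angle in degrees (0 = +x).
#' @return A `tissue_mesh`.
#' @export
make_sheet <- function(nx, ny, h_um = 400, fiber_angle_deg = 0) {
  if (nx < 3 || ny < 1) abort("sheet must be at least 3 x 1.")
  if (h_um <= 0) abort("`h_um` must be positive.")
  n <- as.integer(nx) * as.integer(ny)
  new_tissue_mesh(nx, ny, h_um / 1000, rep(TRUE, n),
                  rep("ra_baseline", n), rep(fiber_angle_deg * pi / 180, n),
                  rep(NA_character_, n), list())
}

#' Total tissue length/area
#'
#' @param mesh A `tissue_mesh`.
#' @return For a cable, its length in mm; otherwise the active area in mm^2.
#' @export
mesh_extent <- function(mesh) {
  if (mesh$ny == 1L) (sum(mesh$active) - 1L) * mesh$h_mm
  else sum(mesh$active) * mesh$h_mm^2
}

# ---- graph utilities (4-connectivity over conducting elements) ----

neighbour_matrix <- function(mesh) {
  n <- mesh_n(mesh); nx <- mesh$nx; ny <- mesh$ny
  idx <- seq_len(n)
  i <- (idx - 1L) %% nx
  j <- (idx - 1L) %/% nx
  nb <- cbind(ifelse(i > 0L, idx - 1L, NA_integer_),
              ifelse(i < nx - 1L, idx + 1L, NA_integer_),
              ifelse(j > 0L, idx - nx, NA_integer_),
              ifelse(j < ny - 1L, idx + nx, NA_integer_))
  nb
}

#' Connected components of the conducting tissue graph
#'
#' Breadth-first flood fill over 4-connected conducting elements.
#'
#' @param mesh A `tissue_mesh`.
#' @return Integer vector (length = number of elements): component id, NA for
#'   non-conducting elements.
#' @export
mesh_components <- function(mesh) {
  n <- mesh_n(mesh)
  ok <- mesh$active & !mesh$removed
  nb <- neighbour_matrix(mesh)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (seed in which(ok)) {
    if (!is.na(comp[seed])) next
    cid <- cid + 1L
    frontier <- seed
    comp[seed] <- cid
    while (length(frontier)) {
      cand <- as.integer(nb[frontier, ])
      cand <- cand[!is.na(cand)]
      cand <- unique(cand[ok[cand] & is.na(comp[cand])])
      comp[cand] <- cid
      frontier <- cand
    }
  }
  comp
}

#' Graph reachability between element sets
#'
#' @param mesh A `tissue_mesh`.
#' @param from,to Integer element indices.
#' @return TRUE if any conducting path joins the two sets.
#' @export
is_connected <- function(mesh, from, to) {
  comp <- mesh_components(mesh)
  any(!is.na(comp[from]) & comp[from] %in% comp[to][!is.na(comp[to])])
}

# ---- idealized two-chamber atria ----

disc_idx <- function(nx, ny, x0, y0, cx, cy, r) {
  # element indices (1-based, full grid) inside a disc; coords in node units
  i <- (seq_len(nx * ny) - 1L) %% nx
  j <- (seq_len(nx * ny) - 1L) %/% nx
  which((i - (x0 + cx))^2 + (j - (y0 + cy))^2 <= r^2)
}

ring_idx <- function(nx, ny, x0, y0, cx, cy, r) {
  i <- (seq_len(nx * ny) - 1L) %% nx
  j <- (seq_len(nx * ny) - 1L) %/% nx
  d2 <- (i - (x0 + cx))^2 + (j - (y0 + cy))^2
  which(d2 > r^2 & d2 <= (r + 1.05)^2)
}

rect_idx <- function(nx, ny, x0, y0, xr, yr) {
  # xr, yr: inclusive ranges in chamber-local node units
  i <- (seq_len(nx * ny) - 1L) %% nx
  j <- (seq_len(nx * ny) - 1L) %/% nx
  which(i >= x0 + xr[1] & i <= x0 + xr[2] & j >= y0 + yr[1] & j <= y0 + yr[2])
}

segment_idx <- function(nx, ny, x0, y0, a, b) {
  # rasterized segment between chamber-local points a, b (node units)
  npt <- max(abs(b[1] - a[1]), abs(b[2] - a[2])) * 2 + 2
  tt <- seq(0, 1, length.out = ceiling(npt))
  i <- round(x0 + a[1] + tt * (b[1] - a[1]))
  j <- round(y0 + a[2] + tt * (b[2] - a[2]))
  unique(i + j * nx + 1L)
}

#' Chamber-volume to sheet-area convention
#'
#' Chamber "volume" (mL) is mapped to unfolded-surface area via a fixed
#' conversion of 40 mm^2 per mL, a documented package convention that keeps
#' the mean anatomy desk-scale while preserving the monotone relation between
#' volume and tissue extent.
#'
#' @param volume_ml Chamber volume in mL.
#' @return Area in mm^2.
#' @export
chamber_area_mm2 <- function(volume_ml) 40 * volume_ml

#' Build an idealized two-chamber atrial mesh
#'
#' Two planar-unfolded square chambers (right atrium left, left atrium right)
#' joined by two inter-atrial bridges, with the full landmark template: four
#' pulmonary-vein (PV) discs with ostium rings, posterior and anterior walls,
#' roof, appendages, mitral and tricuspid annulus holes with their isthmus
#' corridors (mitral isthmus, cavo-tricuspid isthmus), an anterior
#' mitral-line path, and a crista terminalis strip. Chamber side length
#' scales as the square root of [chamber_area_mm2()].
#'
#' @param ra_volume_ml,la_volume_ml Chamber volumes in mL (> 20).
#' @param h_um Edge length in micrometres (default 400; use coarser values
#'   for quick demonstration runs).
#' @param seed Unused placeholder for template jitter (template is fixed).
#' @return A `tissue_mesh` with landmarks and region classes assigned.
#' @export
make_idealized_atria <- function(ra_volume_ml, la_volume_ml, h_um = 400,
                                 seed = NULL) {
  if (ra_volume_ml <= 20 || la_volume_ml <= 20)
    abort("chamber volumes must exceed 20 mL.")
  h_mm <- h_um / 1000
  side <- function(v) max(3L, as.integer(round(sqrt(chamber_area_mm2(v)) / h_mm)))
  nra <- side(ra_volume_ml); nla <- side(la_volume_ml)
  if (min(nra, nla) < 24)
    abort(paste0("volume too small to host all landmarks at h = ", h_um,
                 " um; refine the mesh or enlarge the chamber."))
  gap <- max(2L, as.integer(round(nra * 0.06)))
  nx <- nra + gap + nla
  ny <- max(nra, nla)
  n <- nx * ny
  active <- rep(FALSE, n)
  region <- rep(NA_character_, n)
  chamber <- rep(NA_character_, n)
  fiber <- rep(0, n)
  lm <- list()

  ra0 <- c(0L, 0L)                       # RA chamber origin (node units)
  la0 <- c(nra + gap, 0L)                # LA chamber origin

  ra_box <- rect_idx(nx, ny, ra0[1], ra0[2], c(0, nra - 1), c(0, nra - 1))
  la_box <- rect_idx(nx, ny, la0[1], la0[2], c(0, nla - 1), c(0, nla - 1))
  active[ra_box] <- TRUE; region[ra_box] <- "ra_baseline"; chamber[ra_box] <- "RA"
  active[la_box] <- TRUE; region[la_box] <- "la_body"; chamber[la_box] <- "LA"

  ## --- left atrium template (fractions of chamber side) ---
  f <- function(v) v * (nla - 1)
  pv_c <- list(pv1 = c(0.25, 0.80), pv2 = c(0.75, 0.80),
               pv3 = c(0.25, 0.55), pv4 = c(0.75, 0.55))
  r_pv <- max(2, 0.07 * nla)
  for (k in seq_along(pv_c)) {
    cc <- pv_c[[k]]
    pv <- disc_idx(nx, ny, la0[1], la0[2], f(cc[1]), f(cc[2]), r_pv)
    pv <- pv[active[pv]]
    region[pv] <- "pv_sleeve"
    lm[[names(pv_c)[k]]] <- pv
    ring <- ring_idx(nx, ny, la0[1], la0[2], f(cc[1]), f(cc[2]), r_pv)
    ring <- ring[active[ring]]
    lm[[paste0("pv_ostium", k)]] <- ring
  }
  put <- function(lmname, idx, reg = NULL) {
    idx <- idx[active[idx]]
    if (!is.null(reg)) region[idx] <<- reg
    lm[[lmname]] <<- idx
    idx
  }
  put("posterior_wall",
      rect_idx(nx, ny, la0[1], la0[2], f(c(0.34, 0.66)), f(c(0.50, 0.86))))
  put("roof", rect_idx(nx, ny, la0[1], la0[2], f(c(0, 1)), f(c(0.93, 1))))
  put("anterior_wall",
      rect_idx(nx, ny, la0[1], la0[2], f(c(0.12, 0.88)), f(c(0.16, 0.42))))
  app <- disc_idx(nx, ny, la0[1], la0[2], f(0.07), f(0.33), max(2, 0.06 * nla))
  put("la_appendage", app, "pectinate_appendage")
  # mitral annulus hole + surrounding AV ring + isthmus corridor
  mit_c <- c(f(0.5), f(0.12)); r_mit <- max(2, 0.08 * nla)
  hole <- disc_idx(nx, ny, la0[1], la0[2], mit_c[1], mit_c[2], r_mit)
  active[hole] <- FALSE; region[hole] <- NA; chamber[hole] <- NA
  avr <- ring_idx(nx, ny, la0[1], la0[2], mit_c[1], mit_c[2], r_mit)
  avr <- avr[active[avr]]
  region[avr] <- "av_ring"
  lm[["mitral_annulus"]] <- avr
  put("mitral_isthmus",
      rect_idx(nx, ny, la0[1], la0[2], f(c(0.40, 0.60)),
               c(0, max(0, mit_c[2] - r_mit))))
  put("mitral_line",
      segment_idx(nx, ny, la0[1], la0[2], c(mit_c[1], mit_c[2]),
                  c(f(0.5), 0)))
  # anterior line: annulus top to left-inferior PV
  put("anterior_line",
      segment_idx(nx, ny, la0[1], la0[2],
                  c(mit_c[1], mit_c[2] + r_mit),
                  c(f(pv_c$pv3[1]), f(pv_c$pv3[2]))))
  put("cs_la", rect_idx(nx, ny, la0[1], la0[2], f(c(0.88, 1)), f(c(0, 0.28))),
      "cs_septal")

  ## --- right atrium template ---
  g <- function(v) v * (nra - 1)
  tri_c <- c(g(0.5), g(0.15)); r_tri <- max(2, 0.08 * nra)
  hole <- disc_idx(nx, ny, ra0[1], ra0[2], tri_c[1], tri_c[2], r_tri)
  active[hole] <- FALSE; region[hole] <- NA; chamber[hole] <- NA
  avr <- ring_idx(nx, ny, ra0[1], ra0[2], tri_c[1], tri_c[2], r_tri)
  avr <- avr[active[avr]]
  region[avr] <- "av_ring"
  lm[["tricuspid_annulus"]] <- avr
  put("cti", rect_idx(nx, ny, ra0[1], ra0[2], g(c(0.40, 0.60)),
                      c(0, max(0, tri_c[2] - r_tri))))
  put("cti_line",
      segment_idx(nx, ny, ra0[1], ra0[2], c(tri_c[1], tri_c[2]), c(g(0.5), 0)))
  put("crista", rect_idx(nx, ny, ra0[1], ra0[2], g(c(0.70, 0.76)),
                         g(c(0.30, 0.95))), "crista_terminalis")
  put("ra_appendage", rect_idx(nx, ny, ra0[1], ra0[2], g(c(0, 0.22)),
                               g(c(0.35, 0.90))), "pectinate_appendage")
  put("cs_ra", rect_idx(nx, ny, ra0[1], ra0[2], g(c(0.90, 1)), g(c(0, 0.30))),
      "cs_septal")

  ## --- inter-atrial bridges ---
  bw <- max(1L, as.integer(round(ny * 0.03)))
  yb1 <- as.integer(round(min(nra, nla) * 0.80))
  yb2 <- as.integer(round(min(nra, nla) * 0.22))
  br <- c(rect_idx(nx, ny, nra - 1L, 0L, c(0, gap + 1L), c(yb1, yb1 + bw)),
          rect_idx(nx, ny, nra - 1L, 0L, c(0, gap + 1L), c(yb2, yb2 + bw)))
  newly <- br[!active[br]]
  active[br] <- TRUE
  region[newly] <- "cs_septal"
  chamber[newly] <- ifelse(((newly - 1L) %% nx) < nra + gap %/% 2, "RA", "LA")
  lm[["interatrial"]] <- br

  mesh <- new_tissue_mesh(nx, ny, h_mm, active, region, fiber, chamber, lm)
  mesh$landmarks <- lapply(mesh$landmarks, function(ix) ix[mesh$active[ix]])
  mesh$ra_volume_ml <- ra_volume_ml
  mesh$la_volume_ml <- la_volume_ml
  mesh
}

#' Remove elements from a mesh (generic lesion application)
#'
#' Flags the given elements as removed; they no longer conduct, and wavefront
#' flux across their boundary is suppressed (no-flux).
#'
#' @param mesh A `tissue_mesh`.
#' @param elements Integer element indices, a subset of [conducting()].
#' @return The modified mesh.
#' @export
remove_elements <- function(mesh, elements) {
  if (!length(elements)) {
    warn("empty lesion: no elements removed.")
    return(mesh)
  }
  if (any(!mesh$active[elements]))
    abort("lesion includes elements outside the active tissue.")
  mesh$removed[elements] <- TRUE   # re-removal is a no-op
  mesh
}
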