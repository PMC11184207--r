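# Per-element conduction and ionic parameters: baseline conductivities with
# regional anisotropy, LVA remodelling (slowed, strongly anisotropic,
# ionically remodelled tissue) and ablation as element removal.

#' Monodomain tissue constants
#'
#' Membrane capacitance 1 uF/cm^2 and surface-to-volume ratio 1400 cm^-1,
#' fixed package constants; only conductivity is calibrated.
#'
#' @return Named vector: `chi_per_mm`, `cm_uf_mm2`, and their product
#'   `beta` (uF/mm^3) used to convert conductivity (mS/mm) to a diffusion
#'   coefficient (mm^2/ms).
#' @export
tissue_constants <- function() {
  chi <- 140          # 1/mm
  cm <- 0.01          # uF/mm^2
  c(chi_per_mm = chi, cm_uf_mm2 = cm, beta = chi * cm)
}

#' Assemble per-element tissue properties
#'
#' @param mesh A `tissue_mesh`.
#' @param sigma_l Longitudinal conductivity in mS/mm (scalar or per element).
#' @param anisotropy Bulk longitudinal:transversal conductivity ratio
#'   (default 4, a package assumption for non-LVA tissue).
#' @return A `tissue_props` object: per-element `sigma_l`, `sigma_t`, ionic
#'   remodelling multipliers (identity until [apply_lva_remodelling()]), and
#'   the conversion constants.
#' @export
tissue_properties <- function(mesh, sigma_l, anisotropy = 4) {
  n <- mesh_n(mesh)
  sl <- rep(sigma_l, length.out = n)
  if (any(sl <= 0)) abort("`sigma_l` must be positive.")
  structure(list(sigma_l = sl, sigma_t = sl / anisotropy,
                 ionic = list(ICaL = rep(1, n), INa = rep(1, n),
                              IK1 = rep(1, n)),
                 anisotropy = anisotropy, lva_applied = FALSE,
                 constants = tissue_constants()),
            class = "tissue_props")
}

#' @export
print.tissue_props <- function(x, ...) {
  cat(sprintf("<tissue_props> sigma_l %.4g-%.4g mS/mm, bulk anisotropy %g:1%s\n",
              min(x$sigma_l), max(x$sigma_l), x$anisotropy,
              if (x$lva_applied) ", LVA remodelling applied" else ""))
  invisible(x)
}

#' Apply low-voltage-area remodelling
#'
#' On LVA-labelled elements: longitudinal conductivity reduced by 30%,
#' anisotropy raised to 8:1 (transversal = remodelled longitudinal / 8), and
#' ionic remodelling of 50, 40 and 50% reductions in the L-type calcium,
#' fast sodium and inward-rectifier currents, composed multiplicatively with
#' the patient profile. Non-LVA elements are untouched. Guarded so that
#' applying twice equals applying once.
#'
#' @param props A `tissue_props`.
#' @param lva_map An `lva_map` from [threshold_lva()].
#' @return The remodelled `tissue_props`.
#' @export
apply_lva_remodelling <- function(props, lva_map) {
  if (props$lva_applied) return(props)
  sel <- lva_map$label
  props$sigma_l[sel] <- 0.7 * props$sigma_l[sel]
  props$sigma_t[sel] <- props$sigma_l[sel] / 8
  props$ionic$ICaL[sel] <- props$ionic$ICaL[sel] * 0.5
  props$ionic$INa[sel] <- props$ionic$INa[sel] * 0.6
  props$ionic$IK1[sel] <- props$ionic$IK1[sel] * 0.5
  props$lva_applied <- TRUE
  props
}

#' Apply an ablation lesion
#'
#' Lesions are modelled by removing the elements from the mesh: they stop
#' conducting and their boundaries become no-flux.
#'
#' @param mesh A `tissue_mesh`.
#' @param lesion Integer element indices.
#' @return The ablated mesh.
#' @export
apply_ablation <- function(mesh, lesion) remove_elements(mesh, lesion)

# diffusion tensor components per element (mm^2/ms)
diffusion_tensors <- function(mesh, props) {
  beta <- props$constants[["beta"]]
  Dl <- props$sigma_l / beta
  Dt <- props$sigma_t / beta
  th <- mesh$fiber_angle
  c2 <- cos(th)^2; s2 <- sin(th)^2; cs <- cos(th) * sin(th)
  ok <- mesh$active & !mesh$removed
  z <- function(v) { v[!ok] <- 0; v }
  list(Dxx = z(Dl * c2 + Dt * s2), Dyy = z(Dl * s2 + Dt * c2),
       Dxy = z((Dl - Dt) * cs))
}
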