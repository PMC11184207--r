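# ggplot2 visualisation: mesh/region maps, LVA maps, voltage frames and
# efficacy bar charts.

#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_line geom_col
#'   scale_fill_viridis_c coord_equal labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.tissue_mesh <- function(object, fill = c("region", "chamber"),
                                 ...) {
  fill <- match.arg(fill)
  df <- as_tibble(object) |> filter(.data$active)
  df$value <- df[[fill]]
  df$value[df$removed] <- "ablated"
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_tile() + coord_equal() +
    labs(x = "x (mm)", y = "y (mm)", fill = fill,
         title = "Tissue mesh") +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.lva_map <- function(object, mesh = NULL, ...) {
  if (is.null(mesh)) abort("supply the mesh: autoplot(lva, mesh = mesh).")
  df <- as_tibble(mesh) |>
    mutate(prob = object$prob, lva = object$label) |>
    filter(.data$active)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$prob)) +
    geom_tile() +
    geom_tile(data = df |> filter(.data$lva), fill = NA,
              colour = "red", linewidth = 0.1) +
    scale_fill_viridis_c(limits = c(0, 1)) + coord_equal() +
    labs(x = "x (mm)", y = "y (mm)", fill = "P(LVA)",
         title = "Probabilistic LVA map (labelled elements outlined)") +
    theme_minimal()
}

#' Voltage snapshot of a trajectory frame
#'
#' @param traj A `tissue_trajectory` with snapshots.
#' @param time_ms Frame time (nearest snapshot used; default last).
#' @return A ggplot.
#' @export
plot_vm_frame <- function(traj, time_ms = NULL) {
  if (is.null(traj$vm)) abort("trajectory has no snapshots.")
  if (is.null(time_ms)) time_ms <- max(traj$times)
  f <- which.min(abs(traj$times - time_ms))
  df <- as_tibble(traj$mesh) |>
    mutate(vm = traj$vm[f, ]) |>
    filter(.data$active & !.data$removed)
  ggplot(df, aes(x = .data$x, y = .data$y, fill = .data$vm)) +
    geom_tile() + scale_fill_viridis_c(option = "inferno") + coord_equal() +
    labs(x = "x (mm)", y = "y (mm)", fill = "Vm (mV)",
         title = sprintf("Membrane potential at t = %.0f ms",
                         traj$times[f])) +
    theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.tissue_trajectory <- function(object, ...) {
  if (!is.null(object$probe_vm)) {
    as_tibble(object) |>
      ggplot(aes(x = .data$time_ms, y = .data$vm_mv,
                 colour = factor(.data$element))) +
      geom_line() +
      labs(x = "time (ms)", y = "Vm (mV)", colour = "element") +
      theme_minimal()
  } else plot_vm_frame(object)
}

#' @exportS3Method ggplot2::autoplot
autoplot.efficacy_table <- function(object, ...) {
  ggplot(object, aes(x = .data$therapy, y = .data$pct_free,
                     fill = .data$stratum)) +
    geom_col(position = "dodge") +
    labs(x = NULL, y = "freedom from arrhythmia (%)",
         title = "Treatment efficacy by LVA stratum") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
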