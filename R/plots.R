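# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_rect geom_tile
#'   labs scale_fill_manual theme_minimal
NULL

#' Plot a rarefaction curve
#'
#' Mean core and pan genome sizes against the number of strains compared,
#' with the per-subset values as translucent points.
#'
#' @param object A `panoen_rarefaction`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.panoen_rarefaction <- function(object, ...) {
  curve <- tidy(object) |>
    tidyr::pivot_longer(c("core", "pan"), names_to = "genome",
                        values_to = "size")
  summ <- object$summary |>
    tidyr::pivot_longer(c("mean_core", "mean_pan"), names_to = "genome",
                        values_to = "size") |>
    mutate(genome = sub("mean_", "", .data$genome))
  ggplot(summ, aes(x = .data$x, y = .data$size, colour = .data$genome)) +
    ggplot2::geom_jitter(data = curve, width = 0.12, height = 0,
                         alpha = 0.15, size = 0.5) +
    geom_line(linewidth = 0.9) +
    geom_point(size = 1.8) +
    labs(x = "strains compared", y = "loci",
         colour = NULL, title = "Core and pan genome rarefaction") +
    theme_minimal()
}

#' Plot the presence-absence matrix
#'
#' Tri-state tile view of loci by strains (absent / pseudogene / intact).
#'
#' @param pam A `panoen_pam`.
#' @param max_loci Downsample to at most this many loci rows (default
#'   2000) to keep the plot renderable.
#' @return A ggplot object.
#' @export
plot_presence_absence <- function(pam, max_loci = 2000L) {
  df <- tidy(pam)
  ids <- unique(df$pan_id)
  if (length(ids) > max_loci) {
    keep <- ids[seq(1, length(ids), length.out = max_loci)]
    df <- df |> filter(.data$pan_id %in% keep)
  }
  ggplot(df, aes(x = .data$strain, y = .data$pan_id, fill = .data$status)) +
    geom_tile() +
    scale_fill_manual(values = c(absent = "grey92", pseudogene = "grey55",
                                 intact = "#2166ac")) +
    labs(x = NULL, y = "pan locus", fill = NULL,
         title = "Pan-genome presence/absence") +
    theme_minimal()
}

#' Plot an HGT identity scan
#'
#' Per-locus best donor identity (points), the sliding-window mean
#' (line), and flagged candidate HGT regions (shaded boxes), mirroring the
#' blue-line / red-box presentation of sliding-window identity scans.
#'
#' @param object A `panoen_hgt_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.panoen_hgt_scan <- function(object, ...) {
  pl <- object$per_locus
  w <- object$params$window
  win <- object$windows |>
    mutate(mid = .data$start_order + (w - 1) / 2)
  p <- ggplot(pl, aes(x = .data$order, y = .data$identity)) +
    geom_point(size = 0.4, alpha = 0.5) +
    geom_line(data = win, aes(x = .data$mid, y = .data$mean_identity),
              colour = "#2166ac", linewidth = 0.7)
  if (nrow(object$regions) > 0) {
    p <- p + geom_rect(
      data = object$regions,
      aes(xmin = .data$start_order - 0.5, xmax = .data$end_order + 0.5),
      ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "#b2182b",
      inherit.aes = FALSE)
  }
  p + ggplot2::facet_wrap(~replicon, scales = "free_x") +
    labs(x = "locus (genome order)", y = "best donor identity (%)",
         title = paste("HGT identity scan:", object$strain)) +
    theme_minimal()
}
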