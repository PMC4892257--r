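#' Plot a tissue snapshot
#'
#' Draws the hexagonal lattice with cells coloured by EMT phenotype
#' (epithelial green, hybrid E/M yellow, mesenchymal red) using base
#' graphics.
#'
#' @param snapshot Labelled snapshot `data.frame`.
#' @param lattice Lattice; defaults to the snapshot's attribute.
#' @param main Plot title.
#' @return Invisibly, the data.frame of plotted cell centres.
#' @export
plot_tissue <- function(snapshot, lattice = attr(snapshot, "lattice"),
                        main = sprintf("t = %g h", snapshot$time_h[1])) {
  cols <- c(E = "#1b9e77", `E/M` = "#e6c229", M = "#d7301f")
  x <- snapshot$col + 0.5 * (snapshot$row %% 2)
  y <- -snapshot$row * sqrt(3) / 2
  graphics::plot(x, y, pch = 21, cex = 1.2,
                 bg = cols[snapshot$emt_label], col = "grey30",
                 axes = FALSE, xlab = "", ylab = "", main = main, asp = 1)
  graphics::legend("topright", legend = names(cols), pt.bg = cols,
                   pch = 21, bty = "n", cex = 0.8)
  invisible(data.frame(x = x, y = y, label = snapshot$emt_label))
}

#' Plot a bifurcation sweep
#'
#' miR-200 stable-branch levels against the swept external input, points
#' coloured by EMT phenotype.
#'
#' @param sweep Result of [sweep_parameter()].
#' @param yvar Species column to plot (default `"miR200"`).
#' @param log Use a log y axis (default TRUE).
#' @return Invisibly, the sweep.
#' @export
plot_bifurcation <- function(sweep, yvar = "miR200", log = TRUE) {
  cols <- c(E = "#1b9e77", `E/M` = "#e6c229", M = "#d7301f")
  graphics::plot(sweep$value, sweep[[yvar]],
                 log = if (log) "y" else "",
                 pch = 19, cex = 0.7, col = cols[sweep$emt_label],
                 xlab = paste0(sweep$param[1], " (molecules)"),
                 ylab = paste(yvar, "(molecules)"))
  graphics::legend("bottomleft", legend = names(cols), col = cols,
                   pch = 19, bty = "n", cex = 0.8)
  invisible(sweep)
}

#' Plot a (D_ext, J_ext) phase diagram
#'
#' Tiles the plane with colours keyed by the coexisting-label set.
#'
#' @param pd Result of [phase_diagram()].
#' @return Invisibly, the mapping from label set to colour.
#' @export
plot_phase_diagram <- function(pd) {
  sets <- sort(unique(pd$labels))
  pal <- grDevices::hcl.colors(max(length(sets), 3), "Spectral")
  names(pal) <- c(sets, rep("", max(0, 3 - length(sets))))[seq_along(pal)]
  graphics::plot(pd$D_ext, pd$J_ext, pch = 15, cex = 1.4,
                 col = pal[pd$labels],
                 xlab = "D_ext (molecules)", ylab = "J_ext (molecules)")
  graphics::legend("topright", legend = sets, col = pal[sets], pch = 15,
                   bty = "n", cex = 0.7)
  invisible(pal[sets])
}
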