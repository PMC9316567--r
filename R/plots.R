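## Figure layer: Cartesian scatter of normalized fluorescence and
## phenotype-versus-EU plots. Base graphics; files written as PNG (raster)
## and PDF (vector).

GROUP_COLORS <- c(indist_red = "#c0392b", red_some_green = "#e67e22",
                  uncertain = "#7f8c8d", green_some_red = "#27ae60",
                  indist_green = "#145a32", unclassified = "#bdc3c7")

#' Cartesian plot of normalized fluorescence
#'
#' Scatter of co-cultured cells (green NFU on x, red NFU on y) coloured by
#' classification group, control cells as open triangles, and the
#' complete-mixing diagonal `green = red` as a dashed reference line. In
#' log mode, cells with zero NFU in either channel cannot be drawn; they
#' are dropped and their number annotated on the plot.
#'
#' @param cells classified co-cultured data.frame (`green_norm`,
#'   `red_norm`, `group`).
#' @param control_green,control_red normalized control data.frames.
#' @param scale `"linear"` or `"log"`.
#' @param main plot title.
#' @return invisibly, the number of cells dropped in log mode.
#' @export
plot_cartesian <- function(cells, control_green, control_red,
                           scale = c("linear", "log"),
                           main = "Cartesian plot of fluorescence transfer") {
  scale <- match.arg(scale)
  g <- c(cells$green_norm, control_green$green_norm, control_red$green_norm)
  r <- c(cells$red_norm, control_green$red_norm, control_red$red_norm)
  dropped <- 0L
  logp <- scale == "log"
  if (logp) {
    keep <- cells$green_norm > 0 & cells$red_norm > 0
    dropped <- sum(!keep)
    cells <- cells[keep, , drop = FALSE]
    control_green <- control_green[control_green$green_norm > 0 &
                                   control_green$red_norm > 0, , drop = FALSE]
    control_red <- control_red[control_red$green_norm > 0 &
                               control_red$red_norm > 0, , drop = FALSE]
    lims <- range(c(cells$green_norm, cells$red_norm,
                    control_green$green_norm, control_green$red_norm,
                    control_red$green_norm, control_red$red_norm))
  } else {
    lims <- c(0, max(g, r, 1))
  }
  graphics::plot(cells$green_norm, cells$red_norm,
                 col = GROUP_COLORS[as.character(cells$group)], pch = 16,
                 cex = 0.6, xlim = lims, ylim = lims,
                 log = if (logp) "xy" else "",
                 xlab = "Green fluorescence (NFU)",
                 ylab = "Red fluorescence (NFU)", main = main)
  graphics::points(control_green$green_norm, control_green$red_norm,
                   pch = 2, col = "darkgreen", cex = 0.8)
  graphics::points(control_red$green_norm, control_red$red_norm,
                   pch = 2, col = "red3", cex = 0.8)
  graphics::abline(0, 1, lty = 2)
  graphics::legend("topright", bty = "n", cex = 0.7,
                   legend = c(names(GROUP_COLORS), "controls"),
                   col = c(GROUP_COLORS, "black"),
                   pch = c(rep(16, length(GROUP_COLORS)), 2))
  if (logp && dropped > 0)
    graphics::mtext(sprintf("%d cell(s) with zero NFU not shown", dropped),
                    side = 3, line = 0, cex = 0.7)
  invisible(dropped)
}

# medians of `values` over width-20 EU bins (singleton-pole cells excluded)
eu_bin_medians <- function(eu, values, group) {
  interior <- !as.character(group) %in%
    c("indist_green", "indist_red", "unclassified") & !is.na(eu)
  breaks <- c(-50, -30, -10, 10, 30, 50)
  mids <- c(-40, -20, 0, 20, 40)
  f <- cut(eu[interior], breaks, include.lowest = FALSE)
  med <- tapply(values[interior], f, stats::median, na.rm = TRUE)
  data.frame(eu_mid = mids, median = as.numeric(med),
             n = as.integer(table(f)))
}

#' Phenotype against Exchange Units
#'
#' Scatter of a phenotype (circularity, cell-profile area or normalized
#' cnf) against EU for all classified co-cultured cells, with control
#' population medians drawn as red and green triangles at the two poles
#' and medians of width-20 EU bins overlaid; cells indistinguishable from
#' controls are excluded from the binned medians.
#'
#' @param cells classified co-cultured data.frame.
#' @param control_green,control_red normalized control data.frames.
#' @param phenotype `"circularity"`, `"area"` or `"cnf_norm"`.
#' @param main plot title.
#' @return invisibly, the bin-median data.frame.
#' @export
plot_phenotype_vs_eu <- function(cells, control_green, control_red,
                                 phenotype = c("circularity", "area",
                                               "cnf_norm"),
                                 main = NULL) {
  phenotype <- match.arg(phenotype)
  if (is.null(cells[[phenotype]])) stop("unknown phenotype: ", phenotype)
  if (is.null(main)) main <- paste(phenotype, "vs Exchange Units")
  keep <- !is.na(cells$eu) & !is.na(cells[[phenotype]])
  graphics::plot(cells$eu[keep], cells[[phenotype]][keep], pch = 16,
                 cex = 0.5, col = "grey40", xlim = c(-55, 55),
                 xlab = "Exchange Units", ylab = phenotype, main = main)
  bins <- eu_bin_medians(cells$eu, cells[[phenotype]], cells$group)
  ok <- !is.na(bins$median)
  graphics::lines(bins$eu_mid[ok], bins$median[ok], col = "blue3", lwd = 2)
  graphics::points(bins$eu_mid[ok], bins$median[ok], col = "blue3", pch = 15)
  med_ctrl <- function(x) stats::median(x, na.rm = TRUE)
  if (!is.null(control_red[[phenotype]]))
    graphics::points(-52, med_ctrl(control_red[[phenotype]]), pch = 17,
                     col = "red3", cex = 1.4)
  if (!is.null(control_green[[phenotype]]))
    graphics::points(52, med_ctrl(control_green[[phenotype]]), pch = 17,
                     col = "darkgreen", cex = 1.4)
  invisible(bins)
}

# write a plot expression to <stem>.png and <stem>.pdf
write_figure <- function(stem, expr) {
  grDevices::png(paste0(stem, ".png"), width = 900, height = 900, res = 120)
  tryCatch(eval.parent(substitute(expr)), finally = grDevices::dev.off())
  grDevices::pdf(paste0(stem, ".pdf"), width = 7, height = 7)
  tryCatch(eval.parent(substitute(expr)), finally = grDevices::dev.off())
  invisible(paste0(stem, c(".png", ".pdf")))
}
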