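## The model-fitting surface: one call runs the full quantitation pipeline
## for one experiment and returns a classed object with the usual methods.

#' Cartesian-plot analysis of fluorescence transfer in a co-culture
#'
#' Runs the full quantitation pipeline for one experiment: estimate
#' background rates from the control populations, subtract background in
#' proportion to cell-profile area, normalize both channels so that each
#' control population's median own-channel fluorescence is 100 NFU, derive
#' classification bounds from the control ranges, classify every
#' co-cultured cell into one of the five Cartesian-plot populations, score
#' transfer in Exchange Units (EU, -50 red pole to +50 green pole), bin
#' cells into the seven EU domains, and compute cell circularity. When the
#' nuclear channels are present, corrected nuclear fluorescence
#' (`cnf = f5mc / fpi`) and its normalization against the red-control
#' (fibroblast) median are attached as well.
#'
#' At most `max_controls` cells per control population and `max_cocultured`
#' co-cultured cells enter the analysis (seeded uniform subsampling when a
#' table exceeds its cap); 100 control cells bound the fluorescence ranges
#' without undue influence of outliers.
#'
#' @param cocultured,control_green,control_red data.frames of cell records
#'   (see [read_cell_table()]), all from one experiment.
#' @param trim fraction of extreme control cells excluded per tail when
#'   deriving classification bounds (default 0 = plain min/max).
#' @param flip if `TRUE`, the dye orientation is inverted after
#'   classification (see [flip_orientation()]).
#' @param max_controls,max_cocultured sampling caps.
#' @param seed integer seed for the subsampling.
#' @param background either `"cross"` (default; estimate from the opposite
#'   control population, see [estimate_background()]) or a list with
#'   explicit `green` and `red` rates per unit area.
#' @param cnf_outlier_k if non-`NULL`, control cells with
#'   `|cnf - median| > k * MAD` are excluded before taking the control cnf
#'   median (default `NULL`: no exclusion).
#' @return object of class `"cartesian_transfer"` with components `cells`
#'   (classified co-cultured table), `control_green`, `control_red`
#'   (normalized controls), `background`, `medians`, `bounds`, `summary`
#'   (per-group and per-EU-domain counts, percentages and medians), `n`
#'   (input/analysed counts) and `call`.
#' @examples
#' cfg <- synthetic_config(n_cocultured = 200, seed = 7)
#' ctl <- generate_controls(cfg)
#' cc <- generate_coculture(cfg)
#' fit <- cartesian_transfer(cc$cells, ctl$control_green, ctl$control_red)
#' fit
#' head(coef(fit))
#' @export
cartesian_transfer <- function(cocultured, control_green, control_red,
                               trim = 0, flip = FALSE,
                               max_controls = 100, max_cocultured = 1000,
                               seed = 1, background = "cross",
                               cnf_outlier_k = NULL) {
  cocultured <- as.data.frame(validate_cells(cocultured))
  control_green <- as.data.frame(validate_cells(control_green))
  control_red <- as.data.frame(validate_cells(control_red))
  n_in <- c(cocultured = nrow(cocultured), control_green = nrow(control_green),
            control_red = nrow(control_red))
  if (length(unique(c(cocultured$experiment_id, control_green$experiment_id,
                      control_red$experiment_id))) > 1)
    warning("tables mix experiment_id values; analyse one experiment at a time")

  control_green <- cap_sample(control_green, max_controls, seed)
  control_red <- cap_sample(control_red, max_controls, seed + 1)
  cocultured <- cap_sample(cocultured, max_cocultured, seed + 2)

  bg <- if (identical(background, "cross")) {
    estimate_background(control_green, control_red)
  } else {
    structure(list(green_bg_rate = background$green,
                   red_bg_rate = background$red),
              class = "background_estimate")
  }

  norm <- normalize_cells(cocultured, control_green, control_red, bg)
  bounds <- derive_bounds(norm$control_green, norm$control_red, trim)

  cells <- norm$cells
  cells$group <- classify_cells(cells$green_norm, cells$red_norm, bounds)
  cells$eu <- exchange_units(cells$green_norm, cells$red_norm, cells$group)
  cells$eu_domain <- bin_eu(cells$eu, cells$group)
  if (flip) cells <- flip_orientation(cells)

  has_nuclear <- !all(is.na(cells$f5mc)) && !all(is.na(control_red$f5mc))
  if (has_nuclear) {
    cells$cnf <- cnf(cells$f5mc, cells$fpi)
    norm$control_red$cnf <- cnf(norm$control_red$f5mc, norm$control_red$fpi)
    norm$control_green$cnf <- cnf(norm$control_green$f5mc, norm$control_green$fpi)
    mcnf <- normalize_cnf(cells$cnf, norm$control_red$cnf,
                          outlier_k = cnf_outlier_k)
    cells$cnf_norm <- mcnf$cnf_norm
    norm$control_red$cnf_norm <- 100 * norm$control_red$cnf / mcnf$control_median
    norm$control_green$cnf_norm <- 100 * norm$control_green$cnf / mcnf$control_median
  } else {
    cells$cnf <- cells$cnf_norm <- NA_real_
  }

  unclassified <- sum(cells$group == "unclassified")
  if (unclassified > 0)
    message(unclassified, " co-cultured cell(s) fall below both control ",
            "ranges and are reported as 'unclassified'")

  fit <- structure(list(
    cells = cells,
    control_green = norm$control_green,
    control_red = norm$control_red,
    background = bg,
    medians = norm$medians,
    bounds = bounds,
    n = list(input = n_in,
             analysed = c(cocultured = nrow(cells),
                          control_green = nrow(control_green),
                          control_red = nrow(control_red)),
             unclassified = unclassified),
    options = list(trim = trim, flip = flip, seed = seed,
                   max_controls = max_controls,
                   max_cocultured = max_cocultured,
                   cnf_outlier_k = cnf_outlier_k),
    call = match.call()),
    class = "cartesian_transfer")
  fit$summary <- summarize_coculture(fit)
  fit
}

# per-group / per-domain counts, percentages (denominator: all analysed
# co-cultured cells) and medians of circularity, area and cnf_norm
summarize_coculture <- function(fit) {
  cells <- fit$cells
  total <- nrow(cells)
  med_by <- function(f, col) {
    v <- tapply(cells[[col]], f, stats::median, na.rm = TRUE)
    as.numeric(v)[match(levels(f), names(v))]
  }
  one_table <- function(f) {
    counts <- as.integer(table(f))
    data.frame(level = levels(f), n = counts,
               pct = if (total > 0) round_half_up(100 * counts / total, 1) else 0,
               median_circularity = med_by(f, "circularity"),
               median_area = med_by(f, "area"),
               median_cnf_norm = med_by(f, "cnf_norm"),
               row.names = NULL)
  }
  ctrl_medians <- data.frame(
    population = c("control_green", "control_red"),
    median_circularity = c(stats::median(fit$control_green$circularity),
                           stats::median(fit$control_red$circularity)),
    median_area = c(stats::median(fit$control_green$area),
                    stats::median(fit$control_red$area)),
    median_cnf_norm = c(
      if (is.null(fit$control_green$cnf_norm)) NA_real_ else
        stats::median(fit$control_green$cnf_norm, na.rm = TRUE),
      if (is.null(fit$control_red$cnf_norm)) NA_real_ else
        stats::median(fit$control_red$cnf_norm, na.rm = TRUE)))
  list(groups = one_table(cells$group),
       eu_domains = one_table(cells$eu_domain),
       controls = ctrl_medians,
       total_cocultured = total)
}

#' @export
print.cartesian_transfer <- function(x, ...) {
  cat("Cartesian-plot fluorescence transfer analysis\n")
  cat(sprintf("  co-cultured cells analysed: %d (of %d input)\n",
              x$n$analysed[["cocultured"]], x$n$input[["cocultured"]]))
  cat(sprintf("  controls: %d green, %d red\n",
              x$n$analysed[["control_green"]], x$n$analysed[["control_red"]]))
  cat(sprintf("  background rates (per unit area): green %.4g, red %.4g\n",
              x$background$green_bg_rate, x$background$red_bg_rate))
  cat(sprintf("  normalization medians (corrected): green %.4g, red %.4g\n",
              x$medians[["green"]], x$medians[["red"]]))
  b <- x$bounds
  cat(sprintf("  bounds (NFU): green_lo %.3g, red_bleed_hi %.3g, red_lo %.3g, green_bleed_hi %.3g\n",
              b$green_lo, b$red_bleed_hi, b$red_lo, b$green_bleed_hi))
  g <- x$summary$groups
  cat("  groups: ",
      paste(sprintf("%s %d (%.1f%%)", g$level, g$n, g$pct), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.cartesian_transfer <- function(object, ...) {
  structure(list(summary = object$summary, n = object$n,
                 background = object$background, medians = object$medians,
                 bounds = object$bounds),
            class = "summary.cartesian_transfer")
}

#' @export
print.summary.cartesian_transfer <- function(x, ...) {
  cat("Co-cultured cells by Cartesian-plot group",
      sprintf("(n = %d):\n", x$summary$total_cocultured))
  print(x$summary$groups, digits = 4)
  cat("\nCo-cultured cells by Exchange-Unit domain:\n")
  print(x$summary$eu_domains, digits = 4)
  cat("\nControl population medians:\n")
  print(x$summary$controls, digits = 4)
  invisible(x)
}

#' Derived constants of a transfer analysis
#'
#' The quantities that determine every downstream label: per-channel
#' background rates, control normalization medians and the four
#' classification bounds.
#'
#' @param object a `"cartesian_transfer"` fit.
#' @param ... unused.
#' @return named numeric vector.
#' @export
coef.cartesian_transfer <- function(object, ...) {
  c(green_bg_rate = object$background$green_bg_rate,
    red_bg_rate = object$background$red_bg_rate,
    green_median = unname(object$medians[["green"]]),
    red_median = unname(object$medians[["red"]]),
    green_lo = object$bounds$green_lo,
    red_bleed_hi = object$bounds$red_bleed_hi,
    red_lo = object$bounds$red_lo,
    green_bleed_hi = object$bounds$green_bleed_hi)
}

#' Classify new cells with a fitted analysis
#'
#' Applies the fitted background rates, normalization medians and
#' classification bounds to new raw cell records, without re-deriving any
#' constant.
#'
#' @param object a `"cartesian_transfer"` fit.
#' @param newdata data.frame of cell records ([read_cell_table()] schema).
#' @param ... unused.
#' @return `newdata` with `green_norm`, `red_norm`, `circularity`, `group`,
#'   `eu`, `eu_domain` columns added.
#' @export
predict.cartesian_transfer <- function(object, newdata, ...) {
  newdata <- as.data.frame(validate_cells(newdata))
  newdata <- subtract_background(newdata, object$background)
  newdata$green_norm <- 100 * newdata$green_corr / object$medians[["green"]]
  newdata$red_norm <- 100 * newdata$red_corr / object$medians[["red"]]
  newdata$circularity <- circularity(newdata$area, newdata$perimeter)
  newdata$group <- classify_cells(newdata$green_norm, newdata$red_norm,
                                  object$bounds)
  newdata$eu <- exchange_units(newdata$green_norm, newdata$red_norm,
                               newdata$group)
  newdata$eu_domain <- bin_eu(newdata$eu, newdata$group)
  if (object$options$flip) newdata <- flip_orientation(newdata)
  newdata
}

#' Plot method for a transfer analysis
#'
#' `type = "cartesian"` draws the Cartesian scatter (see
#' [plot_cartesian()]); `type = "phenotype"` draws a phenotype against EU
#' (see [plot_phenotype_vs_eu()]).
#'
#' @param x a `"cartesian_transfer"` fit.
#' @param type `"cartesian"` or `"phenotype"`.
#' @param scale,phenotype passed to the underlying plotting function.
#' @param ... further graphical arguments.
#' @export
plot.cartesian_transfer <- function(x, type = c("cartesian", "phenotype"),
                                    scale = "linear",
                                    phenotype = "circularity", ...) {
  type <- match.arg(type)
  if (type == "cartesian")
    plot_cartesian(x$cells, x$control_green, x$control_red, scale = scale, ...)
  else
    plot_phenotype_vs_eu(x$cells, x$control_green, x$control_red,
                         phenotype = phenotype, ...)
  invisible(x)
}
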