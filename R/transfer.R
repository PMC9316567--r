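## Core quantitation: background subtraction, normalization to control
## medians (100 NFU), control-derived classification bounds, five-population
## classification, Exchange Units and EU-domain binning.

#' Estimate per-channel background fluorescence rates
#'
#' Background fluorescence per unit area for each channel, estimated from
#' the control population *not* labelled in that channel (summated over
#' cells): the red background rate is the total red fluorescence of the
#' green-labelled controls divided by their total cell-profile area, and
#' symmetrically for green. Estimating a channel's background from cells
#' labelled in that channel would subtract signal, so the cross-channel
#' orientation is the default throughout the package; explicit rates can be
#' supplied instead via the `background_mode = "rates"` configuration.
#'
#' @param control_green,control_red data.frames of control cell records.
#' @return list with `green_bg_rate` and `red_bg_rate` (fluorescence per
#'   unit area), class `"background_estimate"`.
#' @export
estimate_background <- function(control_green, control_red) {
  if (nrow(control_green) == 0 || nrow(control_red) == 0)
    stop("both control populations must be non-empty")
  ag <- sum(control_green$area)
  ar <- sum(control_red$area)
  if (ag <= 0 || ar <= 0) stop("zero total control area")
  structure(list(red_bg_rate = sum(control_green$red_raw) / ag,
                 green_bg_rate = sum(control_red$green_raw) / ar),
            class = "background_estimate")
}

#' Subtract area-proportional background from raw fluorescence
#'
#' `corrected = max(0, raw - area * rate)` per channel; negative corrected
#' values are clamped to zero (log-scale plots and the angular transfer
#' measure both require non-negative fluorescence).
#'
#' @param cells data.frame of cell records.
#' @param bg a `"background_estimate"` (or any list with `green_bg_rate`,
#'   `red_bg_rate`).
#' @return `cells` with `green_corr` and `red_corr` columns added.
#' @export
subtract_background <- function(cells, bg) {
  cells$green_corr <- pmax(0, cells$green_raw - cells$area * bg$green_bg_rate)
  cells$red_corr <- pmax(0, cells$red_raw - cells$area * bg$red_bg_rate)
  cells
}

#' Normalize fluorescence against control populations
#'
#' Scales each channel so that the median background-corrected own-channel
#' fluorescence of the corresponding control population equals 100
#' normalized fluorescence units (NFU): `green_norm = 100 * green_corr /
#' median(green_corr of green controls)`, and symmetrically for red. The
#' same scale is applied to controls and co-cultured cells alike, and
#' circularity is computed for every cell.
#'
#' @param cells,control_green,control_red data.frames of cell records (all
#'   from one experiment).
#' @param bg background estimate from [estimate_background()].
#' @return list with components `cells`, `control_green`, `control_red`
#'   (each with `green_norm`, `red_norm`, `circularity` columns) and
#'   `medians` (the two control medians on the corrected scale).
#' @export
normalize_cells <- function(cells, control_green, control_red, bg) {
  cg <- subtract_background(control_green, bg)
  cr <- subtract_background(control_red, bg)
  med_g <- stats::median(cg$green_corr)
  med_r <- stats::median(cr$red_corr)
  if (!is.finite(med_g) || med_g <= 0)
    stop("green control median is not positive after background subtraction")
  if (!is.finite(med_r) || med_r <= 0)
    stop("red control median is not positive after background subtraction")
  to_nfu <- function(x) {
    x$green_norm <- 100 * x$green_corr / med_g
    x$red_norm <- 100 * x$red_corr / med_r
    x$circularity <- circularity(x$area, x$perimeter)
    x
  }
  list(cells = to_nfu(subtract_background(cells, bg)),
       control_green = to_nfu(cg),
       control_red = to_nfu(cr),
       medians = c(green = med_g, red = med_r))
}

#' Derive classification bounds from normalized control populations
#'
#' The range of each control population defines the classification regions:
#' `green_lo` is the (trimmed) minimum green NFU of the green controls and
#' `red_bleed_hi` their (trimmed) maximum red NFU (channel bleed-through
#' plus residual background); `red_lo` and `green_bleed_hi` symmetrically
#' from the red controls. `trim` is the fraction of cells dropped per tail
#' before taking the extremum (default 0, i.e. plain min/max over the
#' sampled control cells). Own-channel ranges are unbounded above: a
#' co-cultured cell brighter than any control in its own channel is still
#' within its population, since transfer only adds opposite-channel signal.
#'
#' Overlapping control populations (`green_bleed_hi >= green_lo` or
#' `red_bleed_hi >= red_lo`) make classification meaningless and abort with
#' a diagnostic.
#'
#' @param control_green,control_red normalized control data.frames (from
#'   [normalize_cells()]).
#' @param trim fraction of extreme cells excluded per tail.
#' @return list of the four bounds plus `trim`, class `"control_bounds"`.
#' @export
derive_bounds <- function(control_green, control_red, trim = 0) {
  stopifnot(trim >= 0, trim < 0.5)
  trimmed <- function(x, which) {
    x <- sort(x)
    k <- floor(trim * length(x) + 1e-9)
    if (2 * k >= length(x)) stop("trim removes all control cells")
    if (which == "min") x[k + 1] else x[length(x) - k]
  }
  b <- structure(list(
    green_lo = trimmed(control_green$green_norm, "min"),
    red_bleed_hi = trimmed(control_green$red_norm, "max"),
    red_lo = trimmed(control_red$red_norm, "min"),
    green_bleed_hi = trimmed(control_red$green_norm, "max"),
    trim = trim), class = "control_bounds")
  if (b$green_bleed_hi >= b$green_lo || b$red_bleed_hi >= b$red_lo)
    stop("control populations overlap: bleed-through range reaches the ",
         "own-channel range (green_lo=", signif(b$green_lo, 4),
         ", green_bleed_hi=", signif(b$green_bleed_hi, 4),
         ", red_lo=", signif(b$red_lo, 4),
         ", red_bleed_hi=", signif(b$red_bleed_hi, 4),
         "); classification aborted")
  b
}

#' Classify cells into the five Cartesian-plot populations
#'
#' With `g`, `r` the normalized green and red fluorescence and bounds from
#' [derive_bounds()]:
#' * `uncertain` — `g >= green_lo` and `r >= red_lo`: fluorescence overlaps
#'   both control populations, origin cannot be assigned;
#' * `indist_green` — `g >= green_lo` and `r <= red_bleed_hi`:
#'   indistinguishable from green controls;
#' * `green_some_red` — `g >= green_lo` and `red_bleed_hi < r < red_lo`:
#'   a green-population cell that acquired some red label;
#' * `indist_red` / `red_some_green` — the mirror images;
#' * `unclassified` — below both own-channel lower bounds.
#'
#' Region boundaries are closed toward the "indistinguishable" labels
#' (conservative toward no transfer), and the uncertain region takes
#' precedence where both own-channel bounds are met.
#'
#' @param g,r numeric vectors of normalized green and red fluorescence.
#' @param bounds a `"control_bounds"` object.
#' @return factor with levels [CARTESIAN_GROUPS].
#' @export
classify_cells <- function(g, r, bounds) {
  in_green <- g >= bounds$green_lo
  in_red <- r >= bounds$red_lo
  out <- rep("unclassified", length(g))
  out[in_green & in_red] <- "uncertain"
  out[in_green & !in_red & r <= bounds$red_bleed_hi] <- "indist_green"
  out[in_green & !in_red & r > bounds$red_bleed_hi] <- "green_some_red"
  out[in_red & !in_green & g <= bounds$green_bleed_hi] <- "indist_red"
  out[in_red & !in_green & g > bounds$green_bleed_hi] <- "red_some_green"
  factor(out, levels = CARTESIAN_GROUPS)
}

#' Exchange Units: the angular measure of fluorescence transfer
#'
#' A line is subtended from each plotted cell to the origin of the
#' Cartesian plane (green NFU on the x axis, red NFU on the y axis) and its
#' angular divergence from the complete-mixing diagonal `green = red` is
#' mapped linearly to Exchange Units: the green axis scores 50, the red
#' axis -50 and the diagonal 0. With `theta = atan2(r, g)` in degrees,
#' `EU = 50 * (45 - theta) / 45`.
#'
#' Cells classified as indistinguishable from a control population are
#' pinned to the corresponding pole (+50 green, -50 red) regardless of the
#' computed angle. Cells at the origin with an unpinned group have no
#' defined angle and get `NA` (excluded from EU summaries, with a warning).
#'
#' @param g,r numeric vectors of normalized green and red fluorescence.
#' @param group optional factor/character of Cartesian groups; pins the
#'   poles and blanks `unclassified` cells.
#' @return numeric vector of EU in `[-50, 50]`.
#' @export
exchange_units <- function(g, r, group = NULL) {
  theta <- atan2(r, g) * 180 / pi
  eu <- 50 * (45 - theta) / 45
  # the anchors are definitional: axes map to +/-50, the diagonal to 0
  eu[r == 0 & g > 0] <- 50
  eu[g == 0 & r > 0] <- -50
  eu[g == r & g > 0] <- 0
  at_origin <- g == 0 & r == 0
  eu[at_origin] <- NA_real_
  if (!is.null(group)) {
    group <- as.character(group)
    eu[group == "indist_green"] <- 50
    eu[group == "indist_red"] <- -50
    eu[group == "unclassified"] <- NA_real_
    if (any(at_origin & !group %in%
            c("indist_green", "indist_red", "unclassified")))
      warning("cell(s) at the origin have undefined EU; set to NA")
  } else if (any(at_origin)) {
    warning("cell(s) at the origin have undefined EU; set to NA")
  }
  eu
}

#' Bin Exchange Units into the seven tabulation domains
#'
#' The two singleton domains `EU=-50` and `EU=50` are defined by group
#' membership — they contain exactly the cells indistinguishable from the
#' red and green controls — and the remaining cells fall into five interior
#' intervals `(-50,-30]`, `(-30,-10]`, `(-10,10]`, `(10,30]`, `(30,50)`.
#'
#' @param eu numeric vector of Exchange Units.
#' @param group factor/character of Cartesian groups.
#' @return factor with levels [EU_DOMAINS]; `NA` for unclassified cells or
#'   undefined EU.
#' @export
bin_eu <- function(eu, group) {
  group <- as.character(group)
  out <- rep(NA_character_, length(eu))
  out[group == "indist_red"] <- "EU=-50"
  out[group == "indist_green"] <- "EU=50"
  interior <- !group %in% c("indist_red", "indist_green", "unclassified") &
    !is.na(eu)
  br <- c(-50, -30, -10, 10, 30, 50)
  lab <- EU_DOMAINS[2:6]
  idx <- findInterval(eu[interior], br, left.open = TRUE, all.inside = TRUE)
  out[interior] <- lab[idx]
  factor(out, levels = EU_DOMAINS)
}

#' Flip the labelling orientation of a classified table
#'
#' For experiments where the dye orientation was swapped between the two
#' populations, EU values are multiplied by -1, the group labels are
#' mirrored (`indist_green` <-> `indist_red`, `green_some_red` <->
#' `red_some_green`) and the EU domains are re-binned from the negated
#' values, bringing the experiment into alignment with the standard
#' orientation. Applying the flip twice restores the original labels.
#'
#' @param cells classified data.frame with `group`, `eu`, `eu_domain`.
#' @return `cells` with the orientation inverted.
#' @export
flip_orientation <- function(cells) {
  swap <- c(indist_red = "indist_green", red_some_green = "green_some_red",
            uncertain = "uncertain", green_some_red = "red_some_green",
            indist_green = "indist_red", unclassified = "unclassified")
  cells$eu <- -cells$eu
  cells$group <- factor(unname(swap[as.character(cells$group)]),
                        levels = CARTESIAN_GROUPS)
  cells$eu_domain <- bin_eu(cells$eu, cells$group)
  cells
}
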