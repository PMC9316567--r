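## Nuclear 5-methylcytosine quantitation: corrected nuclear fluorescence
## (cnf = 5mc / PI, a DNA-content correction) and normalization against the
## control fibroblast population (control median = 100).

#' Corrected nuclear fluorescence
#'
#' Nuclear anti-5mc immunofluorescence divided by propidium-iodide
#' fluorescence of the same nucleus; the PI denominator corrects for total
#' DNA content, so doubling both signals (e.g. a tetraploid nucleus) leaves
#' cnf unchanged.
#'
#' @param f5mc integrated nuclear 5mc fluorescence.
#' @param fpi integrated nuclear propidium-iodide fluorescence; records
#'   with `fpi <= 0` get `NA` (flagged and excluded downstream).
#' @return numeric vector `f5mc / fpi`.
#' @export
cnf <- function(f5mc, fpi) {
  out <- ifelse(!is.na(fpi) & fpi > 0, f5mc / fpi, NA_real_)
  n_bad <- sum(!is.na(f5mc) & (is.na(fpi) | fpi <= 0))
  if (n_bad > 0)
    warning(n_bad, " record(s) with non-positive PI fluorescence excluded ",
            "from cnf")
  out
}

#' Normalize cnf against the control fibroblast population
#'
#' `cnf_norm = 100 * cnf / median(cnf of control red cells)`: the red
#' (fibroblast) controls are the most stable nuclear standard within an
#' experiment, so their median defines 100 on the normalized scale. With no
#' outlier exclusion the control population's own median cnf_norm is
#' exactly 100; with `outlier_k` set, control cells farther than
#' `outlier_k * MAD` from the control median are dropped before the median
#' is taken, and the control median of cnf_norm may then deviate slightly
#' from 100.
#'
#' @param x numeric vector of cnf values to normalize.
#' @param control_cnf cnf values of the control red (fibroblast) cells.
#' @param outlier_k `NULL` (default, no exclusion) or the MAD multiple
#'   beyond which control cells are excluded.
#' @return list with `cnf_norm` (normalized values for `x`),
#'   `control_median` (the median used) and `n_excluded`.
#' @export
normalize_cnf <- function(x, control_cnf, outlier_k = NULL) {
  control_cnf <- control_cnf[!is.na(control_cnf)]
  if (length(control_cnf) == 0) stop("no control cnf values")
  n_excluded <- 0L
  if (!is.null(outlier_k)) {
    med <- stats::median(control_cnf)
    mad <- stats::mad(control_cnf)
    keep <- abs(control_cnf - med) <= outlier_k * mad
    n_excluded <- sum(!keep)
    if (!any(keep)) stop("outlier exclusion removed all control cells")
    control_cnf <- control_cnf[keep]
  }
  m <- stats::median(control_cnf)
  if (!is.finite(m) || m <= 0) stop("control cnf median is not positive")
  list(cnf_norm = 100 * x / m, control_median = m, n_excluded = n_excluded)
}

#' Methylation summary over the Cartesian classification
#'
#' Medians of normalized cnf per Cartesian-plot group and per EU domain,
#' reusing the reporting layer with cnf_norm in place of the morphology
#' phenotype. Domains with no cells are absent from the result rather than
#' reported as zero.
#'
#' @param cells classified data.frame with `group`, `eu_domain` and
#'   `cnf_norm` columns (e.g. the `cells` component of a
#'   [cartesian_transfer()] fit).
#' @param control_green,control_red optional normalized control tables with
#'   `cnf_norm`; their medians are appended.
#' @return list with `by_group` and `by_domain` data.frames (level, n,
#'   median cnf_norm; occupied levels only) and `controls`.
#' @export
methylation_summary <- function(cells, control_green = NULL,
                                control_red = NULL) {
  stopifnot(all(c("group", "eu_domain", "cnf_norm") %in% names(cells)))
  med_table <- function(f) {
    keep <- !is.na(f) & !is.na(cells$cnf_norm)
    if (!any(keep))
      return(data.frame(level = character(), n = integer(),
                        median_cnf_norm = numeric()))
    agg <- tapply(cells$cnf_norm[keep], droplevels(f[keep]), stats::median)
    data.frame(level = names(agg), n = as.integer(table(droplevels(f[keep]))),
               median_cnf_norm = as.numeric(agg), row.names = NULL)
  }
  ctrl <- data.frame(
    population = c("control_green", "control_red"),
    median_cnf_norm = c(
      if (is.null(control_green$cnf_norm)) NA_real_ else
        stats::median(control_green$cnf_norm, na.rm = TRUE),
      if (is.null(control_red$cnf_norm)) NA_real_ else
        stats::median(control_red$cnf_norm, na.rm = TRUE)))
  list(by_group = med_table(cells$group),
       by_domain = med_table(cells$eu_domain),
       controls = ctrl)
}
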