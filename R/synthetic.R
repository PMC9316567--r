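## Synthetic co-culture generator with ground truth. Emulates the salient
## structure of two-population dye-transfer experiments: wide (log-normal)
## spread of own-channel fluorescence in controls, low opposite-channel
## bleed, additive per-area background, predominantly donor->acceptor
## transfer of a variable fraction of a donor-level amount, morphology
## coupled to uptake (area up, circularity down), and nuclear 5mc levels
## with fibroblasts above cancer cells plus a co-culture shift.

#' Synthetic co-culture configuration
#'
#' Defaults are the package's reference study conditions: 100 cells per
#' control population and 500 co-cultured cells; own-channel fluorescence
#' log-normal(log 1000, 0.5) in both channels (a wide, skewed spread best
#' viewed on log axes); opposite-channel bleed log-normal(log 5, 0.4);
#' additive background 0.02 fluorescence per px^2 per channel; 80% of
#' acceptor cells receive label, the received fraction of a donor-level
#' draw following Beta(0.5, 1.5) (heavily right-skewed: most cells take up
#' little, uptake spans orders of magnitude); half the co-cultured cells
#' are donors (red / fibroblast-like). Morphology: red cells larger
#' (median area 2000 px^2) and less circular (0.45) than green cells
#' (900 px^2, 0.75); per unit received fraction, acceptor area scales by
#' `1 + 0.8 a` and circularity by `1 - 0.4 a`. Nuclear channels: red-cell
#' cnf log-normal(log 0.5, 0.15), green-cell cnf log-normal(log 0.25,
#' 0.2), and red cells in co-culture have cnf scaled by 0.6 (a -40% shift).
#'
#' @param ... overrides for any default field.
#' @return list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    n_control_green = 100, n_control_red = 100, n_cocultured = 500,
    green_signal_dist = c(meanlog = log(1000), sdlog = 0.5),
    red_signal_dist = c(meanlog = log(1000), sdlog = 0.5),
    bleed_dist = c(meanlog = log(5), sdlog = 0.4),
    bg_rate = c(green = 0.02, red = 0.02),
    transfer_fraction = 0.8,
    transfer_amount_shape = c(shape1 = 0.5, shape2 = 1.5),
    transfer_amount_scale = 1,
    donor_mix = 0.5,
    area_green_dist = c(meanlog = log(900), sdlog = 0.3),
    area_red_dist = c(meanlog = log(2000), sdlog = 0.3),
    circ_green = c(mean = 0.75, sd = 0.06),
    circ_red = c(mean = 0.45, sd = 0.06),
    area_coupling = 0.8,     # relative area increase per unit received fraction
    circ_coupling = 0.4,     # relative circularity decrease per unit fraction
    cnf_green_dist = c(meanlog = log(0.25), sdlog = 0.2),
    cnf_red_dist = c(meanlog = log(0.5), sdlog = 0.15),
    cnf_coculture_shift_red = 0.6,  # multiplicative cnf shift of co-cultured red
    pi_dist = c(meanlog = log(1e4), sdlog = 0.2),
    with_nuclear = TRUE,
    seed = 1)
  user <- list(...)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown synthetic_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  stopifnot(cfg$n_control_green > 0, cfg$n_control_red > 0,
            cfg$n_cocultured > 0,
            cfg$transfer_fraction >= 0, cfg$transfer_fraction <= 1,
            cfg$donor_mix >= 0, cfg$donor_mix <= 1)
  structure(cfg, class = "synthetic_config")
}

# draw lognormal from a c(meanlog=, sdlog=) pair; sdlog 0 degenerates to
# the point mass exp(meanlog)
rln <- function(n, par) stats::rlnorm(n, par[["meanlog"]], par[["sdlog"]])

# morphology draw: area (lognormal) and circularity (truncated normal in
# (0.05, 1]); perimeter back-computed from circularity = 4*pi*A/P^2
draw_morphology <- function(n, area_dist, circ_par) {
  area <- rln(n, area_dist)
  circ <- pmin(1, pmax(0.05, stats::rnorm(n, circ_par[["mean"]],
                                          circ_par[["sd"]])))
  perimeter <- sqrt(4 * pi * area / circ)
  list(area = area, perimeter = perimeter)
}

make_cells <- function(id_prefix, experiment_id, role, n, green, red,
                       morph, f5mc, fpi) {
  data.frame(cell_id = sprintf("%s%04d", id_prefix, seq_len(n)),
             experiment_id = experiment_id, role = role,
             green_raw = green, red_raw = red,
             area = morph$area, perimeter = morph$perimeter,
             f5mc = f5mc, fpi = fpi, stringsAsFactors = FALSE)
}

#' Generate the two control populations
#'
#' Control cells cultured alone: own-channel fluorescence from the
#' configured log-normal, opposite-channel fluorescence at bleed level,
#' both channels plus `area * bg_rate` additive background; morphology and
#' nuclear channels from the population baselines. Deterministic under
#' `cfg$seed`.
#'
#' @param cfg a [synthetic_config()].
#' @param experiment_id experiment label stamped on every record.
#' @return list with `control_green` and `control_red` data.frames.
#' @export
generate_controls <- function(cfg, experiment_id = "sim") {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr_seed(cfg$seed, {
    ng <- cfg$n_control_green; nr <- cfg$n_control_red
    mg <- draw_morphology(ng, cfg$area_green_dist, cfg$circ_green)
    mr <- draw_morphology(nr, cfg$area_red_dist, cfg$circ_red)
    nuc <- function(n, cnf_dist) {
      if (!cfg$with_nuclear) return(list(f5mc = NA_real_, fpi = NA_real_))
      fpi <- rln(n, cfg$pi_dist)
      list(f5mc = rln(n, cnf_dist) * fpi, fpi = fpi)
    }
    ng_nuc <- nuc(ng, cfg$cnf_green_dist)
    nr_nuc <- nuc(nr, cfg$cnf_red_dist)
    list(
      control_green = make_cells(
        "cg", experiment_id, "control_green", ng,
        green = rln(ng, cfg$green_signal_dist) + mg$area * cfg$bg_rate[["green"]],
        red = rln(ng, cfg$bleed_dist) + mg$area * cfg$bg_rate[["red"]],
        morph = mg, f5mc = ng_nuc$f5mc, fpi = ng_nuc$fpi),
      control_red = make_cells(
        "cr", experiment_id, "control_red", nr,
        green = rln(nr, cfg$bleed_dist) + mr$area * cfg$bg_rate[["green"]],
        red = rln(nr, cfg$red_signal_dist) + mr$area * cfg$bg_rate[["red"]],
        morph = mr, f5mc = nr_nuc$f5mc, fpi = nr_nuc$fpi))
  })
}

#' Generate a co-cultured population with ground truth
#'
#' Each co-cultured cell is a donor (red / fibroblast-like, with
#' probability `donor_mix`) or an acceptor (green / cancer-cell-like).
#' With probability `transfer_fraction` an acceptor receives a fraction
#' `a ~ scale * Beta(shape1, shape2)` of a fresh draw from the donor
#' own-channel distribution in its opposite (red) channel; donors carry
#' bleed-level green only, reflecting the predominantly donor-to-acceptor
#' direction of label movement. Acceptor morphology
#' responds linearly to the received fraction (area up, circularity down);
#' co-cultured red cells carry the configured multiplicative cnf shift.
#' Deterministic under `cfg$seed + 1`.
#'
#' @param cfg a [synthetic_config()].
#' @param experiment_id experiment label.
#' @return list with `cells` (role `cocultured`) and `truth` (per cell:
#'   `true_role` donor/acceptor, `received_fraction` of a donor-level
#'   draw, `received_amount` raw fluorescence actually received).
#' @export
generate_coculture <- function(cfg, experiment_id = "sim") {
  stopifnot(inherits(cfg, "synthetic_config"))
  withr_seed(cfg$seed + 1, {
    n <- cfg$n_cocultured
    donor <- stats::runif(n) < cfg$donor_mix
    transfers <- stats::runif(n) < cfg$transfer_fraction
    frac <- cfg$transfer_amount_scale *
      stats::rbeta(n, cfg$transfer_amount_shape[["shape1"]],
                   cfg$transfer_amount_shape[["shape2"]])
    frac[!transfers | donor] <- 0
    # amount received: a fraction of a donor-level draw from the donor
    # population's own-channel distribution
    recv <- numeric(n)
    recv[!donor] <- frac[!donor] * rln(sum(!donor), cfg$red_signal_dist)

    morph_g <- draw_morphology(n, cfg$area_green_dist, cfg$circ_green)
    morph_r <- draw_morphology(n, cfg$area_red_dist, cfg$circ_red)
    area <- ifelse(donor, morph_r$area, morph_g$area)
    circ0 <- 4 * pi * area / ifelse(donor, morph_r$perimeter,
                                    morph_g$perimeter)^2
    # dose-like morphology response to uptake
    area <- area * (1 + cfg$area_coupling * frac)
    circ <- pmax(0.05, circ0 * (1 - cfg$circ_coupling * frac))
    perimeter <- sqrt(4 * pi * area / circ)

    own_g <- rln(n, cfg$green_signal_dist)
    own_r <- rln(n, cfg$red_signal_dist)
    bleed_g <- rln(n, cfg$bleed_dist)
    bleed_r <- rln(n, cfg$bleed_dist)
    green <- ifelse(donor, bleed_g, own_g) +
      area * cfg$bg_rate[["green"]]
    red <- ifelse(donor, own_r, bleed_r + recv) +
      area * cfg$bg_rate[["red"]]

    if (cfg$with_nuclear) {
      fpi <- rln(n, cfg$pi_dist)
      cnf_true <- ifelse(donor,
                         rln(n, cfg$cnf_red_dist) * cfg$cnf_coculture_shift_red,
                         rln(n, cfg$cnf_green_dist))
      f5mc <- cnf_true * fpi
    } else {
      fpi <- f5mc <- NA_real_
    }

    cells <- make_cells("cc", experiment_id, "cocultured", n,
                        green = green, red = red,
                        morph = list(area = area, perimeter = perimeter),
                        f5mc = f5mc, fpi = fpi)
    truth <- data.frame(cell_id = cells$cell_id,
                        true_role = ifelse(donor, "donor", "acceptor"),
                        received_fraction = frac,
                        received_amount = recv,
                        stringsAsFactors = FALSE)
    list(cells = cells, truth = truth)
  })
}
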