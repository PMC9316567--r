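# Independent oracles used across the suite. These re-derive expected
# values by brute force / closed form, never by calling the code under test.

# region-membership oracle: each predicate evaluated independently over the
# bounds; returns the labels of all predicates that fire
region_oracle <- function(g, r, b) {
  fired <- c(
    uncertain = g >= b$green_lo && r >= b$red_lo,
    indist_green = g >= b$green_lo && r <= b$red_bleed_hi,
    green_some_red = g >= b$green_lo && b$red_bleed_hi < r && r < b$red_lo,
    indist_red = r >= b$red_lo && g <= b$green_bleed_hi,
    red_some_green = r >= b$red_lo && b$green_bleed_hi < g && g < b$green_lo,
    unclassified = g < b$green_lo && r < b$red_lo)
  names(fired)[fired]
}

# angular oracle for Exchange Units: signed angle between the cell's origin
# ray and the diagonal (1,1)/sqrt(2), mapped linearly so the axes are +/-45
# degrees -> +/-50 EU
eu_oracle <- function(g, r) {
  ang <- acos(pmin(1, pmax(-1, (g + r) / sqrt(2 * (g^2 + r^2))))) * 180 / pi
  sign(g - r) * ang * 50 / 45
}

# exact two-sided Mann-Whitney p by enumerating all C(n+m, n) labelings
mw_exact_p <- function(a, b) {
  n <- length(a); m <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  u_all <- apply(combos, 2, function(idx) sum(rk[idx]) - n * (n + 1) / 2)
  pl <- mean(u_all <= u_obs)
  pu <- mean(u_all >= u_obs)
  min(1, 2 * min(pl, pu))
}

# exact two-sided Wilcoxon signed-rank p by enumerating all 2^n sign patterns
wsr_exact_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  rk <- rank(abs(d))
  v_obs <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% rk)
  pl <- mean(v_all <= v_obs)
  pu <- mean(v_all >= v_obs)
  min(1, 2 * min(pl, pu))
}

# closed-form paired t: t = mean(d) / (sd(d) / sqrt(n)), two-sided p
paired_t_oracle <- function(d) {
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# small hand-built measurement table
toy_cells <- function(n = 3, role = "cocultured", experiment_id = "e1",
                      green = 100, red = 10, area = 400,
                      circ = 0.8, f5mc = NA_real_, fpi = NA_real_) {
  data.frame(cell_id = paste0("c", seq_len(n)),
             experiment_id = rep_len(experiment_id, n),
             role = rep_len(role, n), green_raw = rep_len(green, n),
             red_raw = rep_len(red, n), area = rep_len(area, n),
             perimeter = sqrt(4 * pi * rep_len(area, n) / rep_len(circ, n)),
             f5mc = rep_len(f5mc, n), fpi = rep_len(fpi, n),
             stringsAsFactors = FALSE)
}

toy_bounds <- function(green_lo = 60, red_bleed_hi = 5, red_lo = 70,
                       green_bleed_hi = 4, trim = 0) {
  structure(list(green_lo = green_lo, red_bleed_hi = red_bleed_hi,
                 red_lo = red_lo, green_bleed_hi = green_bleed_hi,
                 trim = trim), class = "control_bounds")
}
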