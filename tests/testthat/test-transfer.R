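test_that("background rates are the summed-control per-area averages", {
  cg <- toy_cells(2, role = "control_green", red = c(10, 20),
                  area = c(100, 100))
  cr <- toy_cells(2, role = "control_red", green = c(4, 4), area = c(50, 150))
  bg <- estimate_background(cg, cr)
  expect_equal(bg$red_bg_rate, 30 / 200)   # (10+20)/(100+100)
  expect_equal(bg$green_bg_rate, 8 / 200)
  cg$red_raw <- 0
  expect_equal(estimate_background(cg, cr)$red_bg_rate, 0)
  expect_error(estimate_background(cg[0, ], cr), "non-empty")
})

test_that("background recovery from generator ground truth (no bleed)", {
  cfg <- synthetic_config(n_control_green = 200, n_control_red = 200,
                          bleed_dist = c(meanlog = -Inf, sdlog = 0),
                          bg_rate = c(green = 0.05, red = 0.05), seed = 21)
  ctl <- generate_controls(cfg)
  bg <- estimate_background(ctl$control_green, ctl$control_red)
  expect_equal(bg$red_bg_rate, 0.05, tolerance = 1e-6)
  expect_equal(bg$green_bg_rate, 0.05, tolerance = 1e-6)
})

test_that("background subtraction is area-proportional and clamped at 0", {
  cells <- toy_cells(3, green = c(100, 10, 100), area = 100)
  bg <- structure(list(green_bg_rate = 0.15, red_bg_rate = 0),
                  class = "background_estimate")
  out <- subtract_background(cells, bg)
  expect_equal(out$green_corr, c(85, 0, 85))
  expect_equal(out$red_corr, cells$red_raw)  # rate 0 -> identity
})

test_that("normalization pins each control's own-channel median at 100 NFU", {
  cg <- toy_cells(3, role = "control_green", green = c(50, 100, 150), red = 0)
  cr <- toy_cells(3, role = "control_red", red = c(30, 60, 90), green = 0)
  cells <- toy_cells(1, green = 200, red = 30)
  bg <- structure(list(green_bg_rate = 0, red_bg_rate = 0),
                  class = "background_estimate")
  norm <- normalize_cells(cells, cg, cr, bg)
  expect_equal(norm$cells$green_norm, 200)   # 100 * 200 / 100
  expect_equal(norm$cells$red_norm, 50)      # 100 * 30 / 60
  expect_equal(median(norm$control_green$green_norm), 100)
  expect_equal(median(norm$control_red$red_norm), 100)

  # scale invariance: x7 on all green raw values changes no green_norm
  k <- 7
  cg2 <- cg; cg2$green_raw <- cg2$green_raw * k
  cells2 <- cells; cells2$green_raw <- cells2$green_raw * k
  norm2 <- normalize_cells(cells2, cg2, cr, bg)
  expect_equal(norm2$cells$green_norm, norm$cells$green_norm)
})

test_that("renormalizing an already-normalized dataset is the identity", {
  cfg <- synthetic_config(n_cocultured = 100, seed = 17, with_nuclear = FALSE)
  ctl <- generate_controls(cfg)
  cc <- generate_coculture(cfg)
  bg0 <- structure(list(green_bg_rate = 0, red_bg_rate = 0),
                   class = "background_estimate")
  n1 <- normalize_cells(cc$cells, ctl$control_green, ctl$control_red,
                        estimate_background(ctl$control_green,
                                            ctl$control_red))
  as_raw <- function(x) {
    x$green_raw <- x$green_norm; x$red_raw <- x$red_norm; x
  }
  n2 <- normalize_cells(as_raw(n1$cells), as_raw(n1$control_green),
                        as_raw(n1$control_red), bg0)
  expect_equal(n2$cells$green_norm, n1$cells$green_norm, tolerance = 1e-12)
  expect_equal(n2$cells$red_norm, n1$cells$red_norm, tolerance = 1e-12)
})

test_that("bounds are trimmed control extrema and overlap aborts", {
  cg <- toy_cells(5, role = "control_green", green = c(60, 80, 100, 120, 140),
                  red = c(1, 2, 3, 4, 5))
  cr <- toy_cells(5, role = "control_red", red = c(70, 90, 110, 130, 150),
                  green = c(0, 1, 2, 3, 4))
  cg$green_norm <- cg$green_raw; cg$red_norm <- cg$red_raw
  cr$green_norm <- cr$green_raw; cr$red_norm <- cr$red_raw
  b <- derive_bounds(cg, cr)
  expect_equal(c(b$green_lo, b$red_bleed_hi, b$red_lo, b$green_bleed_hi),
               c(60, 5, 70, 4))

  # trim 0.2 on 5 cells drops one order statistic per tail
  b2 <- derive_bounds(cg, cr, trim = 0.2)
  expect_equal(c(b2$green_lo, b2$red_bleed_hi), c(80, 4))

  cr_bad <- cr; cr_bad$green_norm[1] <- 65  # bleed reaches the green range
  expect_error(derive_bounds(cg, cr_bad), "overlap")
})

test_that("classification matches the spec's worked examples", {
  b <- toy_bounds()
  cases <- list(list(90, 3, "indist_green"), list(90, 40, "green_some_red"),
                list(90, 100, "uncertain"), list(2, 120, "indist_red"),
                list(30, 120, "red_some_green"), list(10, 10, "unclassified"))
  for (cs in cases)
    expect_equal(as.character(classify_cells(cs[[1]], cs[[2]], b)), cs[[3]])
  # closed boundaries toward the indistinguishable labels
  expect_equal(as.character(classify_cells(60, 5, b)), "indist_green")
  expect_equal(as.character(classify_cells(4, 70, b)), "indist_red")
})

test_that("classification agrees with the independent region oracle and
           exactly one predicate fires", {
  b <- toy_bounds()
  set.seed(42)
  g <- c(runif(4000, 0, 200), sample(c(0, 4, 5, 60, 70), 200, replace = TRUE))
  r <- c(runif(4000, 0, 200), sample(c(0, 4, 5, 60, 70), 200, replace = TRUE))
  got <- as.character(classify_cells(g, r, b))
  for (i in seq_along(g)) {
    fired <- region_oracle(g[i], r[i], b)
    expect_length(fired, 1)
    expect_identical(got[i], fired)
  }
})

test_that("channel swap mirrors the classification on mirrored bounds", {
  b <- toy_bounds()
  bm <- toy_bounds(green_lo = b$red_lo, red_bleed_hi = b$green_bleed_hi,
                   red_lo = b$green_lo, green_bleed_hi = b$red_bleed_hi)
  set.seed(7)
  g <- runif(500, 0, 200); r <- runif(500, 0, 200)
  swap <- c(indist_red = "indist_green", red_some_green = "green_some_red",
            uncertain = "uncertain", green_some_red = "red_some_green",
            indist_green = "indist_red", unclassified = "unclassified")
  expect_identical(unname(swap[as.character(classify_cells(g, r, b))]),
                   as.character(classify_cells(r, g, bm)))
})

test_that("Exchange Units hit the published anchors", {
  expect_equal(exchange_units(80, 0), 50)   # green axis
  expect_equal(exchange_units(0, 80), -50)  # red axis
  expect_equal(exchange_units(60, 60), 0)   # complete-mixing diagonal
  expect_equal(exchange_units(1, tan(22.5 * pi / 180)), 25)
  # group pinning
  expect_equal(exchange_units(2, 120, "indist_red"), -50)
  expect_equal(exchange_units(90, 0, "green_some_red"), 50)
  expect_true(is.na(exchange_units(10, 10, "unclassified")))
  expect_warning(eu0 <- exchange_units(0, 0), "origin")
  expect_true(is.na(eu0))
})

test_that("EU agrees with the angular oracle, is antisymmetric and
           monotone in the angle", {
  set.seed(11)
  g <- rlnorm(2000, 3, 1); r <- rlnorm(2000, 3, 1)
  eu <- exchange_units(g, r)
  expect_equal(eu, eu_oracle(g, r), tolerance = 1e-9)
  expect_true(all(eu >= -50 & eu <= 50))
  expect_equal(exchange_units(r, g), -eu, tolerance = 1e-12)
  th <- sort(runif(200, 0, 90))
  eus <- exchange_units(cos(th * pi / 180), sin(th * pi / 180))
  expect_true(all(diff(eus) < 0))  # strictly decreasing in theta
})

test_that("EU domains follow the printed binning", {
  expect_equal(as.character(bin_eu(10, "uncertain")), "(-10,10]")
  expect_equal(as.character(bin_eu(10.01, "uncertain")), "(10,30]")
  expect_equal(as.character(bin_eu(-30, "uncertain")), "(-50,-30]")
  expect_equal(as.character(bin_eu(49.9, "green_some_red")), "(30,50)")
  expect_equal(as.character(bin_eu(-50, "indist_red")), "EU=-50")
  expect_equal(as.character(bin_eu(50, "indist_green")), "EU=50")
  expect_true(is.na(bin_eu(NA, "unclassified")))
})

test_that("orientation flip negates EU, mirrors groups, and is an involution
           up to domain re-binning", {
  cells <- data.frame(
    eu = c(25, -50, 50, 0, NA),
    group = factor(c("green_some_red", "indist_red", "indist_green",
                     "uncertain", "unclassified"),
                   levels = CARTESIAN_GROUPS))
  cells$eu_domain <- bin_eu(cells$eu, cells$group)
  f <- flip_orientation(cells)
  expect_equal(f$eu, c(-25, 50, -50, 0, NA))
  expect_equal(as.character(f$group),
               c("red_some_green", "indist_green", "indist_red", "uncertain",
                 "unclassified"))
  expect_equal(as.character(f$eu_domain[2]), "EU=50")
  ff <- flip_orientation(f)
  expect_equal(ff$eu, cells$eu)
  expect_equal(as.character(ff$group), as.character(cells$group))
})

test_that("channel-scale invariance: rescaling one channel everywhere
           changes no label or EU (zero background)", {
  cfg <- synthetic_config(n_cocultured = 200, seed = 13,
                          bg_rate = c(green = 0, red = 0),
                          with_nuclear = FALSE)
  ctl <- generate_controls(cfg)
  cc <- generate_coculture(cfg)
  base <- cartesian_transfer(cc$cells, ctl$control_green, ctl$control_red)
  k <- 3.7
  scale_col <- function(x, col) { x[[col]] <- x[[col]] * k; x }
  scaled <- cartesian_transfer(scale_col(cc$cells, "red_raw"),
                               scale_col(ctl$control_green, "red_raw"),
                               scale_col(ctl$control_red, "red_raw"))
  expect_identical(as.character(scaled$cells$group),
                   as.character(base$cells$group))
  expect_equal(scaled$cells$eu, base$cells$eu, tolerance = 1e-12)
})

test_that("the fit partitions all co-cultured cells and caps samples", {
  cfg <- synthetic_config(n_cocultured = 300, seed = 29)
  ctl <- generate_controls(cfg)
  cc <- generate_coculture(cfg)
  fit <- cartesian_transfer(cc$cells, ctl$control_green, ctl$control_red,
                            max_cocultured = 250, max_controls = 80)
  expect_equal(fit$n$analysed[["cocultured"]], 250)
  expect_equal(fit$n$analysed[["control_green"]], 80)
  expect_equal(sum(fit$summary$groups$n), 250)  # partition
  expect_equal(sum(fit$summary$eu_domains$n) +
                 sum(fit$cells$group == "unclassified"), 250)
  # EU singleton domains equal the indistinguishable group counts
  g <- fit$summary$groups; d <- fit$summary$eu_domains
  expect_equal(d$n[d$level == "EU=-50"], g$n[g$level == "indist_red"])
  expect_equal(d$n[d$level == "EU=50"], g$n[g$level == "indist_green"])
  # determinism under the seed
  fit2 <- cartesian_transfer(cc$cells, ctl$control_green, ctl$control_red,
                             max_cocultured = 250, max_controls = 80)
  expect_identical(fit$cells$eu, fit2$cells$eu)
  # predict() on the training cells reproduces the fitted labels
  pr <- predict(fit, cc$cells[1:50, ])
  idx <- match(cc$cells$cell_id[1:50], fit$cells$cell_id)
  have <- !is.na(idx)
  expect_identical(as.character(pr$group[have]),
                   as.character(fit$cells$group[idx[have]]))
})
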