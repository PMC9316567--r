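# draw a filled disk into a matrix
disk <- function(img, cx, cy, rad, value = 1) {
  for (y in seq_len(nrow(img)))
    img[y, which((seq_len(ncol(img)) - cx)^2 + (y - cy)^2 <= rad^2)] <- value
  img
}

test_that("circularity follows the closed forms and is scale invariant", {
  r <- 3.2; s <- 5
  expect_equal(circularity(pi * r^2, 2 * pi * r), 1)        # circle
  expect_equal(circularity(s^2, 4 * s), pi / 4)             # square
  # 2:1 ellipse, perimeter by fine polygonal quadrature as oracle
  a <- 2; b <- 1
  t <- seq(0, 2 * pi, length.out = 2e5)
  per <- sum(sqrt(diff(a * cos(t))^2 + diff(b * sin(t))^2))
  expect_equal(per, 9.6884482205, tolerance = 1e-8)
  expect_equal(circularity(pi * a * b, per), 8 * pi^2 / per^2,
               tolerance = 1e-10)
  expect_equal(circularity(pi * a * b, per), 0.841165, tolerance = 1e-6)
  # scale invariance
  k <- 13.7
  expect_equal(circularity(k^2 * 7, k * 11), circularity(7, 11))
  expect_error(circularity(0, 5), "positive")
})

test_that("two-channel segmentation uses union semantics", {
  g <- r <- matrix(0, 80, 80)
  g <- disk(g, 20, 20, 8)      # bright only in green
  r <- disk(r, 60, 60, 8)      # bright only in red
  lab <- segment_cells(g, r, min_size = 10)
  expect_equal(lab$n_cells, 2)
  both_g <- disk(disk(matrix(0, 80, 80), 20, 20, 8), 60, 60, 8)
  lab2 <- segment_cells(both_g, matrix(0, 80, 80), min_size = 10)
  expect_equal(lab2$n_cells, 2)
  expect_warning(out <- segment_cells(matrix(0, 10, 10), matrix(0, 10, 10)),
                 "empty foreground")
  expect_equal(out$n_cells, 0)
  expect_error(segment_cells(matrix(0, 10, 10), matrix(0, 5, 5)), "shape")
})

test_that("measurement integrates fluorescence and counts area", {
  g <- matrix(0, 40, 40)
  g[10:14, 10:11] <- 5                     # 10 px region, all green = 5
  lab <- segment_cells(g, matrix(0, 40, 40), min_size = 5)
  cells <- measure_cells(lab, g, matrix(0, 40, 40))
  expect_equal(nrow(cells), 1)
  expect_equal(cells$green_raw, 50)
  expect_equal(cells$area, 10)
  empty <- segment_cells(matrix(c(0, 1), 20, 20), matrix(0, 20, 20),
                         min_size = 1000)
  expect_equal(nrow(measure_cells(empty, matrix(0, 20, 20),
                                  matrix(0, 20, 20))), 0)
})

test_that("fluorescence and area are additive over label splits", {
  g <- matrix(runif(1600), 40, 40)
  whole <- matrix(0L, 40, 40); whole[5:30, 10:20] <- 1L
  split <- whole; split[18:30, 10:20] <- 2L
  mk <- function(m) structure(list(label_mask = m, n_cells = max(m)),
                              class = "labeled_image")
  w <- measure_cells(mk(whole), g, g)
  s <- measure_cells(mk(split), g, g)
  expect_equal(sum(s$green_raw), w$green_raw)
  expect_equal(sum(s$area), w$area)
})

test_that("rendered synthetic images are recovered by segmentation", {
  cfg <- synthetic_config(n_cocultured = 50, seed = 8,
                          area_green_dist = c(meanlog = log(500), sdlog = 0.2),
                          area_red_dist = c(meanlog = log(800), sdlog = 0.2))
  cc <- generate_coculture(cfg)
  cells <- cc$cells[1:50, ]
  img <- render_images(cells, width = 1024, height = 1024, seed = 8)

  # mask pixel count approximates the requested area
  one <- render_images(cells[1, ], width = 128, height = 128, seed = 1)
  expect_equal(sum(one$mask == 1), cells$area[1], tolerance = 0.05)
  # channel sums over the mask match the raw fluorescence to < 1%
  expect_equal(sum(one$green[one$mask == 1]), cells$green_raw[1],
               tolerance = 0.01)
  expect_equal(sum(one$red[one$mask == 1]), cells$red_raw[1],
               tolerance = 0.01)
  # zero cells -> empty mask
  expect_equal(sum(render_images(cells[0, ], 64, 64)$mask), 0)

  # 50 rendered cells -> 50 labels agreeing with the truth mask by IoU
  lab <- segment_cells(img$green, img$red,
                       threshold = list(green = 1e-6, red = 1e-6),
                       min_size = 20)
  expect_equal(lab$n_cells, 50)
  iou <- sapply(1:50, function(k) {
    truth <- img$mask == k
    hit <- lab$label_mask[truth]
    hit <- hit[hit > 0]
    if (!length(hit)) return(0)
    m <- as.integer(names(which.max(table(hit))))
    got <- lab$label_mask == m
    sum(truth & got) / sum(truth | got)
  })
  expect_gte(mean(iou > 0.9), 0.98)

  # end-to-end fluorescence recovery within 2% for non-touching cells
  meas <- measure_cells(lab, img$green, img$red)
  ctr_true <- t(sapply(1:50, function(k)
    colMeans(which(img$mask == k, arr.ind = TRUE))))
  ctr_got <- t(sapply(seq_len(lab$n_cells), function(k)
    colMeans(which(lab$label_mask == k, arr.ind = TRUE))))
  map <- apply(ctr_true, 1, function(p)
    which.min(colSums((t(ctr_got) - p)^2)))
  expect_equal(meas$green_raw[map], cells$green_raw, tolerance = 0.02)
  expect_equal(meas$area[map], cells$area, tolerance = 0.06)
})

test_that("nuclei are segmented, assigned by majority overlap and pooled", {
  pi_img <- mc5 <- matrix(0, 60, 60)
  cell_lab <- matrix(0L, 60, 60)
  cell_lab[10:40, 10:40] <- 1L
  cell_lab[10:40, 45:58] <- 2L
  pi_img[20:29, 20:29] <- 3                 # 100-px nucleus inside cell 1
  mc5[20:29, 20:29] <- 2
  cl <- structure(list(label_mask = cell_lab, n_cells = 2L),
                  class = "labeled_image")
  nuc <- segment_nuclei(pi_img, cl, min_size = 10)
  expect_equal(nuc$n_cells, 1)
  expect_equal(nuc$cell_of, 1L)
  cells <- toy_cells(2)
  cells <- suppressMessages(measure_nuclei(cells, nuc, mc5, pi_img))
  expect_equal(cells$f5mc[1], 200)          # uniform 2 over 100 px
  expect_equal(cells$fpi[1], 300)
  expect_true(is.na(cells$f5mc[2]))

  # nucleus straddling two cells goes to the majority-overlap cell
  pi2 <- matrix(0, 60, 60)
  pi2[26:35, 38:47] <- 1   # 40 px over cell 1, 60 px over cell 2
  cell_lab2 <- matrix(0L, 60, 60)
  cell_lab2[1:60, 1:41] <- 1L
  cell_lab2[1:60, 42:60] <- 2L
  cl2 <- structure(list(label_mask = cell_lab2, n_cells = 2L),
                   class = "labeled_image")
  nuc2 <- segment_nuclei(pi2, cl2, min_size = 10)
  # overlap oracle: count pixels directly
  ov <- table(cell_lab2[pi2 > 0])
  expect_equal(nuc2$cell_of, as.integer(names(which.max(ov))))

  # two nuclei in one cell are pooled additively
  pi3 <- matrix(0, 60, 60)
  pi3[12:15, 12:15] <- 2
  pi3[30:33, 30:33] <- 4
  nuc3 <- segment_nuclei(pi3, cl, min_size = 10)
  expect_equal(nuc3$n_cells, 2)
  cells3 <- suppressMessages(measure_nuclei(toy_cells(2), nuc3, pi3, pi3))
  expect_equal(cells3$fpi[1], 16 * 2 + 16 * 4)
})

test_that("channel TIFF round trip preserves intensities", {
  img <- list(green = matrix(runif(400) * 1000, 20, 20),
              red = matrix(runif(400) * 50, 20, 20))
  path <- withr::local_tempfile(fileext = ".tif")
  write_channels_tiff(img, path)
  back <- read_channels_tiff(path)
  expect_equal(names(back), c("green", "red"))
  expect_equal(back$green, img$green, tolerance = 1e-6)
  expect_equal(back$red, img$red, tolerance = 1e-6)
})
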