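## Optional image rendering for the synthetic generator, plus multi-page
## TIFF I/O. Rendering is deliberately simple — elliptical blobs with
## punctate intensity — adequate to exercise segmentation, not to mimic
## microscopy optics.

#' Render synthetic cells into channel images with a ground-truth mask
#'
#' Cells are placed on a non-overlapping grid and each is drawn as an
#' elliptical blob whose pixel count approximates the cell's area. Within
#' the blob, intensity is a uniform base plus bright puncta (the punctate
#' organelle-bound appearance of lipophilic dyes); each channel is then
#' rescaled so the summed intensity over the cell's mask equals the cell's
#' raw fluorescence essentially exactly. A concentric ellipse of ~40% area
#' carries the nuclear (5mc, PI) intensities when present.
#'
#' @param cells data.frame of cell records.
#' @param width,height canvas size in pixels; an error is raised when the
#'   grid cannot hold all cells.
#' @param aspect ellipse axis ratio.
#' @param seed seed for punctum placement.
#' @return list with `green`, `red`, `f5mc`, `pi` matrices, the integer
#'   ground-truth `mask` (cell k = label k, row order of `cells`) and
#'   `nuclei_mask`.
#' @export
render_images <- function(cells, width = 1024, height = 1024, aspect = 1.5,
                          seed = 1) {
  n <- nrow(cells)
  chan <- function() matrix(0, height, width)
  out <- list(green = chan(), red = chan(), f5mc = chan(), pi = chan(),
              mask = matrix(0L, height, width),
              nuclei_mask = matrix(0L, height, width))
  if (n == 0) return(out)
  cell_w <- ceiling(2 * sqrt(max(cells$area) * aspect / pi)) + 6
  per_row <- floor(width / cell_w)
  n_rows <- floor(height / cell_w)
  if (per_row < 1 || per_row * n_rows < n)
    stop("canvas overflow: ", n, " cells do not fit a ", width, "x", height,
         " canvas at this cell size")
  withr_seed(seed, {
    for (k in seq_len(n)) {
      a <- sqrt(cells$area[k] * aspect / pi)   # semi-axes, pixels
      b <- sqrt(cells$area[k] / (aspect * pi))
      cx <- ((k - 1) %% per_row) * cell_w + cell_w / 2
      cy <- ((k - 1) %/% per_row) * cell_w + cell_w / 2
      xs <- max(1, floor(cx - a)):min(width, ceiling(cx + a))
      ys <- max(1, floor(cy - b)):min(height, ceiling(cy + b))
      inside <- outer((ys - cy)^2 / b^2, (xs - cx)^2 / a^2, "+") <= 1
      pix <- which(inside, arr.ind = TRUE)
      rows <- ys[pix[, 1]]; cols <- xs[pix[, 2]]
      ind <- cbind(rows, cols)
      out$mask[ind] <- k
      fill <- function(img, total) {
        if (is.na(total) || total <= 0) return(img)
        base <- rep(1, nrow(ind))
        puncta <- sample.int(nrow(ind), max(1, round(nrow(ind) / 30)),
                             replace = TRUE)
        base[puncta] <- base[puncta] + 8
        img[ind] <- img[ind] + base * (total / sum(base))
        img
      }
      out$green <- fill(out$green, cells$green_raw[k])
      out$red <- fill(out$red, cells$red_raw[k])
      nuc_in <- outer((ys - cy)^2 / (0.63 * b)^2,
                      (xs - cx)^2 / (0.63 * a)^2, "+") <= 1
      npix <- which(nuc_in, arr.ind = TRUE)
      nind <- cbind(ys[npix[, 1]], xs[npix[, 2]])
      out$nuclei_mask[nind] <- k
      if (!is.na(cells$fpi[k]) && cells$fpi[k] > 0) {
        out$pi[nind] <- out$pi[nind] + cells$fpi[k] / nrow(nind)
        out$f5mc <- {
          img <- out$f5mc
          base <- rep(1, nrow(nind))
          puncta <- sample.int(nrow(nind), max(1, round(nrow(nind) / 20)),
                               replace = TRUE)
          base[puncta] <- base[puncta] + 5
          img[nind] <- img[nind] + base * (cells$f5mc[k] / sum(base))
          img
        }
      }
    }
  })
  out
}

#' Write channel images as a multi-page float TIFF
#'
#' One 32-bit float page per channel, each rescaled to `[0, 1]` by its own
#' maximum; the per-channel scale factors are returned (and written
#' alongside as a YAML sidecar) so integrated intensities can be restored.
#' All downstream quantities are ratios within a channel, so the scale is
#' immaterial to the analysis itself.
#'
#' @param channels named list of numeric matrices.
#' @param path output TIFF path.
#' @return named vector of scale factors, invisibly.
#' @export
write_channels_tiff <- function(channels, path) {
  scales <- vapply(channels, function(m) max(max(m), 1e-12), numeric(1))
  pages <- mapply(function(m, s) m / s, channels, scales, SIMPLIFY = FALSE)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  yaml::write_yaml(list(channels = names(channels),
                        scales = as.list(scales)),
                   paste0(path, ".scales.yml"))
  invisible(scales)
}

#' Read a multi-page TIFF written by [write_channels_tiff()]
#'
#' @param path TIFF path; the `.scales.yml` sidecar restores channel names
#'   and intensity scales when present.
#' @return named list of numeric matrices.
#' @export
read_channels_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar <- paste0(path, ".scales.yml")
  if (file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    pages <- mapply(function(m, s) m * s, pages, as.numeric(meta$scales),
                    SIMPLIFY = FALSE)
    names(pages) <- meta$channels
  }
  pages
}
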