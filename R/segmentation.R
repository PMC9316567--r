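## Threshold-based segmentation of registered two-channel images and
## per-object quantitation. EBImage provides thresholding, connected
## components and watershed; the perimeter estimate is an 8-connected
## contour chain length (axial step 1, diagonal sqrt(2)), which tracks
## true boundary length far better than raw pixel-edge counting.

#' Cell circularity
#'
#' `4 * pi * area / perimeter^2`: 1 for a circle (the isoperimetric
#' maximum among analytic shapes), smaller for elongated or spread cells,
#' and invariant under rescaling (`circularity(k^2 A, k P) =
#' circularity(A, P)`). Values from digitized boundaries may slightly
#' exceed 1 for tiny regions; they are reported unclamped.
#'
#' @param area cell-profile area (squared length units).
#' @param perimeter cell peripheral circumference (same length unit).
#' @return unitless circularity.
#' @export
circularity <- function(area, perimeter) {
  if (any(is.na(area) | area <= 0) || any(is.na(perimeter) | perimeter <= 0))
    stop("area and perimeter must be positive")
  4 * pi * area / perimeter^2
}

# threshold one channel: "otsu" or an explicit numeric cutoff
channel_mask <- function(img, threshold) {
  if (identical(threshold, "otsu")) {
    rng <- range(img)
    if (rng[2] <= rng[1]) return(img > Inf)  # flat channel: no foreground
    th <- EBImage::otsu(EBImage::Image(img), range = rng)
    img > th
  } else {
    img > threshold
  }
}

#' Segment cells from registered green and red channel images
#'
#' Each channel is thresholded (Otsu's method per channel by default, or
#' explicit cutoffs) and the foreground masks are united before connected-
#' component labelling, so a cell bright in either channel becomes a
#' single object. Components smaller than `min_size` pixels are removed
#' and labels are renumbered contiguously. With `split_touching = TRUE`, a
#' distance-transform watershed separates touching cells (off by default).
#'
#' @param green,red equal-shaped numeric matrices.
#' @param threshold `"otsu"` or `list(green = , red = )` numeric cutoffs.
#' @param min_size smallest object retained, in pixels.
#' @param split_touching logical; watershed splitting of the union mask.
#' @return list of class `"labeled_image"`: `label_mask` (integer matrix,
#'   0 background) and `n_cells`.
#' @export
segment_cells <- function(green, red, threshold = "otsu", min_size = 20,
                          split_touching = FALSE) {
  if (!all(dim(green) == dim(red))) stop("channel shapes differ")
  th_g <- if (is.list(threshold)) threshold$green else threshold
  th_r <- if (is.list(threshold)) threshold$red else threshold
  fg <- channel_mask(green, th_g) | channel_mask(red, th_r)
  if (!any(fg)) {
    warning("empty foreground: no cells segmented")
    return(structure(list(label_mask = matrix(0L, nrow(green), ncol(green)),
                          n_cells = 0L), class = "labeled_image"))
  }
  lab <- if (split_touching) {
    EBImage::watershed(EBImage::distmap(EBImage::Image(fg * 1)))
  } else {
    EBImage::bwlabel(EBImage::Image(fg * 1))
  }
  lab <- EBImage::imageData(lab)
  relabel_min_size(lab, min_size)
}

# drop small components, renumber 1..k
relabel_min_size <- function(lab, min_size) {
  lab <- matrix(as.integer(lab), nrow(lab), ncol(lab))
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_size)
  map <- integer(length(sizes))
  map[keep] <- seq_along(keep)
  lab[lab > 0] <- map[lab[lab > 0]]
  structure(list(label_mask = lab, n_cells = length(keep)),
            class = "labeled_image")
}

# chain-length perimeter of every labelled object
object_perimeters <- function(label_mask) {
  n <- max(label_mask)
  if (n == 0) return(numeric(0))
  oc <- EBImage::ocontour(EBImage::Image(label_mask))
  vapply(seq_len(n), function(k) {
    xy <- oc[[k]]
    if (is.null(xy) || nrow(xy) < 2) return(4)  # ~unit pixel boundary
    d <- sqrt(rowSums((xy - xy[c(2:nrow(xy), 1), , drop = FALSE])^2))
    max(sum(d), 4)
  }, numeric(1))
}

#' Measure segmented cells
#'
#' Per labelled object: integrated green and red fluorescence over the
#' mask, area as pixel count (times `pixel_size^2` if given), and a
#' contour-chain perimeter estimate. Fluorescence and area are exactly
#' additive over label splits.
#'
#' @param labeled a `"labeled_image"` from [segment_cells()].
#' @param green,red channel images aligned to the mask.
#' @param experiment_id,role metadata stamped on the records.
#' @param pixel_size optional physical pixel edge length (e.g. um/px).
#' @return data.frame of cell records ([read_cell_table()] schema).
#' @export
measure_cells <- function(labeled, green, red, experiment_id = "img",
                          role = "cocultured", pixel_size = NULL) {
  lab <- labeled$label_mask
  n <- labeled$n_cells
  if (n == 0)
    return(utils::read.csv(text = paste(CELL_TABLE_COLUMNS, collapse = ",")))
  inside <- lab > 0
  idx <- lab[inside]
  green_sum <- as.numeric(rowsum(green[inside], idx))
  red_sum <- as.numeric(rowsum(red[inside], idx))
  areas <- tabulate(idx, nbins = n)
  per <- object_perimeters(lab)
  scale <- if (is.null(pixel_size)) 1 else pixel_size
  data.frame(cell_id = sprintf("img%04d", seq_len(n)),
             experiment_id = experiment_id, role = role,
             green_raw = green_sum, red_raw = red_sum,
             area = areas * scale^2, perimeter = per * scale,
             f5mc = NA_real_, fpi = NA_real_,
             stringsAsFactors = FALSE)
}

#' Segment nuclei from a propidium-iodide channel
#'
#' Threshold plus connected components, as for cells; when a cell label
#' mask is supplied each nucleus is assigned to the cell whose label
#' covers the majority of its pixels (0 = unassigned when no cell
#' overlaps).
#'
#' @param pi_img PI channel image.
#' @param cell_labels optional cell `"labeled_image"` for assignment.
#' @param threshold,min_size as in [segment_cells()].
#' @return `"labeled_image"` with an extra `cell_of` integer vector
#'   (nucleus k belongs to cell `cell_of[k]`).
#' @export
segment_nuclei <- function(pi_img, cell_labels = NULL, threshold = "otsu",
                           min_size = 10) {
  fg <- channel_mask(pi_img, threshold)
  if (!any(fg)) {
    warning("empty foreground: no nuclei segmented")
    out <- structure(list(label_mask = matrix(0L, nrow(pi_img), ncol(pi_img)),
                          n_cells = 0L), class = "labeled_image")
    out$cell_of <- integer(0)
    return(out)
  }
  out <- relabel_min_size(
    EBImage::imageData(EBImage::bwlabel(EBImage::Image(fg * 1))), min_size)
  out$cell_of <- if (is.null(cell_labels)) {
    rep(0L, out$n_cells)
  } else {
    vapply(seq_len(out$n_cells), function(k) {
      over <- cell_labels$label_mask[out$label_mask == k]
      over <- over[over > 0]
      if (length(over) == 0) return(0L)
      as.integer(names(which.max(table(over))))
    }, integer(1))
  }
  out
}

#' Measure nuclear 5mc and PI fluorescence
#'
#' Integrated 5mc and PI fluorescence per nucleus, attached to the owning
#' cell's record; multiple nuclei in one cell are pooled (summed) before
#' any cnf computation. Cells without an assigned nucleus keep `NA`
#' nuclear fields (logged via message).
#'
#' @param cells data.frame of cell records (rows ordered by cell label).
#' @param nuclei `"labeled_image"` from [segment_nuclei()] with `cell_of`.
#' @param f5mc_img,pi_img registered nuclear channel images.
#' @return `cells` with `f5mc` and `fpi` filled in.
#' @export
measure_nuclei <- function(cells, nuclei, f5mc_img, pi_img) {
  if (nuclei$n_cells == 0) return(cells)
  inside <- nuclei$label_mask > 0
  idx <- nuclei$label_mask[inside]
  s5 <- as.numeric(rowsum(f5mc_img[inside], idx))
  spi <- as.numeric(rowsum(pi_img[inside], idx))
  cells$f5mc <- NA_real_
  cells$fpi <- NA_real_
  for (k in seq_len(nuclei$n_cells)) {
    cell <- nuclei$cell_of[k]
    if (cell < 1 || cell > nrow(cells)) next
    cells$f5mc[cell] <- sum(cells$f5mc[cell], s5[k], na.rm = TRUE)
    cells$fpi[cell] <- sum(cells$fpi[cell], spi[k], na.rm = TRUE)
  }
  n_missing <- sum(is.na(cells$fpi))
  if (n_missing > 0)
    message(n_missing, " cell(s) without an assigned nucleus; nuclear ",
            "fields left missing")
  cells
}
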