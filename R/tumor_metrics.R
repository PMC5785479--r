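## Image-based tumor-size and metastasis scoring.
##
## A larva image is a plain numeric matrix of grayscale intensities (origin
## top-left, rows = y, columns = x). The yolk sac is an analyst-supplied
## elliptical ROI. Tumor burden is the thresholded foreground connected to
## the ROI; metastasis is scored from fluorescent spots strictly outside it.
## No binary image codecs are used: matrices are built in memory or read
## from plain-text PGM (P2).

#' Elliptical yolk-sac region of interest
#'
#' @param center `(x, y)` pixel coordinates of the ellipse center
#'   (x = column, y = row).
#' @param radii `(rx, ry)` pixel radii.
#' @return an object of class `yolk_roi`.
#' @export
yolk_roi <- function(center, radii) {
  stopifnot(length(center) == 2, length(radii) == 2, all(radii > 0))
  structure(list(center = as.numeric(center), radii = as.numeric(radii)),
            class = "yolk_roi")
}

#' Read a yolk ROI from JSON
#'
#' Expects `{"center": [x, y], "radii": [rx, ry]}`.
#'
#' @param path path to the JSON file.
#' @return a [yolk_roi()].
#' @export
read_roi_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  yolk_roi(rec$center, rec$radii)
}

# logical mask of pixels inside the ROI ellipse
roi_mask <- function(dim, roi) {
  stopifnot(inherits(roi, "yolk_roi"))
  rows <- matrix(seq_len(dim[1]), dim[1], dim[2])
  cols <- matrix(rep(seq_len(dim[2]), each = dim[1]), dim[1], dim[2])
  m <- ((cols - roi$center[1]) / roi$radii[1])^2 +
    ((rows - roi$center[2]) / roi$radii[2])^2 <= 1
  if (!any(m)) stop("ROI does not intersect image bounds", call. = FALSE)
  m
}

#' Metastasis-scoring configuration
#'
#' @param min_cells minimum number of dispersed cells beyond the yolk for a
#'   positive metastasis call (default 5, the study's rule).
#' @param min_spot_area,max_spot_area connected-component area bounds
#'   (pixels) for a spot to count as one cell.
#' @param intensity_threshold fixed foreground threshold; `NULL` (default)
#'   selects Otsu's method.
#' @param min_contrast minimum difference between mean foreground and mean
#'   background intensity for thresholded signal to count as real; below it
#'   the image is treated as signal-free (guards auto-thresholding against
#'   splitting pure background noise).
#' @return an object of class `metastasis_config`.
#' @export
metastasis_config <- function(min_cells = 5, min_spot_area = 4,
                              max_spot_area = 400,
                              intensity_threshold = NULL,
                              min_contrast = 30) {
  stopifnot(min_cells >= 1, min_spot_area > 0,
            max_spot_area > min_spot_area, min_contrast >= 0)
  structure(list(min_cells = min_cells, min_spot_area = min_spot_area,
                 max_spot_area = max_spot_area,
                 intensity_threshold = intensity_threshold,
                 min_contrast = min_contrast),
            class = "metastasis_config")
}

# TRUE when the thresholded foreground is genuinely brighter than the
# background (see metastasis_config()$min_contrast)
.has_contrast <- function(img, fg, cfg) {
  if (!any(fg) || all(fg)) return(FALSE)
  mean(img[fg]) - mean(img[!fg]) >= cfg$min_contrast
}

#' Otsu's threshold
#'
#' Maximizes between-class variance on a 256-bin histogram of the input
#' intensities. Errors on constant input (no contrast to threshold).
#'
#' @param x numeric intensities.
#' @return threshold value; pixels strictly above it are foreground.
#' @export
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) stop("no contrast", call. = FALSE)
  breaks <- seq(rng[1], rng[2], length.out = 257)
  h <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w <- cumsum(p)
  mu <- cumsum(p * mids)
  mt <- mu[256]
  between <- (mt * w - mu)^2 / (w * (1 - w))
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Label connected components of a binary mask
#'
#' Breadth-first flood fill over foreground pixels; 8-connectivity by
#' default.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (!length(fg)) return(lab)
  if (connectivity == 4) {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  k <- 0L
  for (seed in fg) {
    if (lab[seed] != 0L) next
    k <- k + 1L
    lab[seed] <- k
    frontier <- seed
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      cc <- (frontier - 1L) %/% nr + 1L
      nb_r <- rep(r, times = length(dr)) + rep(dr, each = length(frontier))
      nb_c <- rep(cc, times = length(dc)) + rep(dc, each = length(frontier))
      ok <- nb_r >= 1L & nb_r <= nr & nb_c >= 1L & nb_c <= nc
      nb <- (nb_c[ok] - 1L) * nr + nb_r[ok]
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- k
      frontier <- nb
    }
  }
  lab
}

#' Segment the tumor mass and measure its area
#'
#' Thresholds the image (Otsu computed on the ROI intensities by default, or
#' a fixed threshold from `cfg`) and measures the total foreground area of
#' all connected components that intersect the yolk ROI, in pixels. An
#' all-background ROI gives area 0; a saturated uniform image is an error
#' (`"no contrast"`). Deterministic for a fixed image and configuration.
#'
#' @param img numeric intensity matrix.
#' @param roi a [yolk_roi()].
#' @param cfg a [metastasis_config()].
#' @return list with `tumor_area` (pixels), logical `mask` of tumor pixels,
#'   and the `threshold` used.
#' @export
segment_tumor_area <- function(img, roi, cfg = metastasis_config()) {
  stopifnot(is.matrix(img), all(is.finite(img)), all(img >= 0))
  inroi <- roi_mask(dim(img), roi)
  vals <- img[inroi]
  if (diff(range(vals)) == 0) {
    if (all(vals == 0)) {
      return(list(tumor_area = 0L,
                  mask = matrix(FALSE, nrow(img), ncol(img)),
                  threshold = NA_real_))
    }
    stop("no contrast", call. = FALSE)
  }
  thr <- cfg$intensity_threshold %||% otsu_threshold(vals)
  fg <- img > thr
  if (!.has_contrast(img, fg, cfg)) {
    return(list(tumor_area = 0L,
                mask = matrix(FALSE, nrow(img), ncol(img)),
                threshold = thr))
  }
  lab <- label_components(fg)
  keep <- setdiff(unique(lab[inroi & fg]), 0L)
  tumor <- matrix(lab %in% keep, nrow(img), ncol(img))
  list(tumor_area = sum(tumor), mask = tumor, threshold = thr)
}

#' Polygon area by the shoelace formula
#'
#' Absolute value of the signed area, so vertex orientation does not matter.
#' Used for manual freehand-polygon tumor and yolk-sac measurements.
#'
#' @param vertices two-column matrix or data frame of ordered `(x, y)`
#'   vertices of a simple (non-self-intersecting) polygon.
#' @return area in squared pixel units.
#' @examples
#' polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3)))  # 6
#' @export
polygon_area <- function(vertices) {
  v <- as.matrix(vertices)
  if (nrow(v) < 3) stop("polygon needs at least 3 vertices", call. = FALSE)
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Average manual and automatic tumor-area measurements
#'
#' @param manual manual (polygon) area in pixels, >= 0; vectorized.
#' @param automatic automatic (threshold segmentation) area in pixels, >= 0.
#' @return arithmetic mean of the two measurements.
#' @export
combine_area <- function(manual, automatic) {
  stopifnot(all(manual >= 0), all(automatic >= 0))
  (manual + automatic) / 2
}

#' Count dispersed cells beyond the yolk sac
#'
#' Thresholds the whole image (Otsu by default) and counts connected
#' components lying strictly outside the ROI whose area falls within the
#' configured single-cell bounds.
#'
#' @param img numeric intensity matrix.
#' @param roi a [yolk_roi()].
#' @param cfg a [metastasis_config()].
#' @return integer count of dispersed cells.
#' @export
count_dispersed_cells <- function(img, roi, cfg = metastasis_config()) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  if (diff(range(img)) == 0) return(0L)
  inroi <- roi_mask(dim(img), roi)
  thr <- cfg$intensity_threshold %||% otsu_threshold(img)
  fg <- img > thr
  if (!.has_contrast(img, fg, cfg)) return(0L)
  lab <- label_components(fg)
  if (!any(lab > 0L)) return(0L)
  touching_roi <- setdiff(unique(lab[inroi]), 0L)
  sizes <- tabulate(lab)
  ids <- setdiff(which(sizes > 0L), touching_roi)
  sum(sizes[ids] >= cfg$min_spot_area & sizes[ids] <= cfg$max_spot_area)
}

#' Classify an embryo's tumor status
#'
#' No signal anywhere is `no_cells`; signal with fewer than `min_cells`
#' dispersed cells is a `localized` tumor (metastasis negative); at least
#' `min_cells` dispersed cells is `invaded` (metastasis positive).
#'
#' @param tumor_area tumor area in pixels (>= 0); vectorized.
#' @param dispersed dispersed-cell count (>= 0).
#' @param cfg a [metastasis_config()].
#' @return data frame with `status` (factor: `no_cells`, `localized`,
#'   `invaded`) and logical `metastasis_positive`.
#' @examples
#' classify_embryo(c(0, 5000, 5000, 5000), c(0, 0, 4, 6))
#' @export
classify_embryo <- function(tumor_area, dispersed, cfg = metastasis_config()) {
  stopifnot(all(tumor_area >= 0), all(dispersed >= 0))
  met <- dispersed >= cfg$min_cells
  status <- ifelse(met, "invaded",
                   ifelse(tumor_area > 0 | dispersed > 0, "localized",
                          "no_cells"))
  data.frame(status = factor(status,
                             levels = c("no_cells", "localized", "invaded")),
             metastasis_positive = met)
}

#' Cohort tumorigenicity and metastasis table
#'
#' Tabulates classified embryos per (cell line, genotype) group:
#' per-category counts, tumorigenicity % = 100 x localized / total injected,
#' and metastasis % with a configurable denominator (the published table's
#' denominators are not recoverable, so the default — embryos with any tumor
#' signal — is an explicit package choice). Percentages are rounded half-up
#' to one decimal; empty denominators give `NA`, never 0.
#'
#' @param phenotypes data frame with columns `cell_line`, `genotype` and
#'   `status` (as produced by [classify_embryo()]).
#' @param metastasis_denominator `"tumor_bearing"` (localized + invaded,
#'   default) or `"injected"` (all embryos in the group).
#' @return data frame with one row per (cell_line, genotype): `n`,
#'   `no_cells`, `localized`, `invaded`, `tumorigenicity_pct`,
#'   `metastasis_pct`.
#' @export
cohort_table <- function(phenotypes,
                         metastasis_denominator = c("tumor_bearing",
                                                    "injected")) {
  metastasis_denominator <- match.arg(metastasis_denominator)
  stopifnot(is.data.frame(phenotypes),
            all(c("cell_line", "genotype", "status") %in% names(phenotypes)))
  key <- paste(phenotypes$cell_line, phenotypes$genotype, sep = "\r")
  groups <- split(seq_len(nrow(phenotypes)), key)
  rows <- lapply(groups, function(idx) {
    st <- as.character(phenotypes$status[idx])
    n <- length(idx)
    loc <- sum(st == "localized")
    inv <- sum(st == "invaded")
    met_denom <- switch(metastasis_denominator,
                        tumor_bearing = loc + inv,
                        injected = n)
    data.frame(cell_line = phenotypes$cell_line[idx[1]],
               genotype = phenotypes$genotype[idx[1]],
               n = n, no_cells = sum(st == "no_cells"),
               localized = loc, invaded = inv,
               tumorigenicity_pct =
                 if (n > 0) round_half_up(100 * loc / n) else NA_real_,
               metastasis_pct =
                 if (met_denom > 0) round_half_up(100 * inv / met_denom)
                 else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "metastasis_denominator") <- metastasis_denominator
  out[order(out$cell_line, out$genotype), , drop = FALSE]
}

#' Read and write plain-text PGM (P2) grayscale images
#'
#' Minimal text-format image interchange: portable graymap, ASCII variant.
#'
#' @param path file path.
#' @return `read_image_pgm` returns a numeric intensity matrix.
#' @export
read_image_pgm <- function(path) {
  tokens <- scan(path, what = character(), quiet = TRUE,
                 comment.char = "#")
  if (tokens[1] != "P2") stop("not an ASCII PGM (P2) file", call. = FALSE)
  nc <- as.integer(tokens[2]); nr <- as.integer(tokens[3])
  vals <- as.numeric(tokens[-(1:4)])
  if (length(vals) != nr * nc) stop("corrupt PGM payload", call. = FALSE)
  matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
}

#' @param img numeric matrix of non-negative intensities.
#' @rdname read_image_pgm
#' @export
write_image_pgm <- function(img, path) {
  stopifnot(is.matrix(img), all(img >= 0))
  vals <- round(img)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)),
               as.character(max(vals, 1))), con)
  writeLines(apply(vals, 1, paste, collapse = " "), con)
  invisible(path)
}
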