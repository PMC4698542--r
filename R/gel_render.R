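#' Band layout geometry for rendered gel images
#'
#' Geometry of a rendered blot image: lanes run left to right (one per lane
#' id), proteins top to bottom (one band row per protein, as if the membrane
#' had been stripped and reprobed). Bands are drawn as 2-D Gaussian bumps
#' truncated to their rectangular ROI, so the background-corrected integral
#' over the ROI equals the band's raw density times the ROI width exactly.
#'
#' @param lane_width,band_height ROI extents in pixels.
#' @param lane_gap,row_gap gaps between adjacent ROIs in pixels (must be
#'   positive so ROIs never overlap).
#' @param margin image border around the outermost ROIs, in pixels. Must be
#'   large enough for the background frame used by [estimate_background()].
#' @param background constant background intensity level added everywhere.
#' @param sigma_frac Gaussian sigma as a fraction of the ROI extent, per axis.
#' @return a list of class `gel_geometry`.
#' @export
gel_geometry <- function(lane_width = 22L, band_height = 14L,
                         lane_gap = 10L, row_gap = 16L, margin = 24L,
                         background = 400, sigma_frac = c(x = 0.18, y = 0.18)) {
  stopifnot(lane_width >= 1, band_height >= 1, lane_gap >= 1, row_gap >= 1,
            margin >= 1, background >= 0, all(sigma_frac > 0))
  structure(list(lane_width = as.integer(lane_width),
                 band_height = as.integer(band_height),
                 lane_gap = as.integer(lane_gap),
                 row_gap = as.integer(row_gap),
                 margin = as.integer(margin),
                 background = background,
                 sigma_frac = sigma_frac),
            class = "gel_geometry")
}

#' Render one blot of a band table as a grayscale gel image
#'
#' Draws every band of the chosen blot as a truncated 2-D Gaussian intensity
#' bump inside its rectangular ROI, normalized so that the densitometry
#' contract (background-subtracted pixel sum divided by ROI width) recovers
#' the table's `raw_density` exactly, up to floating point. A constant
#' background level is added across the whole image. Intensities are kept as
#' doubles; [write_gel_tiff()] quantizes to 16 bit on disk.
#'
#' @param table a `band_table` (see [generate_table()]).
#' @param blot_id which blot to render.
#' @param geometry a [gel_geometry()].
#' @return a list with `image` (numeric matrix, rows = y), `rois` (data frame
#'   with columns `blot_id`, `protein`, `lane_id`, `x0`, `y0`, `width`,
#'   `height`; 0-based, half-open), and `background`.
#' @export
render_gel_image <- function(table, blot_id, geometry = gel_geometry()) {
  stopifnot(is.data.frame(table))
  rows <- table[table$blot_id == blot_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no bands for blot '", blot_id, "'")
  g <- geometry

  design <- attr(table, "design")
  proteins <- if (!is.null(design)) {
    intersect(design$proteins, unique(rows$protein))
  } else unique(rows$protein)
  lanes <- sort(unique(rows$lane_id))

  nx <- 2L * g$margin + length(lanes) * g$lane_width +
    (length(lanes) - 1L) * g$lane_gap
  ny <- 2L * g$margin + length(proteins) * g$band_height +
    (length(proteins) - 1L) * g$row_gap
  img <- matrix(g$background, nrow = ny, ncol = nx)

  rois <- data.frame(
    blot_id = blot_id,
    protein = rep(proteins, each = length(lanes)),
    lane_id = rep(lanes, times = length(proteins)),
    x0 = rep(g$margin + (seq_along(lanes) - 1L) * (g$lane_width + g$lane_gap),
             times = length(proteins)),
    y0 = rep(g$margin + (seq_along(proteins) - 1L) * (g$band_height + g$row_gap),
             each = length(lanes)),
    width = g$lane_width, height = g$band_height,
    stringsAsFactors = FALSE)
  if (rois_overlap(rois)) stop("geometry places overlapping ROIs")

  sx <- g$sigma_frac[["x"]] * g$lane_width
  sy <- g$sigma_frac[["y"]] * g$band_height
  key <- paste(rows$protein, rows$lane_id)
  dens <- stats::setNames(rows$raw_density, key)

  for (i in seq_len(nrow(rois))) {
    r <- rois[i, ]
    d <- dens[paste(r$protein, r$lane_id)]
    if (is.na(d)) next
    if (d == 0) next
    xs <- r$x0 + seq_len(r$width) - 1L
    ys <- r$y0 + seq_len(r$height) - 1L
    cx <- r$x0 + (r$width - 1) / 2
    cy <- r$y0 + (r$height - 1) / 2
    bump <- exp(-(outer((ys - cy)^2 / (2 * sy^2),
                        (xs - cx)^2 / (2 * sx^2), "+")))
    total <- d * r$width                       # densitometry divides by width
    img[ys + 1L, xs + 1L] <- img[ys + 1L, xs + 1L] + total * bump / sum(bump)
  }
  list(image = img, rois = rois, background = g$background)
}

#' Write / read a gel image as 16-bit grayscale TIFF
#'
#' Intensities are stored as 16-bit unsigned integers; values must lie in
#' `[0, 65535]`. Reading returns the integer intensities as a numeric matrix.
#'
#' @param image numeric matrix of intensities.
#' @param path file path.
#' @return `write_gel_tiff()` returns `path` invisibly; `read_gel_tiff()`
#'   returns a numeric matrix.
#' @export
write_gel_tiff <- function(image, path) {
  if (min(image) < 0 || max(image) > 65535) {
    stop("image intensities must lie in [0, 65535] for 16-bit storage")
  }
  tiff::writeTIFF(round(image) / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}

#' @rdname write_gel_tiff
#' @export
read_gel_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  round(img * 65535)
}
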