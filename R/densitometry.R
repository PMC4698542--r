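#' Band ROI constructor
#'
#' Rectangular band region of interest on a blot image. Coordinates are
#' 0-based with half-open extents: the ROI covers pixels `x0 .. x0+width-1`,
#' `y0 .. y0+height-1`.
#'
#' @param blot_id,protein,lane_id identifiers.
#' @param x0,y0 top-left pixel (0-based).
#' @param width,height extents in pixels (>= 1).
#' @return one-row data frame of class `band_roi`.
#' @export
band_roi <- function(blot_id, protein, lane_id, x0, y0, width, height) {
  stopifnot(width >= 1, height >= 1, x0 >= 0, y0 >= 0)
  structure(data.frame(blot_id = blot_id, protein = protein, lane_id = lane_id,
                       x0 = as.integer(x0), y0 = as.integer(y0),
                       width = as.integer(width), height = as.integer(height),
                       stringsAsFactors = FALSE),
            class = c("band_roi", "data.frame"))
}

roi_in_bounds <- function(image, roi) {
  roi$x0 >= 0 && roi$y0 >= 0 &&
    roi$x0 + roi$width <= ncol(image) && roi$y0 + roi$height <= nrow(image)
}

# pairwise rectangle intersection test over an ROI table
rois_overlap <- function(rois) {
  n <- nrow(rois)
  if (n < 2L) return(FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (rois$x0[i] < rois$x0[j] + rois$width[j] &&
          rois$x0[j] < rois$x0[i] + rois$width[i] &&
          rois$y0[i] < rois$y0[j] + rois$height[j] &&
          rois$y0[j] < rois$y0[i] + rois$height[i]) return(TRUE)
    }
  }
  FALSE
}

#' Estimate local background around a band ROI
#'
#' The background is the median intensity of the frame of pixels surrounding
#' the ROI (a border of width `margin` just outside the ROI), excluding any
#' pixel that falls inside another registered ROI. The median is robust to
#' bright specks in the surround.
#'
#' @param image numeric matrix (rows = y).
#' @param roi a one-row ROI data frame (see [band_roi()]).
#' @param margin frame width in pixels; the frame must fit inside the image.
#' @param exclude optional ROI table whose pixels are excluded from the frame
#'   (other bands on the same image).
#' @return scalar background intensity.
#' @export
estimate_background <- function(image, roi, margin = 3L, exclude = NULL) {
  margin <- as.integer(margin)
  stopifnot(margin >= 1L)
  x1 <- roi$x0 - margin; x2 <- roi$x0 + roi$width + margin - 1L
  y1 <- roi$y0 - margin; y2 <- roi$y0 + roi$height + margin - 1L
  if (x1 < 0 || y1 < 0 || x2 >= ncol(image) || y2 >= nrow(image)) {
    stop("background frame extends outside the image for ROI at (",
         roi$x0, ",", roi$y0, ")")
  }
  xs <- x1:x2; ys <- y1:y2
  in_rect <- function(px, py, r) {
    px >= r$x0 & px < r$x0 + r$width & py >= r$y0 & py < r$y0 + r$height
  }
  px <- rep(xs, each = length(ys))
  py <- rep(ys, times = length(xs))
  keep <- !in_rect(px, py, roi)
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    for (j in seq_len(nrow(exclude))) {
      keep <- keep & !in_rect(px, py, exclude[j, ])
    }
  }
  if (!any(keep)) {
    stop("no usable background pixels around ROI at (", roi$x0, ",", roi$y0,
         "): frame fully excluded by neighbouring ROIs")
  }
  stats::median(image[cbind(py[keep] + 1L, px[keep] + 1L)])
}

#' Quantify one band: background-subtracted, width-normalized density
#'
#' Density is the sum over ROI pixels of `max(pixel - background, 0)`,
#' divided by the ROI width (the lane-width direction), to control for
#' variations in lane width. Negative residuals are clipped at zero per
#' pixel, so the result is non-negative and non-increasing in the background
#' estimate.
#'
#' @inheritParams estimate_background
#' @param background background intensity level (>= 0).
#' @return scalar raw density.
#' @export
quantify_band <- function(image, roi, background) {
  stopifnot(background >= 0)
  if (!roi_in_bounds(image, roi)) {
    stop("ROI at (", roi$x0, ",", roi$y0, ") is out of image bounds")
  }
  sub <- image[(roi$y0 + 1L):(roi$y0 + roi$height),
               (roi$x0 + 1L):(roi$x0 + roi$width), drop = FALSE]
  sum(pmax(sub - background, 0)) / roi$width
}

#' Quantify all bands on a blot image
#'
#' Runs [estimate_background()] (excluding all other ROIs from each band's
#' surround) then [quantify_band()] for every ROI, and joins lane identities
#' from `lane_map`. Output row order is canonical — sorted by protein then
#' lane — regardless of the input ROI order.
#'
#' @param image numeric matrix.
#' @param rois ROI table: columns `blot_id`, `protein`, `lane_id`, `x0`,
#'   `y0`, `width`, `height`. ROIs must not overlap.
#' @param lane_map data frame with columns `lane_id`, `animal_id`, `group`
#'   mapping every lane on the image.
#' @param margin background frame width in pixels.
#' @return a `band_table` data frame with columns `blot_id`, `lane_id`,
#'   `animal_id`, `group`, `protein`, `raw_density`, `background_level`.
#' @export
quantify_blot <- function(image, rois, lane_map, margin = 3L) {
  stopifnot(is.data.frame(rois), is.data.frame(lane_map))
  if (nrow(rois) == 0L) {
    return(structure(data.frame(blot_id = character(), lane_id = character(),
                                animal_id = character(), group = character(),
                                protein = character(), raw_density = numeric(),
                                background_level = numeric(),
                                stringsAsFactors = FALSE),
                     class = c("band_table", "data.frame")))
  }
  if (rois_overlap(rois)) stop("ROIs overlap; band regions must be disjoint")
  unmapped <- setdiff(unique(rois$lane_id), lane_map$lane_id)
  if (length(unmapped) > 0L) {
    stop("unmapped lane(s): ", paste(unmapped, collapse = ", "))
  }
  rois <- rois[order(rois$protein, rois$lane_id), , drop = FALSE]
  m <- match(rois$lane_id, lane_map$lane_id)
  bg <- numeric(nrow(rois))
  dens <- numeric(nrow(rois))
  for (i in seq_len(nrow(rois))) {
    bg[i] <- estimate_background(image, rois[i, ], margin = margin,
                                 exclude = rois[-i, , drop = FALSE])
    dens[i] <- quantify_band(image, rois[i, ], bg[i])
  }
  out <- data.frame(blot_id = rois$blot_id, lane_id = rois$lane_id,
                    animal_id = lane_map$animal_id[m],
                    group = lane_map$group[m],
                    protein = rois$protein,
                    raw_density = dens, background_level = bg,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("band_table", "data.frame")
  out
}
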