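# Otsu threshold on an arbitrary-range intensity matrix.
otsu_threshold <- function(img) {
  mx <- max(img)
  if (mx <= 0) return(Inf)
  EBImage::otsu(EBImage::Image(img / mx), range = c(0, 1)) * mx
}

#' Manders pixel co-localization coefficients
#'
#' Pixel-presence Manders coefficients between two channels: the G
#' coefficient is the percentage of green-positive pixels that are also
#' red-positive, and R the converse. Channels are binarized at the given
#' thresholds (Otsu per channel by default). An intensity-weighted
#' variant of the original coefficients is available via
#' `weighted = TRUE`.
#'
#' @param green,red Background-subtracted intensity matrices of equal
#'   shape.
#' @param thr_g,thr_r Channel thresholds; `NULL` uses Otsu.
#' @param weighted Use intensity-weighted coefficients instead of pixel
#'   counts.
#' @return List with `manders_g` and `manders_r`, percentages in
#'   \[0, 100\]; `NA` with a warning when a channel has no positive
#'   pixels.
#' @export
manders <- function(green, red, thr_g = NULL, thr_r = NULL, weighted = FALSE) {
  if (!all(dim(green) == dim(red)))
    invalid_argument("channel images must have the same shape")
  thr_g <- thr_g %||% otsu_threshold(green)
  thr_r <- thr_r %||% otsu_threshold(red)
  gm <- green > thr_g
  rm_ <- red > thr_r
  mg <- mr <- NA_real_
  if (weighted) {
    sg <- sum(green[gm])
    sr <- sum(red[rm_])
    if (sg > 0) mg <- 100 * sum(green[gm & rm_]) / sg
    if (sr > 0) mr <- 100 * sum(red[gm & rm_]) / sr
  } else {
    ng <- sum(gm)
    nr <- sum(rm_)
    if (ng > 0) mg <- 100 * sum(gm & rm_) / ng
    if (nr > 0) mr <- 100 * sum(gm & rm_) / nr
  }
  if (is.na(mg)) warning("no green-positive pixels: Manders G undefined")
  if (is.na(mr)) warning("no red-positive pixels: Manders R undefined")
  list(manders_g = mg, manders_r = mr)
}

#' Binarize an image and label its objects
#'
#' Reproduces a binary object-detection chain: threshold (Otsu default),
#' hole filling, median filtering, optional watershed splitting of merged
#' blobs, and connected-component labeling.
#'
#' @param img Intensity matrix.
#' @param thr Binarization threshold; `NULL` uses Otsu.
#' @param median_size Median filter radius in pixels (window
#'   `2*size + 1`; default 1, i.e. 3 x 3).
#' @param watershed Split touching blobs by watershed on the distance
#'   map.
#' @param fill_holes Fill holes in the binary mask.
#' @return Integer label matrix (0 = background) with attribute
#'   `watershed_used`.
#' @export
binarize_objects <- function(img, thr = NULL, median_size = 1,
                             watershed = TRUE, fill_holes = TRUE) {
  thr <- thr %||% otsu_threshold(img)
  bw <- EBImage::Image((img > thr) * 1)
  if (fill_holes) bw <- EBImage::fillHull(bw)
  if (median_size > 0 && any(bw > 0))
    bw <- EBImage::Image((EBImage::medianFilter(bw, median_size) > 0.5) * 1)
  lab <- if (watershed && any(bw > 0)) {
    EBImage::watershed(EBImage::distmap(bw))
  } else {
    EBImage::bwlabel(bw)
  }
  out <- EBImage::imageData(lab)
  storage.mode(out) <- "integer"
  attr(out, "watershed_used") <- isTRUE(watershed)
  out
}

#' Object-based co-localization percentage
#'
#' Percentage of objects in the first label image containing at least one
#' pixel that overlaps an object in the second label image:
#' `100 * # objects co-localized(1|2) / total # objects(1)`.
#'
#' @param lab1,lab2 Integer label matrices of equal shape (e.g. from
#'   [binarize_objects()]).
#' @return Percentage in \[0, 100\], with attributes `n_objects_1`,
#'   `n_objects_2`, `n_colocalized`.
#' @export
object_colocalization <- function(lab1, lab2) {
  if (!all(dim(lab1) == dim(lab2)))
    invalid_argument("label images must have the same shape")
  n1 <- max(lab1)
  if (n1 < 1) undefined_result("no objects in the first image")
  fg <- lab1 > 0
  ids <- lab1[fg]
  hit <- (lab2 > 0)[fg]
  co <- tapply(hit, ids, any)
  out <- 100 * sum(co) / n1
  attr(out, "n_objects_1") <- as.integer(n1)
  attr(out, "n_objects_2") <- as.integer(max(lab2))
  attr(out, "n_colocalized") <- as.integer(sum(co))
  out
}
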