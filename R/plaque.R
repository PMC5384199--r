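#' Segment plaques within a region mask
#'
#' Thresholds a grayscale histology image inside a binary region mask.
#' Default method computes Otsu's threshold from the in-region pixel
#' intensities only; a fixed threshold can be supplied instead. The
#' returned mask is always a subset of the region mask. The threshold used
#' is attached for reproducibility.
#'
#' @param image Numeric matrix, grayscale intensities in `[0, 1]`.
#' @param region_mask Logical (or 0/1) matrix, same shape; `TRUE` = inside
#'   the region.
#' @param method `"otsu"` (within-region Otsu, default) or `"fixed"`.
#' @param threshold Fixed threshold in `[0, 1]` (required for `"fixed"`).
#' @param min_blob Minimum connected-component size in pixels (default 0:
#'   no size filter).
#' @return Logical plaque mask with attributes `threshold` and `method`.
#' @export
segment_plaques <- function(image, region_mask,
                            method = c("otsu", "fixed"), threshold = NULL,
                            min_blob = 0) {
  method <- match.arg(method)
  image <- as.matrix(image)
  region_mask <- as.matrix(region_mask) > 0
  if (!identical(dim(image), dim(region_mask)))
    stop("image and region mask have different shapes")
  if (!any(region_mask)) stop("region mask is empty")
  vals <- image[region_mask]
  thr <- if (method == "fixed") {
    if (is.null(threshold)) stop("fixed method needs a threshold")
    threshold
  } else {
    if (min(vals) == max(vals)) {
      # constant region: nothing to separate
      max(vals) + 1
    } else {
      EBImage::otsu(EBImage::Image(vals, dim = c(length(vals), 1)),
                    range = c(0, 1))
    }
  }
  mask <- image > thr & region_mask
  if (min_blob > 0 && any(mask)) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1, dim = dim(mask)))
    sizes <- table(as.integer(lab)[as.integer(lab) > 0])
    keep <- as.integer(names(sizes)[sizes >= min_blob])
    mask <- matrix(as.integer(lab) %in% keep, nrow(mask), ncol(mask))
  }
  attr(mask, "threshold") <- as.numeric(thr)
  attr(mask, "method") <- method
  mask
}

#' Plaque burden as an area percentage
#'
#' `100 * (plaque pixel count / region pixel count)` — the stained area as
#' a percentage of the region area.
#'
#' @param plaque_mask Logical plaque mask (subset of the region mask).
#' @param region_mask Logical region mask with nonzero area.
#' @return Burden in percent, in `[0, 100]`.
#' @export
plaque_burden <- function(plaque_mask, region_mask) {
  plaque_mask <- as.matrix(plaque_mask) > 0
  region_mask <- as.matrix(region_mask) > 0
  if (!identical(dim(plaque_mask), dim(region_mask)))
    stop("masks have different shapes")
  area <- sum(region_mask)
  if (area == 0) stop("region mask has zero area")
  if (any(plaque_mask & !region_mask))
    stop("plaque mask extends outside the region mask")
  100 * sum(plaque_mask) / area
}

#' Quantify plaque burden for a set of images
#'
#' Convenience wrapper running [segment_plaques()] + [plaque_burden()] over
#' a list of (image, region mask) pairs.
#'
#' @param images Named list; each element a list with `image` and
#'   `region_mask` (and optionally `animal`, `region`).
#' @param ... Passed to [segment_plaques()].
#' @return Data frame `animal`, `region`, `burden`, `threshold`.
#' @export
plaque_burden_table <- function(images, ...) {
  out <- do.call(rbind, lapply(seq_along(images), function(i) {
    it <- images[[i]]
    m <- segment_plaques(it$image, it$region_mask, ...)
    data.frame(animal = if (!is.null(it$animal)) it$animal else
                 names(images)[i] %||% as.character(i),
               region = it$region %||% NA_character_,
               burden = plaque_burden(m, it$region_mask),
               threshold = attr(m, "threshold"))
  }))
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a grayscale histology image (PNG or TIFF)
#'
#' Reads the file by extension and collapses color channels to grayscale
#' by averaging. Intensities are returned in `[0, 1]`.
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @return Numeric matrix of intensities.
#' @export
read_histology_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = tiff::readTIFF(path),
                stop("unsupported image format: .", ext,
                     " (expected png/tif/tiff)"))
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]),
                                              drop = FALSE], c(1, 2), mean)
  img
}

#' Write a grayscale image or binary mask (PNG or TIFF)
#'
#' @param image Numeric matrix in `[0, 1]` or logical mask.
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_histology_image <- function(image, path) {
  m <- as.matrix(image) * 1
  if (min(m) < 0 || max(m) > 1)
    stop("image intensities must lie in [0, 1]")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(m, path),
         tif = ,
         tiff = tiff::writeTIFF(m, path),
         stop("unsupported image format: .", ext,
              " (expected png/tif/tiff)"))
  invisible(path)
}
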