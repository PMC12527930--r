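#' Virtual-quadrat image of a fossil reef outcrop
#'
#' Wraps a rectangular intensity raster representing a ~0.5 x 0.5 m virtual
#' quadrat delineated on an outcrop face, in which primary framework-building
#' coral clasts appear bright and the pore/matrix space dark. Rasters are
#' either greyscale (0-255) or binary (0/1 framework masks).
#'
#' @param pixels Numeric matrix; greyscale intensities in `[0, 255]` or a
#'   binary 0/1 mask.
#' @param quadrat_side_m Physical side length of the quadrat in metres
#'   (default 0.5).
#' @param class_label Assemblage class of the pictured deposit, or
#'   `"unclassified"`.
#' @param source_id Free-text provenance.
#' @return Object of class `quadrat_image`.
#' @export
quadrat_image <- function(pixels, quadrat_side_m = 0.5,
                          class_label = "unclassified", source_id = "") {
  if (!is.matrix(pixels) || !is.numeric(pixels) || !length(pixels)) {
    stop("pixels must be a non-empty numeric matrix")
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255)) {
    stop("pixel intensities must be finite and in [0, 255]")
  }
  if (quadrat_side_m <= 0) stop("quadrat_side_m must be positive")
  structure(
    list(pixels = pixels, quadrat_side_m = quadrat_side_m,
         class_label = class_label, source_id = source_id),
    class = "quadrat_image"
  )
}

#' @export
print.quadrat_image <- function(x, ...) {
  cat(sprintf("Virtual quadrat %dx%d px, %.2f m side, class \"%s\"%s\n",
              nrow(x$pixels), ncol(x$pixels), x$quadrat_side_m, x$class_label,
              if (is_binary_quadrat(x)) " [binary]" else ""))
  invisible(x)
}

#' Is a quadrat image a binary framework mask?
#' @param image A [quadrat_image()].
#' @return TRUE when all pixels are 0 or 1.
#' @export
is_binary_quadrat <- function(image) {
  stopifnot(inherits(image, "quadrat_image"))
  all(image$pixels %in% c(0, 1))
}

#' Binarize a greyscale quadrat into a framework mask
#'
#' Pixels at or above the threshold are mapped to framework (1), the rest to
#' pore/matrix (0). When no threshold is supplied, Otsu's histogram threshold
#' is computed on the quadrat (via \pkg{EBImage}); a constant-intensity image
#' has no separable histogram and is rejected. Already-binary masks pass
#' through unchanged, so the operation is idempotent.
#'
#' @param image A [quadrat_image()], greyscale or binary.
#' @param threshold Optional intensity cut in `[0, 255]`; overrides the
#'   automatic threshold (useful to reproduce a manual thresholding choice).
#' @return A binary [quadrat_image()].
#' @export
binarize_quadrat <- function(image, threshold = NULL) {
  stopifnot(inherits(image, "quadrat_image"))
  if (is_binary_quadrat(image)) return(image)
  px <- image$pixels
  if (is.null(threshold)) {
    if (diff(range(px)) == 0) stop("degenerate histogram: constant-intensity image")
    threshold <- 255 * EBImage::otsu(px / 255, range = c(0, 1), levels = 256)
  } else {
    if (threshold < 0 || threshold > 255) stop("threshold outside intensity range")
  }
  out <- image
  out$pixels <- (px >= threshold) + 0
  out
}

#' Framework fraction and stacking porosity of a binary mask
#'
#' The framework fraction is the share of mask pixels classed as framework;
#' stacking porosity is its complement, `1 - framework_fraction`: the fraction
#' of the outcrop face occupied by pore space and sediment matrix rather than
#' primary coral framework.
#'
#' @param mask A binary [quadrat_image()] (see [binarize_quadrat()]).
#' @return A list of class `porosity_estimate` with `framework_fraction`,
#'   `porosity` and `n_pixels`.
#' @export
framework_porosity <- function(mask) {
  stopifnot(inherits(mask, "quadrat_image"))
  if (!is_binary_quadrat(mask)) stop("mask must be binary; run binarize_quadrat() first")
  f <- mean(mask$pixels == 1)
  structure(
    list(framework_fraction = f, porosity = 1 - f, n_pixels = length(mask$pixels),
         class_label = mask$class_label, source_id = mask$source_id),
    class = "porosity_estimate"
  )
}

#' @export
print.porosity_estimate <- function(x, ...) {
  cat(sprintf("Porosity %.3f (framework %.3f over %d px), class \"%s\"\n",
              x$porosity, x$framework_fraction, x$n_pixels, x$class_label))
  invisible(x)
}

#' Summarise porosity estimates by assemblage class
#'
#' Computes per-class mean and sample (n-1) standard deviation of porosity,
#' plus the pooled `"mixed"` value: the unweighted mean of the class means
#' (not of all images), so classes with many images do not dominate the
#' pooled figure.
#'
#' @param estimates Either a list of `porosity_estimate` objects carrying
#'   class labels, or a data.frame with columns `class_label` and `porosity`.
#' @return List with `classes` (data.frame: `class_label`, `mean_porosity`,
#'   `sd_porosity` — `NA` for single-image classes — and `n_images`) and
#'   `pooled_mean` (the mixed-assemblage porosity).
#' @export
summarize_classes <- function(estimates) {
  if (is.data.frame(estimates)) {
    df <- estimates[c("class_label", "porosity")]
  } else if (is.list(estimates) && length(estimates) &&
             all(vapply(estimates, inherits, logical(1), "porosity_estimate"))) {
    df <- data.frame(
      class_label = vapply(estimates, `[[`, character(1), "class_label"),
      porosity = vapply(estimates, `[[`, numeric(1), "porosity")
    )
  } else {
    stop("estimates must be porosity_estimate objects or a class_label/porosity data.frame")
  }
  if (!nrow(df)) stop("no porosity estimates supplied")
  if (anyNA(df$porosity) || any(df$porosity < 0) || any(df$porosity > 1)) {
    stop("porosities must lie in [0, 1]")
  }
  sp <- split(df$porosity, df$class_label)
  classes <- data.frame(
    class_label = names(sp),
    mean_porosity = vapply(sp, mean, numeric(1)),
    sd_porosity = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else NA_real_,
                         numeric(1)),
    n_images = vapply(sp, length, integer(1)),
    row.names = NULL
  )
  list(classes = classes, pooled_mean = mean(classes$mean_porosity))
}

#' Read a quadrat image from a PNG or TIFF file
#'
#' Greyscale (or RGB, converted by luminance average) images are rescaled to
#' 0-255 intensities.
#'
#' @param path File path ending in `.png` or `.tif`/`.tiff`.
#' @param ... Passed to [quadrat_image()].
#' @return A [quadrat_image()].
#' @export
read_quadrat_image <- function(path, ...) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE)) stop("package `tiff` required")
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext)
  )
  if (length(dim(arr)) == 3) arr <- apply(arr[, , 1:min(3, dim(arr)[3])], c(1, 2), mean)
  quadrat_image(round(arr * 255), source_id = basename(path), ...)
}

#' Write a binary framework mask as a PNG (0/255)
#'
#' @param mask Binary [quadrat_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quadrat_mask <- function(mask, path) {
  stopifnot(inherits(mask, "quadrat_image"))
  if (!is_binary_quadrat(mask)) stop("mask must be binary")
  png::writePNG(mask$pixels, path)
  invisible(path)
}
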