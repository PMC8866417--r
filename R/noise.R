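# Noise-model calibration and verification.

#' Background region specification
#'
#' A set of rectangular patches asserted to lie outside the object support,
#' used to pool background pixels for Rayleigh fitting.
#'
#' @param patches List of length-4 integer vectors
#'   `c(row_start, row_end, col_start, col_end)` (0-based, half-open, so
#'   `c(0, 8, 0, 8)` is the top-left 8 x 8 corner).
#' @param grid_size Image side length the patches refer to.
#' @return A `background_regions` object.
#' @export
background_regions <- function(patches, grid_size) {
  if (length(patches) == 0) stop_field("patches", "must be non-empty")
  for (p in patches) {
    if (length(p) != 4) stop_field("patches", "each patch needs 4 bounds")
    if (p[1] < 0 || p[3] < 0 || p[2] > grid_size || p[4] > grid_size ||
        p[2] <= p[1] || p[4] <= p[3]) {
      stop_field("patches", sprintf("patch (%s) out of bounds for grid %d",
                                    paste(p, collapse = ","), grid_size))
    }
  }
  structure(list(patches = patches, grid_size = as.integer(grid_size)),
            class = "background_regions")
}

#' Whole-image background region
#' @param grid_size Image side length.
#' @export
whole_image_region <- function(grid_size) {
  background_regions(list(c(0, grid_size, 0, grid_size)), grid_size)
}

#' Four corner patches as background
#' @param grid_size Image side length.
#' @param patch Side length of each corner patch.
#' @export
corner_regions <- function(grid_size, patch = grid_size %/% 8) {
  g <- grid_size; p <- patch
  background_regions(list(c(0, p, 0, p), c(0, p, g - p, g),
                          c(g - p, g, 0, p), c(g - p, g, g - p, g)), g)
}

extract_region_pixels <- function(img, regions) {
  unlist(lapply(regions$patches, function(p) {
    img[(p[1] + 1):p[2], (p[3] + 1):p[4]]
  }), use.names = FALSE)
}

#' Maximum-likelihood Rayleigh scale estimate
#'
#' For samples `x ~ Rayleigh(sigma)` the MLE is
#' `sqrt(mean(x^2) / 2)`; permutation-invariant by construction.
#'
#' @param samples Nonnegative values (at least 2).
#' @return The scale estimate (single number).
#' @export
fit_rayleigh_sigma <- function(samples) {
  if (length(samples) < 2) stop_field("samples", "need at least 2 values")
  if (any(!is.finite(samples)) || any(samples < 0)) {
    stop_field("samples", "must be finite and nonnegative")
  }
  sqrt(mean(samples^2) / 2)
}

#' Estimate the k-space noise standard deviation from magnitude images
#'
#' Pools background pixels (outside the object support) across magnitude
#' images, fits a Rayleigh distribution by maximum likelihood, and rescales
#' the image-domain scale to the per-component k-space standard deviation
#' (`sigma_kspace = sigma_Rayleigh * N` under the package DFT convention).
#' This is the calibration loop used to specify an unknown measurement-noise
#' model from experimental-style magnitude data.
#'
#' @param magnitude_images An `object_ensemble` of magnitude reconstructions
#'   (or a 3D array).
#' @param regions A [background_regions()] specification.
#' @return A `noise_estimate`: list with `sigma` (k-space, per component),
#'   `scale = "kspace_per_component"`, `n_pixels_used` and `method`.
#' @export
estimate_kspace_noise <- function(magnitude_images, regions) {
  imgs <- if (inherits(magnitude_images, "object_ensemble")) {
    magnitude_images$images
  } else {
    magnitude_images
  }
  n <- dim(imgs)[1]
  if (dim(imgs)[2] != n) stop_field("magnitude_images", "images must be square")
  if (regions$grid_size != n) stop_field("regions", "grid size mismatch")
  px <- unlist(lapply(seq_len(dim(imgs)[3]), function(i) {
    extract_region_pixels(imgs[, , i], regions)
  }), use.names = FALSE)
  sigma_img <- if (all(px == 0)) 0 else fit_rayleigh_sigma(px)
  structure(list(sigma = sigma_img * n, scale = "kspace_per_component",
                 n_pixels_used = length(px), method = "rayleigh_mle_pooled"),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> sigma = %.6g (%s, %s; %d px)\n",
              x$sigma, x$scale, x$method, x$n_pixels_used))
  invisible(x)
}

# Finest-scale diagonal Haar detail coefficients of one image.
haar_diagonal_detail <- function(img) {
  n <- nrow(img)
  a <- img[seq(1, n, 2), seq(1, n, 2)]
  b <- img[seq(2, n, 2), seq(1, n, 2)]
  cc <- img[seq(1, n, 2), seq(2, n, 2)]
  d <- img[seq(2, n, 2), seq(2, n, 2)]
  (a - b - cc + d) / 2
}

#' Blind estimate of the white-noise standard deviation in images
#'
#' Robust wavelet-domain estimator: the median absolute deviation of the
#' finest diagonal Haar detail coefficients divided by 0.6745 (the Gaussian
#' consistency constant), per image, averaged over the ensemble.  Smooth
#' image content contributes almost nothing to the diagonal detail band, so
#' the estimate isolates the white-noise floor; it is exactly
#' scale-equivariant.
#'
#' @param images An `object_ensemble`, 3D array, or single image matrix.
#' @return A `noise_estimate` with `scale = "image_domain"`; the `percent`
#'   element reports the estimate relative to a `[0, 1]` intensity range.
#'   Constant images yield 0 with `degenerate = TRUE`.
#' @export
estimate_image_noise_std <- function(images) {
  imgs <- if (inherits(images, "object_ensemble")) {
    images$images
  } else if (is.matrix(images)) {
    array(images, dim = c(dim(images), 1))
  } else {
    images
  }
  n_img <- dim(imgs)[3]
  per_image <- vapply(seq_len(n_img), function(i) {
    d <- haar_diagonal_detail(imgs[, , i])
    stats::median(abs(d)) / 0.6745
  }, numeric(1))
  degenerate <- vapply(seq_len(n_img), function(i) {
    diff(range(imgs[, , i])) == 0
  }, logical(1))
  sigma <- mean(per_image)
  structure(list(sigma = sigma, percent = 100 * sigma,
                 scale = "image_domain", n_pixels_used = length(imgs),
                 per_image = per_image,
                 degenerate = all(degenerate),
                 method = "haar_diagonal_mad"),
            class = "noise_estimate")
}

#' Serialize a noise estimate as a JSON record
#' @param x A `noise_estimate`.
#' @param path Output path; if `NULL`, returns the JSON string.
#' @export
noise_estimate_json <- function(x, path = NULL) {
  rec <- x[c("sigma", "scale", "n_pixels_used", "method")]
  if (!is.null(x$percent)) rec$percent <- x$percent
  if (is.null(path)) {
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA))
  } else {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
  }
}
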