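#' Configuration for the lumpy-background object model
#'
#' The lumpy background is the classic stochastic object model for assessing
#' imaging systems with background-known-statistically detection tasks: each
#' realization superposes a Poisson-distributed number of Gaussian "lumps" at
#' uniformly random (sub-pixel) positions on a square grid, plus a constant
#' offset.  With periodic boundary handling and no normalization the process
#' is strictly stationary, so its mean and autocovariance are available in
#' closed form ([lumpy_autocovariance()]), which makes the model a sharp
#' oracle for downstream statistical machinery.
#'
#' @param grid_size Image side length in pixels; a power of two, at least 4.
#' @param mean_lump_count Expected number of lumps per image (Poisson mean).
#' @param lump_amplitude Peak intensity of a single lump.
#' @param lump_width Gaussian profile standard deviation, in pixels.
#' @param dc_offset Constant added to every pixel.
#' @param boundary `"periodic"` evaluates lump profiles on the torus (exactly
#'   stationary); `"truncated"` evaluates them on the plane and clips at the
#'   image edge.
#' @param normalize `"none"` keeps raw intensities; `"per_image_minmax"`
#'   rescales each image to `[0, 1]` (destroys stationarity; recorded in the
#'   image metadata).
#' @return An object of class `lumpy_config`.
#' @examples
#' cfg <- lumpy_config(grid_size = 32, mean_lump_count = 25)
#' img <- sample_lumpy(cfg, seed = 1)
#' @export
lumpy_config <- function(grid_size = 32, mean_lump_count = 25,
                         lump_amplitude = 1, lump_width = 4,
                         dc_offset = 0,
                         boundary = c("periodic", "truncated"),
                         normalize = c("none", "per_image_minmax")) {
  boundary <- match.arg(boundary)
  normalize <- match.arg(normalize)
  if (!is.numeric(grid_size) || length(grid_size) != 1 || grid_size < 4 ||
      !is_power_of_two(grid_size)) {
    stop_field("grid_size", "must be a power of two >= 4")
  }
  if (!is.numeric(mean_lump_count) || mean_lump_count <= 0) {
    stop_field("mean_lump_count", "must be > 0")
  }
  if (!is.numeric(lump_width) || lump_width <= 0) {
    stop_field("lump_width", "must be > 0")
  }
  if (!is.numeric(lump_amplitude) || length(lump_amplitude) != 1) {
    stop_field("lump_amplitude", "must be a number")
  }
  if (!is.numeric(dc_offset) || length(dc_offset) != 1) {
    stop_field("dc_offset", "must be a number")
  }
  structure(
    list(grid_size = as.integer(grid_size),
         mean_lump_count = mean_lump_count,
         lump_amplitude = lump_amplitude,
         lump_width = lump_width,
         dc_offset = dc_offset,
         boundary = boundary,
         normalize = normalize),
    class = "lumpy_config"
  )
}

#' @export
print.lumpy_config <- function(x, ...) {
  cat(sprintf(
    "<lumpy_config> %dx%d, E[lumps]=%g, amp=%g, width=%g px, dc=%g, %s boundary, normalize=%s\n",
    x$grid_size, x$grid_size, x$mean_lump_count, x$lump_amplitude,
    x$lump_width, x$dc_offset, x$boundary, x$normalize))
  invisible(x)
}

# Gaussian lump evaluated on the pixel grid for a continuous center,
# with optional periodic wrapping of the distance.
lump_profile_1d <- function(coords, center, width, n, periodic) {
  d <- abs(coords - center)
  if (periodic) d <- pmin(d, n - d)
  exp(-d^2 / (2 * width^2))
}

#' Sample one lumpy-background object
#'
#' Draws `N ~ Poisson(mean_lump_count)`, places `N` isotropic Gaussian lumps
#' at continuous uniform positions, sums them on the pixel grid and adds the
#' DC offset.  The result is a pure function of `(config, seed)`.
#'
#' @param config A [lumpy_config()].
#' @param seed Integer seed; the same `(config, seed)` pair always returns a
#'   bitwise-identical image.
#' @return A `grid_size` x `grid_size` numeric matrix with a `meta` attribute
#'   recording the configuration and seed.
#' @export
sample_lumpy <- function(config, seed) {
  if (!inherits(config, "lumpy_config")) {
    stop_field("config", "must be a lumpy_config")
  }
  n <- config$grid_size
  periodic <- config$boundary == "periodic"
  coords <- seq_len(n) - 1
  img <- with_seed(seed, {
    k <- stats::rpois(1, config$mean_lump_count)
    acc <- matrix(0, n, n)
    if (k > 0) {
      cx <- stats::runif(k, 0, n)
      cy <- stats::runif(k, 0, n)
      for (i in seq_len(k)) {
        acc <- acc + config$lump_amplitude *
          outer(lump_profile_1d(coords, cx[i], config$lump_width, n, periodic),
                lump_profile_1d(coords, cy[i], config$lump_width, n, periodic))
      }
    }
    acc
  })
  img <- img + config$dc_offset
  if (config$normalize == "per_image_minmax") {
    rng <- range(img)
    if (rng[2] > rng[1]) img <- (img - rng[1]) / (rng[2] - rng[1])
  }
  attr(img, "meta") <- list(generator = "lumpy", seed = seed, config = unclass(config))
  img
}

#' Analytic autocovariance of the periodic lumpy model
#'
#' For the stationary (periodic, unnormalized) lumpy process the
#' autocovariance at lag `(di, dj)` is
#' `mean_lump_count / grid_size^2` times the circular autocorrelation of the
#' single-lump profile.  Returned as a full lag grid with lag `(0, 0)` at
#' entry `[1, 1]`.
#'
#' @param config A [lumpy_config()] with `boundary = "periodic"` and
#'   `normalize = "none"`.
#' @return A `grid_size` x `grid_size` matrix of covariances indexed by lag.
#' @export
lumpy_autocovariance <- function(config) {
  if (!inherits(config, "lumpy_config")) stop_field("config", "must be a lumpy_config")
  if (config$boundary != "periodic" || config$normalize != "none") {
    stop("analytic autocovariance requires boundary='periodic' and normalize='none'",
         call. = FALSE)
  }
  n <- config$grid_size
  coords <- seq_len(n) - 1
  prof <- config$lump_amplitude *
    outer(lump_profile_1d(coords, 0, config$lump_width, n, TRUE),
          lump_profile_1d(coords, 0, config$lump_width, n, TRUE))
  # circular autocorrelation via the DFT
  acor <- Re(stats::fft(Mod(stats::fft(prof))^2, inverse = TRUE)) / n^2
  config$mean_lump_count / n^2 * acor
}

#' Analytic stationary mean of the periodic lumpy model
#'
#' @param config A [lumpy_config()] with periodic boundary and no
#'   normalization.
#' @return The common expected value of every pixel.
#' @export
lumpy_mean <- function(config) {
  if (config$boundary != "periodic" || config$normalize != "none") {
    stop("analytic mean requires boundary='periodic' and normalize='none'",
         call. = FALSE)
  }
  n <- config$grid_size
  coords <- seq_len(n) - 1
  prof <- config$lump_amplitude *
    outer(lump_profile_1d(coords, 0, config$lump_width, n, TRUE),
          lump_profile_1d(coords, 0, config$lump_width, n, TRUE))
  config$mean_lump_count * sum(prof) / n^2 + config$dc_offset
}

#' Compact Gaussian signal image for detection tasks
#'
#' Builds the signal-present perturbation `s`: a small Gaussian blob of the
#' given amplitude and width, truncated to a compact support disk.
#'
#' @param grid_size Image side length (matching the objects).
#' @param center Length-2 vector of pixel coordinates (1-based, row/col).
#' @param amplitude Peak signal amplitude.
#' @param width Gaussian width (standard deviation) in pixels.
#' @param support_radius Pixels beyond this distance from the center are
#'   exactly zero; defaults to `3 * width`.
#' @return A `grid_size` x `grid_size` matrix of class `signal_image` (zero
#'   outside the support), with the profile parameters attached.
#' @export
gaussian_signal <- function(grid_size, center = (grid_size / 2) + c(1, 1),
                            amplitude = 0.2, width = 1.5,
                            support_radius = 3 * width) {
  if (length(center) != 2) stop_field("center", "must have two coordinates")
  coords <- seq_len(grid_size)
  d2 <- outer((coords - center[1])^2, (coords - center[2])^2, "+")
  s <- amplitude * exp(-d2 / (2 * width^2))
  s[d2 > support_radius^2] <- 0
  if (any(s < 0)) stop_field("amplitude", "signal must be nonnegative")
  structure(s, class = c("signal_image", "matrix"),
            center = center, amplitude = amplitude, width = width)
}

#' Add a signal to an object (signal-present hypothesis)
#'
#' @param f Object image (square matrix).
#' @param s Signal image of the same size.
#' @return The pixelwise sum `f + s` as a plain matrix.
#' @export
insert_signal <- function(f, s) {
  assert_square_image(f, "f")
  if (!all(dim(f) == dim(s))) {
    stop("signal and object grids differ in size", call. = FALSE)
  }
  out <- unclass(f) + unclass(s)
  attr(out, "meta") <- attr(f, "meta")
  out
}

#' Generate an ensemble of lumpy objects
#'
#' Per-image seeds are derived deterministically from `(seed, index)` so the
#' ensemble is reproducible as a whole and any single image can be
#' regenerated in isolation.
#'
#' @param config A [lumpy_config()].
#' @param n Number of images (>= 1).
#' @param seed Master seed for the ensemble.
#' @return An `object_ensemble`: list with `images` (array
#'   `grid_size x grid_size x n`) and a `manifest` recording the
#'   configuration and the per-image seeds.
#' @export
make_ensemble <- function(config, n, seed) {
  if (!is.numeric(n) || n < 1) stop_field("n", "must be >= 1")
  n <- as.integer(n)
  seeds <- vapply(seq_len(n), function(i) derive_seed(seed, "lumpy-image", i - 1),
                  integer(1))
  g <- config$grid_size
  images <- array(0, dim = c(g, g, n))
  for (i in seq_len(n)) {
    images[, , i] <- sample_lumpy(config, seeds[i])
  }
  structure(
    list(images = images,
         manifest = list(config = unclass(config), master_seed = seed,
                         image_seeds = seeds, n = n,
                         config_hash = config_hash(unclass(config)))),
    class = "object_ensemble"
  )
}

#' @export
print.object_ensemble <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<object_ensemble> %d images of %dx%d\n", d[3], d[1], d[2]))
  invisible(x)
}

#' Number of images in an ensemble
#' @param x An `object_ensemble`.
#' @export
ensemble_size <- function(x) dim(x$images)[3]

# n x npix matrix view (column-major pixel order), used by the GAN trainer.
ensemble_matrix <- function(x) {
  d <- dim(x$images)
  t(matrix(x$images, d[1] * d[2], d[3]))
}

matrix_ensemble <- function(m, grid_size, manifest = list()) {
  structure(
    list(images = array(t(m), dim = c(grid_size, grid_size, nrow(m))),
         manifest = manifest),
    class = "object_ensemble"
  )
}

#' Write / read an object ensemble
#'
#' Ensembles are stored as an RDS file holding the image array next to a JSON
#' manifest side-car (`<path>.manifest.json`) so provenance stays readable
#' without loading the data.
#'
#' @param x An `object_ensemble`.
#' @param path Output path (conventionally `.rds`).
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(x, path) {
  saveRDS(x, path)
  jsonlite::write_json(x$manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "object_ensemble")) stop("not an object_ensemble file", call. = FALSE)
  x
}

#' Export ensemble previews as 8-bit PNG
#'
#' Images are windowed to the ensemble min/max (recorded in the manifest
#' side-car written next to the files).
#'
#' @param x An `object_ensemble`.
#' @param dir Output directory.
#' @param n_max Maximum number of images to export.
#' @return The directory, invisibly.
#' @export
export_ensemble_png <- function(x, dir, n_max = 16) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lo <- min(x$images); hi <- max(x$images)
  rng <- if (hi > lo) hi - lo else 1
  n <- min(ensemble_size(x), n_max)
  for (i in seq_len(n)) {
    img <- (x$images[, , i] - lo) / rng
    png::writePNG(img, file.path(dir, sprintf("object_%04d.png", i)))
  }
  jsonlite::write_json(list(window = c(lo, hi), n = n),
                       file.path(dir, "window.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
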