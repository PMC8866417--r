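# Stylized Fourier-space imaging operators.
#
# DFT convention: the forward transform carries no scale factor and the
# inverse carries 1/(H*W) (this is R's fft()).  With i.i.d. complex Gaussian
# k-space noise of per-component standard deviation sigma on an N x N grid,
# the real-part reconstruction of pure noise then has pixel standard
# deviation sigma / N, and magnitude backgrounds are Rayleigh(sigma / N).
# k-space is stored in the centered layout (DC at row/column N/2 + 1) so
# sampling masks are expressed in natural centered phase-encode coordinates.

fftshift_idx <- function(n) c((n / 2 + 1):n, 1:(n / 2))
ifftshift_idx <- function(n) fftshift_idx(n) # n even (power of two) only

fft2_centered <- function(f) {
  n <- nrow(f)
  i <- fftshift_idx(n)
  stats::fft(f)[i, i]
}

ifft2_centered <- function(k) {
  n <- nrow(k)
  i <- ifftshift_idx(n)
  stats::fft(k[i, i], inverse = TRUE) / n^2
}

#' Cartesian phase-encode sampling mask
#'
#' Builds a line mask for accelerated Cartesian acquisition: whole
#' phase-encode rows (centered k-space coordinates, readout direction fully
#' sampled) are kept or dropped.  The acceleration factor `R` is the ratio of
#' the full k-space size to the number of acquired lines; the DC line is
#' always kept.
#'
#' @param grid_size k-space side length (power of two).
#' @param R Acceleration factor in `[1, grid_size]`; the mask keeps
#'   `round(grid_size / R)` lines.
#' @param scheme `"full"` (all lines; forces `R = 1`), `"uniform_random"`
#'   (uniform without replacement, DC forced), or `"center_band_random"`
#'   (keep a central band of 8% of lines, randomize the rest).  All schemes
#'   produce Hermitian-symmetric line sets (lines kept in `+/-k` pairs, the
#'   Nyquist line self-paired): for real-valued objects a line and its mirror
#'   carry identical information, and the symmetric choice makes the
#'   real-part zero-filled reconstruction `H^+ H` an exact orthogonal
#'   projector.
#' @param seed Seed for the random line selection.
#' @return A `sampling_mask`: list with `kept_lines` (sorted centered k_y
#'   indices in `[-N/2, N/2 - 1]`), `grid_size`, `R`, `scheme`, `seed`.
#' @export
make_cartesian_mask <- function(grid_size, R = 1,
                                scheme = c("uniform_random", "center_band_random", "full"),
                                seed = 1) {
  scheme <- match.arg(scheme)
  if (!is_power_of_two(grid_size)) stop_field("grid_size", "must be a power of two")
  if (!is.numeric(R) || R < 1 || R > grid_size) {
    stop_field("R", sprintf("must lie in [1, %d]", grid_size))
  }
  n_keep <- round(grid_size / R)
  if (n_keep < 1) stop_field("R", "keeps no lines")
  all_lines <- seq(-grid_size / 2, grid_size / 2 - 1)
  nyquist <- -grid_size / 2 # self-symmetric on the even grid, like DC
  pair_ids <- seq_len(grid_size / 2 - 1) # pair k <-> -k
  pick_symmetric <- function(budget, forced_pairs = integer(0)) {
    # budget counts lines beyond DC; pairs cost 2, Nyquist costs 1
    kept <- 0
    if (budget %% 2 == 1) { kept <- c(kept, nyquist); budget <- budget - 1 }
    pool <- setdiff(pair_ids, forced_pairs)
    n_pairs <- budget / 2 - length(forced_pairs)
    if (n_pairs < 0 || n_pairs > length(pool)) {
      stop_field("R", "cannot realize a symmetric mask with this budget")
    }
    chosen <- c(forced_pairs, if (n_pairs > 0) sample(pool, n_pairs))
    sort(c(kept, chosen, -chosen))
  }
  if (R == 1 || scheme == "full") {
    if (R != 1) stop_field("scheme", "'full' requires R = 1")
    kept <- all_lines
  } else if (scheme == "uniform_random") {
    kept <- with_seed(derive_seed(seed, "mask-lines"), pick_symmetric(n_keep - 1))
  } else { # center_band_random
    band_half <- max(1, floor(grid_size * 0.08 / 2))
    band_half <- min(band_half, (n_keep - 1) %/% 2)
    kept <- with_seed(derive_seed(seed, "mask-lines"),
                      pick_symmetric(n_keep - 1, forced_pairs = seq_len(band_half)))
  }
  structure(
    list(grid_size = as.integer(grid_size), kept_lines = as.integer(kept),
         R = grid_size / length(kept), scheme = scheme, seed = seed),
    class = "sampling_mask"
  )
}

#' @export
print.sampling_mask <- function(x, ...) {
  cat(sprintf("<sampling_mask> %d/%d lines kept (R = %.3g, scheme = %s)\n",
              length(x$kept_lines), x$grid_size, x$R, x$scheme))
  invisible(x)
}

mask_is_full <- function(mask) length(mask$kept_lines) == mask$grid_size

# centered row indices (1-based) of the kept lines
mask_rows <- function(mask) mask$kept_lines + mask$grid_size / 2 + 1

# logical N x N matrix, TRUE where sampled
mask_matrix <- function(mask) {
  m <- matrix(FALSE, mask$grid_size, mask$grid_size)
  m[mask_rows(mask), ] <- TRUE
  m
}

#' Export a sampling mask as a black/white PNG
#' @param mask A `sampling_mask`.
#' @param path Output PNG path.
#' @export
export_mask_png <- function(mask, path) {
  png::writePNG(mask_matrix(mask) * 1, path)
  invisible(path)
}

#' Forward measurement model (masked DFT plus complex Gaussian noise)
#'
#' @param mask A [make_cartesian_mask()] mask.
#' @param kspace_std Per-component (real and imaginary) standard deviation of
#'   the i.i.d. Gaussian noise added to each *sampled* k-space entry.
#' @return A `forward_model` object.
#' @export
forward_model <- function(mask, kspace_std = 0) {
  if (!inherits(mask, "sampling_mask")) stop_field("mask", "must be a sampling_mask")
  if (kspace_std < 0) stop_field("kspace_std", "must be >= 0")
  structure(list(mask = mask, kspace_std = kspace_std,
                 dft_convention = "forward-unscaled/inverse-1/(HW)"),
            class = "forward_model")
}

#' Simulate measurement data `g = H_n(f)`
#'
#' Computes the centered 2D DFT of the object, adds i.i.d. complex Gaussian
#' noise to the sampled lines and zeros the unsampled ones.
#'
#' @param f Square real object image matching the mask grid.
#' @param model A [forward_model()].
#' @param seed Seed for the noise realization.
#' @return A `kspace_data`: list with complex matrix `values` (centered
#'   layout, exactly zero off-mask), the `mask`, `kspace_std` and `seed`.
#' @export
forward_measure <- function(f, model, seed = 1) {
  assert_square_image(f, "f")
  n <- model$mask$grid_size
  if (nrow(f) != n) stop("object size does not match mask grid", call. = FALSE)
  k <- fft2_centered(unclass(f))
  rows <- mask_rows(model$mask)
  if (model$kspace_std > 0) {
    noise <- with_seed(derive_seed(seed, "kspace-noise"), {
      nr <- length(rows) * n
      complex(real = stats::rnorm(nr, 0, model$kspace_std),
              imaginary = stats::rnorm(nr, 0, model$kspace_std))
    })
    k[rows, ] <- k[rows, ] + matrix(noise, length(rows), n)
  }
  keep <- matrix(FALSE, n, n); keep[rows, ] <- TRUE
  k[!keep] <- 0 + 0i
  structure(list(values = k, mask = model$mask, kspace_std = model$kspace_std,
                 seed = seed),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  cat(sprintf("<kspace_data> %dx%d, R = %.3g, kspace_std = %g\n",
              nrow(x$values), ncol(x$values), x$mask$R, x$kspace_std))
  invisible(x)
}

as_kspace_values <- function(g) {
  if (inherits(g, "kspace_data")) g$values else g
}

#' Zero-filled pseudoinverse reconstruction (real part)
#'
#' `H^+ g` for the masked-DFT operator: apply the 2D inverse DFT to the
#' zero-filled k-space and take the real component.
#'
#' @param g A `kspace_data` (or a bare centered complex matrix).
#' @return A real image matrix.
#' @export
pseudoinverse_reconstruct <- function(g) {
  Re(ifft2_centered(as_kspace_values(g)))
}

#' Magnitude reconstruction
#'
#' Pixelwise modulus of the inverse DFT of the zero-filled k-space; the MRI
#' convention that discards phase.  Background (object-free) pixels of pure
#' noise follow a Rayleigh distribution with scale `kspace_std / N`.
#'
#' @inheritParams pseudoinverse_reconstruct
#' @return A nonnegative real image matrix.
#' @export
magnitude_reconstruct <- function(g) {
  Mod(ifft2_centered(as_kspace_values(g)))
}

#' Reconstruction operator
#'
#' @param mode `"real_part"`, `"magnitude"` or `"corrected_magnitude"` (the
#'   ReLU-corrected magnitude used on the generator branch when training
#'   against magnitude images).
#' @return A `reconstructor` object; apply it with [reconstruct()].
#' @export
reconstructor <- function(mode = c("real_part", "magnitude", "corrected_magnitude")) {
  structure(list(mode = match.arg(mode)), class = "reconstructor")
}

#' Apply a reconstructor to measured data
#' @param g A `kspace_data`.
#' @param recon A [reconstructor()]. For measured (real-branch) data,
#'   `"corrected_magnitude"` coincides with `"magnitude"`.
#' @export
reconstruct <- function(g, recon) {
  switch(recon$mode,
         real_part = pseudoinverse_reconstruct(g),
         magnitude = ,
         corrected_magnitude = magnitude_reconstruct(g))
}

relu <- function(x) pmax(x, 0)

# Internal: corrected magnitude forward with cache for gradient propagation.
# e = abs(F^-1(F(relu(f)) + n)) - relu(f);  output = f + e.
corrected_fake_reconstruct_impl <- function(f_hat, model, seed) {
  n <- nrow(f_hat)
  fp <- relu(f_hat)
  g <- forward_measure(fp, model, seed)
  c_img <- ifft2_centered(g$values)
  mag <- Mod(c_img)
  # algebraically f_hat + (mag - fp); this grouping is bitwise equal to the
  # plain magnitude reconstruction wherever f_hat >= 0
  out <- mag + (f_hat - fp)
  # d out / d f_hat is diagonal: 1 + relu'(f) * (Re(c)/|c| - 1)
  ratio <- ifelse(mag > 0, Re(c_img) / mag, 1)
  diag_grad <- 1 + (f_hat > 0) * (ratio - 1)
  list(out = out, diag_grad = diag_grad)
}

#' Corrected fake magnitude reconstruction for generated objects
#'
#' When the discriminator is fed magnitude images, applying the modulus
#' directly to the simulated measurement of a generated object would let
#' negative-valued objects masquerade as valid magnitude images.  The
#' correction simulates the measurement of `ReLU(f_hat)` and adds the
#' resulting magnitude error back onto the *uncorrected* object:
#' `f_hat + [abs(F^-1(F(ReLU(f_hat)) + n)) - ReLU(f_hat)]`.  For
#' `f_hat >= 0` this equals the plain magnitude reconstruction of the
#' measurement; where `f_hat < 0` the negative values pass through (plus the
#' noise magnitude), so they remain visible to the discriminator.
#'
#' @param f_hat Real image (any sign), square, matching the model grid.
#' @param model A [forward_model()] whose mask is full (the correction is
#'   defined for fully sampled magnitude data).
#' @param seed Seed for the measurement-noise realization.
#' @return A real image matrix.
#' @export
corrected_fake_reconstruct <- function(f_hat, model, seed = 1) {
  assert_square_image(f_hat, "f_hat")
  if (!mask_is_full(model$mask)) {
    stop("corrected_fake_reconstruct requires a full sampling mask", call. = FALSE)
  }
  corrected_fake_reconstruct_impl(unclass(f_hat), model, seed)$out
}

#' Measurement component `f_meas = H^+ H f`
#'
#' Projects an object onto the subspace observable through an undersampling
#' operator: the noiseless masked DFT followed by the zero-filled inverse
#' (real part).  Idempotent; with a full mask it is the identity.
#'
#' @param f Square real object image.
#' @param mask A `sampling_mask`.
#' @return A real image matrix.
#' @export
measurement_component <- function(f, mask) {
  assert_square_image(f, "f")
  if (nrow(f) != mask$grid_size) stop("object size does not match mask grid", call. = FALSE)
  k <- fft2_centered(unclass(f))
  rows <- mask_rows(mask)
  keep <- matrix(FALSE, mask$grid_size, mask$grid_size); keep[rows, ] <- TRUE
  k[!keep] <- 0 + 0i
  Re(ifft2_centered(k))
}

# Adjoint of the real-linear projector f -> measurement_component(f, mask),
# used to backpropagate through the operator insertion during training:
# P^T v = Re(F M F^-1 v).
measurement_component_adjoint <- function(v, mask) {
  n <- mask$grid_size
  i <- fftshift_idx(n)
  ki <- (stats::fft(v, inverse = TRUE) / n^2)[i, i] # centered spectrum of F^-1 v
  rows <- mask_rows(mask)
  keep <- matrix(FALSE, n, n); keep[rows, ] <- TRUE
  ki[!keep] <- 0 + 0i
  j <- ifftshift_idx(n)
  Re(stats::fft(ki[j, j]))
}

#' Write / read measured k-space data
#'
#' Stored as RDS with a JSON manifest side-car holding the mask and noise
#' provenance.
#'
#' @param g A `kspace_data` or a list of them.
#' @param path Output path.
#' @export
write_kspace <- function(g, path) {
  saveRDS(g, path)
  meta <- if (inherits(g, "kspace_data")) {
    list(n = 1, mask = g$mask[c("grid_size", "R", "scheme", "seed")],
         kspace_std = g$kspace_std)
  } else {
    list(n = length(g), mask = g[[1]]$mask[c("grid_size", "R", "scheme", "seed")],
         kspace_std = g[[1]]$kspace_std)
  }
  jsonlite::write_json(meta, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_kspace
#' @export
read_kspace <- function(path) readRDS(path)
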