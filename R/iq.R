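# Objective image-quality evaluation: Hotelling observer SNR for a
# signal-known-exactly / background-known-statistically detection task, and
# Frechet distances between image ensembles.

#' Binary signal-detection task specification
#'
#' Signal-known-exactly, background-known-statistically task: noisy images
#' `g_t = f (+ s) + n_t` are classified as signal-absent or signal-present.
#' The task is evaluated on a square region of interest centered at the
#' signal.
#'
#' @param signal A [gaussian_signal()] (grid-sized matrix, compact support).
#' @param roi_center Length-2 pixel coordinates of the ROI center (defaults
#'   to the signal center).
#' @param roi_size ROI side length in pixels.
#' @param task_noise_std Standard deviation of the i.i.d. Gaussian task noise
#'   `n_t`, as a fraction of the `[0, 1]` intensity range (default 0.02).
#' @return A `detection_task` object.
#' @export
detection_task <- function(signal, roi_center = attr(signal, "center"),
                           roi_size = 8, task_noise_std = 0.02) {
  n <- nrow(signal)
  if (task_noise_std <= 0) stop_field("task_noise_std", "must be > 0")
  half <- roi_size / 2
  lo <- floor(roi_center - half) + 1
  hi <- lo + roi_size - 1
  if (any(lo < 1) || any(hi > n)) stop_field("roi_size", "ROI exceeds the grid")
  sup <- which(unclass(signal) != 0, arr.ind = TRUE)
  if (nrow(sup) > 0) {
    if (min(sup[, 1]) < lo[1] || max(sup[, 1]) > hi[1] ||
        min(sup[, 2]) < lo[2] || max(sup[, 2]) > hi[2]) {
      stop_field("signal", "signal support must lie inside the ROI")
    }
  }
  structure(list(signal = unclass(signal), roi_center = roi_center,
                 roi_size = as.integer(roi_size),
                 roi_rows = lo[1]:hi[1], roi_cols = lo[2]:hi[2],
                 task_noise_std = task_noise_std),
            class = "detection_task")
}

#' Extract the task ROI from an image
#'
#' Exact sub-grid copy; vectorize with `as.vector()` (column-major, the
#' convention used consistently by the covariance and SNR code).
#'
#' @param image Square image matrix.
#' @param task A [detection_task()].
#' @return `roi_size` x `roi_size` matrix.
#' @export
extract_roi <- function(image, task) {
  if (max(task$roi_rows) > nrow(image) || max(task$roi_cols) > ncol(image)) {
    stop("ROI exceeds image bounds", call. = FALSE)
  }
  unclass(image)[task$roi_rows, task$roi_cols]
}

#' Covariance model for the ROI via decomposition
#'
#' Decomposes the data covariance `K` of the noisy ROI into the empirical
#' background component plus the exactly known task-noise component:
#' `K = K_background + task_noise_std^2 * I`.  The diagonal addition makes
#' `K` positive definite by construction even when the number of background
#' samples is modest.
#'
#' @param background_rois Stack of signal-absent ROIs: `m x m x n` array or
#'   `n x m^2` matrix (column-major rows).
#' @param task_noise_std Task noise standard deviation.
#' @return A `covariance_model`: list with `K` (dense), `n_samples`,
#'   `task_noise_std`.
#' @export
estimate_covariance_decomposed <- function(background_rois, task_noise_std) {
  X <- if (is.matrix(background_rois)) {
    background_rois
  } else {
    d <- dim(background_rois)
    t(matrix(background_rois, d[1] * d[2], d[3]))
  }
  if (nrow(X) < 2) stop_field("background_rois", "need at least 2 samples")
  K <- stats::cov(X) * (nrow(X) - 1) / nrow(X) + diag(task_noise_std^2, ncol(X))
  structure(list(K = K, n_samples = nrow(X), task_noise_std = task_noise_std),
            class = "covariance_model")
}

snr_from_K <- function(s_vec, K) {
  # SPD solve via Cholesky; never an explicit inverse
  ch <- chol(K)
  y <- backsolve(ch, forwardsolve(t(ch), s_vec))
  q <- sum(s_vec * y)
  c(snr = sqrt(q), quadratic_form = q)
}

#' Hotelling-observer SNR for a detection task
#'
#' Figure of merit `SNR_HO = sqrt(s_ROI' K^-1 s_ROI)` where `K` is the ROI
#' data covariance from [estimate_covariance_decomposed()] (empirical
#' background + exact task-noise diagonal).  The squared quadratic form is
#' also returned; the square-root convention is flagged in the result.
#'
#' @param task A [detection_task()].
#' @param background_rois Signal-absent ROI stack (array or matrix), or a
#'   ready-made `covariance_model`.
#' @return List with `snr`, `quadratic_form`, `convention = "sqrt"`,
#'   `n_samples`.
#' @export
compute_snr_ho <- function(task, background_rois) {
  cm <- if (inherits(background_rois, "covariance_model")) {
    background_rois
  } else {
    estimate_covariance_decomposed(background_rois, task$task_noise_std)
  }
  s_roi <- extract_roi(task$signal, task)
  s_vec <- as.vector(s_roi)
  if (length(s_vec) != ncol(cm$K)) stop("signal/covariance dimension mismatch", call. = FALSE)
  v <- snr_from_K(s_vec, cm$K)
  list(snr = unname(v["snr"]), quadratic_form = unname(v["quadratic_form"]),
       convention = "sqrt", n_samples = cm$n_samples)
}

#' Analytic ROI covariance for periodic lumpy backgrounds
#'
#' Builds the exact background covariance of an ROI cut from the stationary
#' lumpy process ([lumpy_autocovariance()]), plus the task-noise diagonal —
#' the closed-form oracle against which the empirical covariance route can
#' be validated.
#'
#' @param config A periodic, unnormalized [lumpy_config()].
#' @param task A [detection_task()] on the same grid.
#' @return A `covariance_model`.
#' @export
lumpy_roi_covariance <- function(config, task) {
  acov <- lumpy_autocovariance(config)
  n <- config$grid_size
  m <- task$roi_size
  idx <- expand.grid(r = 0:(m - 1), c = 0:(m - 1))
  K <- matrix(0, m * m, m * m)
  for (a in seq_len(m * m)) {
    dr <- (idx$r - idx$r[a]) %% n
    dc <- (idx$c - idx$c[a]) %% n
    K[a, ] <- acov[cbind(dr + 1, dc + 1)]
  }
  K <- K + diag(task$task_noise_std^2, m * m)
  structure(list(K = K, n_samples = Inf, task_noise_std = task$task_noise_std),
            class = "covariance_model")
}

#' Frechet distance between two Gaussians
#'
#' `d^2 = |mu1 - mu2|^2 + tr(S1 + S2 - 2 (S1 S2)^(1/2))`, computed with a
#' symmetrized eigendecomposition for the matrix square root (negative
#' eigenvalues clipped at -1e-8).
#'
#' @param mean1,mean2 Mean vectors.
#' @param cov1,cov2 Covariance matrices (symmetric positive semidefinite).
#' @return The squared Frechet distance (the conventional FID scale).
#' @export
gaussian_frechet_distance <- function(mean1, cov1, mean2, cov2) {
  cov1 <- as.matrix(cov1); cov2 <- as.matrix(cov2)
  if (length(mean1) != length(mean2) || any(dim(cov1) != dim(cov2)) ||
      nrow(cov1) != length(mean1)) {
    stop("dimension mismatch between means and covariances", call. = FALSE)
  }
  for (S in list(cov1, cov2)) {
    if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S)))) {
      stop("covariance matrix is not symmetric", call. = FALSE)
    }
  }
  e1 <- eigen((cov1 + t(cov1)) / 2, symmetric = TRUE)
  v1 <- pmax(e1$values, 0)
  s1h <- e1$vectors %*% (sqrt(v1) * t(e1$vectors))
  m <- s1h %*% cov2 %*% s1h
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8 * max(1, max(abs(ev))))) {
    warning("matrix square root clipped substantially negative eigenvalues")
  }
  ev <- pmax(ev, 0)
  d2 <- sum((mean1 - mean2)^2) + sum(diag(cov1)) + sum(diag(cov2)) - 2 * sum(sqrt(ev))
  max(d2, 0)
}

#' Feature extractor for FID computation
#'
#' The default `"pixel_pool"` embedding average-pools each image down to
#' `pool_size` x `pool_size` and flattens it — a deterministic, in-package
#' stand-in for pretrained-network features, adequate for comparing
#' ensembles of small grayscale objects.  A custom function
#' `function(image_matrix) numeric_vector` may be supplied for pluggable
#' (e.g., pretrained) embeddings.
#'
#' @param name `"pixel_pool"` or `"custom"`.
#' @param pool_size Output side length for pixel pooling.
#' @param fn Custom embedding function when `name = "custom"`.
#' @return A `feature_extractor`.
#' @export
feature_extractor <- function(name = c("pixel_pool", "custom"), pool_size = 8,
                              fn = NULL) {
  name <- match.arg(name)
  if (name == "custom" && !is.function(fn)) stop_field("fn", "must be a function")
  structure(list(name = name, pool_size = pool_size, fn = fn),
            class = "feature_extractor")
}

avg_pool_to <- function(img, target) {
  n <- nrow(img)
  if (n == target) return(img)
  if (n %% target != 0) stop("image size not divisible by pool target", call. = FALSE)
  f <- n / target
  # block mean
  m <- matrix(0, target, target)
  for (i in seq_len(target)) {
    rows <- ((i - 1) * f + 1):(i * f)
    sub <- img[rows, , drop = FALSE]
    cs <- colMeans(sub)
    m[i, ] <- vapply(seq_len(target), function(j) {
      mean(cs[((j - 1) * f + 1):(j * f)])
    }, numeric(1))
  }
  m
}

extract_features <- function(images, extractor) {
  imgs <- if (inherits(images, "object_ensemble")) images$images else images
  n_img <- dim(imgs)[3]
  feat1 <- function(img) {
    if (extractor$name == "pixel_pool") {
      as.vector(avg_pool_to(img, extractor$pool_size))
    } else {
      extractor$fn(img)
    }
  }
  t(vapply(seq_len(n_img), function(i) feat1(imgs[, , i]),
           numeric(length(feat1(imgs[, , 1])))))
}

#' Frechet distance between two image ensembles (FID-style)
#'
#' Embeds both ensembles with the feature extractor, fits mean and
#' covariance per set, and returns the squared Frechet distance between the
#' Gaussian fits.
#'
#' @param images_a,images_b `object_ensemble`s or 3D arrays.
#' @param extractor A [feature_extractor()].
#' @return The FID value (nonnegative scalar).
#' @export
compute_fid <- function(images_a, images_b, extractor = feature_extractor()) {
  fa <- extract_features(images_a, extractor)
  fb <- extract_features(images_b, extractor)
  d <- ncol(fa)
  if (nrow(fa) < d + 1 || nrow(fb) < d + 1) {
    warning(sprintf(
      "fewer than %d images per set; covariance estimate is rank-deficient", d + 1))
  }
  gaussian_frechet_distance(colMeans(fa), stats::cov(fa), colMeans(fb), stats::cov(fb))
}
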