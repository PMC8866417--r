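# Minimal dense neural-network engine with hand-derived backpropagation.
#
# The generator and discriminator are deliberately small multiresolution
# networks: a dense feature trunk plus per-resolution "to-image" /
# "from-image" dense heads, connected across resolutions by fixed bilinear
# upsampling and average-pool downsampling (precomputed as sparse-structured
# dense matrices).  The discriminator additionally receives per-scale
# band-energy features (mean squared pixel value at each dyadic resolution,
# differenced across scales), which make second-order statistics - in
# particular the white-noise floor of the training images - directly visible
# to the critic.  All gradients, including the second-order backward pass
# needed for gradient penalties (WGAN-GP and R1), are computed in closed
# form and are verified against finite differences in the test suite.
#
# Images are handled as rows of batch x npix matrices, column-major pixel
# order within each row.

lrelu <- function(x) pmax(x, 0.2 * x)
add_bias <- function(x, v) x + rep(v, each = nrow(x))
lrelu_mask <- function(x) 0.2 + 0.8 * (x > 0)
softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
sigmoid <- function(x) 1 / (1 + exp(-x))

resolution_chain <- function(base, final) {
  stopifnot(is_power_of_two(base), is_power_of_two(final), final >= base)
  out <- base
  while (out[length(out)] < final) out <- c(out, 2 * out[length(out)])
  out
}

# 1D bilinear 2x upsampling (half-pixel centers, edge-clamped)
bilinear_up_1d <- function(r) {
  u <- matrix(0, 2 * r, r)
  for (j in 0:(2 * r - 1)) {
    x <- (j + 0.5) / 2 - 0.5
    i0 <- floor(x); w <- x - i0
    i0c <- min(max(i0, 0), r - 1); i1c <- min(max(i0 + 1, 0), r - 1)
    u[j + 1, i0c + 1] <- u[j + 1, i0c + 1] + (1 - w)
    u[j + 1, i1c + 1] <- u[j + 1, i1c + 1] + w
  }
  u
}

avgpool_down_1d <- function(r) { # 2r -> r
  d <- matrix(0, r, 2 * r)
  for (i in seq_len(r)) d[i, c(2 * i - 1, 2 * i)] <- 0.5
  d
}

# cache of 2D resampling matrices, keyed by source resolution
.resample_cache <- new.env(parent = emptyenv())

up2d_mat <- function(r) { # r -> 2r
  key <- paste0("u", r)
  if (is.null(.resample_cache[[key]])) {
    .resample_cache[[key]] <- kronecker(bilinear_up_1d(r), bilinear_up_1d(r))
  }
  .resample_cache[[key]]
}

down2d_mat <- function(r) { # 2r -> r
  key <- paste0("d", r)
  if (is.null(.resample_cache[[key]])) {
    .resample_cache[[key]] <- kronecker(avgpool_down_1d(r), avgpool_down_1d(r))
  }
  .resample_cache[[key]]
}

# cumulative average-pool matrices stage_res -> each r in the chain
cum_down_mats <- function(stage_res, base) {
  key <- paste0("c", stage_res, "_", base)
  if (is.null(.resample_cache[[key]])) {
    out <- list()
    cmat <- diag(stage_res^2)
    r <- stage_res
    out[[as.character(r)]] <- cmat
    while (r > base) {
      r <- r / 2
      cmat <- down2d_mat(r) %*% cmat
      out[[as.character(r)]] <- cmat
    }
    .resample_cache[[key]] <- out
  }
  .resample_cache[[key]]
}

upsample_rows <- function(x, from, to) {
  r <- from
  while (r < to) { x <- tcrossprod(x, up2d_mat(r)); r <- 2 * r }
  x
}

downsample_rows <- function(x, from, to) {
  r <- from
  while (r > to) { r <- r / 2; x <- tcrossprod(x, down2d_mat(r)) }
  x
}

# adjoint of the linear map upsample_rows(., from, to)
upsample_rows_adjoint <- function(g, from, to) {
  seqs <- c(); r <- from
  while (r < to) { seqs <- c(seqs, r); r <- 2 * r }
  for (r2 in rev(seqs)) g <- g %*% up2d_mat(r2)
  g
}

# adjoint of downsample_rows(., from, to)
downsample_rows_adjoint <- function(g, from, to) {
  seqs <- c(); r <- from
  while (r > to) { r <- r / 2; seqs <- c(seqs, r) }
  for (r2 in rev(seqs)) g <- g %*% down2d_mat(r2)
  g
}

he_init <- function(nin, nout, gain = sqrt(2)) {
  matrix(stats::rnorm(nin * nout, 0, gain / sqrt(nin)), nin, nout)
}

# ---- parameter initialization ------------------------------------------------

init_gan_params <- function(gspec, dspec, seed) {
  res <- resolution_chain(gspec$base_resolution, gspec$final_resolution)
  with_seed(derive_seed(seed, "param-init"), {
    G <- list(W0 = he_init(gspec$latent_dim, gspec$hidden),
              b0 = rep(0, gspec$hidden),
              W1 = he_init(gspec$hidden, gspec$hidden),
              b1 = rep(0, gspec$hidden))
    for (r in res) {
      # to-image heads start near zero so early training is dominated by the
      # coarse scales; only the base head carries the initial mean level
      G[[paste0("A", r)]] <- he_init(gspec$hidden, r * r, gain = 0.05)
      G[[paste0("c", r)]] <- rep(if (r == res[1]) 0.4 else 0, r * r)
    }
    dh <- dspec$hidden
    D <- list(W2 = he_init(dh, dh), b2 = rep(0, dh),
              w3 = he_init(dh, 1), b3 = 0)
    for (r in res) {
      D[[paste0("V", r)]] <- he_init(r * r, dh)
      D[[paste0("u", r)]] <- rep(0, dh)
      # band-energy feature rows: large initial gain so the scale-resolved
      # second-order statistics are usable from the first steps
      D[[paste0("E", r)]] <- matrix(stats::rnorm(dh, 0, if (r == res[1]) 4 else 50), 1, dh)
    }
    list(G = G, D = D)
  })
}

# ---- generator ---------------------------------------------------------------

gen_forward <- function(G, Z, stage_res, alpha, res) {
  h1a <- add_bias(Z %*% G$W0, G$b0); h1 <- lrelu(h1a)
  h2a <- add_bias(h1 %*% G$W1, G$b1); h2 <- lrelu(h2a)
  out <- NULL
  for (r in res) {
    if (r > stage_res) break
    img <- add_bias(h2 %*% G[[paste0("A", r)]], G[[paste0("c", r)]])
    if (is.null(out)) {
      out <- img
    } else {
      out <- tcrossprod(out, up2d_mat(r / 2))
      w <- if (r == stage_res) alpha else 1
      out <- out + w * img
    }
  }
  list(out = out, h1a = h1a, h1 = h1, h2a = h2a, h2 = h2, Z = Z)
}

gen_backward <- function(G, cache, d_out, stage_res, alpha, res) {
  gr <- list()
  chain <- res[res <= stage_res]
  d <- d_out
  d_h2 <- matrix(0, nrow(d_out), ncol(cache$h2))
  for (r in rev(chain)) {
    w <- if (r == stage_res && r > chain[1]) alpha else 1
    gr[[paste0("A", r)]] <- crossprod(cache$h2, d) * w
    gr[[paste0("c", r)]] <- colSums(d) * w
    d_h2 <- d_h2 + w * tcrossprod(d, G[[paste0("A", r)]])
    if (r > chain[1]) d <- d %*% up2d_mat(r / 2)
  }
  d_h2a <- d_h2 * lrelu_mask(cache$h2a)
  gr$W1 <- crossprod(cache$h1, d_h2a); gr$b1 <- colSums(d_h2a)
  d_h1a <- tcrossprod(d_h2a, G$W1) * lrelu_mask(cache$h1a)
  gr$W0 <- crossprod(cache$Z, d_h1a); gr$b0 <- colSums(d_h1a)
  gr
}

# ---- discriminator -----------------------------------------------------------

disc_forward <- function(D, X, stage_res, alpha, res, trunk = "plain") {
  base <- res[1]
  fa <- add_bias(X %*% D[[paste0("V", stage_res)]], D[[paste0("u", stage_res)]])
  xd <- NULL
  if (alpha < 1 && stage_res > base) {
    xd <- tcrossprod(X, down2d_mat(stage_res / 2))
    fb <- add_bias(xd %*% D[[paste0("V", stage_res / 2)]],
                   D[[paste0("u", stage_res / 2)]])
    fa <- alpha * fa + (1 - alpha) * fb
  }
  cmats <- cum_down_mats(stage_res, base)
  rset <- res[res <= stage_res]
  pyr <- list(); en <- list(); bn <- list()
  for (r in rset) {
    rc <- as.character(r)
    pyr[[rc]] <- if (r == stage_res) X else tcrossprod(X, cmats[[rc]])
    en[[rc]] <- rowMeans(pyr[[rc]]^2)
  }
  for (r in rset) {
    rc <- as.character(r)
    bn[[rc]] <- if (r == rset[1]) en[[rc]] else en[[rc]] - en[[as.character(r / 2)]]
    fa <- fa + matrix(bn[[rc]], ncol = 1) %*% D[[paste0("E", r)]]
  }
  h1 <- lrelu(fa)
  h2a <- add_bias(h1 %*% D$W2, D$b2)
  h2 <- if (trunk == "residual") h1 + lrelu(h2a) else lrelu(h2a)
  s <- h2 %*% D$w3 + D$b3
  list(s = s, fa = fa, h1 = h1, h2a = h2a, h2 = h2, X = X, xd = xd,
       pyr = pyr, en = en, bn = bn, trunk = trunk)
}

disc_input_grad_linear <- function(D, d_fa, stage_res, alpha, fading) {
  if (fading) {
    alpha * tcrossprod(d_fa, D[[paste0("V", stage_res)]]) +
      tcrossprod(d_fa, D[[paste0("V", stage_res / 2)]]) %*%
        ((1 - alpha) * down2d_mat(stage_res / 2))
  } else {
    tcrossprod(d_fa, D[[paste0("V", stage_res)]])
  }
}

disc_backward <- function(D, cache, ds, stage_res, alpha, res, need_dX = FALSE) {
  base <- res[1]
  gr <- list()
  dsm <- matrix(ds, ncol = 1)
  gr$w3 <- crossprod(cache$h2, dsm); gr$b3 <- sum(ds)
  d_h2 <- dsm %*% t(D$w3)
  if (cache$trunk == "residual") {
    d_h2a <- d_h2 * lrelu_mask(cache$h2a)
    gr$W2 <- crossprod(cache$h1, d_h2a); gr$b2 <- colSums(d_h2a)
    d_h1 <- d_h2 + tcrossprod(d_h2a, D$W2)
  } else {
    d_h2a <- d_h2 * lrelu_mask(cache$h2a)
    gr$W2 <- crossprod(cache$h1, d_h2a); gr$b2 <- colSums(d_h2a)
    d_h1 <- tcrossprod(d_h2a, D$W2)
  }
  d_fa <- d_h1 * lrelu_mask(cache$fa)
  fading <- !is.null(cache$xd)
  if (fading) {
    gr[[paste0("V", stage_res)]] <- crossprod(cache$X, d_fa) * alpha
    gr[[paste0("u", stage_res)]] <- colSums(d_fa) * alpha
    gr[[paste0("V", stage_res / 2)]] <- crossprod(cache$xd, d_fa) * (1 - alpha)
    gr[[paste0("u", stage_res / 2)]] <- colSums(d_fa) * (1 - alpha)
  } else {
    gr[[paste0("V", stage_res)]] <- crossprod(cache$X, d_fa)
    gr[[paste0("u", stage_res)]] <- colSums(d_fa)
  }
  cmats <- cum_down_mats(stage_res, base)
  rset <- res[res <= stage_res]
  for (r in rset) {
    rc <- as.character(r)
    gr[[paste0("E", r)]] <- matrix(colSums(d_fa * cache$bn[[rc]]), 1)
  }
  dX <- NULL
  if (need_dX) {
    dX <- disc_input_grad_linear(D, d_fa, stage_res, alpha, fading)
    dv <- list()
    for (r in rset) dv[[as.character(r)]] <- as.vector(tcrossprod(d_fa, D[[paste0("E", r)]]))
    for (r in rset) {
      rc <- as.character(r)
      de <- dv[[rc]] - if ((2 * r) %in% rset) dv[[as.character(2 * r)]] else 0
      yr <- if (r == stage_res) cache$pyr[[rc]] else cache$pyr[[rc]] %*% cmats[[rc]]
      dX <- dX + (2 / (r * r)) * de * yr
    }
  }
  list(gr = gr, dX = dX)
}

# Gradient-penalty pass: computes q = d D(x)/d x in closed form (masks held
# at their forward values, exact a.e. for piecewise-linear activations) and
# the parameter gradients of the penalty
#   type "gp": coef * mean((|q| - 1)^2)     (WGAN-GP, on interpolates)
#   type "r1": (coef / 2) * mean(|q|^2)     (R1, on real samples)
penalty_grads <- function(D, X, stage_res, alpha, res, trunk,
                          type = c("gp", "r1"), coef = 10) {
  type <- match.arg(type)
  base <- res[1]
  ca <- disc_forward(D, X, stage_res, alpha, res, trunk)
  m2 <- lrelu_mask(ca$h2a)
  m1 <- lrelu_mask(ca$fa)
  fading <- !is.null(ca$xd)
  b <- nrow(X)
  dh <- ncol(m2)
  w3row <- matrix(D$w3[, 1], b, dh, byrow = TRUE)
  if (trunk == "residual") {
    u2 <- m2 * w3row
    u1 <- m1 * (w3row + tcrossprod(u2, D$W2))
  } else {
    u2 <- m2 * w3row
    u1 <- m1 * tcrossprod(u2, D$W2)
  }
  q <- disc_input_grad_linear(D, u1, stage_res, alpha, fading)
  cmats <- cum_down_mats(stage_res, base)
  rset <- res[res <= stage_res]
  ylist <- list(); dvl <- list()
  for (r in rset) dvl[[as.character(r)]] <- as.vector(tcrossprod(u1, D[[paste0("E", r)]]))
  for (r in rset) {
    rc <- as.character(r)
    ylist[[rc]] <- if (r == stage_res) ca$pyr[[rc]] else ca$pyr[[rc]] %*% cmats[[rc]]
    de <- dvl[[rc]] - if ((2 * r) %in% rset) dvl[[as.character(2 * r)]] else 0
    q <- q + ((2 / (r * r)) * de) * ylist[[rc]]
  }
  nq2 <- rowSums(q^2)
  if (type == "gp") {
    nq <- sqrt(nq2)
    penalty <- coef * mean((nq - 1)^2)
    v0 <- q * (coef * 2 * (nq - 1) / pmax(nq, 1e-12) / b)
  } else {
    penalty <- (coef / 2) * mean(nq2)
    v0 <- q * (coef / b)
  }
  gr <- list()
  if (fading) {
    vh <- paste0("V", stage_res); vl <- paste0("V", stage_res / 2)
    gr[[vh]] <- alpha * crossprod(v0, u1)
    dmat <- down2d_mat(stage_res / 2)
    v0d <- tcrossprod(v0, dmat)
    gr[[vl]] <- (1 - alpha) * crossprod(v0d, u1)
    d_u1 <- alpha * v0 %*% D[[vh]] + (1 - alpha) * v0d %*% D[[vl]]
  } else {
    vh <- paste0("V", stage_res)
    gr[[vh]] <- crossprod(v0, u1)
    d_u1 <- v0 %*% D[[vh]]
  }
  tbl <- list()
  for (r in rset) {
    rc <- as.character(r)
    tbl[[rc]] <- (2 / (r * r)) * rowSums(v0 * ylist[[rc]])
  }
  for (r in rset) {
    rc <- as.character(r)
    tv <- tbl[[rc]] - if ((r / 2) %in% rset) tbl[[as.character(r / 2)]] else 0
    gr[[paste0("E", r)]] <- matrix(colSums(u1 * tv), 1)
    d_u1 <- d_u1 + matrix(tv, ncol = 1) %*% D[[paste0("E", r)]]
  }
  d_u1m <- d_u1 * m1
  if (trunk == "residual") {
    # u1 = m1 * (w3row + u2 %*% t(W2))
    gr$W2 <- crossprod(d_u1m, u2)
    d_u2 <- d_u1m %*% D$W2
    gr$w3 <- matrix(colSums(d_u1m) + colSums(d_u2 * m2), ncol = 1)
  } else {
    gr$W2 <- crossprod(d_u1m, u2)
    d_u2 <- d_u1m %*% D$W2
    gr$w3 <- matrix(colSums(d_u2 * m2), ncol = 1)
  }
  list(penalty = penalty, gr = gr)
}

# ---- Adam --------------------------------------------------------------------

adam_new_state <- function() list(t = 0, m = list(), v = list())

adam_update <- function(par, gr, st, lr, lr_mult = NULL,
                        beta1 = 0, beta2 = 0.99, eps = 1e-8) {
  st$t <- st$t + 1
  bc2 <- 1 - beta2^st$t
  for (nm in names(gr)) {
    g <- gr[[nm]]
    if (is.null(st$v[[nm]])) st$v[[nm]] <- g * 0
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    if (beta1 == 0) {
      mh <- g # no first-moment state needed
    } else {
      if (is.null(st$m[[nm]])) st$m[[nm]] <- g * 0
      st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
      mh <- st$m[[nm]] / (1 - beta1^st$t)
    }
    mult <- if (!is.null(lr_mult) && !is.null(lr_mult[[nm]])) lr_mult[[nm]] else 1
    par[[nm]] <- par[[nm]] - (lr * mult) * mh / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = st)
}
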