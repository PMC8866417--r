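# Finite-difference verification of the hand-derived backward passes,
# including the second-order pass behind the gradient penalties.

ns <- asNamespace("ambientsom")
fd_tol <- 1e-4

make_tiny <- function(arch_g = "progressive", arch_d = "progressive", final = 16) {
  gspec <- generator_spec(latent_dim = 5, final_resolution = final, hidden = 9,
                          architecture = arch_g)
  dspec <- discriminator_spec(hidden = 7, architecture = arch_d)
  params <- ns$init_gan_params(gspec, dspec, seed = 5)
  # tame the band-feature gains so FD curvature stays benign
  for (nm in names(params$D)) {
    if (grepl("^E", nm)) params$D[[nm]] <- params$D[[nm]] * 0.03
  }
  list(gspec = gspec, dspec = dspec, params = params,
       res = ns$resolution_chain(gspec$base_resolution, final))
}

test_that("discriminator parameter and input gradients match finite differences", {
  tiny <- make_tiny()
  res <- tiny$res
  for (case in list(list(sr = 4, alpha = 1, trunk = "plain"),
                    list(sr = 8, alpha = 0.4, trunk = "plain"),
                    list(sr = 16, alpha = 1, trunk = "residual"))) {
    sr <- case$sr; alpha <- case$alpha; trunk <- case$trunk
    set.seed(10)
    X <- matrix(rnorm(3 * sr^2), 3)
    fwd <- function(D) sum(ns$disc_forward(D, X, sr, alpha, res, trunk)$s)
    ca <- ns$disc_forward(tiny$params$D, X, sr, alpha, res, trunk)
    bb <- ns$disc_backward(tiny$params$D, ca, rep(1, 3), sr, alpha, res, need_dX = TRUE)
    eps <- 1e-6
    for (nm in names(bb$gr)) {
      idx <- sample(length(tiny$params$D[[nm]]), min(3, length(tiny$params$D[[nm]])))
      for (i in idx) {
        dp <- tiny$params$D; dp[[nm]][i] <- dp[[nm]][i] + eps
        dm <- tiny$params$D; dm[[nm]][i] <- dm[[nm]][i] - eps
        fd <- (fwd(dp) - fwd(dm)) / (2 * eps)
        expect_equal(as.vector(bb$gr[[nm]])[i], fd, tolerance = fd_tol,
                     label = sprintf("d score/d %s[%d] (stage %d)", nm, i, sr))
      }
    }
    for (i in sample(length(X), 4)) {
      xp <- X; xp[i] <- xp[i] + eps
      xm <- X; xm[i] <- xm[i] - eps
      fd <- (sum(ns$disc_forward(tiny$params$D, xp, sr, alpha, res, trunk)$s) -
             sum(ns$disc_forward(tiny$params$D, xm, sr, alpha, res, trunk)$s)) / (2 * eps)
      expect_equal(bb$dX[i], fd, tolerance = fd_tol)
    }
  }
})

test_that("penalty double-backward matches a fully finite-difference route", {
  tiny <- make_tiny()
  res <- tiny$res
  for (case in list(list(sr = 8, alpha = 0.5, trunk = "plain", type = "gp"),
                    list(sr = 16, alpha = 1, trunk = "plain", type = "r1"),
                    list(sr = 16, alpha = 1, trunk = "residual", type = "gp"))) {
    sr <- case$sr
    set.seed(11)
    X <- matrix(rnorm(2 * sr^2), 2)
    pen_fd <- function(D) {
      # independent route: numeric input-gradient of the score, then penalty
      h <- 1e-5
      q <- matrix(0, 2, sr^2)
      for (i in seq_len(sr^2)) for (b in 1:2) {
        xp <- X; xp[b, i] <- xp[b, i] + h
        xm <- X; xm[b, i] <- xm[b, i] - h
        q[b, i] <- (ns$disc_forward(D, xp, sr, case$alpha, res, case$trunk)$s[b] -
                    ns$disc_forward(D, xm, sr, case$alpha, res, case$trunk)$s[b]) / (2 * h)
      }
      if (case$type == "gp") 10 * mean((sqrt(rowSums(q^2)) - 1)^2)
      else (10 / 2) * mean(rowSums(q^2))
    }
    an <- ns$penalty_grads(tiny$params$D, X, sr, case$alpha, res, case$trunk,
                           type = case$type, coef = 10)
    expect_equal(an$penalty, pen_fd(tiny$params$D), tolerance = 1e-6)
    eps <- 1e-5
    for (nm in names(an$gr)) {
      i <- sample(length(tiny$params$D[[nm]]), 1)
      dp <- tiny$params$D; dp[[nm]][i] <- dp[[nm]][i] + eps
      dm <- tiny$params$D; dm[[nm]][i] <- dm[[nm]][i] - eps
      fd <- (pen_fd(dp) - pen_fd(dm)) / (2 * eps)
      expect_equal(as.vector(an$gr[[nm]])[i], fd, tolerance = 5e-3,
                   label = sprintf("d penalty/d %s[%d] (%s, stage %d)",
                                   nm, i, case$type, sr))
    }
  }
})

test_that("generator gradients match finite differences through the operators", {
  tiny <- make_tiny(final = 16)
  res <- tiny$res
  set.seed(12)
  Z <- matrix(rnorm(3 * 5), 3)
  W <- matrix(rnorm(3 * 16^2), 3) # fixed linear readout in place of the critic
  mask <- make_cartesian_mask(16, R = 2, seed = 3)
  bundles <- list(
    identity = operator_bundle(NULL),
    projector = operator_bundle(forward_model(mask, 0), reconstructor("real_part")),
    corrected = operator_bundle(forward_model(make_cartesian_mask(16, R = 1, scheme = "full"), 0.5),
                                reconstructor("corrected_magnitude"))
  )
  for (bname in names(bundles)) {
    bundle <- bundles[[bname]]
    for (case in list(c(8, 0.3), c(16, 1))) {
      sr <- case[1]; alpha <- case[2]
      wsr <- W[, seq_len(sr^2), drop = FALSE]
      loss_fn <- function(G) {
        fb <- ns$fake_branch(G, Z, sr, alpha, res, 16, bundle, seed = 77)
        sum(fb$x * wsr)
      }
      fb <- ns$fake_branch(tiny$params$G, Z, sr, alpha, res, 16, bundle, seed = 77)
      d_fake <- ns$fake_branch_adjoint(wsr, sr, 16, bundle, fb$op_cache)
      gr <- ns$gen_backward(tiny$params$G, fb$gen_cache, d_fake, sr, alpha, res)
      eps <- 1e-6
      for (nm in c("W0", "W1", paste0("A", sr), paste0("c", res[1]))) {
        i <- sample(length(tiny$params$G[[nm]]), 2)
        for (ii in i) {
          gp <- tiny$params$G; gp[[nm]][ii] <- gp[[nm]][ii] + eps
          gm <- tiny$params$G; gm[[nm]][ii] <- gm[[nm]][ii] - eps
          fd <- (loss_fn(gp) - loss_fn(gm)) / (2 * eps)
          expect_equal(as.vector(gr[[nm]])[ii], fd, tolerance = fd_tol,
                       label = sprintf("gen d/d %s[%d] bundle %s stage %d",
                                       nm, ii, bname, sr))
        }
      }
    }
  }
})

test_that("resampling operators satisfy their adjoint identities", {
  set.seed(13)
  x <- matrix(rnorm(2 * 16), 2) # two 4x4 images
  v <- matrix(rnorm(2 * 256), 2) # two 16x16 images
  ip1 <- sum(ns$upsample_rows(x, 4, 16) * v)
  ip2 <- sum(x * ns$upsample_rows_adjoint(v, 4, 16))
  expect_equal(ip1, ip2, tolerance = 1e-12)
  ip3 <- sum(ns$downsample_rows(v, 16, 4) * x)
  ip4 <- sum(v * ns$downsample_rows_adjoint(x, 16, 4))
  expect_equal(ip3, ip4, tolerance = 1e-12)
  # average pooling preserves the mean; bilinear upsampling preserves it too
  expect_equal(rowMeans(ns$downsample_rows(v, 16, 4)), rowMeans(v), tolerance = 1e-12)
  expect_equal(rowMeans(ns$upsample_rows(x, 4, 8)), rowMeans(x), tolerance = 1e-12)
})

test_that("parameter initialization is a pure function of the seed", {
  gs <- generator_spec(latent_dim = 4, final_resolution = 8, hidden = 6)
  ds <- discriminator_spec(hidden = 5)
  p1 <- ns$init_gan_params(gs, ds, seed = 3)
  p2 <- ns$init_gan_params(gs, ds, seed = 3)
  expect_identical(p1, p2)
  p3 <- ns$init_gan_params(gs, ds, seed = 4)
  expect_false(identical(p1$G$W0, p3$G$W0))
})
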