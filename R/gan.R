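# Ambient adversarial training of stochastic object models.
#
# The generator produces objects; before the discriminator sees them they
# are passed through the measurement operator H_n (masked DFT + fresh
# complex Gaussian noise per sample per step) and the reconstruction
# operator O, so the discriminator compares reconstructed fakes against
# reconstructed real measurements in the same (image) Hilbert space.  With
# the progressive schedule the reconstructed images are average-pooled down
# to the active stage resolution on both branches.  Gradients flow through
# O and H_n into the generator via the operators' adjoints.

#' Generator specification
#'
#' @param latent_dim Latent dimensionality (the sampling distribution is
#'   standard normal).  The full-scale convention in this model family is
#'   512; the desk-scale default here is 64.
#' @param final_resolution Output image side (power of two).
#' @param base_resolution Coarsest resolution of the multiresolution chain.
#' @param hidden Width of the dense feature trunk.
#' @param architecture `"progressive"` (grown stage by stage with fade-in)
#'   or `"skip_sum"` (all resolutions summed from the start, trained in a
#'   single stage at the final resolution).
#' @return A `generator_spec`.
#' @export
generator_spec <- function(latent_dim = 64, final_resolution = 32,
                           base_resolution = 4, hidden = 256,
                           architecture = c("progressive", "skip_sum")) {
  architecture <- match.arg(architecture)
  if (latent_dim < 1) stop_field("latent_dim", "must be >= 1")
  if (!is_power_of_two(final_resolution) || !is_power_of_two(base_resolution) ||
      final_resolution < base_resolution) {
    stop_field("final_resolution", "resolutions must be powers of two with final >= base")
  }
  structure(list(latent_dim = as.integer(latent_dim),
                 final_resolution = as.integer(final_resolution),
                 base_resolution = as.integer(base_resolution),
                 hidden = as.integer(hidden),
                 architecture = architecture),
            class = "generator_spec")
}

#' Discriminator specification
#'
#' @param hidden Trunk width.
#' @param architecture `"progressive"` (input resolution tracks the training
#'   stage, with faded from-image heads) or `"residual"` (fixed final
#'   resolution input, residual trunk connection; the companion of the
#'   skip-sum generator).
#' @return A `discriminator_spec`.
#' @export
discriminator_spec <- function(hidden = 128,
                               architecture = c("progressive", "residual")) {
  structure(list(hidden = as.integer(hidden),
                 architecture = match.arg(architecture)),
            class = "discriminator_spec")
}

#' Training configuration
#'
#' @param loss `"wgan_gp"` (Wasserstein critic with gradient penalty; the
#'   default for the progressive architecture) or `"logistic_r1"`
#'   (non-saturating logistic loss with R1 regularization; the default for
#'   the skip-sum architecture).  `NULL` selects by architecture.
#' @param lr Adam learning rate.  `beta1`/`beta2` follow the progressive-GAN
#'   convention (0, 0.99).
#' @param batch_size Minibatch size.
#' @param stage_images Images-seen budget for each non-final stage
#'   (fade-in plus stabilize).
#' @param final_stage_images Images-seen budget for the final stage
#'   (its stabilize phase benefits from a longer run and a larger batch).
#' @param final_batch_size Batch size for the final stabilize phase.
#' @param final_fade_images Images-seen budget of the final stage's fade-in
#'   (the remainder of `final_stage_images` is its stabilize phase).
#' @param fade_fraction Fraction of each grown stage spent fading in the new
#'   resolution (in `[0, 1]`).
#' @param n_critic_final Critic updates per generator update during the
#'   final stage (1 elsewhere).
#' @param head_lr_mult Learning-rate multiplier for the generator to-image
#'   heads; keeping head steps small limits the white high-frequency
#'   parameter noise that Adam otherwise injects at the finest scale.
#' @param final_lr_mult Learning-rate multiplier applied during the final
#'   stabilize phase.
#' @param gp_lambda Gradient-penalty coefficient (WGAN-GP).
#' @param r1_gamma R1 coefficient (logistic loss).
#' @param drift_eps Small quadratic drift penalty on real scores (keeps the
#'   critic output centered; WGAN-GP only).
#' @param seed Master seed; separate named streams are derived for parameter
#'   initialization, latents, measurement noise and data order.
#' @return A `training_config`.
#' @export
training_config <- function(loss = NULL, lr = 1e-3, batch_size = 16,
                            stage_images = 4800, final_stage_images = 36000,
                            final_batch_size = 32,
                            final_fade_images = min(2400, final_stage_images),
                            fade_fraction = 0.5,
                            n_critic_final = 2, head_lr_mult = 0.25,
                            final_lr_mult = 0.2, gp_lambda = 10,
                            r1_gamma = 10, drift_eps = 1e-3, seed = 1) {
  if (!is.null(loss)) loss <- match.arg(loss, c("wgan_gp", "logistic_r1"))
  if (fade_fraction < 0 || fade_fraction > 1) {
    stop_field("fade_fraction", "must lie in [0, 1]")
  }
  if (stage_images < 0 || final_stage_images < 0) {
    stop_field("stage_images", "budgets must be >= 0")
  }
  if (final_fade_images > final_stage_images) {
    stop_field("final_fade_images", "cannot exceed final_stage_images")
  }
  structure(list(loss = loss, lr = lr, batch_size = as.integer(batch_size),
                 stage_images = stage_images,
                 final_stage_images = final_stage_images,
                 final_batch_size = as.integer(final_batch_size),
                 final_fade_images = final_fade_images,
                 fade_fraction = fade_fraction,
                 n_critic_final = as.integer(n_critic_final),
                 head_lr_mult = head_lr_mult, final_lr_mult = final_lr_mult,
                 gp_lambda = gp_lambda, r1_gamma = r1_gamma,
                 drift_eps = drift_eps, seed = seed),
            class = "training_config")
}

#' Progressive training schedule
#'
#' Lists the resolution stages with their images-seen budgets and fade-in
#' fractions.  The skip-sum architecture trains in a single stage at the
#' final resolution (no progressive growing).
#'
#' @param gspec A [generator_spec()].
#' @param config A [training_config()].
#' @return A data frame with columns `resolution`, `images`, `fade_fraction`.
#' @export
progressive_schedule <- function(gspec, config = training_config()) {
  if (!is_power_of_two(gspec$final_resolution)) {
    stop_field("final_resolution", "must be a power of two")
  }
  if (gspec$architecture == "skip_sum") {
    return(data.frame(resolution = gspec$final_resolution,
                      images = config$final_stage_images,
                      fade_fraction = 0))
  }
  res <- resolution_chain(gspec$base_resolution, gspec$final_resolution)
  data.frame(
    resolution = res,
    images = c(rep(config$stage_images, length(res) - 1), config$final_stage_images),
    fade_fraction = c(0, rep(config$fade_fraction, length(res) - 1))
  )
}

# ---- operator bundles --------------------------------------------------------

#' Operator bundle for ambient training
#'
#' Pairs the measurement operator `H_n` with the reconstruction operator `O`
#' for insertion between the generator and the discriminator.  The
#' `"identity"` bundle (full mask, zero noise, real-part reconstruction)
#' short-circuits to an exact pass-through, under which ambient training is
#' bit-identical to plain training.
#'
#' @param model A [forward_model()], or `NULL` for the identity bundle.
#' @param recon A [reconstructor()].
#' @return An `operator_bundle`.
#' @export
operator_bundle <- function(model = NULL, recon = reconstructor("real_part")) {
  if (is.null(model)) {
    return(structure(list(type = "identity"), class = "operator_bundle"))
  }
  if (recon$mode == "corrected_magnitude" && !mask_is_full(model$mask)) {
    stop("corrected_magnitude reconstruction requires a full sampling mask",
         call. = FALSE)
  }
  if (recon$mode == "magnitude") {
    stop(paste0("plain magnitude reconstruction is not differentiable-safe for ",
                "generated objects; use 'corrected_magnitude' for the fake branch"),
         call. = FALSE)
  }
  identity_like <- mask_is_full(model$mask) && model$kspace_std == 0 &&
    recon$mode == "real_part"
  structure(list(type = if (identity_like) "identity" else "fourier",
                 model = model, recon = recon),
            class = "operator_bundle")
}

bundle_is_identity <- function(bundle) bundle$type == "identity"

# Apply O(H_n(.)) to a batch (rows = images at resolution n); returns output
# rows and a cache for the adjoint.
bundle_apply <- function(bundle, x_rows, n, seed) {
  if (bundle_is_identity(bundle)) {
    return(list(out = x_rows, cache = NULL))
  }
  model <- bundle$model
  b <- nrow(x_rows)
  out <- matrix(0, b, ncol(x_rows))
  diag_rows <- if (bundle$recon$mode == "corrected_magnitude") {
    matrix(0, b, ncol(x_rows))
  } else {
    NULL
  }
  for (i in seq_len(b)) {
    f <- unvec_image(x_rows[i, ], n)
    s_i <- derive_seed(seed, "sample-noise", i)
    if (bundle$recon$mode == "corrected_magnitude") {
      cf <- corrected_fake_reconstruct_impl(f, model, s_i)
      out[i, ] <- vec_image(cf$out)
      diag_rows[i, ] <- vec_image(cf$diag_grad)
    } else {
      g <- forward_measure(f, model, s_i)
      out[i, ] <- vec_image(pseudoinverse_reconstruct(g))
    }
  }
  list(out = out, cache = list(diag_rows = diag_rows))
}

bundle_adjoint <- function(bundle, g_rows, n, cache) {
  if (bundle_is_identity(bundle)) return(g_rows)
  if (bundle$recon$mode == "corrected_magnitude") {
    return(g_rows * cache$diag_rows)
  }
  mask <- bundle$model$mask
  if (mask_is_full(mask)) return(g_rows)
  out <- matrix(0, nrow(g_rows), ncol(g_rows))
  for (i in seq_len(nrow(g_rows))) {
    out[i, ] <- vec_image(measurement_component_adjoint(unvec_image(g_rows[i, ], n), mask))
  }
  out
}

# ---- training core -----------------------------------------------------------

default_loss_for <- function(gspec, config) {
  if (!is.null(config$loss)) return(config$loss)
  if (gspec$architecture == "skip_sum") "logistic_r1" else "wgan_gp"
}

# fake branch: generate at stage resolution, upsample to final, apply the
# operator bundle, pool back to stage resolution
fake_branch <- function(G, Z, stage_res, alpha, res, final_res, bundle, seed) {
  gc <- gen_forward(G, Z, stage_res, alpha, res)
  if (bundle_is_identity(bundle)) {
    return(list(x = gc$out, gen_cache = gc, op_cache = NULL))
  }
  f_full <- upsample_rows(gc$out, stage_res, final_res)
  ap <- bundle_apply(bundle, f_full, final_res, seed)
  x <- downsample_rows(ap$out, final_res, stage_res)
  list(x = x, gen_cache = gc, op_cache = ap$cache)
}

fake_branch_adjoint <- function(d_x, stage_res, final_res, bundle, op_cache) {
  if (bundle_is_identity(bundle)) return(d_x)
  d <- downsample_rows_adjoint(d_x, final_res, stage_res)
  d <- bundle_adjoint(bundle, d, final_res, op_cache)
  upsample_rows_adjoint(d, stage_res, final_res)
}

train_core <- function(real_rows, bundle, gspec, dspec, config,
                       resume_state = NULL, log_fn = NULL, max_phases = Inf) {
  final_res <- gspec$final_resolution
  res <- resolution_chain(gspec$base_resolution, final_res)
  trunk <- if (dspec$architecture == "residual") "residual" else "plain"
  loss <- default_loss_for(gspec, config)
  seed <- config$seed
  n_data <- nrow(real_rows)
  if (ncol(real_rows) != final_res^2) {
    stop("real images do not match the generator final resolution", call. = FALSE)
  }
  # pooled real data per resolution (reals pass through the same pooling code
  # path as reconstructed fakes)
  data_at <- list()
  data_at[[as.character(final_res)]] <- real_rows
  r <- final_res
  while (r > res[1]) {
    data_at[[as.character(r / 2)]] <- downsample_rows(data_at[[as.character(r)]], r, r / 2)
    r <- r / 2
  }
  sched <- progressive_schedule(gspec, config)
  # expand to phases
  phases <- list()
  for (i in seq_len(nrow(sched))) {
    sr <- sched$resolution[i]
    fade_imgs <- if (sr == final_res && gspec$architecture == "progressive" &&
                     nrow(sched) > 1) {
      min(config$final_fade_images, sched$images[i])
    } else {
      round(sched$images[i] * sched$fade_fraction[i])
    }
    stab_imgs <- sched$images[i] - fade_imgs
    if (fade_imgs > 0) phases[[length(phases) + 1]] <- list(res = sr, fade = TRUE, images = fade_imgs)
    if (stab_imgs > 0) phases[[length(phases) + 1]] <- list(res = sr, fade = FALSE, images = stab_imgs)
  }
  if (length(phases) == 0) {
    warning("zero training budget; returning the initialized model")
  }
  if (!is.null(resume_state)) {
    params <- resume_state$params
    st_g <- resume_state$adam_g; st_d <- resume_state$adam_d
    step_ct <- resume_state$step_ct
    phase_start <- resume_state$phase_idx + 1
    loss_log <- resume_state$loss_log
  } else {
    params <- init_gan_params(gspec, dspec, seed)
    st_g <- adam_new_state(); st_d <- adam_new_state()
    step_ct <- 0
    phase_start <- 1
    loss_log <- list()
  }
  head_mult <- list()
  for (rr in res) {
    head_mult[[paste0("A", rr)]] <- config$head_lr_mult
    head_mult[[paste0("c", rr)]] <- config$head_lr_mult
  }
  phase_end <- min(length(phases), max_phases)
  if (phase_start <= phase_end) {
    for (pi in phase_start:phase_end) {
      ph <- phases[[pi]]
      sr <- ph$res
      is_final_stab <- sr == final_res && !ph$fade
      batch <- if (is_final_stab) config$final_batch_size else config$batch_size
      lr_ph <- if (is_final_stab) config$lr * config$final_lr_mult else config$lr
      n_steps <- max(1, round(ph$images / batch))
      n_critic <- if (sr == final_res) config$n_critic_final else 1L
      for (it in seq_len(n_steps)) {
        step_ct <- step_ct + 1
        alpha <- if (ph$fade) it / n_steps else 1
        ## ---- critic update(s) ----
        d_loss <- NA_real_; pen_val <- NA_real_; wdist <- NA_real_
        for (ic in seq_len(n_critic)) {
          idx <- with_seed(derive_seed(seed, "data", step_ct * 8 + ic),
                           sample.int(n_data, batch, replace = n_data < batch))
          x_real <- data_at[[as.character(sr)]][idx, , drop = FALSE]
          z <- with_seed(derive_seed(seed, "latent", step_ct * 8 + ic),
                         matrix(stats::rnorm(batch * gspec$latent_dim), batch))
          fb <- fake_branch(params$G, z, sr, alpha, res, final_res, bundle,
                            derive_seed(seed, "noise", step_ct * 8 + ic))
          cr <- disc_forward(params$D, x_real, sr, alpha, res, trunk)
          cf <- disc_forward(params$D, fb$x, sr, alpha, res, trunk)
          if (loss == "wgan_gp") {
            eps_mix <- with_seed(derive_seed(seed, "gp-mix", step_ct * 8 + ic),
                                 stats::runif(batch))
            x_hat <- eps_mix * x_real + (1 - eps_mix) * fb$x
            pen <- penalty_grads(params$D, x_hat, sr, alpha, res, trunk,
                                 type = "gp", coef = config$gp_lambda)
            ds_r <- -1 / batch + 2 * config$drift_eps * cr$s[, 1] / batch
            ds_f <- rep(1 / batch, batch)
            wdist <- mean(cr$s) - mean(cf$s)
            d_loss <- -wdist + pen$penalty + config$drift_eps * mean(cr$s^2)
          } else {
            pen <- penalty_grads(params$D, x_real, sr, alpha, res, trunk,
                                 type = "r1", coef = config$r1_gamma)
            ds_r <- -sigmoid(-cr$s[, 1]) / batch
            ds_f <- sigmoid(cf$s[, 1]) / batch
            wdist <- mean(cr$s) - mean(cf$s)
            d_loss <- mean(softplus(-cr$s)) + mean(softplus(cf$s)) + pen$penalty
          }
          pen_val <- pen$penalty
          br <- disc_backward(params$D, cr, ds_r, sr, alpha, res)
          bf <- disc_backward(params$D, cf, ds_f, sr, alpha, res)
          gr_d <- br$gr
          for (nm in names(bf$gr)) {
            gr_d[[nm]] <- (if (is.null(gr_d[[nm]])) 0 else gr_d[[nm]]) + bf$gr[[nm]]
          }
          for (nm in names(pen$gr)) {
            gr_d[[nm]] <- (if (is.null(gr_d[[nm]])) 0 else gr_d[[nm]]) + pen$gr[[nm]]
          }
          upd <- adam_update(params$D, gr_d, st_d, lr_ph)
          params$D <- upd$par; st_d <- upd$state
        }
        ## ---- generator update ----
        z <- with_seed(derive_seed(seed, "latent", step_ct * 8 + 7),
                       matrix(stats::rnorm(batch * gspec$latent_dim), batch))
        fb <- fake_branch(params$G, z, sr, alpha, res, final_res, bundle,
                          derive_seed(seed, "noise", step_ct * 8 + 7))
        cf <- disc_forward(params$D, fb$x, sr, alpha, res, trunk)
        if (loss == "wgan_gp") {
          g_loss <- -mean(cf$s)
          ds_f <- rep(-1 / batch, batch)
        } else {
          g_loss <- mean(softplus(-cf$s))
          ds_f <- -sigmoid(-cf$s[, 1]) / batch
        }
        bf <- disc_backward(params$D, cf, ds_f, sr, alpha, res, need_dX = TRUE)
        d_fake <- fake_branch_adjoint(bf$dX, sr, final_res, bundle, fb$op_cache)
        gr_g <- gen_backward(params$G, fb$gen_cache, d_fake, sr, alpha, res)
        upd <- adam_update(params$G, gr_g, st_g, lr_ph, lr_mult = head_mult)
        params$G <- upd$par; st_g <- upd$state
        if (!is.finite(d_loss) || !is.finite(g_loss)) {
          stop(sprintf("training diverged (non-finite loss) at stage %d, step %d",
                       sr, step_ct), call. = FALSE)
        }
        if (it == n_steps || it %% 50 == 0) {
          loss_log[[length(loss_log) + 1]] <- data.frame(
            step = step_ct, resolution = sr, fade = ph$fade, alpha = alpha,
            d_loss = d_loss, g_loss = g_loss, wdist = wdist, penalty = pen_val)
          if (!is.null(log_fn)) log_fn(loss_log[[length(loss_log)]])
        }
      }
    }
  }
  manifest <- list(
    loss = loss, schedule = sched, seed = seed,
    seed_streams = c("param-init", "latent", "noise", "data", "gp-mix"),
    steps = step_ct, loss_log = do.call(rbind, loss_log),
    config = unclass(config), config_hash = config_hash(unclass(config))
  )
  structure(list(params = params, gspec = gspec, dspec = dspec,
                 config = config, manifest = manifest,
                 trainer_state = list(params = params, adam_g = st_g,
                                      adam_d = st_d, step_ct = step_ct,
                                      phase_idx = phase_end,
                                      loss_log = loss_log)),
            class = "som_generator")
}

#' @export
print.som_generator <- function(x, ...) {
  cat(sprintf("<som_generator> latent %d -> %dx%d (%s, %s loss, %d steps)\n",
              x$gspec$latent_dim, x$gspec$final_resolution,
              x$gspec$final_resolution, x$gspec$architecture,
              x$manifest$loss, x$manifest$steps))
  invisible(x)
}

#' Train an ambient GAN on measured data
#'
#' The discriminator is shown reconstructed real measurements
#' `f_r = O(g)` and reconstructed simulated measurements of generated
#' objects `O(H_n(G(z)))`, with a fresh measurement-noise realization per
#' generated sample per step.  At progressive stages below the final
#' resolution, generated objects are bilinearly upsampled to full resolution
#' before the operators and the reconstructions are average-pooled back down
#' before the discriminator.
#'
#' @param measurements List of `kspace_data` (all sharing the mask grid), or
#'   a precomputed matrix/ensemble of reconstructed images together with a
#'   non-`NULL` `bundle`.
#' @param bundle An [operator_bundle()] describing `H_n` and `O`.
#' @param gspec,dspec Network specifications.
#' @param config A [training_config()].
#' @param resume Optional `som_generator` whose trainer state should be
#'   continued (reproduces the interrupted run exactly).
#' @return A `som_generator` with the trained parameters and a manifest
#'   (schedule, seeds, loss trajectory).
#' @export
train_ambientgan <- function(measurements, bundle, gspec = generator_spec(),
                             dspec = discriminator_spec(),
                             config = training_config(), resume = NULL) {
  real_rows <- if (is.list(measurements) && inherits(measurements[[1]], "kspace_data")) {
    recon <- if (bundle_is_identity(bundle)) {
      reconstructor("real_part")
    } else {
      bundle$recon
    }
    t(vapply(measurements, function(g) vec_image(reconstruct(g, recon)),
             numeric(gspec$final_resolution^2)))
  } else if (inherits(measurements, "object_ensemble")) {
    ensemble_matrix(measurements)
  } else {
    as.matrix(measurements)
  }
  train_core(real_rows, bundle, gspec, dspec, config,
             resume_state = resume$trainer_state)
}

#' Train a plain (non-ambient) GAN directly on reconstructed images
#'
#' Identical training loop with the identity operator bundle; the baseline
#' that absorbs measurement noise into the learned model.
#'
#' @param recon_images `object_ensemble` or image-row matrix.
#' @inheritParams train_ambientgan
#' @export
train_plain_gan <- function(recon_images, gspec = generator_spec(),
                            dspec = discriminator_spec(),
                            config = training_config(), resume = NULL) {
  rows <- if (inherits(recon_images, "object_ensemble")) {
    ensemble_matrix(recon_images)
  } else {
    as.matrix(recon_images)
  }
  train_core(rows, operator_bundle(NULL), gspec, dspec, config,
             resume_state = resume$trainer_state)
}

#' Sample objects from a trained (or freshly initialized) generator
#'
#' @param model A `som_generator`.
#' @param n Number of objects.
#' @param seed Seed for the latent draws (recorded in the manifest).
#' @return An `object_ensemble` at the generator's final resolution.
#' @export
sample_objects <- function(model, n, seed = 1) {
  if (n < 1) stop_field("n", "must be >= 1")
  res <- resolution_chain(model$gspec$base_resolution, model$gspec$final_resolution)
  final <- model$gspec$final_resolution
  out <- matrix(0, n, final^2)
  chunk <- 256
  done <- 0
  while (done < n) {
    b <- min(chunk, n - done)
    z <- with_seed(derive_seed(seed, "sample-latent", done),
                   matrix(stats::rnorm(b * model$gspec$latent_dim), b))
    out[done + seq_len(b), ] <- gen_forward(model$params$G, z, final, 1, res)$out
    done <- done + b
  }
  matrix_ensemble(out, final,
                  manifest = list(source = "som_generator", n = n, seed = seed,
                                  latent_dim = model$gspec$latent_dim,
                                  model_steps = model$manifest$steps))
}

#' Save / load a generator checkpoint
#'
#' Single-file RDS archive containing parameters, specifications and the
#' training manifest, with a JSON manifest side-car.
#'
#' @param model A `som_generator`.
#' @param path Checkpoint path.
#' @export
save_generator <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(
    list(gspec = unclass(model$gspec), loss = model$manifest$loss,
         steps = model$manifest$steps, seed = model$manifest$seed,
         config_hash = model$manifest$config_hash),
    paste0(path, ".manifest.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname save_generator
#' @export
load_generator <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "som_generator")) stop("not a som_generator checkpoint", call. = FALSE)
  m
}
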