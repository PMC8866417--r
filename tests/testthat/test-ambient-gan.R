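ns <- asNamespace("ambientsom")

test_that("progressive schedule enumerates the doubling chain", {
  gs <- generator_spec(final_resolution = 32)
  sched <- progressive_schedule(gs, training_config())
  expect_equal(sched$resolution, c(4, 8, 16, 32))
  expect_equal(sum(sched$images),
               training_config()$stage_images * 3 + training_config()$final_stage_images)

  skip_gs <- generator_spec(final_resolution = 16, architecture = "skip_sum")
  s2 <- progressive_schedule(skip_gs, training_config())
  expect_equal(nrow(s2), 1)
  expect_equal(s2$resolution, 16)
  expect_equal(s2$fade_fraction, 0)

  cfg0 <- training_config(fade_fraction = 0)
  s3 <- progressive_schedule(gs, cfg0)
  expect_true(all(s3$fade_fraction[-nrow(s3)] == 0))
})

test_that("identity-operator ambient training is bitwise-equal to plain training", {
  rows <- noisy_recon_rows(64, grid = 16, sigma = 1.6, seed = 3)
  cfg <- training_config(batch_size = 8, stage_images = 48,
                         final_stage_images = 96, final_fade_images = 48,
                         final_batch_size = 8, n_critic_final = 1, seed = 4)
  gs <- tiny_gspec(16); ds <- tiny_dspec()
  amb <- train_ambientgan(rows, operator_bundle(
    forward_model(make_cartesian_mask(16, R = 1, scheme = "full"), 0),
    reconstructor("real_part")), gs, ds, cfg)
  pln <- train_plain_gan(rows, gs, ds, cfg)
  expect_identical(amb$manifest$loss_log, pln$manifest$loss_log)
  expect_identical(amb$params, pln$params)
})

test_that("training runs are reproducible and loggable", {
  rows <- lumpy_rows(48, grid = 16, seed = 6)
  cfg <- fast_config(seed = 9)
  m1 <- train_plain_gan(rows, tiny_gspec(16), tiny_dspec(), cfg)
  m2 <- train_plain_gan(rows, tiny_gspec(16), tiny_dspec(), cfg)
  expect_identical(m1$manifest$loss_log, m2$manifest$loss_log)
  expect_true(all(is.finite(m1$manifest$loss_log$d_loss)))
  s1 <- sample_objects(m1, 5, seed = 2)
  s2 <- sample_objects(m1, 5, seed = 2)
  expect_identical(s1$images, s2$images)
  expect_false(identical(s1$images, sample_objects(m1, 5, seed = 3)$images))
  expect_equal(dim(s1$images), c(16, 16, 5))
})

test_that("an untrained generator still produces finite well-formed images", {
  cfg <- training_config(stage_images = 0, final_stage_images = 0,
                         final_fade_images = 0, seed = 1)
  expect_warning(
    m <- train_plain_gan(lumpy_rows(4, grid = 8), tiny_gspec(8), tiny_dspec(), cfg),
    "zero training budget")
  s <- sample_objects(m, 3, seed = 1)
  expect_true(all(is.finite(s$images)))
  expect_equal(dim(s$images), c(8, 8, 3))
})

test_that("fresh measurement noise is drawn per step but is seed-reproducible", {
  bundle <- operator_bundle(
    forward_model(make_cartesian_mask(8, R = 1, scheme = "full"), 2),
    reconstructor("real_part"))
  x <- matrix(runif(4 * 64), 4)
  a <- ns$bundle_apply(bundle, x, 8, seed = 1)
  b <- ns$bundle_apply(bundle, x, 8, seed = 1)
  c2 <- ns$bundle_apply(bundle, x, 8, seed = 2)
  expect_identical(a$out, b$out)
  expect_false(identical(a$out, c2$out))
  # distinct samples in a batch get distinct noise
  same <- rbind(x[1, ], x[1, ])
  ab <- ns$bundle_apply(bundle, same, 8, seed = 5)
  expect_false(identical(ab$out[1, ], ab$out[2, ]))
})

test_that("perturbing generator parameters moves the discriminator's fake input", {
  tiny <- generator_spec(latent_dim = 4, final_resolution = 8, hidden = 6)
  params <- ns$init_gan_params(tiny, discriminator_spec(hidden = 5), seed = 2)
  res <- ns$resolution_chain(4, 8)
  z <- matrix(rnorm(2 * 4), 2)
  bundle <- operator_bundle(forward_model(make_cartesian_mask(8, R = 2, seed = 1), 0),
                            reconstructor("real_part"))
  base <- ns$fake_branch(params$G, z, 8, 1, res, 8, bundle, seed = 3)$x
  params$G$W0[1, 1] <- params$G$W0[1, 1] + 1e-3
  pert <- ns$fake_branch(params$G, z, 8, 1, res, 8, bundle, seed = 3)$x
  expect_gt(max(abs(pert - base)), 0)
})

test_that("interrupted training resumes to the exact same trajectory", {
  rows <- lumpy_rows(32, grid = 8, seed = 8)
  cfg <- training_config(batch_size = 8, stage_images = 64,
                         final_stage_images = 64, final_fade_images = 32,
                         final_batch_size = 8, n_critic_final = 1, seed = 12)
  gs <- tiny_gspec(8); ds <- tiny_dspec()
  full <- train_plain_gan(rows, gs, ds, cfg)
  part <- ns$train_core(rows, operator_bundle(NULL), gs, ds, cfg, max_phases = 1)
  resumed <- train_plain_gan(rows, gs, ds, cfg, resume = part)
  expect_identical(resumed$params, full$params)
  expect_identical(resumed$manifest$loss_log, full$manifest$loss_log)
})

test_that("checkpoints round-trip through disk", {
  m <- train_plain_gan(lumpy_rows(16, grid = 8), tiny_gspec(8), tiny_dspec(),
                       fast_config(seed = 3))
  path <- tempfile(fileext = ".rds")
  save_generator(m, path)
  expect_true(file.exists(paste0(path, ".manifest.json")))
  back <- load_generator(path)
  expect_identical(back$params, m$params)
  expect_identical(sample_objects(back, 2, seed = 1)$images,
                   sample_objects(m, 2, seed = 1)$images)
})

test_that("the skip-sum / residual variant trains with the logistic-R1 loss", {
  rows <- lumpy_rows(48, grid = 16, seed = 5)
  cfg <- training_config(batch_size = 8, final_stage_images = 128,
                         final_fade_images = 0, final_batch_size = 8,
                         n_critic_final = 1, seed = 2)
  m <- train_ambientgan(rows, operator_bundle(
    forward_model(make_cartesian_mask(16, R = 1, scheme = "full"), 1.6),
    reconstructor("real_part")),
    tiny_gspec(16, arch = "skip_sum"), tiny_dspec("residual"), cfg)
  expect_equal(m$manifest$loss, "logistic_r1")
  expect_equal(unique(m$manifest$loss_log$resolution), 16)
  expect_true(all(is.finite(m$manifest$loss_log$d_loss)))
})

test_that("magnitude-mode bundles enforce their preconditions", {
  full <- forward_model(make_cartesian_mask(16, R = 1, scheme = "full"), 1)
  under <- forward_model(make_cartesian_mask(16, R = 2, seed = 1), 1)
  expect_error(operator_bundle(under, reconstructor("corrected_magnitude")), "full")
  expect_error(operator_bundle(full, reconstructor("magnitude")), "corrected_magnitude")
  expect_s3_class(operator_bundle(full, reconstructor("corrected_magnitude")),
                  "operator_bundle")
})
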