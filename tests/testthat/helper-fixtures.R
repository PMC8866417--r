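# Shared fixtures, built in code at test time.

desk_lumpy <- function(grid = 32, normalize = "per_image_minmax") {
  lumpy_config(grid_size = grid, mean_lump_count = 25, lump_width = 4,
               normalize = normalize)
}

# small ensemble as a rows-matrix (n x npix)
lumpy_rows <- function(n, grid = 32, seed = 11, normalize = "per_image_minmax") {
  ens <- make_ensemble(desk_lumpy(grid, normalize), n, seed)
  ambientsom:::ensemble_matrix(ens)
}

# noisy real-part reconstructions of lumpy objects at k-space noise sigma
noisy_recon_rows <- function(n, grid = 32, sigma = 0.1 * grid, seed = 11) {
  ens <- make_ensemble(desk_lumpy(grid), n, seed)
  model <- forward_model(make_cartesian_mask(grid, R = 1, scheme = "full"), sigma)
  t(vapply(seq_len(n), function(i) {
    g <- forward_measure(ens$images[, , i], model, ambientsom:::derive_seed(seed, "recon", i))
    as.vector(pseudoinverse_reconstruct(g))
  }, numeric(grid^2)))
}

rows_to_array <- function(rows, grid) {
  array(t(rows), dim = c(grid, grid, nrow(rows)))
}

tiny_gspec <- function(final = 16, arch = "progressive") {
  generator_spec(latent_dim = 16, final_resolution = final, hidden = 48,
                 architecture = arch)
}

tiny_dspec <- function(arch = "progressive") {
  discriminator_spec(hidden = 24, architecture = arch)
}

fast_config <- function(seed = 1, ...) {
  training_config(batch_size = 8, stage_images = 64, final_stage_images = 64,
                  final_batch_size = 8, n_critic_final = 1, seed = seed, ...)
}
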