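# Config-driven end-to-end runs: simulate -> train -> generate -> evaluate,
# replicating the stylized study designs at desk scale.

#' Load and validate a run configuration
#'
#' Configurations are YAML (or an equivalent R list) with blocks:
#' `study` (one of `fully_sampled`, `undersampled`, `magnitude_experimental`),
#' `object` (lumpy config fields plus `n_train`), `imaging`
#' (`kspace_std`, `R`, `scheme`), `training` (any [training_config()] field
#' plus `latent_dim`, `hidden`, `architecture`, `ambient`), `evaluation`
#' (`n_samples`, `roi_size`, `task_noise_std`, `signal_amplitude`) and
#' `seed`.  Study-mode consistency is enforced: `magnitude_experimental`
#' forces corrected-magnitude reconstruction on a full mask;
#' `undersampled` forces real-part reconstruction.
#'
#' @param x Path to a YAML file, or a named list.
#' @return A validated `run_config`.
#' @export
run_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  study <- match.arg(cfg$study %||% "fully_sampled",
                     c("fully_sampled", "undersampled", "magnitude_experimental"))
  obj <- cfg$object %||% list()
  img <- cfg$imaging %||% list()
  trn <- cfg$training %||% list()
  evl <- cfg$evaluation %||% list()
  grid <- obj$grid_size %||% 32
  R_val <- img$R %||% if (study == "undersampled") 4 else 1
  if (study != "undersampled" && R_val != 1) {
    stop(sprintf("config error at imaging.R: study '%s' requires R = 1", study),
         call. = FALSE)
  }
  if (study == "undersampled" && R_val <= 1) {
    stop("config error at imaging.R: undersampled study requires R > 1", call. = FALSE)
  }
  recon_mode <- switch(study,
                       fully_sampled = "real_part",
                       undersampled = "real_part",
                       magnitude_experimental = "corrected_magnitude")
  out <- list(
    study = study,
    object = list(grid_size = grid,
                  mean_lump_count = obj$mean_lump_count %||% 25,
                  lump_amplitude = obj$lump_amplitude %||% 1,
                  lump_width = obj$lump_width %||% 4,
                  normalize = obj$normalize %||% "per_image_minmax",
                  n_train = obj$n_train %||% 512),
    imaging = list(kspace_std = img$kspace_std %||% (0.1 * grid),
                   R = R_val,
                   scheme = img$scheme %||% if (R_val > 1) "uniform_random" else "full",
                   recon_mode = recon_mode),
    training = trn,
    evaluation = list(n_samples = evl$n_samples %||% 200,
                      roi_size = evl$roi_size %||% 8,
                      task_noise_std = evl$task_noise_std %||% 0.02,
                      signal_amplitude = evl$signal_amplitude %||% 0.2),
    seed = cfg$seed %||% 1
  )
  class(out) <- "run_config"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

run_lumpy_config <- function(cfg) {
  lumpy_config(grid_size = cfg$object$grid_size,
               mean_lump_count = cfg$object$mean_lump_count,
               lump_amplitude = cfg$object$lump_amplitude,
               lump_width = cfg$object$lump_width,
               normalize = cfg$object$normalize)
}

run_forward_model <- function(cfg) {
  mask <- make_cartesian_mask(cfg$object$grid_size, R = cfg$imaging$R,
                              scheme = cfg$imaging$scheme,
                              seed = derive_seed(cfg$seed, "mask"))
  forward_model(mask, cfg$imaging$kspace_std)
}

#' Simulate the measurement dataset for a run
#'
#' Generates the synthetic object ensemble and its k-space measurements
#' according to the study design, fully seeded from the configuration.
#'
#' @param cfg A [run_config()].
#' @param out_dir Optional directory; when given, objects, k-space and a
#'   manifest are written there.
#' @return List with `objects` (`object_ensemble`), `measurements`
#'   (list of `kspace_data`), `model` (the [forward_model()]) and `manifest`.
#' @export
run_simulate <- function(cfg, out_dir = NULL) {
  lcfg <- run_lumpy_config(cfg)
  objects <- make_ensemble(lcfg, cfg$object$n_train, derive_seed(cfg$seed, "objects"))
  model <- run_forward_model(cfg)
  measurements <- lapply(seq_len(ensemble_size(objects)), function(i) {
    forward_measure(objects$images[, , i], model,
                    derive_seed(cfg$seed, "measure", i))
  })
  manifest <- list(study = cfg$study, object = cfg$object, imaging = cfg$imaging,
                   seed = cfg$seed, n = ensemble_size(objects),
                   config_hash = config_hash(unclass(cfg)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_ensemble(objects, file.path(out_dir, "objects.rds"))
    write_kspace(measurements, file.path(out_dir, "kspace.rds"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(objects = objects, measurements = measurements, model = model,
       manifest = manifest)
}

run_training_config <- function(cfg) {
  trn <- cfg$training
  tc_args <- trn[names(trn) %in% names(formals(training_config))]
  tc_args$seed <- tc_args$seed %||% derive_seed(cfg$seed, "training")
  do.call(training_config, tc_args)
}

run_specs <- function(cfg) {
  trn <- cfg$training
  arch <- trn$architecture %||% "progressive"
  gspec <- generator_spec(latent_dim = trn$latent_dim %||% 64,
                          final_resolution = cfg$object$grid_size,
                          hidden = trn$hidden %||% 256,
                          architecture = arch)
  dspec <- discriminator_spec(hidden = trn$dhidden %||% 128,
                              architecture = if (arch == "skip_sum") "residual" else "progressive")
  list(gspec = gspec, dspec = dspec)
}

#' Train the configured model on a simulated dataset
#'
#' @param cfg A [run_config()].
#' @param dataset Result of [run_simulate()].
#' @param ambient Train the ambient model (`TRUE`, default) or the plain
#'   baseline on the reconstructed images (`FALSE`).
#' @param checkpoint Optional path for [save_generator()].
#' @return A `som_generator`.
#' @export
run_train <- function(cfg, dataset, ambient = TRUE, checkpoint = NULL) {
  sp <- run_specs(cfg)
  tc <- run_training_config(cfg)
  recon <- reconstructor(cfg$imaging$recon_mode)
  model <- if (ambient) {
    bundle <- operator_bundle(dataset$model, recon)
    train_ambientgan(dataset$measurements, bundle, sp$gspec, sp$dspec, tc)
  } else {
    recon_imgs <- t(vapply(dataset$measurements, function(g) {
      vec_image(reconstruct(g, recon))
    }, numeric(cfg$object$grid_size^2)))
    train_plain_gan(recon_imgs, sp$gspec, sp$dspec, tc)
  }
  model$manifest$dataset_hash <- dataset$manifest$config_hash
  model$manifest$ambient <- ambient
  if (!is.null(checkpoint)) save_generator(model, checkpoint)
  model
}

#' Evaluate a trained model against the reference ensemble
#'
#' Computes the FID between generated and reference objects, the FID between
#' their measurement components (undersampled studies), the blind noise
#' estimates, and the Hotelling-observer SNR on both ensembles.
#'
#' @param cfg A [run_config()].
#' @param model A `som_generator`.
#' @param reference The ground-truth `object_ensemble` (synthetic studies).
#' @param out Optional path for the JSON report.
#' @return The report as a list.
#' @export
run_evaluate <- function(cfg, model, reference, out = NULL) {
  if (missing(reference) || is.null(reference)) {
    stop("evaluation requires a reference ensemble; experimental-style runs ",
         "support noise metrics only", call. = FALSE)
  }
  n_eval <- cfg$evaluation$n_samples
  fake <- sample_objects(model, n_eval, seed = derive_seed(cfg$seed, "eval-sample"))
  n_ref <- min(ensemble_size(reference), n_eval)
  ref_sub <- reference$images[, , seq_len(n_ref), drop = FALSE]
  fid_obj <- compute_fid(ref_sub, fake$images)
  fid_meas <- NA_real_
  if (cfg$imaging$R > 1) {
    mask <- run_forward_model(cfg)$mask
    proj <- function(arr) {
      out_a <- arr
      for (i in seq_len(dim(arr)[3])) {
        out_a[, , i] <- measurement_component(arr[, , i], mask)
      }
      out_a
    }
    fid_meas <- compute_fid(proj(ref_sub), proj(fake$images))
  }
  grid <- cfg$object$grid_size
  m_roi <- cfg$evaluation$roi_size
  sig <- gaussian_signal(grid, amplitude = cfg$evaluation$signal_amplitude,
                         width = m_roi / 8, support_radius = m_roi / 2 - 0.6)
  task <- detection_task(sig, roi_size = m_roi,
                         task_noise_std = cfg$evaluation$task_noise_std)
  roi_stack <- function(arr) {
    n_i <- dim(arr)[3]
    m <- task$roi_size
    out_a <- array(0, dim = c(m, m, n_i))
    for (i in seq_len(n_i)) out_a[, , i] <- extract_roi(arr[, , i], task)
    out_a
  }
  snr_ref <- compute_snr_ho(task, roi_stack(ref_sub))
  snr_fake <- compute_snr_ho(task, roi_stack(fake$images))
  report <- list(
    study = cfg$study,
    fid_objects = fid_obj,
    fid_measurement_components = fid_meas,
    noise_std_generated = estimate_image_noise_std(fake)$sigma,
    noise_std_reference = estimate_image_noise_std(ref_sub)$sigma,
    snr_ho = snr_fake$snr, snr_ho_reference = snr_ref$snr,
    snr_ho_convention = "sqrt",
    n_samples = n_eval, extractor = "pixel_pool8",
    seeds = list(master = cfg$seed),
    model_hash = model$manifest$config_hash
  )
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  report
}

#' Run the full scaled-down noisy fully-sampled comparison
#'
#' Simulates lumpy objects, trains the ambient model and the plain baseline
#' on the same noisy reconstructions, and reports the generated-image noise
#' estimates and FIDs for both — the desk-scale version of the headline
#' denoising comparison.
#'
#' @param cfg A [run_config()] (defaults to the fully sampled study).
#' @param out Optional JSON report path.
#' @return Report list with one entry per model.
#' @export
run_demo <- function(cfg = run_config(list(study = "fully_sampled")), out = NULL) {
  dataset <- run_simulate(cfg)
  amb <- run_train(cfg, dataset, ambient = TRUE)
  pln <- run_train(cfg, dataset, ambient = FALSE)
  rep_a <- run_evaluate(cfg, amb, dataset$objects)
  rep_p <- run_evaluate(cfg, pln, dataset$objects)
  recon_noise <- cfg$imaging$kspace_std / cfg$object$grid_size
  report <- list(ambient = rep_a, plain = rep_p,
                 true_reconstruction_noise = recon_noise)
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  report
}

#' Validate an evaluation report against the bundled schema
#'
#' Structural validation (required fields, basic types and bounds) against
#' `inst/extdata/report-schema.json`.
#'
#' @param report A report list from [run_evaluate()] or a path to its JSON.
#' @return `TRUE` invisibly, or an error describing the first violation.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- jsonlite::read_json(report)
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "ambientsom"))
  for (req in unlist(schema$required)) {
    if (is.null(report[[req]])) {
      stop(sprintf("report is missing required field '%s'", req), call. = FALSE)
    }
  }
  for (nm in names(schema$properties)) {
    val <- report[[nm]]
    if (is.null(val)) next
    prop <- schema$properties[[nm]]
    types <- unlist(prop$type)
    ok <- any(vapply(types, function(tp) {
      switch(tp,
             number = is.numeric(val) && (length(val) != 1 || !is.na(val)),
             integer = is.numeric(val) && all(val == round(val)),
             string = is.character(val),
             object = is.list(val),
             null = length(val) == 1 && is.na(val),
             FALSE)
    }, logical(1)))
    if (!ok) {
      stop(sprintf("report field '%s' is not of type %s", nm,
                   paste(types, collapse = "/")), call. = FALSE)
    }
    if (!is.null(prop$minimum) && is.numeric(val) && !anyNA(val) &&
        any(val < prop$minimum)) {
      stop(sprintf("report field '%s' is below %s", nm, prop$minimum),
           call. = FALSE)
    }
    if (!is.null(prop$enum) && !val %in% unlist(prop$enum)) {
      stop(sprintf("report field '%s' not in allowed values", nm), call. = FALSE)
    }
  }
  invisible(TRUE)
}
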