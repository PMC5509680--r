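#' Experiment configuration
#'
#' One declarative object driving the whole pipeline: phantom cohort,
#' discovery/validation split, preprocessing, sampling, network, training
#' and inference. Any subset of fields can be overridden; the rest keep
#' their defaults. Fully serializable ([save_experiment_config()]), and a
#' saved config plus its seed reproduces the run.
#'
#' @param phantom,split,registration,sampling,model,train,infer named lists
#'   overriding the defaults of the corresponding stage.
#' @param seed global seed; all stage seeds are derived from it.
#' @param out_dir optional output directory for artefacts.
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = list(), split = list(),
                              registration = list(), sampling = list(),
                              model = list(), train = list(),
                              infer = list(), seed = 1L, out_dir = NULL) {
  defaults <- list(
    phantom = list(
      n_subjects = 12L, grid_shape = c(48L, 48L, 12L), spacing = c(2, 2, 5),
      tumour_radius = 8, tumour_intensity = c(t2w = 1.5, dwi_b0 = 0.5,
                                              dwi_high_b = 4),
      noise_sd = 1, artefact_mode = "none", misalignment = 0,
      shape_perturbation = 0,
      distractors = list(list(centre_offset = c(24, -20, 0), radius = 4.5,
                              offsets = c(t2w = 3.2, dwi_b0 = 2,
                                          dwi_high_b = 4)))
    ),
    split = list(rule = "parity", n_validation = NULL),
    registration = list(enabled = FALSE, grid_spacing = 4,
                        penalty_weight = 20, n_resolutions = 2,
                        max_iterations = 40),
    sampling = list(n_per_class = 200L, M = 11L, dilation_radius_mm = 10,
                    threshold = 2.0),
    model = list(conv_filters = c(4L, 8L, 16L, 32L),
                 conv_kernels = c(5L, 5L, 3L, 3L), fc_width = 48L),
    train = list(lr = 1.0, rho = 0.9, eps = 1e-6, l2 = 1e-4,
                 batch_size = 128L, patience = 5L, improvement_tol = 1e-3,
                 train_fraction = 0.8, max_epochs = 10L, verbose = FALSE),
    infer = list(threshold = 0.5, connectivity = 26L, batch = 1024L)
  )
  cfg <- list(
    phantom = modifyList(defaults$phantom, phantom),
    split = modifyList(defaults$split, split),
    registration = modifyList(defaults$registration, registration),
    sampling = modifyList(defaults$sampling, sampling),
    model = modifyList(defaults$model, model),
    train = modifyList(defaults$train, train),
    infer = modifyList(defaults$infer, infer),
    seed = as.integer(seed), out_dir = out_dir
  )
  class(cfg) <- "experiment_config"
  cfg
}

#' Desk-scale end-to-end configuration
#'
#' The scaled-down experiment exercised by the acceptance suite: 30 phantom
#' subjects of 64 x 64 x 16 voxels at 2 x 2 x 5 mm (20 discovery, 10
#' held-out), 500 patches per class per discovery subject, patch edge 11,
#' the nine-layer topology at reduced width (4/8/16/32 filters, doubling
#' rule preserved), and an epoch cap of 15 (the patience rule rarely fires
#' at this scale: epoch-to-epoch test-cost noise stays above the 1e-3
#' improvement tolerance). Runs end to end on one CPU in about ten
#' minutes.
#'
#' @param seed global seed.
#' @return An [experiment_config()].
#' @export
desk_scale_config <- function(seed = 1L) {
  experiment_config(
    phantom = list(n_subjects = 30L, grid_shape = c(64L, 64L, 16L),
                   tumour_radius = 9,
                   distractors = list(list(centre_offset = c(30, -26, 0),
                                           radius = 5,
                                           offsets = c(t2w = 3.2, dwi_b0 = 2,
                                                       dwi_high_b = 4)))),
    split = list(rule = "random", n_validation = 10L),
    sampling = list(n_per_class = 500L, M = 11L),
    model = list(conv_filters = c(4L, 8L, 16L, 32L), fc_width = 48L),
    train = list(lr = 1.0, max_epochs = 15L),
    seed = seed
  )
}

# Build the per-subject phantom base config from the experiment config
# (distractor centres are stored as offsets from the tumour centre).
phantom_base_config <- function(pc, seed) {
  centre <- (pc$grid_shape - 1) / 2 * pc$spacing
  distractors <- lapply(pc$distractors, function(d) {
    list(centre = centre + d$centre_offset, radius = d$radius,
         offsets = d$offsets)
  })
  phantom_config(
    grid_shape = pc$grid_shape, spacing = pc$spacing,
    tumour_radius = pc$tumour_radius, tumour_centre = centre,
    tumour_intensity = pc$tumour_intensity, distractors = distractors,
    noise_sd = pc$noise_sd, artefact_mode = pc$artefact_mode,
    misalignment = pc$misalignment,
    shape_perturbation = pc$shape_perturbation, seed = seed
  )
}

#' Run the full experiment
#'
#' Generates (or accepts) a phantom cohort, assigns the
#' discovery/validation split, standardizes every subject, samples
#' stratified patches from the discovery subjects, splits them 80/20 into
#' training and test patches, trains the classifier with early stopping,
#' produces probability maps and segmentations for every validation
#' subject, and evaluates DSC and voxelwise AUC against the ground truth.
#'
#' @param config an [experiment_config()].
#' @param cohort optional pre-built `phantom_cohort` (otherwise generated
#'   from `config$phantom`).
#' @param out_dir optional artefact directory (overrides the config);
#'   receives the manifest, model checkpoint, history, per-subject
#'   probability/segmentation NIfTI volumes, the metrics table and the
#'   config itself.
#' @return List with `metrics` (a [metrics_report()]), `model`, `history`,
#'   `maps`, `masks`, `split` (per-subject assignment), `config`.
#' @export
run_experiment <- function(config, cohort = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  out_dir <- out_dir %||% config$out_dir
  seeds <- derive_seeds(config$seed, 5L)
  if (is.null(cohort)) {
    cohort <- generate_cohort(config$phantom$n_subjects,
                              phantom_base_config(config$phantom, seeds[1]),
                              seed = seeds[1])
  }
  ids <- vapply(cohort, function(s) s$volume$subject_id, character(1))
  split <- switch(
    config$split$rule,
    parity = split_by_parity(ids),
    random = with_seed(seeds[2], {
      nv <- config$split$n_validation %||% max(1L, length(ids) %/% 3L)
      val <- sample.int(length(ids), nv)
      ifelse(seq_along(ids) %in% val, "validation", "discovery")
    }),
    stopf("unknown split rule '%s'", config$split$rule)
  )
  names(split) <- ids
  # preprocessing: per-sequence standardization (registration only when
  # channels are deliberately misaligned)
  std <- lapply(cohort, function(s) {
    v <- standardize_volume(s$volume)
    if (isTRUE(config$registration$enabled)) {
      rc <- registration_config(
        grid_spacing = config$registration$grid_spacing,
        penalty_weight = config$registration$penalty_weight,
        n_resolutions = config$registration$n_resolutions,
        max_iterations = config$registration$max_iterations
      )
      reg <- register_to_reference(v$sequences$t2w, v$sequences$dwi_b0,
                                   rc, v$spacing)
      v$sequences$t2w <- reg$warped
    }
    v
  })
  disc <- which(split == "discovery")
  vali <- which(split == "validation")
  if (length(disc) == 0L || length(vali) == 0L) {
    stopf("split leaves an empty discovery or validation set")
  }
  samp_seeds <- derive_seeds(seeds[3], length(disc))
  sets <- vector("list", length(disc))
  for (j in seq_along(disc)) {
    i <- disc[j]
    regions <- decompose_regions(std[[i]]$sequences$dwi_high_b,
                                 cohort[[i]]$labels, std[[i]]$spacing,
                                 config$sampling$dilation_radius_mm,
                                 config$sampling$threshold)
    sets[[j]] <- sample_patches(std[[i]], regions,
                                config$sampling$n_per_class,
                                config$sampling$M, seed = samp_seeds[j])
  }
  discovery_patches <- combine_patch_sets(sets)
  tc <- do.call(train_config,
                c(config$train, list(seed = seeds[4])))
  sp <- split_discovery(discovery_patches, tc$train_fraction, seed = seeds[4])
  spec <- network_spec(conv_filters = config$model$conv_filters,
                       conv_kernels = config$model$conv_kernels,
                       fc_width = config$model$fc_width)
  net <- build_network(spec, config$sampling$M, seed = seeds[5])
  net <- train_network(net, sp$train, sp$test, tc)
  maps <- vector("list", length(vali))
  masks <- vector("list", length(vali))
  truths <- vector("list", length(vali))
  for (j in seq_along(vali)) {
    i <- vali[j]
    maps[[j]] <- predict_volume(net, std[[i]], batch = config$infer$batch)
    masks[[j]] <- threshold_and_select(maps[[j]], config$infer$threshold,
                                       config$infer$connectivity)
    truths[[j]] <- cohort[[i]]$labels
  }
  metrics <- metrics_report(maps, masks, truths)
  result <- list(metrics = metrics, model = net, history = net$history,
                 maps = maps, masks = masks, split = split, config = config)
  if (!is.null(out_dir)) write_experiment(result, cohort, out_dir)
  result
}

# Persist all artefacts of a run, each alongside the config and seed that
# produced it.
write_experiment <- function(result, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(cohort, file.path(out_dir, "cohort"),
               split = unname(result$split))
  save_model(result$model, file.path(out_dir, "model.json"))
  write_history(result$model, file.path(out_dir, "history.tsv"))
  save_experiment_config(result$config, file.path(out_dir, "config.json"))
  pred_dir <- file.path(out_dir, "predictions")
  dir.create(pred_dir, showWarnings = FALSE)
  for (j in seq_along(result$maps)) {
    id <- result$maps[[j]]$subject_id
    write_nifti(result$maps[[j]]$p,
                file.path(pred_dir, sprintf("%s_prob.nii", id)),
                result$maps[[j]]$spacing)
    write_nifti(result$masks[[j]]$mask,
                file.path(pred_dir, sprintf("%s_seg.nii", id)),
                result$maps[[j]]$spacing)
  }
  write.table(result$metrics$per_subject,
              file.path(out_dir, "metrics.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(out_dir)
}

#' Reproduce the candidate-selection failure mode
#'
#' Generates a phantom whose distractor is larger than the tumour and
#' locally indistinguishable from it (identical per-sequence intensity
#' offsets), applies a trained model, and post-processes the probability
#' map. The classifier assigns high probability to both structures; the
#' largest-component selection then picks the distractor, so the DSC
#' against the truth collapses to zero even though the voxelwise AUC of
#' the same map stays high.
#'
#' @param model a trained `mparseg_model`.
#' @param config the [experiment_config()] the model was trained under
#'   (grid, spacing and intensity settings are reused).
#' @param seed phantom seed.
#' @return List with `dsc`, `auc`, `map`, `mask`, `phantom`.
#' @export
failure_mode_case <- function(model, config, seed = 99L) {
  pc <- config$phantom
  centre <- (pc$grid_shape - 1) / 2 * pc$spacing
  mimic_radius <- pc$tumour_radius * 1.5
  cfg <- phantom_config(
    grid_shape = pc$grid_shape, spacing = pc$spacing,
    tumour_radius = pc$tumour_radius * 0.9, tumour_centre = centre,
    tumour_intensity = pc$tumour_intensity,
    distractors = list(list(centre = centre + c(32, -26, 0),
                            radius = mimic_radius,
                            offsets = pc$tumour_intensity)),
    noise_sd = pc$noise_sd, seed = seed
  )
  ph <- generate_phantom(cfg, subject_id = "sub-failure")
  v <- standardize_volume(ph$volume)
  map <- predict_volume(model, v, batch = config$infer$batch)
  mask <- threshold_and_select(map, config$infer$threshold,
                               config$infer$connectivity)
  list(dsc = dsc(mask, ph$labels), auc = voxel_auc(map, ph$labels),
       map = map, mask = mask, phantom = ph)
}

#' Save / load an experiment configuration
#'
#' @param config an [experiment_config()].
#' @param path JSON path.
#' @return `path` invisibly; `load_experiment_config()` returns the
#'   restored config (unspecified fields get their defaults).
#' @export
save_experiment_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname save_experiment_config
#' @export
load_experiment_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$phantom$tumour_intensity <- unlist(raw$phantom$tumour_intensity)
  if (!is.null(raw$phantom$distractors)) {
    if (is.data.frame(raw$phantom$distractors)) {
      raw$phantom$distractors <- lapply(
        seq_len(nrow(raw$phantom$distractors)), function(i) {
          list(centre_offset = unlist(raw$phantom$distractors$centre_offset[[i]]),
               radius = raw$phantom$distractors$radius[[i]],
               offsets = unlist(raw$phantom$distractors$offsets[[i]]))
        })
    } else {
      raw$phantom$distractors <- lapply(raw$phantom$distractors, function(d) {
        list(centre_offset = unlist(d$centre_offset), radius = d$radius,
             offsets = unlist(d$offsets))
      })
    }
  }
  experiment_config(
    phantom = raw$phantom, split = raw$split,
    registration = raw$registration, sampling = raw$sampling,
    model = raw$model, train = raw$train, infer = raw$infer,
    seed = raw$seed, out_dir = raw$out_dir
  )
}
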