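#' Default experiment configuration
#'
#' Bundles every physical constant, corpus range, tiling and training
#' hyperparameter with its package default; any field can be overridden via
#' `...` (unknown names are rejected). `scale` controls the corpus sizes.
#'
#' @param ... Named overrides of the defaults.
#' @return A validated `pmi_config` list.
#' @export
pmi_config <- function(...) {
  cfg <- list(
    radius = 12.5,                # mm, 25-mm diameter phantom
    mesh_nodes = 852,             # representative mesh size
    mesh_seed = 11L,
    background_mua = 0.01,        # mm^-1
    background_musp = 0.8,        # mm^-1
    thermal = thermal_params(),
    resolution = 256L,
    grid_shape = 7L,
    duration_sim = 8,             # s, four-sided simulation study
    duration_twin = 12,           # s, experimental twin
    dt = 0.2,                     # s
    n_train = 600L,
    n_test = 150L,
    n_train_twin = 600L,
    corpus_seed = 101L,
    test_seed = 202L,
    train_seed = 303L,
    noise_sigma = 0,
    stop_accuracy = 0.9,
    split = 0.75,
    max_epochs = 40L,
    batch_size = 128L,
    inclusion_mua_cases = 0.023,
    alpha = NULL,
    max_iter = 12L,
    jacobian_perturbation = 0.01,
    source_sim = source_spec(),                      # four-sided
    source_twin = source_spec(angles_deg = 90, width_mm = 8),
    fusion = "vote-ratio")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pmi_config")
}

#' Write / read a config as YAML
#' @param cfg A `pmi_config`.
#' @param path YAML file path.
#' @export
write_config_yaml <- function(cfg, path) {
  plain <- lapply(unclass(cfg), function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$thermal)) raw$thermal <- do.call(thermal_params, raw$thermal)
  for (nm in c("source_sim", "source_twin")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- do.call(source_spec, raw[[nm]])
  }
  do.call(pmi_config, raw)
}

#' Run the simulated detector evaluation study
#'
#' Generates a seeded training corpus of 25-mm phantoms with 1-3 absorbing
#' inclusions under four-sided illumination, trains the two-stage detector,
#' measures tile-classification accuracy on a freshly seeded test corpus,
#' and evaluates hot-node detection on the three representative cases
#' (ellipse; three circles; two closely spaced circles).
#'
#' @param config A [pmi_config()].
#' @param verbose Print stage progress.
#' @return List with the `detector`, per-case `confusions`, pooled
#'   `sensitivity` (%), summed `fn_total`, `fp_mean_distance_mm`,
#'   `tile_test_accuracy` (%), `validation_accuracy` (%), and the `mesh`.
#' @export
run_simulation_study <- function(config = pmi_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  mesh <- generate_disk_mesh(config$radius, config$mesh_nodes,
                             seed = config$mesh_seed)
  say("corpus: %d training phantoms", config$n_train)
  phantoms <- generate_corpus(mesh, config$n_train, corpus_ranges(),
                              seed = config$corpus_seed,
                              background_mua = config$background_mua,
                              background_musp = config$background_musp)
  corpus <- build_detector_corpus(phantoms, config$source_sim,
                                  config$thermal, config$duration_sim,
                                  config$grid_shape, config$resolution,
                                  config$dt, config$noise_sigma,
                                  seed = config$corpus_seed)
  say("training detector")
  detector <- train_detector(corpus, seed = config$train_seed,
                             stop_accuracy = config$stop_accuracy,
                             split = config$split,
                             max_epochs = config$max_epochs,
                             batch_size = config$batch_size)
  val_acc <- utils::tail(detector$classifier$log$val_accuracy, 1)
  say("validation accuracy %.3f; test corpus: %d phantoms", val_acc,
      config$n_test)
  test_ph <- generate_corpus(mesh, config$n_test, corpus_ranges(),
                             seed = config$test_seed,
                             background_mua = config$background_mua,
                             background_musp = config$background_musp)
  test_corpus <- build_detector_corpus(test_ph, config$source_sim,
                                       config$thermal, config$duration_sim,
                                       config$grid_shape, config$resolution,
                                       config$dt, config$noise_sigma,
                                       seed = config$test_seed)
  store <- tile_store(test_corpus$maps, test_corpus$grid,
                      test_corpus$resolution)
  probs <- predict_in_batches(detector$classifier$params,
                              detector$classifier$dims, store)
  test_acc <- mean((probs > 0.5) == (as.integer(test_corpus$tile_labels) == 1))
  say("tile test accuracy %.3f; evaluating representative cases", test_acc)
  cases <- representative_cases(mesh, config$inclusion_mua_cases)
  confusions <- list(); fp_all <- integer(0); truth_all_of_fp <- list()
  fp_dists <- numeric(0)
  for (nm in names(cases)) {
    ph <- cases[[nm]]
    dm <- simulate_difference_map(ph, config$source_sim, config$thermal,
                                  config$duration_sim, config$resolution,
                                  config$dt,
                                  homogeneous_map = corpus$homogeneous_map)
    pred <- detect_hot_nodes(detector, dm, mesh, fusion = config$fusion)
    cm <- confusion(pred$predicted_hot, ph$hot_nodes, mesh$n_nodes)
    confusions[[nm]] <- cm
    fp_nodes <- setdiff(pred$predicted_hot, ph$hot_nodes)
    if (length(fp_nodes)) {
      fp_dists <- c(fp_dists, rep(fp_mean_distance(fp_nodes, ph$hot_nodes,
                                                   mesh), length(fp_nodes)))
    }
  }
  tp <- sum(vapply(confusions, `[[`, numeric(1), "TP"))
  fn <- sum(vapply(confusions, `[[`, numeric(1), "FN"))
  out <- list(detector = detector, mesh = mesh, confusions = confusions,
              sensitivity = 100 * tp / (tp + fn),
              fn_total = fn,
              fp_mean_distance_mm = if (length(fp_dists)) mean(fp_dists) else 0,
              tile_test_accuracy = 100 * test_acc,
              validation_accuracy = 100 * val_acc,
              homogeneous_map = corpus$homogeneous_map)
  say("sensitivity %.1f%%, FN %d, FP mean distance %.3f mm",
      out$sensitivity, out$fn_total, out$fp_mean_distance_mm)
  out
}

#' Run the experimental-phantom twin reconstruction study
#'
#' Simulates the printed two-inclusion phantom under top-only illumination
#' (12 s), trains a detector on a corpus simulated under the same
#' acquisition, extracts the hot-node prior from the measured difference
#' map, and reconstructs the absorption map with the soft-prior update and
#' with the standard identity-regularized update, reporting per-inclusion
#' errors and background artifact levels.
#'
#' @param config A [pmi_config()].
#' @param detector Optional pre-trained `pmi_detector` matching the twin
#'   acquisition (trained internally when `NULL`).
#' @param prior_nodes Optional explicit prior node set (bypasses the
#'   detector, e.g. ground-truth hot nodes).
#' @param verbose Print stage progress.
#' @return List with both `pmi_recon` results, the detection confusion,
#'   per-inclusion percent errors and artifact levels, and Table-style
#'   region statistics.
#' @export
run_experiment_twin <- function(config = pmi_config(), detector = NULL,
                                prior_nodes = NULL, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  mesh <- generate_disk_mesh(config$radius, config$mesh_nodes,
                             seed = config$mesh_seed)
  twin <- experiment_twin_phantom(mesh)
  source <- config$source_twin
  duration <- config$duration_twin
  say("simulating twin measurement (top illumination, %g s)", duration)
  optics <- phantom_optics(twin$phantom)
  T_final <- final_temperature(mesh, optics, source, config$thermal,
                               duration, config$dt)
  measured <- rasterize(T_final, mesh, config$resolution)
  # preprocessing: recover the average homogeneous absorption near the spot
  mua0 <- fit_homogeneous_mua(measured, mesh, source, config$thermal,
                              duration, musp = config$background_musp,
                              dt = config$dt)
  say("fitted homogeneous mua %.5f mm^-1", mua0)
  homog <- homogeneous_reference_map(mesh, mua0, config$background_musp,
                                     source, config$thermal, duration,
                                     config$resolution, config$dt)
  diff_map <- homogeneous_difference(measured, homog)
  cm <- NULL
  if (is.null(prior_nodes)) {
    if (is.null(detector)) {
      say("training twin detector (%d phantoms, top illumination)",
          config$n_train_twin)
      phantoms <- generate_corpus(mesh, config$n_train_twin, corpus_ranges(),
                                  seed = config$corpus_seed + 1L,
                                  background_mua = config$background_mua,
                                  background_musp = config$background_musp)
      corpus <- build_detector_corpus(phantoms, source, config$thermal,
                                      duration, config$grid_shape,
                                      config$resolution, config$dt,
                                      config$noise_sigma,
                                      seed = config$corpus_seed + 1L)
      detector <- train_detector(corpus, seed = config$train_seed + 1L,
                                 stop_accuracy = config$stop_accuracy,
                                 split = config$split,
                                 max_epochs = config$max_epochs,
                                 batch_size = config$batch_size)
    }
    pred <- detect_hot_nodes(detector, diff_map, mesh,
                             fusion = config$fusion)
    prior_nodes <- pred$predicted_hot
    cm <- confusion(prior_nodes, twin$phantom$hot_nodes, mesh$n_nodes)
    say("detected %d hot nodes (truth %d), sensitivity %.3f",
        length(prior_nodes), length(twin$phantom$hot_nodes), cm$sensitivity)
  }
  say("reconstructing with soft prior")
  rec_prior <- reconstruct(measured, mesh, source, config$thermal, duration,
                           initial_mua = mua0, musp = config$background_musp,
                           prior = prior_nodes, alpha = config$alpha,
                           max_iter = config$max_iter, dt = config$dt,
                           perturbation = config$jacobian_perturbation)
  say("reconstructing without prior")
  rec_plain <- reconstruct(measured, mesh, source, config$thermal, duration,
                           initial_mua = mua0, musp = config$background_musp,
                           prior = NULL, alpha = config$alpha,
                           max_iter = config$max_iter, dt = config$dt,
                           perturbation = config$jacobian_perturbation)
  inc1 <- twin$inclusion_nodes[[1]]; inc2 <- twin$inclusion_nodes[[2]]
  inc_all <- unique(c(inc1, inc2))
  # background excludes a 1-mm guard band around the inclusions
  d_to_inc <- apply(mesh$node_coords, 1, function(p) {
    min(sqrt(colSums((t(mesh$node_coords[inc_all, , drop = FALSE]) - p)^2)))
  })
  bg_nodes <- setdiff(which(d_to_inc > 1), inc_all)
  truth_mua <- twin$phantom$mua
  regions <- list(inclusion1 = inc1, inclusion2 = inc2,
                  background = bg_nodes)
  stats_prior <- region_stats(rec_prior$mua, truth_mua, regions, bg_nodes,
                              inc_all, reference_mua = config$background_mua)
  stats_plain <- region_stats(rec_plain$mua, truth_mua, regions, bg_nodes,
                              inc_all, reference_mua = config$background_mua)
  out <- list(
    recon_with_prior = rec_prior, recon_without_prior = rec_plain,
    detection_confusion = cm, prior_nodes = prior_nodes,
    fitted_background_mua = mua0,
    stats_with_prior = stats_prior, stats_without_prior = stats_plain,
    inclusion1_error_with_prior = stats_prior$percent_error[1],
    inclusion2_error_with_prior = stats_prior$percent_error[2],
    inclusion1_error_without_prior = stats_plain$percent_error[1],
    inclusion2_error_without_prior = stats_plain$percent_error[2],
    artifact_with_prior = attr(stats_prior, "artifact_level"),
    artifact_without_prior = attr(stats_plain, "artifact_level"),
    mesh = mesh, twin = twin, measured = measured, diff_map = diff_map)
  say("inclusion errors with prior: %.2f%% / %.2f%%; artifacts %.1f%% vs %.1f%%",
      out$inclusion1_error_with_prior, out$inclusion2_error_with_prior,
      out$artifact_with_prior, out$artifact_without_prior)
  out
}
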