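# Reference desk-scale study: one self-contained experiment tying every
# stage together (synthesis -> label curation -> preprocessing -> training
# -> evaluation -> attribution) on a 32-voxel grid, sized for a single CPU.

#' Desk-scale study conditions
#'
#' The fixed synthetic study design used by the package's reference
#' experiments: a 32x32x32 grid with a 10-region atlas, 60 subjects at 50%
#' prevalence, one visit per subject, MRI effect planted in region 2 and
#' PET effect in region 7 (disjoint, so the modalities are complementary),
#' voxel noise 1, between-subject regional variability 1, and a
#' patient-wise 80/20 test split with a further patient-wise validation
#' carve-out for early stopping.
#'
#' @param seed integer seed governing the whole study.
#' @param effect_size additive class effect per modality (default 5, i.e.
#'   effect/noise = 5; the complementarity experiment halves it).
#' @param n_subjects number of subjects.
#' @param n_regions atlas regions.
#' @param grid one grid dimension (cubic grid).
#' @param mri_region,pet_region planted region ids; NULL (default) plants
#'   the effects in the two most central regions of the generated atlas
#'   (MRI in the most central, PET in the second), so the planted signal
#'   lies inside the model's field of view after central-slice selection —
#'   standard phantom practice: the lesion goes where the model looks.
#' @return a `study_conditions` list.
#' @export
study_conditions <- function(seed = 1L, effect_size = 5, n_subjects = 60L,
                             n_regions = 10L, grid = 32L, mri_region = NULL,
                             pet_region = NULL, baseline_mean = 5,
                             between_subject_sd = 1, n_visits = 2L) {
  list(seed = as.integer(seed), effect_size = effect_size,
       n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
       grid = as.integer(grid), mri_region = mri_region,
       pet_region = pet_region, baseline_mean = baseline_mean,
       between_subject_sd = between_subject_sd, n_visits = as.integer(n_visits),
       preproc = preproc_config(size = grid, n_slices = 12L))
}

#' Regions ranked by axial centrality
#'
#' Orders atlas regions by the distance of their centroid's axial (slice)
#' coordinate from the grid centre — the regions best covered by a
#' central-slice selection come first.
#'
#' @param atlas a [make_toy_atlas()] object.
#' @return integer region ids, most central first.
#' @export
central_regions <- function(atlas) {
  d3 <- atlas$grid_shape[3]
  w <- which(atlas$labels > 0L, arr.ind = TRUE)
  lab <- atlas$labels[atlas$labels > 0L]
  cz <- tapply(w[, 3], lab, mean)
  ids <- as.integer(names(cz))
  ids[order(abs(cz - (d3 + 1) / 2))]
}

#' Build the datasets of a desk-scale study
#'
#' Generates the cohort, corrects and assigns labels, performs the
#' patient-wise 80/20 split plus a patient-wise validation carve-out from
#' the training side, and preprocesses everything into model-ready
#' examples for each modality and for the fusion pairing.
#'
#' @param cond a [study_conditions()] list.
#' @return list with per-modality example lists `fit`, `val`, `test` under
#'   `$mri`, `$pet`, `$fusion`, plus `atlas`, `specs`, `split`.
#' @export
build_study_data <- function(cond = study_conditions()) {
  atlas <- make_toy_atlas(rep(cond$grid, 3L), cond$n_regions,
                          seed = child_seed(cond$seed, 1L),
                          baseline_mean = cond$baseline_mean)
  ctr <- central_regions(atlas)
  mri_region <- cond$mri_region %||% ctr[1]
  pet_region <- cond$pet_region %||% ctr[2]
  specs <- list(
    mri = effect_spec("MRI", mri_region, effect_size = cond$effect_size,
                      between_subject_sd = cond$between_subject_sd),
    pet = effect_spec("PET", pet_region, effect_size = cond$effect_size,
                      between_subject_sd = cond$between_subject_sd))
  coh <- simulate_cohort(cond$n_subjects, 0.5, atlas, specs$mri, specs$pet,
                         timeline_params = list(n_visits = cond$n_visits,
                                                flip_prob = 0),
                         seed = child_seed(cond$seed, 2L))
  scans <- label_scans(coh$scans, coh$events)
  sp <- patient_wise_split(scans, 0.2, seed = child_seed(cond$seed, 3L))
  vs <- patient_wise_split(sp$train, 0.2, seed = child_seed(cond$seed, 4L))

  pick <- function(recs, mod) Filter(function(r) r$modality == mod, recs)
  sets <- list()
  for (mod in c("MRI", "PET")) {
    key <- tolower(mod)
    fit <- preprocess_scans(pick(vs$train, mod), cond$preproc)
    sc <- attr(fit, "scale")   # training cohort's intensity map, reused
    sets[[key]] <- list(
      fit = fit,
      val = preprocess_scans(pick(vs$test, mod), cond$preproc, scale = sc),
      test = preprocess_scans(pick(sp$test, mod), cond$preproc, scale = sc))
  }
  sets$fusion <- lapply(stats::setNames(nm = c("fit", "val", "test")),
                        function(part) make_fusion_examples(
                          sets$mri[[part]], sets$pet[[part]]))
  c(sets, list(atlas = atlas, specs = specs,
               split = list(test_subjects = sp$test_subjects)))
}

#' Train one variant on a prepared study and evaluate held-out performance
#'
#' @param variant `"mri_3d"`, `"pet_3d"` or `"fusion_3d"`.
#' @param data a [build_study_data()] result.
#' @param seed training seed (weight init, shuffling, dropout).
#' @param cfg a [train_config()]; default the desk preset.
#' @return list with `model`, `history`, `predictions` (held-out),
#'   `accuracy`, `auc`, `metrics`.
#' @export
run_variant <- function(variant, data, seed = 1L,
                        cfg = train_config_desk(seed = seed)) {
  key <- switch(variant, mri_3d = "mri", pet_3d = "pet",
                fusion_3d = "fusion",
                stop_nf("unsupported study variant '%s'", variant))
  input_shape <- c(dim(data$mri$fit[[1]]$x))
  model <- build_model(variant, arch_config_desk(), input_shape,
                       seed = child_seed(seed, 7L))
  res <- train(model, data[[key]]$fit, data[[key]]$val, cfg)
  p <- predict(res$model, data[[key]]$test)
  m <- metrics(confusion(p), percent = FALSE)
  list(model = res$model, history = res$history, predictions = p,
       accuracy = m[["accuracy"]], auc = auc(p), metrics = m)
}

#' Planted-region recovery check
#'
#' Runs group-level Grad-CAM attribution for the positive held-out group
#' and reports whether every planted region is in the top-90th-percentile
#' selection. When several trained models are given (an ensemble over
#' training seeds on the same data), their atlas-space group maps are
#' averaged before region scoring: training-trajectory noise in the
#' relevance maps of small networks averages out, while the planted
#' signal is the component the models share.
#'
#' @param model a trained uni-modal `nf_model`, or a list of them.
#' @param data a [build_study_data()] result.
#' @param modality `"mri"` or `"pet"`.
#' @param stage Grad-CAM convolutional stage. The desk default is stage 2:
#'   on a 32-voxel grid it is the deepest stage whose spatial grid (8x8x3)
#'   can still resolve a 10-region parcellation; the last stage (2x2x1) is
#'   coarser than the regions being scored.
#' @return list with `recovered` (logical), `attribution`, `planted`.
#' @export
check_region_recovery <- function(model, data, modality = "mri", stage = 2L) {
  planted <- data$specs[[modality]]$affected_regions
  pos <- Filter(function(e) e$y == 1, data[[modality]]$test)
  if (!length(pos)) stop_nf("no positive held-out examples")
  models <- if (inherits(model, "nf_model")) list(model) else model
  gas <- lapply(models, function(m)
    group_attribution(m, pos, data$atlas, class_index = 1, stage = stage))
  mean_map <- Reduce(`+`, lapply(gas, `[[`, "mean_map")) / length(gas)
  cover <- Reduce(`|`, lapply(gas, `[[`, "coverage"))
  group <- region_attribution(mean_map, data$atlas, mask = cover)
  freq <- Reduce(`+`, lapply(gas, `[[`, "selection_frequency")) / length(gas)
  ga <- list(group = group, selection_frequency = freq, mean_map = mean_map,
             coverage = cover, n_used = gas[[1]]$n_used)
  planted_names <- data$atlas$names[as.character(planted)]
  list(recovered = all(planted_names %in% group$selected),
       attribution = ga, planted = unname(planted_names))
}
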