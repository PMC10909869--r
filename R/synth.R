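#' Generate a toy brain atlas on a voxel grid
#'
#' Builds an ellipsoidal "brain" mask centred in the grid and partitions it
#' into `n_regions` connected regions by seeded Voronoi assignment: region
#' seed points are drawn uniformly from the mask and every brain voxel is
#' labelled by its nearest seed. Because a Voronoi cell intersected with an
#' ellipsoid is convex, every region is connected and non-empty. The atlas
#' plays the role a full anatomical parcellation (e.g. a 120-region
#' cortical/sub-cortical atlas) plays on real data, on the same grid as the
#' simulated volumes so no registration is needed.
#'
#' Each region also receives a fixed baseline intensity (drawn once, from
#' `seed`), which [simulate_volume()] uses as the class-independent tissue
#' contrast.
#'
#' @param grid_shape integer vector of 3 voxel dimensions, each >= 16.
#' @param n_regions number of regions (>= 1; >= 10 recommended so that a
#'   90th-percentile region selection is meaningful).
#' @param seed integer seed; the atlas is a pure function of its arguments.
#' @param baseline_mean,baseline_sd mean and spread of the per-region
#'   baseline intensities. The default spread (1, the voxel-noise unit)
#'   gives a near-homogeneous tissue background — the classic localization-
#'   phantom design, in which a planted effect is not outshone by baseline
#'   anatomy contrast.
#' @return an object of class `toy_atlas`: list with `labels` (3D integer
#'   array, 0 outside the brain, 1..R inside), `names` (region id -> name),
#'   `grid_shape`, `baseline` (per-region baseline intensity), `n_regions`.
#' @export
make_toy_atlas <- function(grid_shape, n_regions, seed, baseline_mean = 20,
                           baseline_sd = 1) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L) stop_nf("grid_shape must have 3 dimensions")
  if (any(grid_shape < 16L))
    stop_nf("each grid dimension must be >= 16 (got %s)",
            paste(grid_shape, collapse = "x"))
  n_regions <- as.integer(n_regions)
  if (n_regions < 1L) stop_nf("n_regions must be >= 1")

  ctr <- (grid_shape + 1) / 2
  semi <- 0.42 * grid_shape
  co <- expand.grid(i = seq_len(grid_shape[1]),
                    j = seq_len(grid_shape[2]),
                    l = seq_len(grid_shape[3]))
  d2 <- ((co$i - ctr[1]) / semi[1])^2 +
        ((co$j - ctr[2]) / semi[2])^2 +
        ((co$l - ctr[3]) / semi[3])^2
  inside <- d2 <= 1
  n_brain <- sum(inside)
  if (n_brain < n_regions)
    stop_nf("grid too small: brain mask has %d voxels but %d regions requested",
            n_brain, n_regions)

  labels <- integer(prod(grid_shape))
  seeded(seed, {
    if (n_regions == 1L) {
      labels[inside] <- 1L
    } else {
      # multi-source region growing from random seed voxels: each region is
      # 6-connected by construction (a discrete geodesic Voronoi partition)
      pts <- which(inside)[sample.int(n_brain, n_regions)]
      labels[pts] <- seq_len(n_regions)
      d1 <- grid_shape[1]; d12 <- grid_shape[1] * grid_shape[2]
      shifts <- c(-1L, 1L, -d1, d1, -d12, d12)
      # guard against wrap-around at the lattice edges per axis
      ii <- co$i; jj <- co$j; ll <- co$l
      ok_dir <- list(ii > 1L, ii < grid_shape[1], jj > 1L, jj < grid_shape[2],
                     ll > 1L, ll < grid_shape[3])
      repeat {
        grew <- FALSE
        for (s in seq_along(shifts)) {
          src <- which(labels > 0L & ok_dir[[s]])
          dst <- src + shifts[s]
          new <- dst[labels[dst] == 0L & inside[dst]]
          if (length(new)) {
            labels[new] <- labels[new - shifts[s]]
            grew <- TRUE
          }
        }
        if (!grew) break
      }
    }
    baseline <- rnorm(n_regions, mean = baseline_mean, sd = baseline_sd)
  }) -> baseline

  structure(list(
    labels = array(labels, dim = grid_shape),
    names = stats::setNames(sprintf("region_%02d", seq_len(n_regions)),
                            seq_len(n_regions)),
    grid_shape = grid_shape,
    baseline = baseline,
    n_regions = n_regions
  ), class = "toy_atlas")
}

#' Specify a planted class effect for one modality
#'
#' Encodes how the positive class differs from the negative class in one
#' modality: which atlas regions carry the effect, how large the additive
#' intensity shift is, the voxel noise level, and (for PET) how many time
#' frames are acquired. MRI and PET specs with disjoint `affected_regions`
#' make the modalities complementary, so multi-modal fusion has genuinely
#' more information than either modality alone.
#'
#' @param modality `"MRI"` or `"PET"`.
#' @param affected_regions integer region ids carrying the class effect.
#' @param effect_size additive intensity shift (arbitrary units, >= 0).
#' @param noise_sd standard deviation of i.i.d. Gaussian voxel noise.
#' @param n_frames number of PET time frames (ignored for MRI).
#' @param between_subject_sd standard deviation of a per-volume scalar
#'   intensity shift applied to the affected regions in *both* classes —
#'   the biological between-subject variability of regional intensity that
#'   keeps the classification task from being trivially separable. Drawn
#'   once per volume, so it cancels exactly when two volumes share a seed.
#' @return an `effect_spec` list.
#' @export
effect_spec <- function(modality = c("MRI", "PET"), affected_regions,
                        effect_size = 5, noise_sd = 1, n_frames = 4,
                        between_subject_sd = 1) {
  modality <- match.arg(modality)
  if (effect_size < 0) stop_nf("effect_size must be >= 0")
  if (noise_sd < 0) stop_nf("noise_sd must be >= 0")
  if (between_subject_sd < 0) stop_nf("between_subject_sd must be >= 0")
  if (modality == "PET" && n_frames < 1) stop_nf("n_frames must be >= 1")
  structure(list(modality = modality,
                 affected_regions = as.integer(affected_regions),
                 effect_size = effect_size, noise_sd = noise_sd,
                 n_frames = as.integer(n_frames),
                 between_subject_sd = between_subject_sd),
            class = "effect_spec")
}

#' Simulate one subject's diagnosis timeline
#'
#' Produces dated binary diagnosis events with strictly increasing days.
#' Labels follow `base_label_path` (the subject's true disease course,
#' typically monotone 0 -> 1) with independent random flips injected at rate
#' `flip_prob` — the isolated false positives/negatives that longitudinal
#' label correction is designed to undo.
#'
#' @param n_visits number of visits (>= 1).
#' @param day_gap_range integer range (lo, hi) of days between consecutive
#'   visits; the first visit day is drawn from the same range.
#' @param base_label_path binary vector of length `n_visits`: the true labels.
#' @param flip_prob per-visit probability of recording the wrong label.
#' @param seed integer seed.
#' @return data.frame with columns `day` (integer), `label` (0/1 recorded)
#'   and `true_label` (0/1 before flips).
#' @export
simulate_timeline <- function(n_visits, day_gap_range = c(180L, 400L),
                              base_label_path = rep(0L, n_visits),
                              flip_prob = 0, seed = 1) {
  n_visits <- as.integer(n_visits)
  if (n_visits < 1L) stop_nf("n_visits must be >= 1")
  if (flip_prob < 0 || flip_prob > 1) stop_nf("flip_prob must be in [0, 1]")
  if (length(base_label_path) != n_visits)
    stop_nf("base_label_path must have length n_visits")
  seeded(seed, {
    gaps <- sample(seq(day_gap_range[1], day_gap_range[2]), n_visits,
                   replace = TRUE)
    flips <- rbinom(n_visits, 1L, flip_prob)
  })
  labels <- as.integer(xor(base_label_path, flips))
  data.frame(day = cumsum(gaps), label = labels,
             true_label = as.integer(base_label_path))
}

#' Simulate one MRI- or PET-like volume
#'
#' Inside the brain mask each voxel gets its region's baseline intensity,
#' plus `effect_size` in the spec's affected regions when `class_label` is
#' positive, plus i.i.d. Gaussian voxel noise; the background is zero-mean
#' noise. For PET the function returns a 4D array of `n_frames` frames, each
#' an independently noised copy of the same 3D target, so the per-voxel
#' frame mean equals the target in expectation (and exactly when
#' `noise_sd = 0`).
#'
#' @param atlas a [make_toy_atlas()] object.
#' @param class_label 0 (negative) or 1 (positive).
#' @param spec an [effect_spec()].
#' @param seed integer seed.
#' @return 3D array (MRI) or 4D array (PET, last axis = time).
#' @export
simulate_volume <- function(atlas, class_label, spec, seed) {
  stopifnot(inherits(atlas, "toy_atlas"), inherits(spec, "effect_spec"))
  if (!class_label %in% c(0, 1)) stop_nf("class_label must be 0 or 1")
  bad <- setdiff(spec$affected_regions, seq_len(atlas$n_regions))
  if (length(bad))
    stop_nf("unknown atlas region id(s): %s", paste(bad, collapse = ", "))

  lab <- atlas$labels
  target <- array(0, dim = atlas$grid_shape)
  inside <- lab > 0L
  target[inside] <- atlas$baseline[lab[inside]]
  if (class_label == 1 && spec$effect_size > 0 && length(spec$affected_regions))
    target[lab %in% spec$affected_regions] <-
      target[lab %in% spec$affected_regions] + spec$effect_size

  seeded(seed, {
    if (spec$between_subject_sd > 0 && length(spec$affected_regions)) {
      # subject-level regional intensity shift, class-independent; drawn
      # first so two volumes sharing a seed share it (it cancels in
      # class-difference checks)
      target[lab %in% spec$affected_regions] <-
        target[lab %in% spec$affected_regions] +
        rnorm(1, 0, spec$between_subject_sd)
    }
    if (spec$modality == "PET") {
      out <- array(0, dim = c(atlas$grid_shape, spec$n_frames))
      for (t in seq_len(spec$n_frames))
        out[, , , t] <- target +
          if (spec$noise_sd > 0) rnorm(length(target), 0, spec$noise_sd) else 0
      out
    } else {
      target + if (spec$noise_sd > 0)
        array(rnorm(length(target), 0, spec$noise_sd), dim = dim(target))
      else 0
    }
  })
}

#' Simulate a longitudinal multi-modal cohort
#'
#' Assigns each subject a class (positive with probability `prevalence`);
#' positive subjects follow a monotone disease path converting at a random
#' visit, negatives stay negative. Each visit yields one diagnosis event
#' (with label flips at `flip_prob`, the noise label correction should
#' repair) and one paired MRI + PET scan generated from the visit's *true*
#' disease state.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param prevalence probability a subject is positive, in (0, 1).
#' @param atlas a [make_toy_atlas()] object.
#' @param mri_spec,pet_spec [effect_spec()] objects for the two modalities.
#' @param timeline_params list with `n_visits`, `day_gap_range`, `flip_prob`.
#' @param seed integer seed.
#' @return list with `scans` (list of scan records: `subject_id`, `modality`,
#'   `day`, `volume`, `true_label`, `label` (NA until assigned), `scan_id`)
#'   and `events` (data.frame `subject_id`, `day`, `label`, `true_label`).
#' @export
simulate_cohort <- function(n_subjects, prevalence, atlas, mri_spec, pet_spec,
                            timeline_params = list(), seed = 1) {
  if (n_subjects < 2) stop_nf("n_subjects must be >= 2")
  if (prevalence <= 0 || prevalence >= 1)
    stop_nf("prevalence must be in (0, 1)")
  tp <- utils::modifyList(
    list(n_visits = 4L, day_gap_range = c(180L, 400L), flip_prob = 0.1),
    timeline_params)
  nv <- as.integer(tp$n_visits)

  cls <- seeded(seed, rbinom(n_subjects, 1L, prevalence))
  conv <- seeded(child_seed(seed, 1L),
                 sample.int(nv, n_subjects, replace = TRUE))

  scans <- list()
  events <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%03d", s)
    path <- if (cls[s] == 1L) as.integer(seq_len(nv) >= conv[s]) else
      rep(0L, nv)
    tl <- simulate_timeline(nv, tp$day_gap_range, path, tp$flip_prob,
                            seed = child_seed(seed, 10L + s))
    events[[s]] <- cbind(subject_id = sid, tl)
    for (v in seq_len(nv)) {
      vol_m <- simulate_volume(atlas, path[v], mri_spec,
                               seed = child_seed(seed, 1000L + s * 10L + v))
      vol_p <- simulate_volume(atlas, path[v], pet_spec,
                               seed = child_seed(seed, 100000L + s * 10L + v))
      scans[[length(scans) + 1L]] <- list(
        subject_id = sid, modality = "MRI", day = tl$day[v], volume = vol_m,
        true_label = path[v], label = NA_integer_,
        scan_id = sprintf("%s_v%d_MRI", sid, v))
      scans[[length(scans) + 1L]] <- list(
        subject_id = sid, modality = "PET", day = tl$day[v], volume = vol_p,
        true_label = path[v], label = NA_integer_,
        scan_id = sprintf("%s_v%d_PET", sid, v))
    }
  }
  list(scans = scans, events = do.call(rbind, events))
}

#' Summarise scan records as a data.frame
#'
#' @param scans list of scan records (see [simulate_cohort()]).
#' @return data.frame with one row per scan (volumes omitted).
#' @export
scan_table <- function(scans) {
  do.call(rbind, lapply(scans, function(r)
    data.frame(subject_id = r$subject_id, modality = r$modality, day = r$day,
               label = r$label, true_label = r$true_label %||% NA_integer_,
               scan_id = r$scan_id)))
}
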