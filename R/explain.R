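# Grad-CAM relevance maps and atlas-region attribution.

# Index of the post-ReLU activation of conv stage `stage` within a feature
# block built by build_feature_block (conv, relu, pool, bn per stage).
relu_index <- function(stage) (stage - 1L) * 4L + 2L

#' Grad-CAM relevance map for one example
#'
#' Computes the neuron importance weights
#' `alpha_k = (1/Z) * sum over spatial positions of d score / d A_k`
#' (global average pooling of the backpropagated gradients, Z = number of
#' spatial positions) and the relevance map
#' `L = ReLU(sum_k alpha_k A_k)`, where `A_k` are the post-ReLU feature
#' maps of the chosen convolutional stage. The class score is the model's
#' pre-sigmoid logit: for the positive class the logit itself, for the
#' negative class its negation. For 3D models the pooling runs over all
#' three spatial axes and Z is the voxel count.
#'
#' @param model a trained `nf_model`.
#' @param example one example (`list(x = array, ...)`, or
#'   `list(mri =, pet =)` for fusion).
#' @param class_index target class: 1/`"positive"` (default) or
#'   0/`"negative"`.
#' @param stage convolutional stage whose feature maps are used (1-4);
#'   default the last (standard Grad-CAM practice).
#' @param branch for fusion models, `"mri"` or `"pet"`; ignored otherwise.
#' @return a `cam_map` object: list with `L` (nonnegative array at the
#'   stage's spatial size), `alpha` (length-K weights), `Z`, `stage`,
#'   `class_index`, `A` (the feature maps, spatial x K matrix).
#' @export
gradcam <- function(model, example, class_index = 1, stage = 4L,
                    branch = NULL) {
  stopifnot(inherits(model, "nf_model"))
  if (is.character(class_index))
    class_index <- match.arg(class_index, c("positive", "negative")) == "positive"
  sign <- if (as.integer(class_index) == 1L) 1 else -1
  if (stage < 1L || stage > 4L) stop_nf("stage must be in 1..4")
  branch <- if (model$variant == "fusion_3d")
    match.arg(branch, c("mri", "pet")) else "main"

  fw <- model_forward(model, list(example), training = FALSE, record = TRUE)
  # backprop from the logit (exclude the sigmoid, the classifier's last layer)
  ncl <- length(model$classifier)
  cb <- net_backward(model$classifier[-ncl], fw$classifier$caches[-ncl],
                     matrix(sign, 1L, 1L))
  dz <- cb$din
  col0 <- 0L
  for (nm in names(model$branches)) {
    ncols <- fw$feat_cols[[nm]]
    if (nm == branch) dz_branch <- dz[, (col0 + 1L):(col0 + ncols), drop = FALSE]
    col0 <- col0 + ncols
  }
  layers <- model$branches[[branch]]
  t <- relu_index(stage)
  bb <- net_backward(layers[(t + 1L):length(layers)],
                     fw$branch[[branch]]$caches[(t + 1L):length(layers)],
                     dz_branch)
  A_tensor <- fw$branch[[branch]]$outputs[[t]]
  A <- A_tensor$x                       # spatial x K feature maps
  dA <- bb$din$x
  Z <- nrow(A)
  alpha <- colMeans(dA)                 # (1/Z) sum_ij dscore/dA
  L <- pmax(as.vector(A %*% alpha), 0)  # ReLU(sum_k alpha_k A_k)
  structure(list(L = array(L, dim = A_tensor$spatial), alpha = alpha, Z = Z,
                 stage = stage, class_index = as.integer(class_index),
                 A = A, spatial = A_tensor$spatial, branch = branch),
            class = "cam_map")
}

# Multi-linear (bilinear/trilinear) resize of an array to target_shape,
# reusing the preprocessing interpolation weights axis by axis.
resize_linear <- function(arr, target_shape) {
  d <- dim(arr)
  for (ax in seq_along(d)) {
    if (d[ax] == target_shape[ax]) next
    W <- bilinear_weights(d[ax], target_shape[ax])
    perm <- c(ax, setdiff(seq_along(d), ax))
    m <- W %*% matrix(aperm(arr, perm), nrow = d[ax])
    nd <- d; nd[ax] <- target_shape[ax]
    arr <- aperm(array(m, dim = nd[perm]), order(perm))
    d <- nd
  }
  arr
}

#' Upsample a relevance map to input resolution
#'
#' Trilinear (bilinear in 2D) interpolation of the coarse Grad-CAM map to
#' `target_shape`. Nonnegativity is preserved; each target axis must be at
#' least the map's size on that axis.
#'
#' @param cam a `cam_map` (or a bare nonnegative array).
#' @param target_shape integer output shape.
#' @return relevance array of shape `target_shape`.
#' @export
upsample_cam <- function(cam, target_shape) {
  L <- if (inherits(cam, "cam_map")) cam$L else cam
  if (any(target_shape < dim(L)))
    stop_nf("target_shape must be >= the map's shape on every axis")
  resize_linear(L, as.integer(target_shape))
}

#' Map an input-resolution relevance map back to the original voxel grid
#'
#' Inverts the preprocessing geometry (crop box, in-plane resize, central
#' slice selection): the in-plane map is resized to the box extent and
#' placed at the box offset on the slices that were kept; voxels outside
#' the preprocessed field of view get zero relevance.
#'
#' @param rel relevance array at model-input resolution (H, W, n_slices).
#' @param geometry the `geometry` attribute of [preprocess_volume()] output.
#' @return relevance array on the original grid.
#' @export
cam_to_grid <- function(rel, geometry) {
  gs <- geometry$grid_shape
  box <- geometry$box
  out <- array(0, dim = gs)
  hw <- c(box$hi[1] - box$lo[1], box$hi[2] - box$lo[2])
  for (i in seq_along(geometry$slices_abs)) {
    sl <- resize_linear(rel[, , i], hw)
    out[(box$lo[1] + 1L):box$hi[1], (box$lo[2] + 1L):box$hi[2],
        geometry$slices_abs[i]] <- sl
  }
  cov <- array(FALSE, dim = gs)
  cov[(box$lo[1] + 1L):box$hi[1], (box$lo[2] + 1L):box$hi[2],
      geometry$slices_abs] <- TRUE
  attr(out, "coverage") <- cov
  out
}

#' Mean relevance per atlas region with 90th-percentile selection
#'
#' Averages a relevance grid over each atlas region's voxels and selects as
#' "critical" the regions whose mean is at or above the chosen percentile
#' of region means (ties included).
#'
#' @param rel relevance array, same shape as the atlas grid.
#' @param atlas a [make_toy_atlas()] object.
#' @param percentile selection percentile (default 90).
#' @param mask optional logical array (same shape): voxels the relevance
#'   map actually covers (the model's field of view after crop and slice
#'   selection). When given, each region's mean is taken over its covered
#'   voxels only, so a region partly outside the field of view is not
#'   diluted by structurally-zero voxels; uncovered regions are dropped.
#' @param min_coverage with `mask`, the minimum fraction of a region's
#'   voxels that must be covered for the region to be assessable (default
#'   0.5). A small covered fragment of a mostly-unseen region is a
#'   high-variance mean that cannot be compared fairly with fully observed
#'   regions, so such regions are excluded from ranking and selection.
#' @return a `region_attribution`: list with `means` (named by region),
#'   `selected` (region names), `selected_ids`, `cut` (the percentile
#'   value), `percentile`.
#' @export
region_attribution <- function(rel, atlas, percentile = 90, mask = NULL,
                               min_coverage = 0.5) {
  if (!identical(dim(rel), dim(atlas$labels)))
    stop_nf("relevance grid shape (%s) does not match atlas (%s)",
            paste(dim(rel), collapse = "x"),
            paste(dim(atlas$labels), collapse = "x"))
  lab <- as.vector(atlas$labels)
  inside <- lab > 0L
  if (!is.null(mask)) {
    covered <- inside & as.vector(mask)
    frac <- tapply(as.vector(mask)[inside], lab[inside], mean)
    keep <- names(frac)[frac >= min_coverage]
    inside <- covered & (lab %in% as.integer(keep))
    if (!any(inside))
      stop_nf("no region has coverage >= %.2f", min_coverage)
  }
  means <- tapply(as.vector(rel)[inside], lab[inside], mean)
  nm <- atlas$names[names(means)]
  means <- stats::setNames(as.vector(means), nm)
  cut <- quantile(means, percentile / 100, names = FALSE)
  sel <- means >= cut
  structure(list(means = means, selected = names(means)[sel],
                 selected_ids = as.integer(names(atlas$names))[
                   match(names(means)[sel], atlas$names)],
                 cut = cut, percentile = percentile),
            class = "region_attribution")
}

#' Group-level Grad-CAM attribution
#'
#' For every example of one class: Grad-CAM, upsample to input resolution,
#' map back to the atlas grid via the example's preprocessing geometry.
#' The per-example grids are averaged and region means plus the
#' 90th-percentile selection are computed on the group-mean map; in
#' addition the fraction of examples in which each region was individually
#' selected is reported.
#'
#' @param model a trained `nf_model`.
#' @param examples preprocessed examples of one class (each `x` carrying a
#'   `geometry` attribute; for fusion, `mri`/`pet` arrays carry it).
#' @param atlas a [make_toy_atlas()] object.
#' @param class_index,stage,branch passed to [gradcam()].
#' @param only_correct if TRUE, restrict to correctly classified examples.
#' @return list with `group` (a [region_attribution()] of the group-mean
#'   map), `selection_frequency` (named, in [0, 1]), `mean_map` (atlas-grid
#'   array), `n_used`.
#' @export
group_attribution <- function(model, examples, atlas, class_index = 1,
                              stage = 4L, branch = NULL,
                              only_correct = FALSE) {
  if (!length(examples)) stop_nf("empty example group")
  if (only_correct) {
    p <- predict(model, examples)
    examples <- examples[(p$y_hat >= 0.5) == (p$y == 1)]
    if (!length(examples)) stop_nf("no correctly classified examples")
  }
  input_shape <- model$input_shape
  acc <- array(0, dim = atlas$grid_shape)
  cover <- array(FALSE, dim = atlas$grid_shape)
  freq <- stats::setNames(numeric(atlas$n_regions), atlas$names)
  for (e in examples) {
    cam <- gradcam(model, e, class_index = class_index, stage = stage,
                   branch = branch)
    up <- upsample_cam(cam, input_shape)
    src <- if (!is.null(e$x)) e$x else e[[branch %||% "mri"]]
    geom <- attr(src, "geometry")
    if (is.null(geom)) stop_nf("examples must carry preprocessing geometry")
    g <- cam_to_grid(up, geom)
    acc <- acc + g
    cover <- cover | attr(g, "coverage")
    ra <- region_attribution(g, atlas, mask = attr(g, "coverage"))
    freq[ra$selected] <- freq[ra$selected] + 1
  }
  acc <- acc / length(examples)
  list(group = region_attribution(acc, atlas, mask = cover),
       selection_frequency = freq / length(examples),
       mean_map = acc, coverage = cover, n_used = length(examples))
}
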