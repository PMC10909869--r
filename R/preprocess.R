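#' Average the time frames of a 4D PET volume
#'
#' Condenses a dynamic PET acquisition (3D images over time) into a single
#' 3D volume by the per-voxel arithmetic mean over the time axis.
#'
#' @param v 4D array (H, W, D, T). Passing an already-3D volume is an error,
#'   to catch pipeline misordering.
#' @return 3D array (H, W, D).
#' @export
average_frames <- function(v) {
  d <- dim(v)
  if (is.null(d) || length(d) != 4L)
    stop_nf("average_frames expects a 4D (H, W, D, T) volume; got %s dims",
            length(d) %||% 0L)
  out <- array(0, dim = d[1:3])
  for (t in seq_len(d[4])) out <- out + v[, , , t]
  out / d[4]
}

# Internal: 1D truncated, renormalized Gaussian taps.
gauss_taps <- function(kernel_size, sigma) {
  half <- (kernel_size - 1L) / 2L
  w <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  w / sum(w)
}

#' Gaussian blur of a 2D slice
#'
#' Convolves with a truncated, renormalized `kernel_size` x `kernel_size`
#' Gaussian (separable), with borders handled by edge replication. The
#' default 13x13 kernel with sigma = 150 is so wide relative to its support
#' that its taps are nearly uniform — effectively a box smoother — and is
#' applied exactly as specified.
#'
#' @param slice2d numeric matrix.
#' @param kernel_size odd kernel width (default 13).
#' @param sigma Gaussian standard deviation in pixels (default 150).
#' @return blurred matrix of the same size.
#' @export
gaussian_blur <- function(slice2d, kernel_size = 13L, sigma = 150) {
  if (kernel_size %% 2L == 0L) stop_nf("kernel_size must be odd")
  if (sigma <= 0) stop_nf("sigma must be > 0")
  w <- gauss_taps(kernel_size, sigma)
  half <- (kernel_size - 1L) / 2L
  conv1 <- function(m) { # along rows (dim 1), edge-replicated
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (t in seq_along(w)) {
      idx <- pmin(pmax(seq_len(n) + (t - 1L - half), 1L), n)
      out <- out + w[t] * m[idx, , drop = FALSE]
    }
    out
  }
  t(conv1(t(conv1(slice2d))))
}

#' Otsu's threshold
#'
#' Builds a 256-bin histogram over the image's intensity range and returns
#' the threshold maximizing the between-class variance; ties are broken by
#' the lower threshold. The returned value is the upper edge of the optimal
#' split bin, so "above threshold" means strictly greater.
#'
#' @param image numeric array with at least 2 distinct values.
#' @param n_bins number of histogram bins (default 256).
#' @return scalar threshold on the image's intensity scale.
#' @export
otsu_threshold <- function(image, n_bins = 256L) {
  x <- as.vector(image)
  lo <- min(x); hi <- max(x)
  if (hi <= lo) stop_nf("otsu_threshold requires >= 2 distinct values")
  bin <- pmin(floor((x - lo) / (hi - lo) * n_bins), n_bins - 1L)
  h <- tabulate(bin + 1L, nbins = n_bins)
  p <- h / length(x)
  centers <- lo + (seq_len(n_bins) - 0.5) * (hi - lo) / n_bins
  w0 <- cumsum(p)
  m0 <- cumsum(p * centers)
  mt <- m0[n_bins]
  k <- seq_len(n_bins - 1L)          # split after bin k
  w1 <- 1 - w0[k]
  valid <- w0[k] > 0 & w1 > 0
  sb <- rep(-Inf, n_bins - 1L)
  sb[valid] <- (mt * w0[k][valid] - m0[k][valid])^2 /
    (w0[k][valid] * w1[valid])
  best <- which.max(sb)              # first (lowest) maximiser
  lo + best * (hi - lo) / n_bins     # upper edge of bin `best`
}

#' Brain bounding box from high-intensity regions
#'
#' For every axial slice: Gaussian-blur, compute Otsu's threshold on the
#' blurred slice (the blur stabilizes the histogram split), and mark the
#' voxels of the *original* slice strictly above that threshold — so a
#' crisp phantom yields exactly its own extent, unwidened by blur spread.
#' The box is the tightest half-open box `[lo, hi)` (0-based voxel indices)
#' containing every above-threshold voxel across all slices. Constant
#' slices contribute no voxels.
#'
#' @param volume3d 3D array.
#' @param kernel_size,sigma blur parameters, see [gaussian_blur()].
#' @return list with `lo` and `hi`, integer vectors of length 3 (half-open).
#' @export
brain_bounding_box <- function(volume3d, kernel_size = 13L, sigma = 150) {
  d <- dim(volume3d)
  if (length(d) != 3L) stop_nf("expected a 3D volume")
  any_mask <- FALSE
  rng <- matrix(c(Inf, Inf, Inf, -Inf, -Inf, -Inf), 3L, 2L)
  for (z in seq_len(d[3])) {
    sl <- volume3d[, , z]
    if (max(sl) <= min(sl)) next
    b <- gaussian_blur(sl, kernel_size, sigma)
    if (max(b) <= min(b)) next
    mask <- sl > otsu_threshold(b)
    if (!any(mask)) next
    any_mask <- TRUE
    w <- which(mask, arr.ind = TRUE)
    rng[1, 1] <- min(rng[1, 1], min(w[, 1])); rng[1, 2] <- max(rng[1, 2], max(w[, 1]))
    rng[2, 1] <- min(rng[2, 1], min(w[, 2])); rng[2, 2] <- max(rng[2, 2], max(w[, 2]))
    rng[3, 1] <- min(rng[3, 1], z);           rng[3, 2] <- max(rng[3, 2], z)
  }
  if (!any_mask) stop_nf("no voxel above threshold in any slice")
  list(lo = as.integer(rng[, 1] - 1L), hi = as.integer(rng[, 2]))
}

# Internal: bilinear interpolation weight matrix mapping n_in samples to
# n_out, half-pixel-center convention (output center i maps to input
# coordinate (i + 0.5) * n_in / n_out - 0.5), clamped at the edges.
bilinear_weights <- function(n_in, n_out) {
  W <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5   # 0-based input coord
  i0 <- floor(src)
  fr <- src - i0
  lo <- pmin(pmax(i0, 0), n_in - 1) + 1
  hi <- pmin(pmax(i0 + 1, 0), n_in - 1) + 1
  for (r in seq_len(n_out)) {
    W[r, lo[r]] <- W[r, lo[r]] + (1 - fr[r])
    W[r, hi[r]] <- W[r, hi[r]] + fr[r]
  }
  W
}

#' Crop to a bounding box and resize slices in-plane
#'
#' Crops the volume to `box`, then bilinearly resizes each axial slice to
#' `out_hw`; the slice count is unchanged (no resampling along the slice
#' axis).
#'
#' @param volume3d 3D array.
#' @param box bounding box from [brain_bounding_box()].
#' @param out_hw output in-plane size, default `c(128, 128)`.
#' @return 3D array of size (out_hw[1], out_hw[2], slices in box).
#' @export
crop_resize <- function(volume3d, box, out_hw = c(128L, 128L)) {
  if (any(box$hi <= box$lo)) stop_nf("degenerate bounding box")
  d <- dim(volume3d)
  if (any(box$lo < 0L) || any(box$hi > d)) stop_nf("box outside volume")
  cr <- volume3d[(box$lo[1] + 1L):box$hi[1],
                 (box$lo[2] + 1L):box$hi[2],
                 (box$lo[3] + 1L):box$hi[3], drop = FALSE]
  Wr <- bilinear_weights(dim(cr)[1], out_hw[1])
  Wc <- bilinear_weights(dim(cr)[2], out_hw[2])
  out <- array(0, dim = c(out_hw[1], out_hw[2], dim(cr)[3]))
  for (z in seq_len(dim(cr)[3])) out[, , z] <- Wr %*% cr[, , z] %*% t(Wc)
  out
}

#' Select the central axial slices
#'
#' Returns the `n` axial slices centred on the volume's middle slice, with
#' the centre biased low when the remainder is odd: slices
#' `[floor((D - n)/2), floor((D - n)/2) + n)`.
#'
#' @param volume3d 3D array with D slices.
#' @param n number of slices to keep (default 50).
#' @param strict if TRUE (default) a volume with fewer than `n` slices is an
#'   error; if FALSE all slices are returned with a warning.
#' @return 3D array with `n` slices.
#' @export
central_slices <- function(volume3d, n = 50L, strict = TRUE) {
  if (n < 1L) stop_nf("n must be >= 1")
  D <- dim(volume3d)[3]
  if (D < n) {
    if (strict) stop_nf("volume has %d slices but %d requested", D, n)
    warning(sprintf("volume has %d < %d slices; returning all", D, n))
    return(volume3d)
  }
  start <- floor((D - n) / 2)
  volume3d[, , (start + 1L):(start + n), drop = FALSE]
}

#' Explode a 3D volume into labelled 2D slice examples
#'
#' For models with 2D input, each axial slice becomes an independent
#' example inheriting the scan's label, with provenance retained so slice
#' predictions can be regrouped to their source scan.
#'
#' @param volume3d 3D array.
#' @param label binary scan label.
#' @param subject_id,scan_id provenance identifiers.
#' @return list of examples `list(x = slice matrix, y = label, subject_id,
#'   scan_id, slice_index)`.
#' @export
to_2d_dataset <- function(volume3d, label, subject_id = NA_character_,
                          scan_id = NA_character_) {
  lapply(seq_len(dim(volume3d)[3]), function(z)
    list(x = volume3d[, , z], y = label, subject_id = subject_id,
         scan_id = scan_id, slice_index = z))
}

#' Preprocessing configuration
#'
#' @param size in-plane output size (square), default 128.
#' @param n_slices number of central axial slices, default 50.
#' @param kernel_size,sigma blur parameters.
#' @param strict error (TRUE) or warn (FALSE) when fewer slices available.
#' @param normalize intensity normalization: `"cohort"` (default; one
#'   affine map to [0, 1] shared by every volume of a batch, computed from
#'   the pooled intensity range in [preprocess_scans()]), `"volume"`
#'   (per-volume min-max) or `"none"`. Per-volume min-max compensates
#'   arbitrary per-scan gain but couples every voxel to the volume's
#'   extremes: an additive regional effect then also shifts *all other*
#'   voxels after scaling, turning local class evidence into a global
#'   contrast change and blurring attribution; the shared map preserves
#'   locality.
#' @return a `preproc_config` list. The desk-scale configuration used
#'   throughout the tests is `preproc_config(size = 32, n_slices = 12)`.
#' @export
preproc_config <- function(size = 128L, n_slices = 50L, kernel_size = 13L,
                           sigma = 150, strict = TRUE,
                           normalize = c("cohort", "volume", "none")) {
  list(size = as.integer(size), n_slices = as.integer(n_slices),
       kernel_size = as.integer(kernel_size), sigma = sigma, strict = strict,
       normalize = match.arg(normalize))
}

#' Run the full preprocessing chain on one volume
#'
#' 4D PET volumes are first frame-averaged; then brain bounding box (blur +
#' Otsu per slice), crop + in-plane bilinear resize to `size` x `size`,
#' central `n_slices` selection, and intensity normalization per the
#' config (per-volume min-max, or an externally supplied shared affine
#' map). Deterministic: identical inputs give bit-identical outputs.
#'
#' @param volume 3D array (MRI or averaged PET) or 4D array (raw PET).
#' @param config a [preproc_config()].
#' @param scale optional `c(lo, hi)` shared intensity range for
#'   `normalize = "cohort"`; when NULL the volume is left unscaled here
#'   and [preprocess_scans()] applies the pooled map.
#' @return 3D array of shape (size, size, n_slices).
#' @export
preprocess_volume <- function(volume, config = preproc_config(),
                              scale = NULL) {
  if (length(dim(volume)) == 4L) volume <- average_frames(volume)
  grid_shape <- dim(volume)
  box <- brain_bounding_box(volume, config$kernel_size, config$sigma)
  v <- crop_resize(volume, box, out_hw = c(config$size, config$size))
  D <- dim(v)[3]
  n <- min(config$n_slices, D)
  start <- floor((D - n) / 2)
  v <- central_slices(v, n = config$n_slices, strict = config$strict)
  if (config$normalize == "volume") {
    rng <- range(v)
    if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1])
  } else if (config$normalize == "cohort" && !is.null(scale) &&
             scale[2] > scale[1]) {
    v <- (v - scale[1]) / (scale[2] - scale[1])
  }
  # geometry lets relevance maps computed on the model grid be mapped back
  # into the original (atlas) voxel grid
  attr(v, "geometry") <- list(box = box, grid_shape = grid_shape,
                              slices_abs = box$lo[3] + start + seq_len(n))
  v
}

#' Preprocess a list of scan records
#'
#' Applies [preprocess_volume()] to every record's volume, returning model
#' examples with provenance. Under `normalize = "cohort"` the shared
#' intensity range is either taken from `scale` (e.g. the training
#' cohort's, when preprocessing held-out scans) or computed as the pooled
#' min-max over the given scans and returned in the `scale` attribute.
#'
#' @param scans list of labelled scan records.
#' @param config a [preproc_config()].
#' @param scale optional `c(lo, hi)` shared intensity range.
#' @return list of examples `list(x, y, subject_id, scan_id, modality)`;
#'   with cohort normalization the list carries a `scale` attribute.
#' @export
preprocess_scans <- function(scans, config = preproc_config(), scale = NULL) {
  out <- lapply(scans, function(r) list(
    x = preprocess_volume(r$volume, config), y = r$label,
    subject_id = r$subject_id, scan_id = r$scan_id, modality = r$modality))
  if (config$normalize == "cohort") {
    if (is.null(scale))
      scale <- range(vapply(out, function(e) range(e$x), numeric(2)))
    if (scale[2] > scale[1])
      out <- lapply(out, function(e) {
        g <- attr(e$x, "geometry")
        e$x <- (e$x - scale[1]) / (scale[2] - scale[1])
        attr(e$x, "geometry") <- g
        e
      })
    attr(out, "scale") <- scale
  }
  out
}
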