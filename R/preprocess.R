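# Preprocessing of a single-slice multi-volume DWI stack: cropping to the
# intra-spinal space, anterior-posterior motion correction driven by
# midsagittal intensity profiles, and repetition averaging.

#' Multi-volume 2-D diffusion-weighted image stack
#'
#' Container for a single axial slice acquired repeatedly: a 3-D array
#' `[row (AP), col (RL), volume]` plus per-volume metadata (b-value,
#' direction index with 0 = b0, repetition index).
#'
#' @param voxels 3-D numeric array of non-negative intensities.
#' @param spacing in-plane pixel spacing in mm, `c(row, col)`.
#' @param volumes data frame with columns `b`, `direction_index`,
#'   `repetition` (one row per volume).
#' @param provenance character log of applied operations.
#' @return An object of class `dwi_stack`.
#' @export
dwi_stack <- function(voxels, spacing, volumes, provenance = character()) {
  stopifnot(length(dim(voxels)) == 3)
  if (nrow(volumes) != dim(voxels)[3])
    stopf("volumes metadata (%d rows) does not match %d volumes",
          nrow(volumes), dim(voxels)[3])
  if (min(voxels) < 0) stopf("intensities must be >= 0")
  if (!any(volumes$direction_index == 0))
    stopf("stack must contain at least one b0 volume")
  structure(list(voxels = voxels, spacing = spacing, volumes = volumes,
                 provenance = provenance), class = "dwi_stack")
}

#' @export
print.dwi_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<dwi_stack> %dx%d px (%.2fx%.2f mm), %d volumes (%d b0, %d directions, %d repetitions)\n",
              d[1], d[2], x$spacing[1], x$spacing[2], d[3],
              sum(x$volumes$direction_index == 0),
              length(setdiff(unique(x$volumes$direction_index), 0L)),
              max(x$volumes$repetition)))
  invisible(x)
}

#' Mean b0 image of a stack
#' @param stack a [dwi_stack()].
#' @return 2-D matrix.
#' @export
mean_b0 <- function(stack) {
  idx <- which(stack$volumes$direction_index == 0)
  apply(stack$voxels[, , idx, drop = FALSE], c(1, 2), mean)
}

#' Crop a stack to the intra-spinal space
#'
#' Extracts a square window around the cord.  `center = "auto"` centres
#' the window on the intensity centroid of the mean b0 image (the bright
#' CSF ring dominates the centroid, which sits at the canal centre);
#' an explicit `c(row, col)` pixel coordinate overrides it.
#'
#' @param stack a [dwi_stack()].
#' @param center `"auto"` or pixel coordinate `c(row, col)`.
#' @param half_width half-width of the window in pixels; the crop is
#'   `(2 * half_width + 1)` pixels square.
#' @return The cropped [dwi_stack()].
#' @export
crop_to_canal <- function(stack, center = "auto", half_width = 16L) {
  d <- dim(stack$voxels)
  if (identical(center, "auto")) {
    b0 <- mean_b0(stack)
    tot <- sum(b0)
    if (tot <= 0) stopf("cannot auto-centre on an all-zero b0")
    center <- c(sum(row(b0) * b0), sum(col(b0) * b0)) / tot
  }
  ctr <- round(center)
  rows <- (ctr[1] - half_width):(ctr[1] + half_width)
  cols <- (ctr[2] - half_width):(ctr[2] + half_width)
  if (min(rows) < 1 || max(rows) > d[1] || min(cols) < 1 || max(cols) > d[2])
    stopf("crop window [%d..%d]x[%d..%d] outside the %dx%d matrix",
          min(rows), max(rows), min(cols), max(cols), d[1], d[2])
  dwi_stack(stack$voxels[rows, cols, , drop = FALSE], stack$spacing,
            stack$volumes,
            c(stack$provenance,
              sprintf("crop_to_canal(center=(%d,%d), half_width=%d)",
                      ctr[1], ctr[2], half_width)))
}

#' Midsagittal intensity profile
#'
#' Mean intensity over the central columns at each anterior-posterior row,
#' the 1-D trace used to estimate between-volume slice displacement.
#'
#' @param image 2-D matrix.
#' @param band_width number of central columns to average (>= 1).
#' @return Numeric vector of length `nrow(image)`.
#' @export
midsagittal_profile <- function(image, band_width = 3L) {
  if (length(image) == 0) stopf("empty image")
  nc <- ncol(image)
  if (band_width < 1 || band_width > nc)
    stopf("band_width must be in [1, %d]", nc)
  mid <- (nc + 1) / 2
  cols <- round(seq(mid - (band_width - 1) / 2, mid + (band_width - 1) / 2))
  rowMeans(image[, cols, drop = FALSE])
}

#' Estimate the AP shift between two midsagittal profiles
#'
#' Integer shift in `[-max_shift, max_shift]` maximizing the normalized
#' cross-correlation of the overlapping segments; ties break toward the
#' smaller absolute shift.  A positive return value means `profile` is
#' displaced toward higher row indices relative to `reference`.
#'
#' @param profile,reference numeric vectors of equal length.
#' @param max_shift maximum shift magnitude in pixels.
#' @return Integer shift with attribute `score` (correlation at optimum).
#' @export
estimate_shift <- function(profile, reference, max_shift = 5L) {
  if (length(profile) != length(reference)) stopf("profile lengths differ")
  if (max_shift < 0) stopf("max_shift must be >= 0")
  if (stats::sd(profile) == 0 || stats::sd(reference) == 0) {
    warnf("zero-variance profile; returning shift 0")
    return(structure(0L, score = NA_real_))
  }
  n <- length(profile)
  cand <- seq(-max_shift, max_shift)
  cand <- cand[order(abs(cand), cand)]   # prefer smaller |shift| on ties
  best <- c(shift = 0L, score = -Inf)
  for (s in cand) {
    if (s >= 0) { a <- profile[(1 + s):n]; b <- reference[1:(n - s)] }
    else        { a <- profile[1:(n + s)]; b <- reference[(1 - s):n] }
    if (length(a) < 3 || stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(a, b)
    if (r > best[["score"]] + 1e-12) best <- c(shift = s, score = r)
  }
  structure(as.integer(best[["shift"]]), score = best[["score"]])
}

#' Motion-correct a stack against its mean-b0 profile
#'
#' Computes the midsagittal profile of every volume, estimates its AP
#' shift relative to the mean-b0 profile, and translates the volume by the
#' negated shift (edge rows padded by the nearest row).
#'
#' Diffusion-weighted volumes have inverted cord/CSF contrast relative to
#' the b0 reference (CSF attenuates strongly), so by default every profile
#' is saturated toward a tissue-support box (values clipped at half its
#' 98th percentile) before correlation; alignment is then driven by the
#' contrast-independent tissue edges.
#'
#' @param stack a [dwi_stack()].
#' @param band_width profile band width in columns.
#' @param max_shift maximum correctable shift in pixels.
#' @param profile_transform `"saturate"` (default) or `"none"` to
#'   correlate raw intensity profiles.
#' @return List with the corrected `stack` and a `shifts` data frame
#'   (volume, shift_px, score).
#' @export
correct_stack <- function(stack, band_width = 3L, max_shift = 5L,
                          profile_transform = c("saturate", "none")) {
  profile_transform <- match.arg(profile_transform)
  xf <- if (profile_transform == "saturate") {
    function(p) pmin(p / (0.5 * stats::quantile(p, 0.98) + 1e-12), 1)
  } else identity
  ref <- xf(midsagittal_profile(mean_b0(stack), band_width))
  nvol <- dim(stack$voxels)[3]
  out <- stack$voxels
  est <- data.frame(volume = seq_len(nvol), shift_px = 0L, score = NA_real_)
  for (v in seq_len(nvol)) {
    s <- estimate_shift(xf(midsagittal_profile(stack$voxels[, , v], band_width)),
                        ref, max_shift)
    est$shift_px[v] <- as.integer(s)
    est$score[v] <- attr(s, "score")
    if (s != 0) out[, , v] <- shift_rows_int(stack$voxels[, , v], -as.integer(s))
  }
  corrected <- dwi_stack(out, stack$spacing, stack$volumes,
                         c(stack$provenance,
                           sprintf("correct_stack(band_width=%d, max_shift=%d)",
                                   band_width, max_shift)))
  list(stack = corrected, shifts = est)
}

# integer row translation with nearest-row edge padding
shift_rows_int <- function(img, shift) {
  nr <- nrow(img)
  src <- pmin(pmax(seq_len(nr) - shift, 1L), nr)
  img[src, , drop = FALSE]
}

#' Average repetitions per diffusion direction
#'
#' Collapses the repetition axis: one mean image per direction plus the
#' mean b0, preserving b-value and direction metadata.
#'
#' @param stack a (motion-corrected) [dwi_stack()].
#' @return A [dwi_stack()] with `n_directions + 1` volumes.
#' @export
average_repetitions <- function(stack) {
  meta <- stack$volumes
  dirs <- sort(unique(meta$direction_index))
  counts <- table(meta$direction_index)
  if (length(unique(counts)) != 1)
    stopf("unequal repetition counts across directions: %s",
          paste(counts, collapse = ", "))
  d <- dim(stack$voxels)
  out <- array(0, c(d[1], d[2], length(dirs)))
  newmeta <- data.frame(volume = seq_along(dirs), b = 0,
                        direction_index = dirs, repetition = 1L)
  for (i in seq_along(dirs)) {
    idx <- which(meta$direction_index == dirs[i])
    out[, , i] <- apply(stack$voxels[, , idx, drop = FALSE], c(1, 2), mean)
    newmeta$b[i] <- meta$b[idx[1]]
  }
  dwi_stack(out, stack$spacing, newmeta,
            c(stack$provenance,
              sprintf("average_repetitions(n=%d)", max(counts))))
}
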