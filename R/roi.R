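# Elliptical cord model and tract ROIs: segment the cord inside the bright
# CSF ring, fit an ellipse from image moments, sample a 600-point angular
# FA profile, locate the posterior-horn exit angles, place the six 1.05 mm
# circular ROIs (pyramidal tracts, dorsal columns, anterior horns,
# left/right) and extract per-region mean metrics.

ROI_LABELS <- c("PT_L", "PT_R", "DC_L", "DC_R", "AH_L", "AH_R")

# label connected components of a logical matrix (4-connectivity)
connected_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    lab[start] <- comp
    while (length(queue) > 0) {
      p <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      for (nb in c(if (r > 1) p - 1L, if (r < nr) p + 1L,
                   if (c > 1) p - nr, if (c < nc) p + nr)) {
        if (mask[nb] && lab[nb] == 0L) {
          lab[nb] <- comp
          queue <- c(queue, nb)
        }
      }
    }
  }
  lab
}

#' Segment the spinal cord inside the CSF ring
#'
#' The CSF ring is the brightest tissue on b0.  A rough cord level is
#' estimated as the median b0 of mid-intensity pixels; the cord/CSF
#' boundary is then placed at the half-maximum between the cord level and
#' the CSF level (the 98th percentile), so that partial-volume blending at
#' the boundary does not inflate the mask.  The largest connected
#' component is kept.
#'
#' @param b0_map mean b0 image (matrix).
#' @param fa_map optional co-registered FA map; when given, pixels with
#'   `NA` FA are excluded.
#' @param background_frac rough lower bound as a fraction of the CSF
#'   level, used to estimate the cord level.
#' @param csf_frac rough upper bound as a fraction of the CSF level, used
#'   to estimate the cord level.
#' @return Logical cord mask.
#' @export
segment_cord <- function(b0_map, fa_map = NULL,
                         background_frac = 0.1, csf_frac = 0.75) {
  ref <- stats::quantile(b0_map, 0.98, na.rm = TRUE)
  rough <- b0_map > background_frac * ref & b0_map < csf_frac * ref
  if (!any(rough)) stopf("cord segmentation is empty")
  cord_level <- stats::median(b0_map[rough])
  mask <- b0_map > 0.5 * cord_level & b0_map < (cord_level + ref) / 2
  if (!is.null(fa_map)) mask <- mask & !is.na(fa_map)
  if (!any(mask)) stopf("cord segmentation is empty")
  comp <- connected_components(mask)
  sizes <- tabulate(comp[comp > 0])
  comp == which.max(sizes)
}

#' Fit an ellipse to a binary mask from image moments
#'
#' Centre = mask centroid; axis directions and axis ratio from the
#' second-order central moments; both semi-axes scaled so the ellipse area
#' equals the mask area.  For a near-circular mask the rotation is
#' reported as 0 by convention.
#'
#' @param mask logical matrix.
#' @param spacing pixel spacing in mm `c(row, col)`.
#' @return An object of class `ellipse_model`: `center` (mm, row/col),
#'   `semi_major`, `semi_minor` (mm), `rotation` (degrees of the major
#'   axis from the column/right-left axis), `exit_angles` (filled by
#'   [adjust_exit_angles()], initialised to `c(left = 35, right = 35)`).
#' @export
fit_ellipse <- function(mask, spacing = c(1, 1)) {
  if (!any(mask)) stopf("empty mask")
  rows_mm <- (row(mask)[mask] - 0.5) * spacing[1]
  cols_mm <- (col(mask)[mask] - 0.5) * spacing[2]
  ctr <- c(row = mean(rows_mm), col = mean(cols_mm))
  n <- length(rows_mm)
  covm <- stats::cov(cbind(cols_mm, rows_mm)) * (n - 1) / n
  if (any(!is.finite(covm)) || det(covm) <= 0)
    stopf("degenerate mask: pixels are collinear")
  ev <- eigen(covm, symmetric = TRUE)
  a <- 2 * sqrt(ev$values[1])     # filled ellipse: cov eigenvalue = a^2/4
  b <- 2 * sqrt(ev$values[2])
  area <- n * spacing[1] * spacing[2]
  scale <- sqrt(area / (pi * a * b))
  a <- a * scale; b <- b * scale
  rot <- if ((ev$values[1] - ev$values[2]) / ev$values[1] < 1e-3) 0 else {
    v <- ev$vectors[, 1]          # (col, row) components of the major axis
    atan2(v[2], v[1]) * 180 / pi
  }
  if (rot > 90) rot <- rot - 180
  if (rot <= -90) rot <- rot + 180
  structure(list(center = ctr, semi_major = a, semi_minor = b,
                 rotation = rot, exit_angles = c(left = 35, right = 35)),
            class = "ellipse_model")
}

# mm point on (a scaled copy of) the ellipse at parametric angle theta
# (degrees from the posterior midline, positive = left)
ellipse_point <- function(ellipse, theta_deg, frac = 1) {
  d <- angle_dir(theta_deg)                  # (row, col) direction
  th <- ellipse$rotation * pi / 180
  u <- c(col = cos(th), row = sin(th))       # major axis
  v <- c(col = -sin(th), row = cos(th))      # minor axis
  du <- d[["col"]] * u[["col"]] + d[["row"]] * u[["row"]]
  dv <- d[["col"]] * v[["col"]] + d[["row"]] * v[["row"]]
  r <- frac / sqrt((du / ellipse$semi_major)^2 + (dv / ellipse$semi_minor)^2)
  c(row = ellipse$center[["row"]] + r * d[["row"]],
    col = ellipse$center[["col"]] + r * d[["col"]])
}

# bilinear interpolation of a matrix at mm coordinates (pixel centres at
# (i - 0.5) * spacing)
bilinear_at <- function(map, spacing, row_mm, col_mm) {
  ri <- row_mm / spacing[1] + 0.5
  ci <- col_mm / spacing[2] + 0.5
  if (any(ri < 1 | ri > nrow(map) | ci < 1 | ci > ncol(map)))
    stopf("sampling point outside the map")
  r0 <- pmin(floor(ri), nrow(map) - 1L); wr <- ri - r0
  c0 <- pmin(floor(ci), ncol(map) - 1L); wc <- ci - c0
  map[cbind(r0, c0)] * (1 - wr) * (1 - wc) +
    map[cbind(r0 + 1, c0)] * wr * (1 - wc) +
    map[cbind(r0, c0 + 1)] * (1 - wr) * wc +
    map[cbind(r0 + 1, c0 + 1)] * wr * wc
}

#' Sample a metric along the cord ellipse
#'
#' Bilinear samples at `n` equally spaced parametric angles on a scaled
#' copy of the ellipse.  Angle 0 is the posterior midline; positive
#' angles run toward the left side of the cord.
#'
#' @param map metric matrix (e.g. the FA map).
#' @param ellipse an `ellipse_model`.
#' @param spacing map pixel spacing in mm.
#' @param radial_fraction scale of the sampling ellipse relative to the
#'   cord ellipse.
#' @param n number of angular samples for the full circle (default 600,
#'   i.e. 0.6 degree spacing).
#' @return A list of class `angular_profile` with `angles` (degrees,
#'   `[0, 360)`) and `values`.
#' @export
sample_profile <- function(map, ellipse, spacing, radial_fraction = 0.6,
                           n = 600L) {
  angles <- seq(0, 360, length.out = n + 1L)[seq_len(n)]
  pts <- vapply(angles, function(a) ellipse_point(ellipse, a, radial_fraction),
                numeric(2))
  vals <- bilinear_at(map, spacing, pts[1, ], pts[2, ])
  structure(list(angles = angles, values = vals,
                 radial_fraction = radial_fraction), class = "angular_profile")
}

#' Locate the posterior-horn exit angles on an FA profile
#'
#' The gray-matter posterior horns depress the FA profile on either side
#' of the posterior midline.  The profile is smoothed with a short
#' circular moving average and the exit angle per side is the smoothed
#' minimum within the search window.
#'
#' @param ellipse an `ellipse_model`.
#' @param fa_profile an `angular_profile` sampled on the FA map.
#' @param window angular search window (degrees from the posterior
#'   midline) on each side.
#' @param smooth_halfwidth half-width of the circular moving average, in
#'   profile samples (default 7, i.e. +/- 4.2 degrees at 600 samples).
#' @return The ellipse with `exit_angles` updated (left/right, degrees).
#' @export
adjust_exit_angles <- function(ellipse, fa_profile, window = c(15, 75),
                               smooth_halfwidth = 7L) {
  ang <- fa_profile$angles
  val <- fa_profile$values
  if (max(val) - min(val) < 1e-9) {
    warnf("flat FA profile; keeping prior exit angles")
    return(ellipse)
  }
  if (smooth_halfwidth > 0) {
    n <- length(val)
    k <- 2L * smooth_halfwidth + 1L
    padded <- c(val[(n - smooth_halfwidth + 1L):n], val,
                val[1:smooth_halfwidth])
    val <- as.numeric(stats::filter(padded, rep(1 / k, k)))[
      smooth_halfwidth + seq_len(n)]
  }
  signed <- ifelse(ang > 180, ang - 360, ang)   # left > 0, right < 0
  find_side <- function(side) {
    sel <- which(signed * side >= window[1] & signed * side <= window[2])
    if (length(sel) == 0) return(NA_real_)
    abs(signed[sel[which.min(val[sel])]])
  }
  left <- find_side(+1); right <- find_side(-1)
  if (is.na(left) || is.na(right)) {
    warnf("no FA minimum in the search window; keeping prior exit angles")
    return(ellipse)
  }
  ellipse$exit_angles <- c(left = left, right = right)
  ellipse
}

#' Place the six circular tract ROIs
#'
#' Mirror-symmetric pairs parameterized by (angle from the posterior
#' midline, radial fraction of the cord ellipse): dorsal columns
#' paramedian-posterior, pyramidal tracts lateral (offset from the
#' posterior-horn exit angles), anterior horns anterolateral in the gray
#' matter.
#'
#' @param ellipse an `ellipse_model` (with adjusted exit angles).
#' @param params placement parameters: per-region `angle` (degrees; for PT
#'   an offset added to the exit angle), `frac` (radial fraction) and the
#'   common `diameter` in mm (default 1.05).
#' @return An object of class `roi_set`: data frame with `label`,
#'   `region`, `side`, centre coordinates (mm) and `diameter`.
#' @export
place_rois <- function(ellipse,
                       params = list(dc = list(angle = 15, frac = 0.72),
                                     pt = list(angle_offset = 25, frac = 0.70),
                                     ah = list(angle = 150, frac = 0.45),
                                     diameter = 1.05)) {
  mk <- function(label, angle, frac) {
    p <- ellipse_point(ellipse, angle, frac)
    if (frac >= 1)
      stopf("ROI %s falls outside the cord ellipse (radial fraction %.2f)",
            label, frac)
    data.frame(label = label, region = sub("_.*", "", label),
               side = sub(".*_", "", label),
               row_mm = p[["row"]], col_mm = p[["col"]],
               angle = angle, frac = frac, diameter = params$diameter)
  }
  pt_l <- ellipse$exit_angles[["left"]] + params$pt$angle_offset
  pt_r <- -(ellipse$exit_angles[["right"]] + params$pt$angle_offset)
  rois <- rbind(
    mk("PT_L", pt_l, params$pt$frac),
    mk("PT_R", pt_r, params$pt$frac),
    mk("DC_L", +params$dc$angle, params$dc$frac),
    mk("DC_R", -params$dc$angle, params$dc$frac),
    mk("AH_L", +params$ah$angle, params$ah$frac),
    mk("AH_R", -params$ah$angle, params$ah$frac))
  structure(rois, class = c("roi_set", "data.frame"))
}

# logical membership matrix of one circular ROI on a map grid
roi_pixels <- function(map_dim, spacing, row_mm, col_mm, diameter) {
  rows <- (seq_len(map_dim[1]) - 0.5) * spacing[1]
  cols <- (seq_len(map_dim[2]) - 0.5) * spacing[2]
  outer(rows, cols, function(r, c)
    (r - row_mm)^2 + (c - col_mm)^2 <= (diameter / 2)^2)
}

#' Extract per-region mean metrics from the ROI set
#'
#' ROI mean over pixels whose centres lie inside each 1.05 mm circle on
#' the interpolated maps; the region value is the arithmetic mean of its
#' left and right ROI means (actual calculated values, no normalization).
#'
#' @param maps interpolated `metric_maps`.
#' @param roiset a `roi_set`.
#' @return A list of class `tract_metrics`: `per_roi` (one row per ROI and
#'   metric, with pixel counts) and `per_region` (left/right-averaged).
#' @export
extract_tract_metrics <- function(maps, roiset) {
  metrics <- c("FA", "MD", "AD", "RD")
  per_roi <- do.call(rbind, lapply(seq_len(nrow(roiset)), function(i) {
    px <- roi_pixels(dim(maps$FA), maps$spacing,
                     roiset$row_mm[i], roiset$col_mm[i], roiset$diameter[i])
    if (!any(px)) stopf("ROI %s contains no pixels at this resolution",
                        roiset$label[i])
    vals <- vapply(metrics, function(m) mean(maps[[m]][px], na.rm = TRUE),
                   numeric(1))
    data.frame(label = roiset$label[i], region = roiset$region[i],
               side = roiset$side[i], n_pixels = sum(px),
               metric = metrics, value = unname(vals))
  }))
  per_region <- stats::aggregate(value ~ region + metric, per_roi, mean)
  structure(list(per_roi = per_roi, per_region = per_region),
            class = "tract_metrics")
}

#' Run the full ROI stage on interpolated maps
#'
#' Segments the cord, fits the ellipse, samples the 600-point FA profile,
#' adjusts the posterior-horn exit angles, places the six ROIs and
#' extracts tract metrics.
#'
#' @param maps interpolated `metric_maps`.
#' @param radial_fraction sampling-ellipse scale for the FA profile.
#' @param roi_params placement parameters, see [place_rois()].
#' @return List with `mask`, `ellipse`, `profile`, `rois`, `metrics`.
#' @export
roi_stage <- function(maps, radial_fraction = 0.6,
                      roi_params = list(dc = list(angle = 15, frac = 0.72),
                                        pt = list(angle_offset = 25, frac = 0.70),
                                        ah = list(angle = 150, frac = 0.45),
                                        diameter = 1.05)) {
  mask <- segment_cord(maps$b0, maps$FA)
  ellipse <- fit_ellipse(mask, maps$spacing)
  profile <- sample_profile(maps$FA, ellipse, maps$spacing, radial_fraction)
  ellipse <- adjust_exit_angles(ellipse, profile)
  rois <- place_rois(ellipse, roi_params)
  metrics <- extract_tract_metrics(maps, rois)
  list(mask = mask, ellipse = ellipse, profile = profile, rois = rois,
       metrics = metrics)
}
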