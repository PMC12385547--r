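# Synthetic axial spinal-cord DWI phantom: a single 5 mm slice at the C2
# level with an elliptical cord, a gray-matter butterfly, a bright CSF ring,
# anterior-posterior motion between volumes, and Rician noise.  Every pixel
# carries a known diffusion tensor, so the phantom is an exact oracle for
# the tensor-fitting and ROI-extraction stages.

PHANTOM_LABELS <- c("background", "CSF", "WM", "GM",
                    "PT_L", "PT_R", "DC_L", "DC_R", "AH_L", "AH_R")

#' Phantom specification for a single axial cervical-cord slice
#'
#' Defines the acquisition grid, cord/CSF geometry, the gray-matter
#' butterfly, per-region diffusion tensors, baseline signal per tissue,
#' Rician noise scale, repetition count and the between-volume
#' anterior-posterior motion model.
#'
#' Geometry is expressed in mm around the matrix centre.  The image row
#' axis is anterior-posterior (row index increases posterior to anterior)
#' and the column axis is right-left.  Angles are measured from the
#' posterior midline; positive angles are the left side of the cord.
#' Region tensors are axially symmetric with the principal eigenvector
#' along the slice normal (the cord runs parallel to the scanner z-axis),
#' given as eigenvalues `c(l1, l2, l3)` in 1e-3 mm^2/s.
#'
#' @param matrix_size image matrix, pixels (rows, cols).
#' @param pixel_spacing in-plane resolution in mm (rows, cols).
#' @param cord_semi_axes cord ellipse semi-axes in mm, `c(rl = , ap = )`.
#' @param cord_rotation cord ellipse rotation, degrees.
#' @param csf_semi_axes outer margin of the CSF ring, mm.
#' @param gm_butterfly geometric parameters of the gray-matter "H": central
#'   band semi-axes, anterior-horn lobe angle/radial fraction/radius, and
#'   posterior-horn angle/fraction/semi-axes (all mm or degrees).
#' @param region_tensors named list of eigenvalue triples per region
#'   (`WM`, `GM`, `PT`, `DC`, `AH`, `CSF`), 1e-3 mm^2/s.
#' @param s0_by_tissue named baseline signal per tissue class
#'   (`background`, `CSF`, `WM`, `GM`).
#' @param noise_sigma Rician noise scale in signal units (>= 0).
#' @param n_repetitions number of repetitions of the b0 + 6-direction block.
#' @param motion_model `"none"`, a numeric vector of per-volume AP shifts
#'   in pixels, `list(type = "ar1", sd = , phi = )` (mean-reverting
#'   breathing-like displacement, the default), or
#'   `list(type = "random_walk", sd = )`.
#' @param seed integer seed controlling noise and motion.
#' @param tract_geometry true tract-region geometry: `dc` (posterior
#'   annular sector: `half_angle` degrees, `frac_inner` radial fraction),
#'   `pt` (lateral circles: `angle`, `frac`, `radius` mm).  Anterior-horn
#'   labels are the gray-matter lobes defined in `gm_butterfly`, split at
#'   the midline.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(matrix_size = c(128L, 128L),
                         pixel_spacing = c(0.78, 0.78),
                         cord_semi_axes = c(rl = 5.4, ap = 4.3),
                         cord_rotation = 0,
                         csf_semi_axes = c(rl = 8.2, ap = 7.0),
                         gm_butterfly = list(
                           band_semi = c(rl = 2.0, ap = 0.6),
                           ah_angle = 150, ah_frac = 0.45, ah_radius = 1.6,
                           horn_angle = 48, horn_frac = 0.60,
                           horn_semi = c(radial = 1.5, tangential = 0.5)),
                         region_tensors = list(
                           WM  = c(2.20, 0.450, 0.450),
                           GM  = c(1.50, 0.950, 0.750),
                           PT  = c(2.57, 0.410, 0.410),
                           DC  = c(2.66, 0.345, 0.345),
                           AH  = c(1.50, 0.950, 0.750),
                           CSF = c(3.00, 3.000, 3.000)),
                         s0_by_tissue = c(background = 0, CSF = 1200,
                                          WM = 800, GM = 850),
                         noise_sigma = 20,
                         n_repetitions = 32L,
                         motion_model = list(type = "ar1", sd = 0.5, phi = 0.9),
                         seed = 1L,
                         tract_geometry = list(
                           dc = list(half_angle = 38, frac_inner = 0.40),
                           pt = list(angle = 73, frac = 0.70, radius = 1.5))) {
  for (rg in names(region_tensors)) {
    ev <- region_tensors[[rg]]
    if (any(!is.finite(ev)) || any(ev <= 0))
      stopf("region_tensors[[%s]]: eigenvalues must be finite and > 0", rg)
    if (is.unsorted(rev(ev)))
      stopf("region_tensors[[%s]]: eigenvalues must satisfy l1 >= l2 >= l3", rg)
  }
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  if (n_repetitions < 1) stopf("n_repetitions must be >= 1")
  fov <- matrix_size * pixel_spacing
  if (2 * csf_semi_axes[["rl"]] >= fov[2] || 2 * csf_semi_axes[["ap"]] >= fov[1])
    stopf("cord/CSF geometry does not fit inside the image matrix")
  if (any(cord_semi_axes <= 0)) stopf("cord semi-axes must be > 0")
  structure(list(
    matrix_size = as.integer(matrix_size), pixel_spacing = pixel_spacing,
    cord_semi_axes = cord_semi_axes, cord_rotation = cord_rotation,
    csf_semi_axes = csf_semi_axes, gm_butterfly = gm_butterfly,
    region_tensors = region_tensors, s0_by_tissue = s0_by_tissue,
    noise_sigma = noise_sigma, n_repetitions = as.integer(n_repetitions),
    motion_model = motion_model, seed = seed,
    tract_geometry = tract_geometry), class = "phantom_spec")
}

# direction unit vector of an in-plane angle (degrees from the posterior
# midline, positive toward the left): c(row, col) components
angle_dir <- function(theta_deg) {
  t <- theta_deg * pi / 180
  c(row = -cos(t), col = sin(t))
}

# radius of an axis-aligned ellipse (semi-axes rl along cols, ap along rows)
# along the direction of angle theta
ellipse_radius_at <- function(semi_rl, semi_ap, theta_deg) {
  d <- angle_dir(theta_deg)
  1 / sqrt((d[["col"]] / semi_rl)^2 + (d[["row"]] / semi_ap)^2)
}

# mm coordinates of pixel centres: centre of pixel (i, j) is at
# ((i - 0.5) * spacing_row, (j - 0.5) * spacing_col)
pixel_grid <- function(matrix_size, pixel_spacing) {
  rows <- (seq_len(matrix_size[1]) - 0.5) * pixel_spacing[1]
  cols <- (seq_len(matrix_size[2]) - 0.5) * pixel_spacing[2]
  list(row_mm = matrix(rows, matrix_size[1], matrix_size[2]),
       col_mm = matrix(cols, matrix_size[1], matrix_size[2], byrow = TRUE),
       centre = c(row = matrix_size[1] * pixel_spacing[1] / 2,
                  col = matrix_size[2] * pixel_spacing[2] / 2))
}

in_ellipse <- function(grid, centre, semi_rl, semi_ap, rotation_deg = 0) {
  dr <- grid$row_mm - centre[["row"]]
  dc <- grid$col_mm - centre[["col"]]
  if (rotation_deg != 0) {
    th <- rotation_deg * pi / 180
    dc2 <- dc * cos(th) - dr * sin(th)
    dr2 <- dc * sin(th) + dr * cos(th)
    dc <- dc2; dr <- dr2
  }
  (dc / semi_rl)^2 + (dr / semi_ap)^2 <= 1
}

in_circle <- function(grid, centre, radius) {
  (grid$row_mm - centre[["row"]])^2 + (grid$col_mm - centre[["col"]])^2 <= radius^2
}

# centre (mm) of a feature at polar position (angle, radial fraction of the
# cord ellipse), relative to the cord centre
polar_point <- function(cord_centre, semi_axes, theta_deg, frac) {
  r <- frac * ellipse_radius_at(semi_axes[["rl"]], semi_axes[["ap"]], theta_deg)
  d <- angle_dir(theta_deg)
  c(row = cord_centre[["row"]] + r * d[["row"]],
    col = cord_centre[["col"]] + r * d[["col"]])
}

# ellipse elongated along the radial direction at angle theta (posterior horn)
in_radial_lobe <- function(grid, cord_centre, semi_axes, theta_deg, frac,
                           semi_radial, semi_tangential) {
  ctr <- polar_point(cord_centre, semi_axes, theta_deg, frac)
  d <- angle_dir(theta_deg)                       # radial unit vector
  tvec <- c(row = d[["col"]], col = -d[["row"]])  # tangential unit vector
  dr <- grid$row_mm - ctr[["row"]]
  dc <- grid$col_mm - ctr[["col"]]
  u <- dr * d[["row"]] + dc * d[["col"]]
  v <- dr * tvec[["row"]] + dc * tvec[["col"]]
  (u / semi_radial)^2 + (v / semi_tangential)^2 <= 1
}

#' Build the phantom label map
#'
#' Paints, in order, the CSF outer ellipse, the white-matter cord ellipse,
#' the gray-matter butterfly (central band, two posterior horns, the
#' merged anterior-horn lobes), the dorsal-column posterior sector and the
#' pyramidal-tract circles.  The dorsal columns form one contiguous
#' posterior block and the ventral gray one contiguous anterior block, as
#' in the real cord; their left/right labels are split at the midline.
#' Later paints overwrite earlier ones, so labels are disjoint by
#' construction.
#'
#' @param spec a [phantom_spec()].
#' @return Integer matrix of indices into `PHANTOM_LABELS`, with a
#'   `labels` attribute.
#' @export
phantom_label_map <- function(spec) {
  g <- pixel_grid(spec$matrix_size, spec$pixel_spacing)
  ctr <- g$centre
  lab <- matrix(1L, spec$matrix_size[1], spec$matrix_size[2])  # background
  lab[in_ellipse(g, ctr, spec$csf_semi_axes[["rl"]], spec$csf_semi_axes[["ap"]])] <- 2L
  cord <- in_ellipse(g, ctr, spec$cord_semi_axes[["rl"]], spec$cord_semi_axes[["ap"]],
                     spec$cord_rotation)
  lab[cord] <- 3L
  # polar coordinates of every pixel relative to the cord centre
  dr <- g$row_mm - ctr[["row"]]
  dc <- g$col_mm - ctr[["col"]]
  theta <- atan2(dc, -dr) * 180 / pi      # 0 = posterior midline, left > 0
  rr <- sqrt(dr^2 + dc^2)
  r_cord <- matrix(vapply(as.vector(theta), function(a)
    ellipse_radius_at(spec$cord_semi_axes[["rl"]], spec$cord_semi_axes[["ap"]], a),
    numeric(1)), nrow(lab), ncol(lab))
  frac <- rr / r_cord
  left <- dc > 0
  bf <- spec$gm_butterfly
  gm <- in_ellipse(g, ctr, bf$band_semi[["rl"]], bf$band_semi[["ap"]])
  ah <- matrix(FALSE, nrow(lab), ncol(lab))
  for (s in c(-1, 1)) {
    gm <- gm | in_radial_lobe(g, ctr, spec$cord_semi_axes, s * bf$horn_angle,
                              bf$horn_frac, bf$horn_semi[["radial"]],
                              bf$horn_semi[["tangential"]])
    ah <- ah | in_circle(g, polar_point(ctr, spec$cord_semi_axes,
                                        s * bf$ah_angle, bf$ah_frac),
                         bf$ah_radius)
  }
  lab[(gm | ah) & cord] <- 4L
  tg <- spec$tract_geometry
  wm <- lab == 3L
  dc_sector <- wm & abs(theta) <= tg$dc$half_angle & frac >= tg$dc$frac_inner
  lab[dc_sector & left] <- 7L    # DC_L
  lab[dc_sector & !left] <- 8L   # DC_R
  for (s in c(-1, 1)) {
    ptc <- in_circle(g, polar_point(ctr, spec$cord_semi_axes,
                                    s * tg$pt$angle, tg$pt$frac),
                     tg$pt$radius) & lab == 3L
    lab[ptc] <- if (s > 0) 5L else 6L            # PT_L / PT_R
  }
  lab[ah & cord & left] <- 9L    # AH_L
  lab[ah & cord & !left] <- 10L  # AH_R
  attr(lab, "labels") <- PHANTOM_LABELS
  lab
}

label_to_region <- c(background = "background", CSF = "CSF", WM = "WM",
                     GM = "GM", PT_L = "PT", PT_R = "PT", DC_L = "DC",
                     DC_R = "DC", AH_L = "AH", AH_R = "AH")
label_to_tissue <- c(background = "background", CSF = "CSF", WM = "WM",
                     GM = "GM", PT_L = "WM", PT_R = "WM", DC_L = "WM",
                     DC_R = "WM", AH_L = "GM", AH_R = "GM")

# per-pixel tensor 6-vectors (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) from the label
# map; axially symmetric tensors with l1 along z, l2 along x (right-left),
# l3 along y (anterior-posterior)
phantom_tensor_field <- function(spec, lab) {
  npix <- length(lab)
  D <- matrix(0, npix, 6,
              dimnames = list(NULL, c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")))
  regions <- label_to_region[PHANTOM_LABELS[as.vector(lab)]]
  for (rg in names(spec$region_tensors)) {
    ev <- spec$region_tensors[[rg]]
    idx <- regions == rg
    D[idx, "Dzz"] <- ev[1]; D[idx, "Dxx"] <- ev[2]; D[idx, "Dyy"] <- ev[3]
  }
  D
}

#' Noise-free diffusion-weighted signal of a single tensor
#'
#' Stejskal-Tanner attenuation `S = s0 * exp(-b * g' D g)` with the
#' encoding direction normalized to unit length, so the listed direction
#' scaling (e.g. the norm-sqrt(2) printed scheme) does not change the
#' attenuation.
#'
#' @param tensor 3x3 symmetric matrix or 6-vector
#'   `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`, 1e-3 mm^2/s.
#' @param direction encoding direction, any non-zero 3-vector.
#' @param b b-value in s/mm^2.
#' @param s0 non-diffusion-weighted signal.
#' @return The attenuated signal; equals `s0` at `b = 0`.
#' @export
dwi_signal <- function(tensor, direction, b, s0 = 1) {
  if (length(direction) != 3 || all(direction == 0))
    stopf("direction must be a non-zero 3-vector")
  if (b < 0) stopf("b must be >= 0")
  D <- as_tensor_matrix(tensor)
  if (any(!is.finite(D))) stopf("tensor must be finite")
  g <- direction / sqrt(sum(direction^2))
  adc <- drop(t(g) %*% D %*% g) * 1e-3          # mm^2/s
  s0 * exp(-b * adc)
}

as_tensor_matrix <- function(tensor) {
  if (is.matrix(tensor)) {
    stopifnot(all(dim(tensor) == c(3, 3)))
    return(tensor)
  }
  stopifnot(length(tensor) == 6)
  matrix(c(tensor[1], tensor[4], tensor[5],
           tensor[4], tensor[2], tensor[6],
           tensor[5], tensor[6], tensor[3]), 3, 3)
}

#' Add Rician noise to magnitude-MRI signal
#'
#' Magnitude of a complex signal whose real and imaginary channels carry
#' independent Gaussian noise: `sqrt((s + e1)^2 + e2^2)` with
#' `e1, e2 ~ N(0, sigma)`.  A noise-free-zero input acquires the Rayleigh
#' mean `sigma * sqrt(pi/2)`; at high SNR the noise approaches Gaussian
#' with SD `sigma`.
#'
#' @param signal numeric vector/array of noise-free magnitudes.
#' @param sigma noise scale (>= 0) in signal units.
#' @return Noisy magnitudes, same shape as `signal`.
#' @export
add_rician_noise <- function(signal, sigma) {
  if (sigma < 0) stopf("sigma must be >= 0")
  if (sigma == 0) return(signal)
  n <- length(signal)
  out <- sqrt((signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  if (!is.null(dim(signal))) dim(out) <- dim(signal)
  out
}

# realized per-volume AP shifts (pixels) under the motion model
motion_shifts <- function(motion_model, n_volumes) {
  if (is.null(motion_model) || identical(motion_model, "none"))
    return(rep(0, n_volumes))
  if (is.numeric(motion_model)) {
    if (length(motion_model) != n_volumes)
      stopf("motion vector length %d != %d volumes",
            length(motion_model), n_volumes)
    return(motion_model)
  }
  if (identical(motion_model$type, "random_walk")) {
    steps <- rnorm(n_volumes, 0, motion_model$sd %||% 0.5)
    sh <- cumsum(steps)
    return(sh - sh[1])   # first volume is the reference position
  }
  if (identical(motion_model$type, "ar1")) {
    # mean-reverting displacement: stationary SD `sd`, lag-1 correlation
    # `phi`; mimics periodic breathing displacement without unbounded drift
    sd <- motion_model$sd %||% 0.5
    phi <- motion_model$phi %||% 0.9
    innov <- rnorm(n_volumes, 0, sd * sqrt(1 - phi^2))
    sh <- numeric(n_volumes)
    for (v in 2:n_volumes) sh[v] <- phi * sh[v - 1] + innov[v]
    return(sh)
  }
  stopf("unknown motion model")
}

# translate an image along rows (AP) by `shift` pixels, edge rows padded by
# the nearest row; fractional shifts use linear interpolation between rows
shift_rows <- function(img, shift) {
  if (shift == 0) return(img)
  nr <- nrow(img)
  src <- seq_len(nr) - shift
  lo <- floor(src); w <- src - lo
  lo_c <- pmin(pmax(lo, 1L), nr)
  hi_c <- pmin(pmax(lo + 1L, 1L), nr)
  img[lo_c, , drop = FALSE] * (1 - w) + img[hi_c, , drop = FALSE] * w
}

#' Generate a synthetic axial cord DWI stack with ground truth
#'
#' Builds the label map and per-pixel tensor field, synthesizes one b0
#' plus six diffusion-weighted volumes per repetition under the given
#' scheme, applies the per-volume anterior-posterior motion, and adds
#' Rician noise.  Deterministic under the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @param scheme a [diffusion_scheme()]; defaults to the six-direction
#'   cervical-cord scheme at b = 750 s/mm^2.
#' @return A list with `truth` (label map, tensor field, analytic
#'   per-region metrics, realized shifts) and `stack` (a [dwi_stack()]).
#' @export
generate_phantom <- function(spec, scheme = diffusion_scheme()) {
  lab <- phantom_label_map(spec)
  D <- phantom_tensor_field(spec, lab)
  s0 <- matrix(spec$s0_by_tissue[label_to_tissue[PHANTOM_LABELS[as.vector(lab)]]],
               spec$matrix_size[1], spec$matrix_size[2])
  ndir <- nrow(scheme$unit_directions)
  nvol_rep <- ndir + 1L
  nvol <- nvol_rep * spec$n_repetitions
  # per-pixel ADC along each unit direction: quadratic form g' D g
  G <- scheme$unit_directions
  adc <- sapply(seq_len(ndir), function(i) {
    g <- G[i, ]
    D[, "Dxx"] * g[1]^2 + D[, "Dyy"] * g[2]^2 + D[, "Dzz"] * g[3]^2 +
      2 * (D[, "Dxy"] * g[1] * g[2] + D[, "Dxz"] * g[1] * g[3] +
             D[, "Dyz"] * g[2] * g[3])
  }) * 1e-3
  base <- vector("list", nvol_rep)
  base[[1]] <- s0
  for (i in seq_len(ndir)) {
    img <- s0 * exp(-scheme$b * matrix(adc[, i], nrow(s0), ncol(s0)))
    base[[i + 1L]] <- img
  }
  vox <- array(0, c(spec$matrix_size, nvol))
  meta <- data.frame(volume = seq_len(nvol),
                     b = 0, direction_index = 0L, repetition = 0L,
                     shift_px = 0)
  shifts <- with_seed(spec$seed, {
    sh <- motion_shifts(spec$motion_model, nvol)
    v <- 0L
    for (rep_i in seq_len(spec$n_repetitions)) {
      for (k in seq_len(nvol_rep)) {
        v <- v + 1L
        img <- shift_rows(base[[k]], sh[v])
        if (spec$noise_sigma > 0) img <- add_rician_noise(img, spec$noise_sigma)
        vox[, , v] <- img
        meta$b[v] <- if (k == 1L) 0 else scheme$b
        meta$direction_index[v] <- k - 1L
        meta$repetition[v] <- rep_i
        meta$shift_px[v] <- sh[v]
      }
    }
    sh
  })
  true_metrics <- do.call(rbind, lapply(
    setdiff(unique(label_to_region[PHANTOM_LABELS[as.vector(lab)]]), "background"),
    function(rg) {
      ev <- spec$region_tensors[[rg]]
      m <- metrics_from_eigenvalues(ev[1], ev[2], ev[3])
      data.frame(region = rg, FA = m[["FA"]], MD = m[["MD"]],
                 AD = m[["AD"]], RD = m[["RD"]])
    }))
  stack <- dwi_stack(vox, spacing = spec$pixel_spacing, volumes = meta,
                     provenance = "generate_phantom")
  list(truth = list(label_map = lab, tensor_field = D,
                    true_region_metrics = true_metrics, shifts = meta$shift_px,
                    spec = spec),
       stack = stack)
}
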