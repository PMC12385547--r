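# Log-linear diffusion tensor fitting from the six-direction cervical-cord
# scheme, eigenvalue metric maps (FA/MD/AD/RD), and interpolation of the
# metric maps to a finer grid.

#' Six-direction diffusion-encoding scheme
#'
#' The encoding set e1 = (1,0,1), e2 = (-1,0,1), e3 = (0,1,1),
#' e4 = (0,1,-1), e5 = (1,1,0), e6 = (-1,1,0) in the scanner frame (cord
#' along z), normalized to unit vectors; the b-value applies to the unit
#' directions.
#'
#' @param b b-value in s/mm^2 (default 750, typical for cervical-cord DTI).
#' @param raw_directions matrix of encoding directions (rows), any scaling.
#' @param n_b0 number of b0 volumes per repetition.
#' @return An object of class `diffusion_scheme` with `raw_directions`,
#'   `unit_directions`, `b`, `n_b0`.
#' @export
diffusion_scheme <- function(b = 750,
                             raw_directions = rbind(
                               e1 = c( 1, 0, 1), e2 = c(-1, 0, 1),
                               e3 = c( 0, 1, 1), e4 = c( 0, 1, -1),
                               e5 = c( 1, 1, 0), e6 = c(-1, 1, 0)),
                             n_b0 = 1L) {
  if (b < 0) stopf("b must be >= 0")
  norms <- sqrt(rowSums(raw_directions^2))
  if (any(norms == 0)) stopf("zero direction vector in scheme")
  unit <- raw_directions / norms
  sch <- structure(list(b = b, raw_directions = raw_directions,
                        unit_directions = unit, n_b0 = as.integer(n_b0)),
                   class = "diffusion_scheme")
  if (nrow(unit) >= 6 && qr(design_matrix(sch))$rank < 6)
    stopf("rank-deficient scheme: the %d directions span only rank %d of the 6 tensor components",
          nrow(unit), qr(design_matrix(sch))$rank)
  sch
}

#' Design matrix of the linearized Stejskal-Tanner model
#'
#' Row i is `b * (gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz)` for unit
#' direction i, so that `design %*% d = log(s0 / S)` for tensor 6-vector
#' `d = (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#'
#' @param scheme a [diffusion_scheme()].
#' @return `n_directions x 6` matrix.
#' @export
design_matrix <- function(scheme) {
  G <- scheme$unit_directions
  scheme$b * cbind(G[, 1]^2, G[, 2]^2, G[, 3]^2,
                   2 * G[, 1] * G[, 2], 2 * G[, 1] * G[, 3],
                   2 * G[, 2] * G[, 3])
}

#' Fit the diffusion tensor of a single pixel
#'
#' Ordinary least squares on log-attenuations: solves
#' `design %*% d = log(s0 / S_i)`.  With exactly six independent
#' directions the solve is exact, so noise-free signals are recovered to
#' numerical precision.
#'
#' @param signals per-direction diffusion-weighted signals (> 0).
#' @param s0 non-diffusion-weighted signal (> 0).
#' @param scheme a [diffusion_scheme()].
#' @return Tensor 6-vector `(Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)` in
#'   1e-3 mm^2/s, with attribute `residual` (RMS log-signal residual).
#' @export
fit_pixel <- function(signals, s0, scheme) {
  if (s0 <= 0 || any(signals <= 0)) stopf("signals and s0 must be > 0")
  X <- design_matrix(scheme)
  y <- log(s0 / signals)
  fit <- qr.solve(X, y)
  res <- sqrt(mean((X %*% fit - y)^2))
  structure(fit * 1e3, residual = res,
            names = c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz"))
}

#' Analytic DTI metrics from sorted eigenvalues
#'
#' MD = (l1 + l2 + l3)/3, AD = l1, RD = (l2 + l3)/2,
#' FA = sqrt(3/2) * sqrt(sum((l - mean)^2)) / sqrt(sum(l^2)); FA is 0 for
#' the all-zero tensor.  The alternative printed radial-diffusivity
#' convention `(l1 + l2)/2` is available via `rd_convention`.
#'
#' @param l1,l2,l3 eigenvalues sorted descending, 1e-3 mm^2/s.
#' @param rd_convention `"standard"` for (l2 + l3)/2 or `"l1l2"` for the
#'   (l1 + l2)/2 variant.
#' @return Named vector `(l1, l2, l3, FA, MD, AD, RD)`.
#' @export
metrics_from_eigenvalues <- function(l1, l2, l3, rd_convention = "standard") {
  lam <- c(l1, l2, l3)
  md <- mean(lam)
  ss <- sum(lam^2)
  fa <- if (ss == 0) 0 else sqrt(3 / 2) * sqrt(sum((lam - md)^2)) / sqrt(ss)
  rd <- switch(rd_convention,
               standard = (l2 + l3) / 2,
               l1l2 = (l1 + l2) / 2,
               stopf("unknown rd_convention '%s'", rd_convention))
  c(l1 = l1, l2 = l2, l3 = l3, FA = fa, MD = md, AD = l1, RD = rd)
}

#' Eigen-decompose a tensor and compute its metrics
#'
#' Eigenvalues are sorted descending and floored at `epsilon` (negative
#' values from noisy fits are clamped) before the metric formulas.
#'
#' @param tensor 6-vector or 3x3 symmetric matrix, 1e-3 mm^2/s.
#' @param epsilon eigenvalue floor (>= 0).
#' @inheritParams metrics_from_eigenvalues
#' @return Named vector `(l1, l2, l3, FA, MD, AD, RD)` with attribute
#'   `n_clamped` (count of floored eigenvalues).
#' @export
eigen_metrics <- function(tensor, epsilon = 0, rd_convention = "standard") {
  D <- as_tensor_matrix(tensor)
  if (any(!is.finite(D))) stopf("non-finite tensor")
  lam <- sort(eigen(D, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  n_clamped <- sum(lam < epsilon)
  lam <- pmax(lam, epsilon)
  structure(metrics_from_eigenvalues(lam[1], lam[2], lam[3], rd_convention),
            n_clamped = n_clamped)
}

#' FA/MD/AD/RD maps from an averaged stack
#'
#' Per-pixel log-linear tensor fit over all pixels whose mean b0 exceeds a
#' background threshold (default 10% of the 98th-percentile b0
#' intensity), followed by eigenvalue metrics.  Invalid pixels (background
#' or non-positive signals) carry `NA`.
#'
#' @param stack averaged [dwi_stack()] (one volume per direction + b0).
#' @param scheme a [diffusion_scheme()].
#' @param mask_threshold background threshold as a fraction of the 98th
#'   percentile of the b0 image.
#' @param epsilon eigenvalue floor passed to [eigen_metrics()].
#' @inheritParams metrics_from_eigenvalues
#' @return An object of class `metric_maps`: matrices `FA`, `MD`, `AD`,
#'   `RD` (1e-3 mm^2/s), `b0`, logical `mask`, `spacing`, `interpolated`
#'   flag and a `qc` list (clamped eigenvalue count, mean fit residual).
#' @export
compute_maps <- function(stack, scheme, mask_threshold = 0.1, epsilon = 0,
                         rd_convention = "standard") {
  meta <- stack$volumes
  b0_idx <- which(meta$direction_index == 0)
  if (length(b0_idx) == 0) stopf("stack has no b0 volume")
  dir_idx <- which(meta$direction_index > 0)
  if (length(dir_idx) < 6) stopf("need >= 6 diffusion-weighted volumes")
  b0 <- apply(stack$voxels[, , b0_idx, drop = FALSE], c(1, 2), mean)
  thresh <- mask_threshold * stats::quantile(b0, 0.98)
  mask <- b0 > thresh
  d <- dim(b0)
  FA <- MD <- AD <- RD <- matrix(NA_real_, d[1], d[2])
  X <- design_matrix(scheme)
  Xinv <- solve(qr(X), diag(nrow(X)))  # 6x6 exact inverse for the 6-dir scheme
  n_clamped <- 0L; res_sum <- 0; n_fit <- 0L
  sig <- matrix(stack$voxels[, , dir_idx[order(meta$direction_index[dir_idx])]],
                nrow = d[1] * d[2])
  b0v <- as.vector(b0)
  floor_sig <- 1e-6
  for (p in which(as.vector(mask))) {
    s <- pmax(sig[p, ], floor_sig)
    y <- log(b0v[p] / s)
    dvec <- drop(Xinv %*% y) * 1e3
    m <- eigen_metrics(dvec, epsilon = epsilon, rd_convention = rd_convention)
    n_clamped <- n_clamped + attr(m, "n_clamped")
    n_fit <- n_fit + 1L
    FA[p] <- min(max(m[["FA"]], 0), 1)
    MD[p] <- m[["MD"]]; AD[p] <- m[["AD"]]; RD[p] <- m[["RD"]]
  }
  structure(list(FA = FA, MD = MD, AD = AD, RD = RD, b0 = b0, mask = mask,
                 spacing = stack$spacing, interpolated = FALSE,
                 qc = list(n_clamped = n_clamped, n_fit = n_fit)),
            class = "metric_maps")
}

#' @export
print.metric_maps <- function(x, ...) {
  cat(sprintf("<metric_maps> %dx%d px at %.2fx%.2f mm%s; %d fitted pixels\n",
              nrow(x$FA), ncol(x$FA), x$spacing[1], x$spacing[2],
              if (x$interpolated) " (interpolated)" else "",
              sum(x$mask)))
  invisible(x)
}

# separable cubic-spline resampling of one 2-D map onto a finer grid;
# exact at sample-coincident points
resample_map <- function(map, spacing, target_spacing, out_dim) {
  src_r <- (seq_len(nrow(map)) - 0.5) * spacing[1]
  src_c <- (seq_len(ncol(map)) - 0.5) * spacing[2]
  out_r <- (seq_len(out_dim[1]) - 0.5) * target_spacing
  out_c <- (seq_len(out_dim[2]) - 0.5) * target_spacing
  out_r <- pmin(pmax(out_r, src_r[1]), src_r[length(src_r)])
  out_c <- pmin(pmax(out_c, src_c[1]), src_c[length(src_c)])
  tmp <- apply(map, 2, function(col)
    stats::splinefun(src_r, col, method = "monoH.FC")(out_r))
  t(apply(tmp, 1, function(rowv)
    stats::splinefun(src_c, rowv, method = "monoH.FC")(out_c)))
}

#' Interpolate metric maps to a finer grid
#'
#' Resamples each metric map (not the raw DWIs) with a separable cubic
#' spline onto a square grid of the target spacing covering the same
#' field of view; FA is clipped back to `[0, 1]`.  `NA` background pixels
#' are filled with 0 before resampling and re-masked afterwards.
#'
#' @param maps a `metric_maps` object at native resolution.
#' @param target_spacing target pixel size in mm (default 0.2).
#' @return A `metric_maps` object with `interpolated = TRUE`.
#' @export
interpolate_maps <- function(maps, target_spacing = 0.2) {
  if (target_spacing <= 0) stopf("target_spacing must be > 0")
  if (any(target_spacing >= maps$spacing))
    stopf("target_spacing must be finer than the native %.2f mm", maps$spacing[1])
  out_dim <- round(dim(maps$FA) * maps$spacing / target_spacing)
  fill <- function(m) { m[is.na(m)] <- 0; m }
  res <- lapply(maps[c("FA", "MD", "AD", "RD")], function(m)
    resample_map(fill(m), maps$spacing, target_spacing, out_dim))
  b0 <- resample_map(maps$b0, maps$spacing, target_spacing, out_dim)
  mask <- resample_map(maps$mask + 0, maps$spacing, target_spacing, out_dim) > 0.5
  res$FA <- pmin(pmax(res$FA, 0), 1)
  for (nm in names(res)) res[[nm]][!mask] <- NA_real_
  structure(list(FA = res$FA, MD = res$MD, AD = res$AD, RD = res$RD,
                 b0 = b0, mask = mask,
                 spacing = c(target_spacing, target_spacing),
                 interpolated = TRUE, qc = maps$qc),
            class = "metric_maps")
}
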