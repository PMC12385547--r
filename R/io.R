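# Standard-format I/O: NIfTI images (volumes along the third axis) with
# FSL-style bvals/bvecs text files for DWI stacks, NIfTI metric maps, and
# tidy CSV for tract metrics.

#' Write a DWI stack as NIfTI + bvals/bvecs
#'
#' Writes `<prefix>.nii.gz` (a 3-D NIfTI whose third axis indexes
#' volumes, with the 2-D slice geometry in the header), `<prefix>.bval`
#' and `<prefix>.bvec` (FSL convention: bvals on one line, bvecs as three
#' lines of x/y/z components) and `<prefix>_volumes.csv` with the full
#' per-volume metadata.
#'
#' @param stack a [dwi_stack()].
#' @param prefix output path prefix.
#' @param scheme the [diffusion_scheme()] used (for bvec directions).
#' @return Invisibly, the vector of files written.
#' @export
write_dwi_stack <- function(stack, prefix, scheme = diffusion_scheme()) {
  img <- RNifti::asNifti(stack$voxels)
  RNifti::pixdim(img) <- c(stack$spacing, 1)
  nii <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(img, nii)
  bvals <- stack$volumes$b
  dirs <- matrix(0, 3, nrow(stack$volumes))
  dwi <- stack$volumes$direction_index > 0
  dirs[, dwi] <- t(scheme$unit_directions[stack$volumes$direction_index[dwi], ,
                                          drop = FALSE])
  bval_f <- paste0(prefix, ".bval")
  bvec_f <- paste0(prefix, ".bvec")
  writeLines(paste(format(bvals, trim = TRUE), collapse = " "), bval_f)
  writeLines(apply(dirs, 1, function(r)
    paste(format(r, trim = TRUE, digits = 8), collapse = " ")), bvec_f)
  meta_f <- paste0(prefix, "_volumes.csv")
  utils::write.csv(stack$volumes, meta_f, row.names = FALSE)
  invisible(c(nii, bval_f, bvec_f, meta_f))
}

#' Read a DWI stack written by [write_dwi_stack()]
#'
#' @param prefix path prefix used when writing.
#' @return A [dwi_stack()].
#' @export
read_dwi_stack <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  vox <- array(as.numeric(img), dim = dim(img))
  spacing <- RNifti::pixdim(img)[1:2]
  meta_f <- paste0(prefix, "_volumes.csv")
  meta <- if (file.exists(meta_f)) utils::read.csv(meta_f) else {
    bvals <- scan(paste0(prefix, ".bval"), quiet = TRUE)
    data.frame(volume = seq_along(bvals), b = bvals,
               direction_index = ifelse(bvals == 0, 0L, NA_integer_),
               repetition = NA_integer_)
  }
  dwi_stack(vox, spacing, meta, provenance = sprintf("read_dwi_stack(%s)", prefix))
}

#' Write FA/MD/AD/RD maps as NIfTI files plus a QC JSON
#'
#' @param maps a `metric_maps` object.
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return Invisibly, the files written.
#' @export
write_metric_maps <- function(maps, dir, prefix = "maps") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (m in c("FA", "MD", "AD", "RD")) {
    f <- file.path(dir, sprintf("%s_%s.nii.gz", prefix, m))
    img <- maps[[m]]
    img[is.na(img)] <- 0
    img <- RNifti::asNifti(img)
    RNifti::pixdim(img) <- maps$spacing
    RNifti::writeNifti(img, f)
    files <- c(files, f)
  }
  qc_f <- file.path(dir, sprintf("%s_qc.json", prefix))
  jsonlite::write_json(c(maps$qc, list(interpolated = maps$interpolated,
                                       spacing_mm = maps$spacing)),
                       qc_f, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, qc_f))
}

#' Write tidy tract metrics as CSV
#'
#' One row per participant x scanner x session x region x metric, the
#' interchange format between the ROI stage and the reliability battery.
#'
#' @param tidy data frame.
#' @param file output path.
#' @export
write_tidy_metrics <- function(tidy, file) {
  utils::write.csv(tidy, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_tidy_metrics
#' @export
read_tidy_metrics <- function(file) utils::read.csv(file)
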