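# NIfTI / text-format interfaces: volumes, FSL-style bval/bvec, AIF and
# record tables.

#' Write a volume to NIfTI
#'
#' @param volume 3D or 4D numeric array; a `voxdim` attribute (mm) is
#'   honoured.
#' @param path output file (.nii or .nii.gz).
#' @param voxdim voxel sizes (mm), overriding the attribute.
#' @return the path, invisibly.
#' @export
write_volume_nifti <- function(volume, path, voxdim = NULL) {
  if (is.null(voxdim)) voxdim <- attr(volume, "voxdim")
  if (is.null(voxdim)) voxdim <- c(1, 1, 1)
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- voxdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' @param path NIfTI file.
#' @return array with a `voxdim` attribute.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxdim") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  out
}

#' Write / read an acquisition scheme as FSL-style bval/bvec files
#'
#' Whitespace-separated rows: one row of b-values; three rows of gradient
#' components.
#'
#' @param scheme an [acquisition_scheme()].
#' @param bval_path,bvec_path output paths.
#' @return paths, invisibly.
#' @export
write_scheme_fsl <- function(scheme, bval_path, bvec_path) {
  writeLines(paste(format(scheme$bval, trim = TRUE), collapse = " "),
             bval_path)
  writeLines(apply(t(scheme$bvec), 1, function(r)
    paste(format(r, trim = TRUE, digits = 10), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' @rdname write_scheme_fsl
#' @export
read_scheme_fsl <- function(bval_path, bvec_path) {
  bval <- scan(bval_path, quiet = TRUE)
  rows <- lapply(strsplit(trimws(readLines(bvec_path)), "\\s+"), as.numeric)
  bvec <- t(do.call(rbind, rows))
  acquisition_scheme(bval, bvec)
}

#' Write an AIF as a two-column TSV (time_s, concentration)
#'
#' @param aif tibble with `time_s` and `concentration`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_aif_tsv <- function(aif, path) {
  utils::write.table(aif[, c("time_s", "concentration")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_aif_tsv
#' @export
read_aif_tsv <- function(path) {
  tibble::as_tibble(utils::read.delim(path))
}

write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
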