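#' Read / write volumes as NIfTI
#'
#' Thin wrappers over the RNifti package (Suggests) for the optional
#' volumetric external interface; the core pipeline works on plain arrays.
#'
#' @param path NIfTI file path.
#' @param volume numeric array (3-D mask/Z map or 4-D time series).
#' @return `read_nifti_volume` returns a plain numeric array;
#'   `write_nifti_volume` returns `path` invisibly.
#' @export
read_nifti_volume <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI requires the RNifti package")
  arr <- RNifti::readNifti(path)
  array(as.numeric(arr), dim = dim(arr))
}

#' @rdname read_nifti_volume
#' @export
write_nifti_volume <- function(volume, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writing NIfTI requires the RNifti package")
  RNifti::writeNifti(RNifti::asNifti(volume), path)
  invisible(path)
}
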