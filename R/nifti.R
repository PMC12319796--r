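#' Voxelwise OEF from NIfTI parametric maps
#'
#' Reads MTT and CTH parametric maps (NIfTI-1, seconds), evaluates the OEF
#' model voxelwise with [oef_map()], and optionally writes the result as a
#' NIfTI image inheriting the MTT map's header and affine. Requires the
#' suggested RNifti package.
#'
#' @param mtt_file,cth_file paths to NIfTI images of MTT and CTH (s).
#' @param out_file optional output path for the OEF image.
#' @param constants an [oef_constants()] object.
#' @param mask_file optional NIfTI mask (non-zero = evaluate).
#' @param lookup passed to [oef_map()]; recommended for whole-brain maps.
#' @return The OEF image as an `RNifti` "niftiImage" (invisibly if written).
#' @export
oef_nifti <- function(mtt_file, cth_file, out_file = NULL,
                      constants = oef_constants(), mask_file = NULL,
                      lookup = TRUE) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("oef_nifti() requires the RNifti package", call. = FALSE)
  mtt <- RNifti::readNifti(mtt_file)
  cth <- RNifti::readNifti(cth_file)
  mask <- if (!is.null(mask_file)) {
    m <- RNifti::readNifti(mask_file)
    array(as.logical(m != 0), dim = dim(m))
  }
  res <- oef_map(array(as.numeric(mtt), dim = dim(mtt)),
                 array(as.numeric(cth), dim = dim(cth)),
                 constants = constants, mask = mask, lookup = lookup)
  img <- RNifti::asNifti(res, reference = mtt)
  if (!is.null(out_file)) {
    RNifti::writeNifti(img, out_file)
    return(invisible(img))
  }
  img
}
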