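#' NIfTI-1 input/output for BOLD runs, masks and statistic maps
#'
#' Thin wrappers over RNifti. Voxel data are stored as float32 (maps and 4D
#' BOLD) or uint8 (masks); the voxel-to-mm affine is carried in the sform.
#'
#' @param run a `bold_run` object.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_bold_nifti` returns `path` invisibly; `read_bold_nifti`
#'   returns a `bold_run` (metadata not representable in the NIfTI header —
#'   pair/participant identity, task type — must be supplied).
#' @export
write_bold_nifti <- function(run, path) {
  stopifnot(inherits(run, "bold_run"))
  img <- RNifti::asNifti(bold_array(run), datatype = "float")
  img <- RNifti::`sform<-`(img, structure(run$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @param tr_s repetition time in seconds.
#' @param participant_id,pair_id,run_index,task_type metadata to attach.
#' @export
read_bold_nifti <- function(path, tr_s = 2.5, participant_id = NA,
                            pair_id = NA, run_index = NA, task_type = NA) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4) stop("expected a 4D BOLD image", call. = FALSE)
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  dat <- matrix(as.numeric(img), prod(d[1:3]), d[4])
  structure(list(data = dat, dim = d[1:3], voxel_mm = abs(aff[1, 1]),
                 affine = matrix(as.numeric(aff), 4, 4), tr_s = tr_s,
                 n_volumes = d[4], participant_id = participant_id,
                 pair_id = pair_id, run_index = run_index,
                 task_type = task_type),
            class = "bold_run")
}

#' Write a 3D map or byte mask as NIfTI
#'
#' @param values numeric or logical vector/3D array of voxel values.
#' @param dim integer length-3 grid dimensions (taken from `values` if it is
#'   an array).
#' @param affine 4x4 voxel-to-mm matrix (default: centred `voxel_mm`-isotropic).
#' @param voxel_mm isotropic voxel size used when `affine` is missing.
#' @param path file path.
#' @export
write_map_nifti <- function(values, path, dim = NULL, affine = NULL,
                            voxel_mm = 3) {
  if (is.null(dim)) dim <- base::dim(values)
  stopifnot(length(dim) == 3)
  if (is.null(affine)) affine <- mni_like_affine(dim, voxel_mm)
  dtype <- if (is.logical(values)) "uint8" else "float"
  arr <- array(if (is.logical(values)) as.integer(values) else as.numeric(values),
               dim = dim)
  img <- RNifti::asNifti(arr, datatype = dtype)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
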