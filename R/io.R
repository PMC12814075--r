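#' Write / read a BOLD run as NIfTI
#'
#' @param run a `bold_run`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_bold <- function(run, path) {
  img <- RNifti::asNifti(run$data)
  img <- RNifti::`pixdim<-`(img, c(sqrt(colSums(run$affine[1:3, 1:3]^2)),
                                   run$tr_seconds))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold
#' @param tr_seconds repetition time; taken from the NIfTI header when
#'   `NULL`.
#' @param affine 4x4 affine; identity-scaled from the header pixdim when
#'   `NULL`.
#' @export
read_bold <- function(path, tr_seconds = NULL, affine = NULL) {
  img <- RNifti::readNifti(path)
  pd <- attr(img, "pixdim") %||% RNifti::pixdim(img)
  if (is.null(tr_seconds)) tr_seconds <- if (length(pd) >= 4) pd[4] else 1
  if (is.null(affine)) {
    affine <- diag(4)
    diag(affine)[1:3] <- pd[1:3]
  }
  bold_run(unclass(img)[, , , , drop = FALSE], affine, tr_seconds)
}

#' Write a 3D mask or label array as NIfTI
#' @param arr logical or integer 3D array.
#' @param path output path.
#' @export
write_mask <- function(arr, path) {
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(arr), dim(arr))), path)
  invisible(path)
}

#' Write a simulated subject to disk
#'
#' BOLD and the four lesion masks as NIfTI, confounds as TSV, the
#' ground-truth record as JSON — the on-disk layout a scanner-facing
#' pipeline would consume.
#'
#' @param subject a `glioma_subject`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject <- function(subject, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_bold(subject$bold, file.path(dir, "bold.nii.gz"))
  les <- subject$lesions
  for (nm in c("larger_mask", "smaller_mask", "larger_control",
               "smaller_control")) {
    write_mask(les[[nm]], file.path(dir, paste0(nm, ".nii.gz")))
  }
  write.table(subject$confounds, file.path(dir, "confounds.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(subject$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a confounds TSV
#' @param path TSV with columns trans_x/y/z, rot_x/y/z, wm, csf.
#' @return Tibble.
#' @export
read_confounds <- function(path) {
  tibble::as_tibble(read.delim(path))
}
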