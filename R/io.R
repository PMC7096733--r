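# NIfTI-1 I/O via RNifti. The synthetic grid uses a diagonal affine:
# world = (index - 1) * voxel size, origin at voxel (1,1,1).

#' Write / read a 4D BOLD volume as NIfTI-1
#'
#' The affine encodes the isotropic voxel size; the TR is stored in the fourth
#' pixdim slot.
#'
#' @param bold a [bold4d()].
#' @param path destination path (`.nii`).
#' @return `read_bold` returns a [bold4d()].
#' @export
write_bold <- function(bold, path) {
  img <- RNifti::asNifti(bold$data)
  RNifti::pixdim(img) <- c(bold$voxel_size_mm, bold$tr_s)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold
#' @param tr_s repetition time override; by default taken from the header.
#' @export
read_bold <- function(path, tr_s = NULL) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  if (is.null(tr_s)) tr_s <- if (length(pd) >= 4) pd[4] else 2
  bold4d(array(as.numeric(img), dim = dim(img)), tr_s,
         voxel_size_mm = pd[1:3])
}

#' Write / read a 3D mask or map as NIfTI-1
#'
#' @param mask logical or numeric 3D array.
#' @param path destination path.
#' @param voxel_size_mm per-axis voxel size.
#' @return `read_mask` returns a logical array; `read_map_values` a numeric
#'   array.
#' @export
write_mask <- function(mask, path, voxel_size_mm = 3) {
  img <- RNifti::asNifti(array(as.numeric(mask), dim(mask)))
  RNifti::pixdim(img) <- rep_len(voxel_size_mm, 3)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img) > 0.5, dim = dim(img))
}

#' @rdname write_mask
#' @export
read_map_values <- function(path) {
  img <- RNifti::readNifti(path)
  array(as.numeric(img), dim = dim(img))
}

#' Write a metric map as NIfTI-1 with a TSV sidecar
#'
#' The sidecar records the map kind and any provenance parameters.
#'
#' @param map a [metric_map()].
#' @param path destination `.nii` path; the sidecar uses the same stem with
#'   `.tsv`.
#' @return The path, invisibly.
#' @export
write_metric_map <- function(map, path) {
  write_mask(map$values, path, map$voxel_size_mm)
  side <- data.frame(key = c("kind", names(map$provenance)),
                     value = c(map$kind,
                               vapply(map$provenance, function(x)
                                 paste(format(x), collapse = ","), "")))
  utils::write.table(side, sub("\\.nii$", ".tsv", path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
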