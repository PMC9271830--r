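#' Read a volume from NIfTI
#'
#' Loads image data and voxel spacing. Only the spacing of the affine is
#' honored (the package works in scanner-agnostic voxel/world coordinates
#' \code{world = 0-based index * spacing}).
#'
#' @param path a .nii or .nii.gz file.
#' @return list with \code{data} (array) and \code{spacing} (length 3).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  spc <- RNifti::pixdim(img)
  list(data = as.array(img), spacing = as.numeric(spc[seq_len(3)]))
}

#' Write a volume to NIfTI
#'
#' @param data numeric/integer 3D array.
#' @param path output .nii or .nii.gz path.
#' @param spacing voxel sizes (default 1 mm isotropic).
#' @return the path, invisibly.
#' @export
write_volume <- function(data, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(data, pixdim = spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write an interface point cloud as CSV
#'
#' Columns x, y, z (world coordinates) and r (radius from center), one row
#' per interface point; header row included.
#'
#' @param interface a [extract_interface()] result.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_interface_csv <- function(interface, path) {
  stopifnot(inherits(interface, "tumor_interface"))
  df <- data.frame(x = interface$points[, 1], y = interface$points[, 2],
                   z = interface$points[, 3], r = interface$radii)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an interface point cloud from CSV
#'
#' Expects columns x, y, z; the center defaults to the point centroid if
#' not supplied, and radii are recomputed from it.
#'
#' @param path CSV with x, y, z columns.
#' @param center optional known tumor center.
#' @return a \code{tumor_interface}.
#' @export
read_interface_csv <- function(path, center = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("x", "y", "z") %in% names(df)))
  pts <- as.matrix(df[, c("x", "y", "z")])
  if (is.null(center)) center <- colMeans(pts)
  radii <- sqrt(rowSums((pts - rep(center, each = nrow(pts)))^2))
  structure(list(points = pts, vox = round(pts) + 1L, center = center,
                 radii = radii, spacing = c(1, 1, 1), n_points = nrow(pts),
                 rejected = FALSE), class = "tumor_interface")
}

#' Write a tumor record (scalars and fit diagnostics) as JSON
#'
#' @param rec a \code{tumor_record}.
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_record_json <- function(rec, path) {
  row <- record_row(rec)
  extra <- list(qc = rec$qc)
  if (!is.null(rec$scaling$d_F_fit))
    extra$d_F_fit <- unclass(rec$scaling$d_F_fit)
  if (!is.null(rec$scaling$alpha_loc_fit))
    extra$alpha_loc_fit <- unclass(rec$scaling$alpha_loc_fit)
  jsonlite::write_json(c(as.list(row), extra), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}
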