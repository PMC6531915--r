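# File interfaces: legacy-ASCII VTK export of grids and maps, NIfTI
# volumes (via RNifti when available), CSV traces and JSON specs.

#' Write a tissue grid as a legacy VTK structured-points-free file
#'
#' Exports the hexahedral grid as a VTK legacy unstructured grid with
#' cell-data arrays \code{label}, \code{layer}, \code{sigma_l},
#' \code{sigma_t} and \code{fiber} (vectors), readable by ParaView.
#'
#' @param grid a [TissueGrid-class].
#' @param file output path (.vtk).
#' @param pointData optional named list of per-node scalar vectors (e.g.
#'   LAT or APD maps on the full node lattice).
#' @return the file path, invisibly.
#' @export
writeGridVTK <- function(grid, file, pointData = list()) {
  stopifnot(is(grid, "TissueGrid"))
  nodes <- nodeCoordinates(grid)
  en <- .elem_nodes(grid@dims)
  # VTK hexahedron ordering: bottom face CCW, then top face CCW
  vtkOrder <- c(1, 2, 4, 3, 5, 6, 8, 7)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "ivtlab tissue grid", "ASCII",
               "DATASET UNSTRUCTURED_GRID"), con)
  writeLines(sprintf("POINTS %d double", nrow(nodes)), con)
  writeLines(apply(format(nodes, trim = TRUE), 1, paste, collapse = " "), con)
  ne <- nrow(en)
  writeLines(sprintf("CELLS %d %d", ne, ne * 9), con)
  cellTxt <- cbind(8L, en[, vtkOrder, drop = FALSE] - 1L)
  writeLines(apply(cellTxt, 1, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(as.character(rep(12L, ne)), con)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeScalar <- function(name, x, type = "float") {
    writeLines(sprintf("SCALARS %s %s 1", name, type), con)
    writeLines("LOOKUP_TABLE default", con)
    writeLines(as.character(x), con)
  }
  writeScalar("label", grid@label, "int")
  writeScalar("layer", grid@layer, "int")
  writeScalar("sigma_l", grid@sigma[, 1])
  writeScalar("sigma_t", grid@sigma[, 2])
  writeLines("VECTORS fiber float", con)
  writeLines(apply(format(grid@fiber, trim = TRUE), 1, paste,
                   collapse = " "), con)
  if (length(pointData)) {
    writeLines(sprintf("POINT_DATA %d", nrow(nodes)), con)
    for (nm in names(pointData)) writeScalar(nm, pointData[[nm]])
  }
  invisible(file)
}

#' Read or write a voxel volume as NIfTI
#'
#' Thin wrappers over RNifti (a suggested dependency); intensities and
#' the isotropic spacing round-trip.
#'
#' @param volume a [VoxelVolume-class].
#' @param file path (.nii or .nii.gz).
#' @return \code{readVolumeNifti}: a [VoxelVolume-class].
#' @export
writeVolumeNifti <- function(volume, file) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI I/O")
  arr <- volume@data
  attr(arr, "pixdim") <- rep(volume@spacing, 3)
  attr(arr, "pixunits") <- c("mm", "s")
  RNifti::writeNifti(RNifti::asNifti(arr), file)
  invisible(file)
}

#' @rdname writeVolumeNifti
#' @export
readVolumeNifti <- function(file) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI I/O")
  img <- RNifti::readNifti(file)
  sp <- RNifti::pixdim(img)[1]
  new("VoxelVolume", data = array(as.numeric(img), dim = dim(img)),
      spacing = sp, origin = rep(sp / 2, 3))
}

#' Write a membrane-potential trace as CSV
#'
#' @param trace data.frame from [paceSingleCell()] or probe traces.
#' @param file output path.
#' @export
writeTraceCSV <- function(trace, file) {
  write.csv(trace, file, row.names = FALSE)
  invisible(file)
}

#' Write biomarkers or protocol definitions as JSON
#'
#' @param x a list or data.frame.
#' @param file output path.
#' @export
writeJSON <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(file)
}
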