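#' Write a scalar field as a legacy VTK structured-points file
#'
#' ASCII legacy VTK (`STRUCTURED_POINTS`, point data at voxel centres), the
#' lowest-common-denominator format every scientific viewer reads.
#'
#' @param values 3-d numeric array.
#' @param spacing voxel spacing, m.
#' @param path output path (conventionally `.vtk`).
#' @param name array name in the file.
#' @return the path, invisibly.
#' @export
write_field_vtk <- function(values, spacing, path, name = "field") {
  d <- dim(values)
  stopifnot(length(d) == 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("photoseed field:", name),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", spacing / 2, spacing / 2,
                       spacing / 2),
               sprintf("SPACING %g %g %g", spacing, spacing, spacing),
               sprintf("POINT_DATA %d", prod(d)),
               sprintf("SCALARS %s double 1", name),
               "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(values), scientific = TRUE, digits = 9), con)
  invisible(path)
}

#' Write a phantom's material labels as a VTK file
#'
#' Labels are encoded as integer codes; the mapping is recorded in the file
#' header comment.
#'
#' @param phantom a `tissue_phantom`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_phantom_vtk <- function(phantom, path) {
  labs <- as.vector(phantom$labels)
  ulab <- sort(unique(labs))
  codes <- match(labs, ulab)
  d <- phantom$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               paste("photoseed labels:",
                     paste(sprintf("%d=%s", seq_along(ulab), ulab),
                           collapse = " ")),
               "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", phantom$spacing / 2,
                       phantom$spacing / 2, phantom$spacing / 2),
               sprintf("SPACING %g %g %g", phantom$spacing, phantom$spacing,
                       phantom$spacing),
               sprintf("POINT_DATA %d", prod(d)),
               "SCALARS material int 1",
               "LOOKUP_TABLE default"), con)
  writeLines(as.character(codes), con)
  invisible(path)
}
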