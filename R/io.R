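## TIFF I/O. Stacks travel as multi-page 32-bit float TIFF (one page per z
## slice); integer label volumes as 16-bit pages. The installed TIFF writer
## carries no resolution tags, so the physical voxel size is stored in a
## YAML sidecar ("<file>.meta.yaml") written next to each image and read
## back automatically; an explicit voxelSize argument always wins.

.sidecarPath <- function(path) paste0(path, ".meta.yaml")

.writeSidecar <- function(path, voxelSize, origin, extra = list()) {
  meta <- c(list(voxel_size_um = as.numeric(voxelSize),
                 origin_um = as.numeric(origin)), extra)
  yaml::write_yaml(meta, .sidecarPath(path))
}

.readSidecar <- function(path) {
  sp <- .sidecarPath(path)
  if (!file.exists(sp)) return(NULL)
  yaml::read_yaml(sp)
}

#' Read and write image stacks
#'
#' \code{writeStack} writes a \linkS4class{VoxelGrid} as a multi-page
#' 32-bit float TIFF plus a voxel-size sidecar; \code{readStack} reads it
#' back. Without a sidecar, \code{voxelSize} must be supplied.
#'
#' @param stack a \linkS4class{VoxelGrid}.
#' @param path TIFF file path.
#' @param voxelSize optional voxel size override (length 1 or 3,
#'   micrometres).
#' @return \code{readStack}: a \linkS4class{VoxelGrid};
#'   \code{writeStack}: the path, invisibly.
#' @name stack-io
NULL

#' @rdname stack-io
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "VoxelGrid"))
  nd <- dim(stack@values)
  ## the TIFF writer stores samples in [0, 1]; rescale and keep the
  ## original intensity range in the sidecar
  rng <- range(stack@values)
  span <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(seq_len(nd[3]), function(z)
    (stack@values[, , z] - rng[1]) / span)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "LZW")
  .writeSidecar(path, stack@voxelSize, stack@origin,
                list(intensity_min = rng[1], intensity_span = span))
  invisible(path)
}

#' @rdname stack-io
#' @export
readStack <- function(path, voxelSize = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- simplify2array(pages)
  if (length(dim(arr)) != 3) stop("expected single-channel pages")
  meta <- .readSidecar(path)
  origin <- c(0, 0, 0)
  if (is.null(voxelSize)) {
    if (is.null(meta))
      stop("no voxel size: supply voxelSize or provide the sidecar ",
           .sidecarPath(path))
    voxelSize <- meta$voxel_size_um
    if (!is.null(meta$origin_um)) origin <- meta$origin_um
  }
  if (!is.null(meta$intensity_span))
    arr <- arr * meta$intensity_span + meta$intensity_min
  if (length(voxelSize) == 1) voxelSize <- rep(voxelSize, 3)
  new("VoxelGrid", values = arr, voxelSize = as.numeric(voxelSize),
      origin = origin)
}

#' Read and write label volumes
#'
#' Segmentations are stored as multi-page 16-bit TIFF (values are the cell
#' labels; at most 65535 cells) with the voxel-size sidecar.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param path TIFF file path.
#' @param voxelSize optional voxel size override.
#' @return \code{readLabelVolume}: a \linkS4class{LabelVolume};
#'   \code{writeLabelVolume}: the path, invisibly.
#' @name label-io
NULL

#' @rdname label-io
#' @export
writeLabelVolume <- function(labels, path) {
  stopifnot(is(labels, "LabelVolume"))
  if (max(labels@labels) > 65535L) stop("more than 65535 labels")
  nd <- dim(labels@labels)
  pages <- lapply(seq_len(nd[3]), function(z)
    labels@labels[, , z] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "LZW")
  .writeSidecar(path, labels@voxelSize, labels@origin)
  invisible(path)
}

#' @rdname label-io
#' @export
readLabelVolume <- function(path, voxelSize = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- simplify2array(pages)
  storage.mode(arr) <- "integer"
  meta <- .readSidecar(path)
  origin <- c(0, 0, 0)
  if (is.null(voxelSize)) {
    if (is.null(meta))
      stop("no voxel size: supply voxelSize or provide the sidecar ",
           .sidecarPath(path))
    voxelSize <- meta$voxel_size_um
    if (!is.null(meta$origin_um)) origin <- meta$origin_um
  }
  if (length(voxelSize) == 1) voxelSize <- rep(voxelSize, 3)
  new("LabelVolume", labels = arr, voxelSize = as.numeric(voxelSize),
      origin = origin)
}

#' Export a mesh as ASCII PLY
#'
#' Vertices carry the owning interface's cell pair as per-face properties;
#' an optional per-vertex scalar (e.g. the binarized signal) is stored as
#' the \code{quality} property.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param path output file.
#' @param vertexScalar optional numeric per-vertex values.
#' @return the path, invisibly.
#' @export
writeMeshPLY <- function(mesh, path, vertexScalar = NULL) {
  stopifnot(is(mesh, "SurfaceMesh"))
  nv <- nrow(mesh@vertices)
  nt <- nrow(mesh@triangles)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nv),
               "property float x", "property float y", "property float z",
               if (!is.null(vertexScalar)) "property float quality",
               paste("element face", nt),
               "property list uchar int vertex_indices",
               "property int cell_a", "property int cell_b",
               "end_header"), con)
  vm <- mesh@vertices
  if (!is.null(vertexScalar)) vm <- cbind(vm, vertexScalar)
  utils::write.table(format(vm, trim = TRUE, digits = 7), con,
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  tab <- mesh@interfaces
  fm <- cbind(3L, mesh@triangles - 1L,
              tab$cell_a[mesh@triInterface], tab$cell_b[mesh@triInterface])
  utils::write.table(fm, con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a simulated sample to disk
#'
#' Writes the two channels and the true segmentation as TIFF (with
#' sidecars) and the ground-truth tables as CSV into a directory.
#'
#' @param sim a \linkS4class{SimulatedRoot}.
#' @param dir output directory (created if needed).
#' @return invisible character vector of the files written.
#' @export
writeSimulatedRoot <- function(sim, dir) {
  stopifnot(is(sim, "SimulatedRoot"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(
    writeStack(sim@wall, file.path(dir, "wall.tif")),
    writeStack(sim@pd, file.path(dir, "pd.tif")),
    writeLabelVolume(sim@labels, file.path(dir, "labels.tif")))
  for (nm in c("cells", "interfaces", "spots")) {
    f <- file.path(dir, paste0("truth_", nm, ".csv"))
    utils::write.csv(slot(sim@truth, nm), f, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Build simulation parameters from a YAML config
#'
#' Reads a YAML file whose top-level keys \code{geometry}, \code{pit_field}
#' and \code{wall} map onto the arguments of \code{\link{rootGeometry}},
#' \code{\link{pitFieldParams}} and \code{\link{simulateRoot}}.
#'
#' @param path YAML file.
#' @return list with elements \code{geometry}, \code{pit}, \code{wall}
#'   (a list of wall rendering arguments) and \code{seed}.
#' @export
readSimConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  geom <- do.call(rootGeometry, cfg$geometry %||% list())
  pitArgs <- cfg$pit_field %||% list()
  if (!is.null(pitArgs$ratePerArea))
    pitArgs$ratePerArea <- unlist(pitArgs$ratePerArea)
  pit <- do.call(pitFieldParams, pitArgs)
  list(geometry = geom, pit = pit, wall = cfg$wall %||% list(),
       seed = cfg$seed %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
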