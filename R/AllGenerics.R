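#' Accessors for image and mesh containers
#'
#' Small accessor generics used across the package: \code{voxelSize} and
#' \code{gridOrigin} return the physical voxel geometry, \code{voxelData}
#' the raw array of a \linkS4class{VoxelGrid}, \code{labelData} the integer
#' array and \code{labelIds} the positive labels of a
#' \linkS4class{LabelVolume}, \code{vertices}/\code{triangles}/
#' \code{interfaceTable} the components of a \linkS4class{SurfaceMesh}.
#'
#' @param x the object.
#' @return the corresponding component.
#' @name accessors
#' @aliases voxelSize gridOrigin voxelData labelData labelIds vertices
#'   triangles interfaceTable
NULL

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("labelData", function(x) standardGeneric("labelData"))
#' @rdname accessors
#' @export
setGeneric("labelIds", function(x) standardGeneric("labelIds"))
#' @rdname accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname accessors
#' @export
setGeneric("triangles", function(x) standardGeneric("triangles"))
#' @rdname accessors
#' @export
setGeneric("interfaceTable", function(x) standardGeneric("interfaceTable"))

#' @rdname accessors
setMethod("voxelSize", "VoxelGrid", function(x) x@voxelSize)
#' @rdname accessors
setMethod("voxelSize", "LabelVolume", function(x) x@voxelSize)
#' @rdname accessors
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)
#' @rdname accessors
setMethod("gridOrigin", "LabelVolume", function(x) x@origin)
#' @rdname accessors
setMethod("voxelData", "VoxelGrid", function(x) x@values)
#' @rdname accessors
setMethod("labelData", "LabelVolume", function(x) x@labels)
#' @rdname accessors
setMethod("labelIds", "LabelVolume", function(x) {
  ids <- sort(unique(as.vector(x@labels)))
  ids[ids > 0]
})
#' @rdname accessors
setMethod("vertices", "SurfaceMesh", function(x) x@vertices)
#' @rdname accessors
setMethod("triangles", "SurfaceMesh", function(x) x@triangles)
#' @rdname accessors
setMethod("interfaceTable", "SurfaceMesh", function(x) x@interfaces)

#' Ground-truth accessors
#'
#' @param x a \linkS4class{RootTruth} or \linkS4class{SimulatedRoot}.
#' @return the requested ground-truth table.
#' @name truth-accessors
#' @aliases truthCells truthInterfaces truthSpots
NULL

#' @rdname truth-accessors
#' @export
setGeneric("truthCells", function(x) standardGeneric("truthCells"))
#' @rdname truth-accessors
#' @export
setGeneric("truthInterfaces", function(x) standardGeneric("truthInterfaces"))
#' @rdname truth-accessors
#' @export
setGeneric("truthSpots", function(x) standardGeneric("truthSpots"))

#' @rdname truth-accessors
setMethod("truthCells", "RootTruth", function(x) x@cells)
#' @rdname truth-accessors
setMethod("truthInterfaces", "RootTruth", function(x) x@interfaces)
#' @rdname truth-accessors
setMethod("truthSpots", "RootTruth", function(x) x@spots)
#' @rdname truth-accessors
setMethod("truthCells", "SimulatedRoot", function(x) x@truth@cells)
#' @rdname truth-accessors
setMethod("truthInterfaces", "SimulatedRoot", function(x) x@truth@interfaces)
#' @rdname truth-accessors
setMethod("truthSpots", "SimulatedRoot", function(x) x@truth@spots)

setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@values)
  cat("VoxelGrid:", paste(d, collapse = " x "), "voxels,",
      paste(signif(object@voxelSize, 3), collapse = " x "), "um/voxel\n")
  cat("  intensity range:", paste(signif(range(object@values), 4),
                                  collapse = " .. "), "\n")
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  ids <- labelIds(object)
  cat("LabelVolume:", paste(d, collapse = " x "), "voxels,",
      length(ids), "cells,",
      paste(signif(object@voxelSize, 3), collapse = " x "), "um/voxel\n")
})

setMethod("show", "SurfaceMesh", function(object) {
  cat("SurfaceMesh:", nrow(object@vertices), "vertices,",
      nrow(object@triangles), "triangles,",
      nrow(object@interfaces), "interfaces\n")
  cat("  cube size", object@cubeSize, "um,", object@smoothPasses,
      "smoothing passes, total area",
      signif(sum(object@interfaces$area_um2), 5), "um^2\n")
})

setMethod("show", "VertexSignal", function(object) {
  cat("VertexSignal:", length(object@raw), "vertices,",
      sum(object@binary > 0), "positive after trim/binarize\n")
  if (object@nOutOfBounds > 0)
    cat("  ", object@nOutOfBounds, "vertices outside the stack\n")
})

setMethod("show", "RootAxis", function(object) {
  cat("RootAxis: point (", paste(signif(object@axisPoint, 4), collapse = ", "),
      "), direction (", paste(signif(object@axisDirection, 4),
                              collapse = ", "), ")\n")
})

setMethod("show", "RootGeometry", function(object) {
  cat("RootGeometry:", length(object@layerRadii), "layers (",
      paste(object@layerNames, collapse = ", "), ")\n")
  cat("  outer radii:", paste(object@layerRadii, collapse = ", "),
      "um; sectors:", paste(object@cellsPerRing, collapse = ", "), "\n")
  cat("  stack", paste(object@stackExtent, collapse = " x "), "um at",
      paste(object@voxelSize, collapse = " x "), "um/voxel\n")
})

setMethod("show", "RootTruth", function(object) {
  cat("RootTruth:", nrow(object@cells), "cells,",
      nrow(object@interfaces), "interface patches,",
      nrow(object@spots), "spots\n")
})

setMethod("show", "SimulatedRoot", function(object) {
  cat("SimulatedRoot with channels wall + pd\n")
  show(object@labels)
  show(object@truth)
})
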