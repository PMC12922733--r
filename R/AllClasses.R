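#' @useDynLib pdmap, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' VoxelGrid: a 3D scalar image with physical voxel dimensions
#'
#' Container for one channel of a confocal stack (or any intermediate 3D
#' scalar field such as a blurred wall channel). Values are stored in a
#' numeric 3D array indexed (x, y, z); voxel centres sit at
#' \code{origin + (i - 0.5) * voxelSize} along each axis, all in micrometres.
#'
#' @slot values numeric 3D array of intensities.
#' @slot voxelSize numeric(3), voxel edge lengths in micrometres (x, y, z).
#' @slot origin numeric(3), physical position of the array corner in
#'   micrometres.
#' @export
setClass("VoxelGrid",
  representation(values = "array", voxelSize = "numeric", origin = "numeric"),
  prototype(voxelSize = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("VoxelGrid", function(object) {
  d <- dim(object@values)
  if (length(d) != 3) return("values must be a 3D array")
  if (any(d < 2)) return("each dimension must be at least 2")
  if (length(object@voxelSize) != 3 || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive finite numbers")
  if (length(object@origin) != 3 || any(!is.finite(object@origin)))
    return("origin must be 3 finite numbers")
  TRUE
})

#' LabelVolume: a 3D cell segmentation
#'
#' Integer 3D array assigning each voxel to a cell; 0 is reserved for
#' background/outside. Shares the voxel geometry conventions of
#' \linkS4class{VoxelGrid}.
#'
#' @slot labels integer 3D array; 0 = background.
#' @slot voxelSize numeric(3), micrometres.
#' @slot origin numeric(3), micrometres.
#' @export
setClass("LabelVolume",
  representation(labels = "array", voxelSize = "numeric", origin = "numeric"),
  prototype(voxelSize = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("LabelVolume", function(object) {
  d <- dim(object@labels)
  if (length(d) != 3) return("labels must be a 3D array")
  if (!is.integer(object@labels)) return("labels must be integer")
  if (any(object@labels < 0)) return("labels must be non-negative")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive numbers")
  TRUE
})

#' SurfaceMesh: triangulated cell surfaces partitioned into interfaces
#'
#' The boundary surface of a \linkS4class{LabelVolume}, extracted at a
#' requested sampling step (\code{cubeSize}) and smoothed. Every triangle
#' belongs to exactly one interface: an unordered pair of adjacent cell
#' labels, where label 0 denotes the exterior. Triangle winding is oriented
#' so normals point from \code{cell_a} toward \code{cell_b}.
#'
#' @slot vertices numeric matrix (n x 3) of vertex positions, micrometres.
#' @slot triangles integer matrix (m x 3) of vertex indices (1-based).
#' @slot triInterface integer(m), interface id per triangle (row index into
#'   the interface table).
#' @slot interfaces data.frame with one row per interface: \code{interface_id},
#'   \code{cell_a}, \code{cell_b} (0 = exterior), \code{area_um2}, and after
#'   annotation \code{orientation_class} and \code{interaction_class}.
#' @slot cubeSize numeric(1), sampling step used for extraction (micrometres).
#' @slot smoothPasses integer(1), smoothing passes applied.
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", triangles = "matrix",
                 triInterface = "integer", interfaces = "data.frame",
                 cubeSize = "numeric", smoothPasses = "integer"))

setValidity("SurfaceMesh", function(object) {
  nv <- nrow(object@vertices)
  if (ncol(object@vertices) != 3) return("vertices must have 3 columns")
  if (ncol(object@triangles) != 3) return("triangles must have 3 columns")
  tr <- object@triangles
  if (nrow(tr) > 0 && (min(tr) < 1 || max(tr) > nv))
    return("triangles index invalid vertices")
  if (length(object@triInterface) != nrow(tr))
    return("triInterface must have one entry per triangle")
  if (nrow(object@interfaces) > 0 &&
      any(object@interfaces$area_um2 < 0))
    return("interface areas must be non-negative")
  TRUE
})

#' VertexSignal: projected marker intensity per mesh vertex
#'
#' Raw, background-trimmed and binarized pit-field marker intensity sampled
#' at each vertex of a \linkS4class{SurfaceMesh}.
#'
#' @slot raw numeric, raw projected intensity per vertex.
#' @slot trimmed numeric, intensity after the background trim (0 where
#'   removed).
#' @slot binary numeric, \code{maxValue} where trimmed intensity is positive,
#'   0 elsewhere.
#' @slot maxValue numeric(1), value assigned to positive vertices.
#' @slot nOutOfBounds integer(1), number of vertices whose position fell
#'   outside the stack (sampled as 0).
#' @export
setClass("VertexSignal",
  representation(raw = "numeric", trimmed = "numeric", binary = "numeric",
                 maxValue = "numeric", nOutOfBounds = "integer"),
  prototype(maxValue = 1, nOutOfBounds = 0L))

setValidity("VertexSignal", function(object) {
  n <- length(object@raw)
  if (length(object@trimmed) != n || length(object@binary) != n)
    return("raw, trimmed and binary must have equal length")
  if (any(object@binary != 0 & object@binary != object@maxValue))
    return("binary values must be 0 or maxValue")
  TRUE
})

#' RootAxis: cylindrical coordinate frame of a root sample
#'
#' The organ axis estimated from a segmentation, defining the cylindrical
#' coordinates (axial position s, radial distance r, azimuth theta) used for
#' layer annotation and interface orientation classification.
#'
#' @slot axisPoint numeric(3), a point on the axis (micrometres).
#' @slot axisDirection numeric(3), unit direction; s increases along it.
#' @export
setClass("RootAxis",
  representation(axisPoint = "numeric", axisDirection = "numeric"))

setValidity("RootAxis", function(object) {
  if (length(object@axisDirection) != 3 ||
      abs(sqrt(sum(object@axisDirection^2)) - 1) > 1e-6)
    return("axisDirection must be a 3D unit vector")
  if (length(object@axisPoint) != 3) return("axisPoint must be length 3")
  TRUE
})

#' RootGeometry: parameters of the synthetic cylindrical root
#'
#' Describes a straight, radially layered cylindrical root aligned with the
#' z axis: concentric cell layers split into angular sectors and axial
#' segments. Created with \code{\link{rootGeometry}}.
#'
#' @slot layerRadii numeric, outer radius of each layer in micrometres,
#'   strictly decreasing inward.
#' @slot cellsPerRing integer, angular sectors per layer (1 or >= 3).
#' @slot axialCellLength numeric, axial cell length per layer (micrometres).
#' @slot stackExtent numeric(3), physical stack size (x, y, z) micrometres.
#' @slot voxelSize numeric(3), micrometres.
#' @slot layerNames character, layer names outermost first.
#' @slot sectorOffset numeric, angular offset (radians) of the sector
#'   boundaries of each layer.
#' @slot coreRadius numeric(1), radius of the inner core; 0 for none.
#' @export
setClass("RootGeometry",
  representation(layerRadii = "numeric", cellsPerRing = "integer",
                 axialCellLength = "numeric", stackExtent = "numeric",
                 voxelSize = "numeric", layerNames = "character",
                 sectorOffset = "numeric", coreRadius = "numeric"))

setValidity("RootGeometry", function(object) {
  L <- length(object@layerRadii)
  if (L < 1) return("at least one layer required")
  if (any(diff(object@layerRadii) >= 0))
    return("layerRadii must be strictly decreasing inward")
  if (any(object@layerRadii <= 0)) return("radii must be positive")
  if (length(object@cellsPerRing) != L ||
      any(object@cellsPerRing < 1))
    return("cellsPerRing must give >= 1 sectors per layer")
  if (any(object@cellsPerRing == 2))
    return("cellsPerRing of 2 is not supported (ambiguous sector walls)")
  if (length(object@axialCellLength) != L ||
      any(object@axialCellLength <= 0))
    return("axialCellLength must be positive per layer")
  if (length(object@stackExtent) != 3 || any(object@stackExtent <= 0))
    return("stackExtent must be 3 positive numbers")
  if (length(object@voxelSize) != 3 || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive numbers")
  if (length(object@layerNames) != L)
    return("layerNames must name every layer")
  if (object@coreRadius < 0 ||
      object@coreRadius >= object@layerRadii[L])
    return("coreRadius must be in [0, innermost layer radius)")
  TRUE
})

#' PitFieldParams: pit-field placement and rendering parameters
#'
#' Controls the punctate plasmodesmata-marker channel of the synthetic root:
#' expected spot count per unit interface area by interface class, spatial
#' placement mode (uniform or Thomas parent-offspring clustering), the
#' imaging point-spread width of a rendered spot, and additive noise.
#' Created with \code{\link{pitFieldParams}}.
#'
#' @slot ratePerArea named numeric, expected spots per square micrometre for
#'   classes \code{apical_basal}, \code{radial}, \code{circumferential}.
#' @slot clusterMode character, "uniform" or "thomas".
#' @slot parentsPerArea numeric(1), parent intensity per square micrometre in
#'   thomas mode; \code{NA} derives it as rate / offspringPerParent so both
#'   modes share the same expected spot count.
#' @slot offspringPerParent numeric(1), mean offspring per parent.
#' @slot clusterSigma numeric(1), in-plane offspring dispersion (micrometres).
#' @slot spotSigma numeric(1), rendered spot Gaussian width (micrometres).
#' @slot spotAmplitude numeric(1), peak intensity of a spot.
#' @slot noiseSd numeric(1), additive Gaussian noise SD.
#' @export
setClass("PitFieldParams",
  representation(ratePerArea = "numeric", clusterMode = "character",
                 parentsPerArea = "numeric", offspringPerParent = "numeric",
                 clusterSigma = "numeric", spotSigma = "numeric",
                 spotAmplitude = "numeric", noiseSd = "numeric"))

setValidity("PitFieldParams", function(object) {
  need <- c("apical_basal", "radial", "circumferential")
  if (!all(need %in% names(object@ratePerArea)))
    return("ratePerArea must name apical_basal, radial and circumferential")
  if (any(object@ratePerArea < 0)) return("rates must be >= 0")
  if (!object@clusterMode %in% c("uniform", "thomas"))
    return("clusterMode must be 'uniform' or 'thomas'")
  if (object@clusterMode == "thomas" && object@offspringPerParent <= 0)
    return("offspringPerParent must be > 0 in thomas mode")
  if (object@clusterSigma < 0 || object@spotSigma < 0 ||
      object@spotAmplitude < 0 || object@noiseSd < 0)
    return("sigmas, amplitude and noise must be >= 0")
  TRUE
})

#' RootTruth: ground truth of a synthetic root
#'
#' Analytic ground truth emitted by the generator: the cell table (label,
#' layer, sector, axial segment, centroid, volume), the interface patch table
#' (cell pair, class, analytic area and the surface parametrisation used for
#' spot placement) and, after pit-field placement, the individual spot
#' positions.
#'
#' @slot cells data.frame of true cells.
#' @slot interfaces data.frame of true interface patches; one row per
#'   contiguous patch, several rows may share a cell pair.
#' @slot spots data.frame of placed marker spots (empty until
#'   \code{\link{placePitFields}} is run).
#' @slot geometry the \linkS4class{RootGeometry} that produced it.
#' @export
setClass("RootTruth",
  representation(cells = "data.frame", interfaces = "data.frame",
                 spots = "data.frame", geometry = "RootGeometry"))

#' SimulatedRoot: a complete synthetic sample
#'
#' Bundles the two image channels, the true segmentation and the ground
#' truth returned by \code{\link{simulateRoot}}.
#'
#' @slot wall \linkS4class{VoxelGrid}, cell-wall stain channel.
#' @slot pd \linkS4class{VoxelGrid}, plasmodesmata marker channel.
#' @slot labels \linkS4class{LabelVolume}, true segmentation.
#' @slot truth \linkS4class{RootTruth}.
#' @export
setClass("SimulatedRoot",
  representation(wall = "VoxelGrid", pd = "VoxelGrid",
                 labels = "LabelVolume", truth = "RootTruth"))
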