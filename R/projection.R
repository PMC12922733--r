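#' Project the marker channel onto the mesh
#'
#' For every vertex, the marker stack is sampled by trilinear interpolation
#' at evenly spaced positions along the vertex normal within plus/minus
#' \code{bandHalfwidth}; the sampling step never exceeds half the smallest
#' voxel edge. The per-vertex value is the maximum over the band by
#' default, which is robust to the exact wall offset of the punctate
#' pit-field signal; \code{aggregate = "mean"} averages instead. Vertices
#' lying outside the stack sample as 0 and are counted in
#' \code{nOutOfBounds}. Projection is monotone in the stack: scaling the
#' stack by c > 0 scales raw intensities by c.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param pdStack the marker channel, a \linkS4class{VoxelGrid} sharing the
#'   mesh coordinate frame.
#' @param bandHalfwidth projection distance on either side of the surface,
#'   micrometres (default 0.5).
#' @param aggregate "max" (default) or "mean" within the band.
#' @return a \linkS4class{VertexSignal} with raw intensities (trimmed and
#'   binary initialised to the raw values and their positivity).
#' @export
projectSignal <- function(mesh, pdStack, bandHalfwidth = 0.5,
                          aggregate = c("max", "mean")) {
  stopifnot(is(mesh, "SurfaceMesh"), is(pdStack, "VoxelGrid"),
            bandHalfwidth > 0)
  aggregate <- match.arg(aggregate)
  nrm <- vertexNormals(mesh)
  step <- min(pdStack@voxelSize) / 2
  res <- cpp_sample_normal(pdStack@values, dim(pdStack@values),
                           pdStack@voxelSize, pdStack@origin,
                           mesh@vertices, nrm, bandHalfwidth, step,
                           aggregate == "max")
  raw <- as.numeric(res$value)
  new("VertexSignal", raw = raw, trimmed = raw,
      binary = as.numeric(raw > 0), maxValue = 1,
      nOutOfBounds = as.integer(res$n_out_of_bounds))
}

#' Depth-compensated background trim
#'
#' Removes background by thresholding the projected intensity, with the
#' threshold decaying geometrically into the inner cell layers to
#' compensate photobleaching and depth attenuation: a vertex of layer index
#' l keeps its value only if it exceeds \code{baseTrim * layerDecay^l}.
#' Vertices without a layer annotation use the layer-0 threshold (with a
#' warning).
#'
#' @param signal a \linkS4class{VertexSignal}.
#' @param vertexLayers integer layer index per vertex (0 = outermost), e.g.
#'   from \code{\link{vertexLayerIndex}}; NA allowed.
#' @param baseTrim threshold at layer 0. Defaults to the 97.5th percentile
#'   of the raw projected intensities ("low trim" for sparse signal).
#' @param layerDecay multiplicative decay per layer inward, in (0, 1].
#' @return the signal with \code{trimmed} and \code{binary} updated.
#' @export
trimBackground <- function(signal, vertexLayers = NULL, baseTrim = NULL,
                           layerDecay = 0.8) {
  stopifnot(is(signal, "VertexSignal"), layerDecay > 0, layerDecay <= 1)
  n <- length(signal@raw)
  if (is.null(vertexLayers)) vertexLayers <- rep(0L, n)
  stopifnot(length(vertexLayers) == n)
  if (anyNA(vertexLayers)) {
    warning(sum(is.na(vertexLayers)),
            " vertices without layer annotation; using the layer-0 trim")
    vertexLayers[is.na(vertexLayers)] <- 0L
  }
  if (is.null(baseTrim))
    baseTrim <- stats::quantile(signal@raw, 0.975, names = FALSE)
  if (baseTrim < 0) stop("baseTrim must be >= 0")
  thr <- baseTrim * layerDecay^vertexLayers
  trimmed <- ifelse(signal@raw > thr, signal@raw, 0)
  initialize(signal, trimmed = trimmed,
             binary = as.numeric(trimmed > 0) * signal@maxValue)
}

#' Binarize the trimmed signal
#'
#' Sets every vertex with positive trimmed intensity to \code{maxValue} and
#' all others to 0 (idempotent), defining where pit-field signal is present
#' or absent.
#'
#' @param signal a \linkS4class{VertexSignal}.
#' @param maxValue value assigned to positive vertices (default 1).
#' @return the signal with \code{binary} (and \code{maxValue}) updated.
#' @export
binarizeSignal <- function(signal, maxValue = 1) {
  stopifnot(is(signal, "VertexSignal"), maxValue > 0)
  initialize(signal, binary = as.numeric(signal@trimmed > 0) * maxValue,
             maxValue = maxValue)
}

#' Layer index of each mesh vertex
#'
#' A vertex inherits the layer of the deepest (largest layer index) cell
#' among the interfaces it belongs to, so the background trim decays with
#' the depth of the wall it sits on. Vertices only touching interfaces of
#' unannotated cells get NA.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param cells annotated cell table from \code{\link{assignCellLayers}}.
#' @return integer vector, one layer index per vertex (NA possible).
#' @export
vertexLayerIndex <- function(mesh, cells) {
  stopifnot(is(mesh, "SurfaceMesh"), "layer_index" %in% names(cells))
  tab <- mesh@interfaces
  li <- function(lbl) cells$layer_index[match(lbl, cells$label)]
  ifLayer <- pmax(li(tab$cell_a),
                  ifelse(tab$cell_b == 0, -Inf, li(tab$cell_b)), na.rm = TRUE)
  ifLayer[!is.finite(ifLayer)] <- NA
  vi <- data.frame(v = as.vector(mesh@triangles),
                   l = ifLayer[rep(mesh@triInterface, 3)])
  nv <- nrow(mesh@vertices)
  out <- rep(NA_real_, nv)
  agg <- tapply(vi$l, vi$v, function(x)
    if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE))
  out[as.integer(names(agg))] <- unname(agg)
  as.integer(out)
}
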