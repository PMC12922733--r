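#' Moran's I spatial autocorrelation on a graph
#'
#' Computes \deqn{I = \frac{N}{W} \frac{\sum_{ij} w_{ij} (x_i - \bar x)(x_j
#' - \bar x)}{\sum_i (x_i - \bar x)^2}}{I = (N/W) sum_ij w_ij (x_i - xbar)
#' (x_j - xbar) / sum_i (x_i - xbar)^2} with unweighted symmetric binary
#' adjacency given as an undirected edge list (each edge once; it counts
#' twice in W). On an even checkerboard with rook adjacency I is exactly
#' -1; a half-and-half segregated two-block pattern approaches +1 as the
#' grid grows. Values with zero variance have no defined I: the function
#' returns NA with attribute \code{reason = "no variance"}.
#'
#' @param x numeric values, one per node.
#' @param edges two-column integer matrix of undirected edges (1-based node
#'   indices, no self loops).
#' @return Moran's I, or NA (reason attribute) for constant x.
#' @examples
#' cb <- outer(1:4, 1:4, "+") %% 2   # 4 x 4 checkerboard
#' moransI(as.vector(cb), gridRookEdges(4, 4))  # exactly -1
#' @export
moransI <- function(x, edges) {
  n <- length(x)
  if (n < 2) stop("need at least 2 nodes")
  edges <- rbind(edges)
  if (nrow(edges) == 0) stop("need at least one edge")
  if (any(edges < 1 | edges > n)) stop("edge index out of range")
  if (any(edges[, 1] == edges[, 2])) stop("self loops not allowed")
  d <- x - mean(x)
  den <- sum(d^2)
  if (den == 0) {
    out <- NA_real_
    attr(out, "reason") <- "no variance"
    return(out)
  }
  W <- 2 * nrow(edges)
  num <- 2 * sum(d[edges[, 1]] * d[edges[, 2]])
  ## single division keeps integer-valued anchors (checkerboard = -1) exact
  (n * num) / (W * den)
}

#' Rook-adjacency edges of a rectangular grid
#'
#' Edge list of the 4-neighbour (edge-sharing) adjacency graph of an
#' \code{nr x nc} grid, nodes numbered column-major.
#'
#' @param nr,nc grid dimensions.
#' @return two-column integer matrix of undirected edges.
#' @export
gridRookEdges <- function(nr, nc) {
  id <- function(i, j) (j - 1L) * nr + i
  horiz <- cbind(as.vector(outer(1:nr, 1:(nc - 1), id)),
                 as.vector(outer(1:nr, 2:nc, id)))
  vert <- cbind(as.vector(outer(1:(nr - 1), 1:nc, id)),
                as.vector(outer(2:nr, 1:nc, id)))
  rbind(horiz, vert)
}

#' Total Signal of an interface
#'
#' The binary pit-field signal integrated over the patch: each vertex
#' contributes its binary value times its patch vertex area (one third of
#' the incident triangle areas), so with \code{maxValue = 1} Total Signal
#' is the signal-covered area in square micrometres.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param signal a \linkS4class{VertexSignal} on that mesh.
#' @param interfaceId interface id(s); default all.
#' @return named numeric vector of Total Signal per interface.
#' @export
totalSignal <- function(mesh, signal,
                        interfaceId = mesh@interfaces$interface_id) {
  stopifnot(is(mesh, "SurfaceMesh"), is(signal, "VertexSignal"),
            length(signal@binary) == nrow(mesh@vertices))
  if (length(interfaceId) == 0) return(numeric(0))
  if (any(!interfaceId %in% mesh@triInterface)) stop("empty interface patch")
  areas <- .triangleAreas(mesh)
  b <- signal@binary
  tr <- mesh@triangles
  contrib <- areas / 3 * (b[tr[, 1]] + b[tr[, 2]] + b[tr[, 3]])
  s <- rowsum(contrib, mesh@triInterface, reorder = TRUE)
  out <- s[match(interfaceId, as.integer(rownames(s))), 1]
  names(out) <- interfaceId
  out
}

#' Signal Density
#'
#' Total Signal divided by interface area. Dimensionless (coverage
#' fraction) when the signal is binarized with \code{maxValue = 1}.
#'
#' @param S Total Signal value(s).
#' @param A interface area(s), square micrometres, > 0.
#' @return S / A.
#' @export
signalDensity <- function(S, A) {
  if (any(A <= 0)) stop("interface area must be > 0")
  S / A
}

#' Normalize interface measurements to sample percentages
#'
#' Divides each interface's Total Signal (and Signal Density) by the sum
#' over all retained interfaces of the sample and expresses the result as
#' a percentage, so the values over a sample add to 100. This removes
#' between-sample differences in expression level and imaging settings.
#'
#' @param quants data.frame with columns \code{total_signal} and
#'   \code{signal_density} (retained, cell-cell interfaces of one sample).
#' @return the data.frame with \code{pct_total_signal} and
#'   \code{pct_signal_density} added.
#' @export
normalizeSample <- function(quants) {
  stopifnot(is.data.frame(quants),
            all(c("total_signal", "signal_density") %in% names(quants)))
  sS <- sum(quants$total_signal)
  if (sS == 0) stop("no signal in sample")
  sD <- sum(quants$signal_density)
  quants$pct_total_signal <- 100 * quants$total_signal / sS
  quants$pct_signal_density <- 100 * quants$signal_density / sD
  quants
}

#' Moran's I of the binary signal on each interface patch
#'
#' Runs \code{\link{moransI}} on the binarized per-vertex signal of each
#' requested interface, with adjacency = the patch's mesh edges. Use a fine
#' mesh (cube size 0.2) for this statistic. Patches whose binary signal has
#' no variance (all 0 or all 1) return NA.
#'
#' @param mesh a \linkS4class{SurfaceMesh} (fine mesh recommended).
#' @param signal a \linkS4class{VertexSignal} on that mesh.
#' @param interfaceId interface id(s); default all.
#' @return named numeric vector (NA where undefined).
#' @export
moransIInterfaces <- function(mesh, signal,
                              interfaceId = mesh@interfaces$interface_id) {
  stopifnot(is(mesh, "SurfaceMesh"), is(signal, "VertexSignal"),
            length(signal@binary) == nrow(mesh@vertices))
  triAreas <- .triangleAreas(mesh)
  bySlice <- split(seq_along(mesh@triInterface), mesh@triInterface)
  out <- vapply(interfaceId, function(i) {
    rows <- bySlice[[as.character(i)]]
    if (is.null(rows)) return(NA_real_)
    tris <- mesh@triangles[rows, , drop = FALSE]
    verts <- sort(unique(as.vector(tris)))
    if (length(verts) < 2) return(NA_real_)
    local <- matrix(match(tris, verts), nrow = nrow(tris))
    edges <- .meshEdges(local)
    if (nrow(edges) == 0) return(NA_real_)
    as.numeric(moransI(signal@binary[verts], edges))
  }, 0)
  names(out) <- interfaceId
  out
}

#' Quantify one sample: Total Signal, Signal Density, percentages, Moran's I
#'
#' The full per-interface quantification: abundance metrics are measured on
#' the coarse mesh, the spatial statistic on the fine mesh, and results are
#' joined by cell pair with the orientation and interaction annotations.
#' Exterior interfaces and interfaces smaller than \code{minArea} are
#' excluded before normalization.
#'
#' @param meshCoarse annotated coarse mesh (areas, Total Signal).
#' @param meshFine fine mesh on the same label volume (Moran's I); NULL
#'   skips the spatial statistic.
#' @param signalCoarse,signalFine binarized \linkS4class{VertexSignal}s on
#'   the two meshes.
#' @param minArea interface area filter in square micrometres (default 3).
#' @return data.frame, one row per retained interface: cell pair, classes,
#'   \code{area_um2}, \code{total_signal}, \code{signal_density},
#'   \code{pct_total_signal}, \code{pct_signal_density}, \code{morans_I},
#'   \code{n_vertices}.
#' @export
quantifyInterfaces <- function(meshCoarse, signalCoarse, meshFine = NULL,
                               signalFine = NULL, minArea = 3) {
  stopifnot(is(meshCoarse, "SurfaceMesh"))
  tab <- extractInterfaces(meshCoarse)
  keep <- filterInterfaces(tab, minArea = minArea, dropExterior = TRUE)
  if (nrow(keep) == 0) stop("no retained interfaces")
  S <- totalSignal(meshCoarse, signalCoarse, keep$interface_id)
  out <- data.frame(
    cell_a = keep$cell_a, cell_b = keep$cell_b,
    orientation_class = keep$orientation_class,
    interaction_class = keep$interaction_class,
    area_um2 = keep$area_um2,
    total_signal = as.numeric(S),
    n_vertices = keep$n_vertices)
  out$signal_density <- signalDensity(out$total_signal, out$area_um2)
  out <- normalizeSample(out)
  out$morans_I <- NA_real_
  if (!is.null(meshFine)) {
    stopifnot(is(meshFine, "SurfaceMesh"), !is.null(signalFine))
    fineTab <- meshFine@interfaces
    keyC <- paste(out$cell_a, out$cell_b)
    keyF <- paste(fineTab$cell_a, fineTab$cell_b)
    m <- match(keyC, keyF)
    ok <- !is.na(m)
    if (any(ok)) {
      mi <- moransIInterfaces(meshFine, signalFine,
                              fineTab$interface_id[m[ok]])
      out$morans_I[ok] <- as.numeric(mi)
    }
  }
  out
}

#' Run the complete pipeline on a segmented sample
#'
#' From a label volume and a marker channel to the per-interface
#' quantification table: builds the coarse and fine meshes, annotates
#' layers and interface classes, projects / trims / binarizes the marker
#' signal on both meshes and calls \code{\link{quantifyInterfaces}}.
#'
#' @param labels a \linkS4class{LabelVolume} (from
#'   \code{\link{segmentCells}} or a generator truth).
#' @param pdStack the marker channel, a \linkS4class{VoxelGrid}.
#' @param layerNames layer names outermost first.
#' @param cubeSizeCoarse,cubeSizeFine mesh sampling steps, micrometres.
#' @param smoothPasses mesh smoothing passes.
#' @param bandHalfwidth projection distance, micrometres.
#' @param baseTrim background trim threshold; NULL = 97.5th percentile of
#'   the projected signal.
#' @param layerDecay trim decay per layer inward.
#' @param minArea interface area filter, square micrometres.
#' @param innerCore see \code{\link{assignCellLayers}}.
#' @param withMoransI compute Moran's I on the fine mesh (slower).
#' @return see \code{\link{quantifyInterfaces}}.
#' @export
quantifySample <- function(labels, pdStack,
                           layerNames = c("epidermis", "cortex",
                                          "endodermis"),
                           cubeSizeCoarse = 0.5, cubeSizeFine = 0.2,
                           smoothPasses = 10, bandHalfwidth = 0.5,
                           baseTrim = NULL, layerDecay = 0.8, minArea = 3,
                           innerCore = FALSE, withMoransI = TRUE) {
  if (is.null(baseTrim))  # low trim: the marker is sparse in the stack
    baseTrim <- stats::quantile(pdStack@values, 0.975, names = FALSE)
  meshC <- buildInterfaceMesh(labels, cubeSizeCoarse, smoothPasses)
  ann <- annotateSample(labels, meshC, layerNames, innerCore = innerCore)
  meshC <- ann$mesh
  prep <- function(mesh) {
    sig <- projectSignal(mesh, pdStack, bandHalfwidth)
    sig <- trimBackground(sig, vertexLayerIndex(mesh, ann$cells),
                          baseTrim = baseTrim, layerDecay = layerDecay)
    binarizeSignal(sig)
  }
  sigC <- prep(meshC)
  meshF <- NULL; sigF <- NULL
  if (withMoransI) {
    meshF <- buildInterfaceMesh(labels, cubeSizeFine, smoothPasses)
    sigF <- prep(meshF)
  }
  quantifyInterfaces(meshC, sigC, meshF, sigF, minArea = minArea)
}
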