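## Surface extraction. Cell surfaces are extracted as the boundary-face
## (cuberille) surface of the label grid at native voxel resolution: every
## lattice face between two voxels carrying different labels becomes two
## triangles. This dual construction gives each cell-cell interface a
## single shared triangle patch (used by both cells), an exact partition of
## every cell surface into its interfaces, and a mesh-edge graph on which
## spatial statistics run. The surface is then resampled to the requested
## cube size by vertex clustering (cluster representative = mean member
## position, which restores sub-voxel boundary placement), and the
## staircase geometry relaxed by constrained uniform Laplacian smoothing.

#' Build the interface mesh of a label volume
#'
#' Extracts the full boundary surface of a segmentation, resamples it to
#' sampling step \code{cubeSize}, and partitions it into cell-cell and
#' cell-exterior interface patches. The raw surface follows the voxel
#' faces; vertex clustering on the \code{cubeSize} lattice then coarsens it
#' (cluster positions average their member vertices, recovering sub-voxel
#' boundary placement), and the requested number of uniform-neighbourhood
#' smoothing passes relaxes the residual staircase while preserving
#' cellular connectivity: vertices interior to a patch average over all
#' their neighbours, vertices on a junction line between patches average
#' only along vertices of the same junction, and corner points (with no
#' same-junction neighbour) stay fixed.
#'
#' Triangle winding is oriented so normals point from \code{cell_a} toward
#' \code{cell_b} (and outward for exterior patches, \code{cell_b = 0}).
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param cubeSize sampling step in micrometres (0.5 for abundance
#'   analyses, 0.2 for spatial statistics); NULL keeps the native voxel
#'   resolution.
#' @param smoothPasses number of smoothing passes (default 10); passes
#'   alternate a positive and a slightly larger negative relaxation step
#'   (Taubin-style), so smoothing flattens the staircase without shrinking
#'   closed surfaces.
#' @param relax positive relaxation step size in (0, 1].
#' @return a \linkS4class{SurfaceMesh}.
#' @export
buildInterfaceMesh <- function(labels, cubeSize = 0.5, smoothPasses = 10,
                               relax = 0.5) {
  stopifnot(is(labels, "LabelVolume"))
  if (max(labels@labels) == 0) stop("empty label volume")
  lab <- labels@labels
  h <- labels@voxelSize
  ## the face lattice must oversample the requested cube size so that
  ## vertex clustering can average boundary positions to sub-step
  ## accuracy; when the voxels are not at least twice as fine as the cube
  ## size, resample the labels to a cubeSize/2 lattice first
  if (!is.null(cubeSize) && cubeSize < 2 * min(h)) {
    e <- cubeSize / 2
    nd <- dim(lab)
    extent <- nd * h
    ndNew <- pmax(2L, as.integer(floor(extent / e + 1e-9)))
    idx <- lapply(1:3, function(a) {
      centres <- (seq_len(ndNew[a]) - 0.5) * e
      pmin(nd[a], pmax(1L, as.integer(floor(centres / h[a]) + 1L)))
    })
    lab <- lab[idx[[1]], idx[[2]], idx[[3]]]
    h <- rep(e, 3)
  }
  nd <- dim(lab)
  Q <- array(0L, nd + 2L)
  Q[1L + seq_len(nd[1]), 1L + seq_len(nd[2]), 1L + seq_len(nd[3])] <- lab

  cornersAll <- vector("list", 3)
  pairAll <- vector("list", 3)
  flipAll <- vector("list", 3)
  nxc <- nd[1] + 1L; nyc <- nd[2] + 1L  # corner lattice dims (x, y)
  cornerId <- function(x, y, z) x + nxc * (y + nyc * z) + 1
  for (axis in 1:3) {
    da <- nd; da[axis] <- da[axis] + 1L
    iA <- lapply(1:3, function(a)
      if (a == axis) seq_len(da[a]) else 1L + seq_len(nd[a]))
    iB <- iA; iB[[axis]] <- iA[[axis]] + 1L
    A <- Q[iA[[1]], iA[[2]], iA[[3]]]
    B <- Q[iB[[1]], iB[[2]], iB[[3]]]
    d <- which(A != B)
    if (length(d) == 0) next
    la <- A[d]; lb <- B[d]
    i1 <- (d - 1L) %% da[1]
    i2 <- ((d - 1L) %/% da[1]) %% da[2]
    i3 <- (d - 1L) %/% (da[1] * da[2])
    ## plane index along `axis` is 0-based already (i - 1 + 1 - 1); the
    ## in-plane indices are 1-based voxel indices
    if (axis == 1) {
      p <- i1; j <- i2 + 1L; k <- i3 + 1L
      cs <- cbind(cornerId(p, j - 1, k - 1), cornerId(p, j, k - 1),
                  cornerId(p, j, k), cornerId(p, j - 1, k))
    } else if (axis == 2) {
      i <- i1 + 1L; p <- i2; k <- i3 + 1L
      cs <- cbind(cornerId(i - 1, p, k - 1), cornerId(i - 1, p, k),
                  cornerId(i, p, k), cornerId(i, p, k - 1))
    } else {
      i <- i1 + 1L; j <- i2 + 1L; p <- i3
      cs <- cbind(cornerId(i - 1, j - 1, p), cornerId(i, j - 1, p),
                  cornerId(i, j, p), cornerId(i - 1, j, p))
    }
    extA <- la == 0L
    cellA <- ifelse(extA, lb, ifelse(lb == 0L, la, pmin(la, lb)))
    cellB <- ifelse(extA | lb == 0L, 0L, pmax(la, lb))
    ## normal must point cell_a -> cell_b: geometric normal is +axis (from
    ## the A side to the B side); flip when cell_a sits on the B side
    flip <- (extA) | (lb != 0L & la != 0L & lb < la)
    cornersAll[[axis]] <- cs
    pairAll[[axis]] <- cbind(cellA, cellB)
    flipAll[[axis]] <- flip
  }
  corners <- do.call(rbind, cornersAll)
  pairs <- do.call(rbind, pairAll)
  flip <- unlist(flipAll)
  if (is.null(corners)) stop("label volume has no boundary surface")

  key <- paste(pairs[, 1], pairs[, 2])
  ifFac <- factor(key, levels = unique(key))
  ifPairs <- do.call(rbind, strsplit(levels(ifFac), " "))
  interfaces <- data.frame(
    interface_id = seq_len(nlevels(ifFac)),
    cell_a = as.integer(ifPairs[, 1]), cell_b = as.integer(ifPairs[, 2]))
  faceIf <- as.integer(ifFac)

  uid <- sort(unique(as.vector(corners)))
  vidx <- matrix(match(corners, uid), nrow = nrow(corners))
  x <- (uid - 1) %% nxc
  y <- ((uid - 1) %/% nxc) %% nyc
  z <- (uid - 1) %/% (nxc * nyc)
  verts <- cbind(x * h[1], y * h[2], z * h[3])
  verts <- sweep(verts, 2, labels@origin, "+")

  nf <- nrow(vidx)
  tri <- matrix(0L, 2L * nf, 3L)
  fwd <- !flip
  tri[seq_len(nf) * 2L - 1L, ] <- cbind(vidx[, 1],
                                        ifelse(fwd, vidx[, 2], vidx[, 3]),
                                        ifelse(fwd, vidx[, 3], vidx[, 2]))
  tri[seq_len(nf) * 2L, ] <- cbind(vidx[, 1],
                                   ifelse(fwd, vidx[, 3], vidx[, 4]),
                                   ifelse(fwd, vidx[, 4], vidx[, 3]))
  triIf <- integer(2L * nf)
  triIf[seq_len(nf) * 2L - 1L] <- faceIf
  triIf[seq_len(nf) * 2L] <- faceIf

  if (!is.null(cubeSize) && any(cubeSize > h)) {
    cl <- .clusterVertices(verts, tri, triIf, labels@origin, cubeSize)
    verts <- cl$verts; tri <- cl$tri; triIf <- cl$triIf
  }

  mesh <- new("SurfaceMesh", vertices = verts,
              triangles = tri, triInterface = triIf,
              interfaces = interfaces,
              cubeSize = if (is.null(cubeSize)) min(h) else cubeSize,
              smoothPasses = as.integer(smoothPasses))
  if (smoothPasses > 0)
    mesh <- .smoothMesh(mesh, smoothPasses, relax)
  ar <- rowsum(.triangleAreas(mesh), mesh@triInterface, reorder = TRUE)
  areaVec <- numeric(nrow(interfaces))
  areaVec[as.integer(rownames(ar))] <- ar[, 1]
  mesh@interfaces$area_um2 <- areaVec
  mesh@interfaces$orientation_class <- NA_character_
  mesh@interfaces$interaction_class <- NA_character_
  validObject(mesh)
  mesh
}

## decimate by clustering vertices on a cube-size lattice; the cluster
## representative is the mean member position. Clustering is patch-aware:
## vertices merge only with vertices belonging to the same set of
## interfaces, so patch-interior vertices average onto their surface and
## junction-line vertices average along the junction, keeping patch
## borders sub-voxel accurate. Triangles collapsing inside one or two
## clusters vanish; coincident survivors (same cluster triple and
## interface) are kept once.
.clusterVertices <- function(verts, tri, triIf, origin, cube) {
  rel <- sweep(verts, 2, origin, "-")
  k <- floor(rel / cube + 1e-7)
  k1 <- k[, 1] - min(k[, 1]); k2 <- k[, 2] - min(k[, 2])
  k3 <- k[, 3] - min(k[, 3])
  code <- k1 + (max(k1) + 1) * (k2 + (max(k2) + 1) * k3)
  vik <- .vertexInterfaceKeys(list(triangles = tri, triInterface = triIf,
                                   nVertices = nrow(verts)))
  code <- paste(code, vik$key)
  fac <- match(code, unique(code))
  cnt <- tabulate(fac)
  reps <- rowsum(verts, fac, reorder = TRUE) / cnt
  t2 <- matrix(fac[tri], ncol = 3)
  keep <- t2[, 1] != t2[, 2] & t2[, 2] != t2[, 3] & t2[, 1] != t2[, 3]
  t2 <- t2[keep, , drop = FALSE]
  triIf <- triIf[keep]
  lo <- pmin(t2[, 1], t2[, 2], t2[, 3])
  hi <- pmax(t2[, 1], t2[, 2], t2[, 3])
  mid <- t2[, 1] + t2[, 2] + t2[, 3] - lo - hi
  dup <- duplicated(paste(lo, mid, hi, triIf))
  list(verts = unname(as.matrix(reps)), tri = t2[!dup, , drop = FALSE],
       triIf = triIf[!dup])
}

.triangleAreas <- function(mesh) {
  v <- mesh@vertices
  t1 <- mesh@triangles[, 1]; t2 <- mesh@triangles[, 2]
  t3 <- mesh@triangles[, 3]
  e1 <- v[t2, , drop = FALSE] - v[t1, , drop = FALSE]
  e2 <- v[t3, , drop = FALSE] - v[t1, , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

## oriented triangle normal vectors scaled by area (cross / 2)
.triangleNormalsArea <- function(mesh) {
  v <- mesh@vertices
  t1 <- mesh@triangles[, 1]; t2 <- mesh@triangles[, 2]
  t3 <- mesh@triangles[, 3]
  e1 <- v[t2, , drop = FALSE] - v[t1, , drop = FALSE]
  e2 <- v[t3, , drop = FALSE] - v[t1, , drop = FALSE]
  0.5 * cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

## undirected unique mesh edges (m x 2, col1 < col2)
.meshEdges <- function(triangles) {
  e <- rbind(triangles[, 1:2], triangles[, 2:3], triangles[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

## per-vertex incidence key over interfaces; returns list(nIf, key)
.vertexInterfaceKeys <- function(mesh) {
  nv <- if (is.list(mesh) && !is.null(mesh$nVertices)) mesh$nVertices
    else nrow(mesh@vertices)
  tri <- if (is.list(mesh)) mesh$triangles else mesh@triangles
  tif <- if (is.list(mesh)) mesh$triInterface else mesh@triInterface
  ## encode (vertex, interface) pairs numerically for a fast unique()
  pair <- as.double(as.vector(tri)) + as.double(nv + 1) * rep(as.double(tif), 3)
  pair <- unique(pair)
  v <- as.integer(pair %% (nv + 1))
  f <- as.integer(pair %/% (nv + 1))
  nIf <- tabulate(v, nbins = nv)
  ord <- order(v, f)
  keys <- rep("", nv)
  agg <- tapply(f[ord], v[ord], paste, collapse = ",")
  keys[as.integer(names(agg))] <- unname(agg)
  list(nIf = nIf, key = keys)
}

.smoothMesh <- function(mesh, passes, relax) {
  v <- mesh@vertices
  nv <- nrow(v)
  edges <- .meshEdges(mesh@triangles)
  vik <- .vertexInterfaceKeys(mesh)
  ## directed edges src -> tgt, both directions
  src <- c(edges[, 1], edges[, 2])
  tgt <- c(edges[, 2], edges[, 1])
  ## patch-interior vertices average over all neighbours; junction-line
  ## vertices (>= 2 patches) only along vertices of the same junction, so
  ## patch borders relax along themselves and true corner points (no
  ## same-junction neighbour) stay fixed
  tgtFree <- vik$nIf[tgt] == 1L
  allowed <- tgtFree | vik$key[src] == vik$key[tgt]
  src <- src[allowed]; tgt <- tgt[allowed]
  cnt <- tabulate(tgt, nbins = nv)
  ## Taubin shrink-free smoothing: each pass takes a positive step toward
  ## the neighbourhood mean followed by a slightly larger negative step,
  ## damping the voxel staircase without contracting closed surfaces
  for (step in rep(c(relax, -(relax + 0.03)), passes)) {
    acc <- rowsum(v[src, , drop = FALSE], tgt, reorder = TRUE)
    ids <- as.integer(rownames(acc))
    mean_ <- acc / cnt[ids]
    v[ids, ] <- v[ids, , drop = FALSE] +
      step * (mean_ - v[ids, , drop = FALSE])
  }
  mesh@vertices <- v
  mesh
}

#' Interface table of a mesh
#'
#' One row per interface patch with the owning cell pair (cell_b = 0 for
#' the exterior), the summed triangle area, triangle/vertex counts, and the
#' orientation and interaction classes once annotated.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return data.frame.
#' @export
extractInterfaces <- function(mesh) {
  stopifnot(is(mesh, "SurfaceMesh"))
  tab <- mesh@interfaces
  nvert <- vapply(seq_len(nrow(tab)), function(i)
    length(unique(as.vector(
      mesh@triangles[mesh@triInterface == i, , drop = FALSE]))), 0L)
  tab$n_triangles <- tabulate(mesh@triInterface, nbins = nrow(tab))
  tab$n_vertices <- nvert
  tab
}

#' Filter interfaces by area
#'
#' Retains interfaces whose area is at least \code{minArea} (boundary
#' included: an interface of exactly \code{minArea} is kept, matching the
#' rule that interfaces smaller than the threshold are removed).
#'
#' @param interfaces a data.frame with an \code{area_um2} column (e.g. from
#'   \code{\link{extractInterfaces}}).
#' @param minArea threshold in square micrometres (default 3).
#' @param dropExterior also drop cell-exterior rows (\code{cell_b == 0}).
#' @return the filtered data.frame.
#' @export
filterInterfaces <- function(interfaces, minArea = 3, dropExterior = FALSE) {
  stopifnot(is.data.frame(interfaces), "area_um2" %in% names(interfaces))
  out <- interfaces[interfaces$area_um2 >= minArea, , drop = FALSE]
  if (dropExterior) out <- out[out$cell_b != 0, , drop = FALSE]
  out
}

#' Total mesh area of each cell
#'
#' Sums the areas of all interface patches a cell participates in; because
#' the patches partition each cell's surface, this is the cell's total
#' surface area.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return named numeric vector, one entry per cell label.
#' @export
cellMeshArea <- function(mesh) {
  tab <- mesh@interfaces
  cells <- sort(unique(c(tab$cell_a, tab$cell_b)))
  cells <- cells[cells > 0]
  out <- vapply(cells, function(cl)
    sum(tab$area_um2[tab$cell_a == cl | tab$cell_b == cl]), 0)
  names(out) <- cells
  out
}

## triangles / vertices / per-vertex areas / edges restricted to one patch;
## pass precomputed whole-mesh triangle areas when calling in a loop
.patchData <- function(mesh, interfaceId, triAreas = .triangleAreas(mesh)) {
  sel <- mesh@triInterface == interfaceId
  tris <- mesh@triangles[sel, , drop = FALSE]
  if (nrow(tris) == 0) stop("empty interface patch")
  areas <- triAreas[sel]
  verts <- sort(unique(as.vector(tris)))
  local <- matrix(match(tris, verts), nrow = nrow(tris))
  va <- rowsum(rep(areas / 3, 3), as.vector(local),
               reorder = TRUE)[, 1]
  edges <- .meshEdges(local)
  list(vertexIds = verts, vertexAreas = va, edges = edges,
       triangles = local, triAreas = areas)
}

#' Per-vertex outward normals
#'
#' Area-weighted average of the oriented normals of the triangles incident
#' to each vertex (normals point from \code{cell_a} to \code{cell_b} of the
#' triangle's interface). Vertices with a degenerate (zero) normal get the
#' zero vector.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @return numeric matrix (n x 3) of unit normals.
#' @export
vertexNormals <- function(mesh) {
  stopifnot(is(mesh, "SurfaceMesh"))
  tn <- .triangleNormalsArea(mesh)
  nv <- nrow(mesh@vertices)
  acc <- matrix(0, nv, 3)
  for (c in 1:3) {
    s <- rowsum(rbind(tn, tn, tn)[, c],
                as.vector(mesh@triangles), reorder = TRUE)
    acc[as.integer(rownames(s)), c] <- s[, 1]
  }
  len <- sqrt(rowSums(acc^2))
  len[len == 0] <- 1
  acc / len
}
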