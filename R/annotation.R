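#' Estimate the root axis from a segmentation
#'
#' The organ axis is the first principal direction of the foreground voxel
#' coordinates through their centroid, oriented so the axial coordinate
#' increases toward higher z. A clearly elongated volume is required: the
#' ratio of the first to the second principal standard deviation must reach
#' \code{minAnisotropy}.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param minAnisotropy required sd ratio between the first two principal
#'   directions (default 1.5).
#' @param maxVoxels foreground voxels are subsampled (deterministically,
#'   evenly spaced) to at most this many before the PCA.
#' @return a \linkS4class{RootAxis}.
#' @export
estimateRootAxis <- function(labels, minAnisotropy = 1.5, maxVoxels = 2e5) {
  stopifnot(is(labels, "LabelVolume"))
  idx <- which(labels@labels > 0)
  if (length(idx) == 0) stop("empty label volume")
  if (length(idx) > maxVoxels)
    idx <- idx[seq(1, length(idx), length.out = maxVoxels)]
  nd <- dim(labels@labels)
  vs <- labels@voxelSize
  i1 <- (idx - 1) %% nd[1]
  i2 <- ((idx - 1) %/% nd[1]) %% nd[2]
  i3 <- (idx - 1) %/% (nd[1] * nd[2])
  pts <- cbind((i1 + 0.5) * vs[1], (i2 + 0.5) * vs[2], (i3 + 0.5) * vs[3])
  pts <- sweep(pts, 2, labels@origin, "+")
  pc <- stats::prcomp(pts, center = TRUE, scale. = FALSE)
  if (pc$sdev[1] / max(pc$sdev[2], .Machine$double.eps) < minAnisotropy)
    stop("no dominant axis: volume is not elongated (anisotropy ratio ",
         signif(pc$sdev[1] / pc$sdev[2], 3), " < ", minAnisotropy, ")")
  dir <- pc$rotation[, 1]
  if (dir[3] < 0 || (dir[3] == 0 && dir[1] < 0)) dir <- -dir
  new("RootAxis", axisPoint = colMeans(pts), axisDirection = unname(dir))
}

#' Cylindrical coordinates of points in a root-axis frame
#'
#' @param points numeric matrix (n x 3) of positions in micrometres.
#' @param axis a \linkS4class{RootAxis}.
#' @return data.frame with axial position \code{s}, radial distance
#'   \code{r} and azimuth \code{theta} (radians).
#' @export
cylindricalCoords <- function(points, axis) {
  stopifnot(is(axis, "RootAxis"))
  points <- rbind(points)
  rel <- sweep(points, 2, axis@axisPoint, "-")
  a <- axis@axisDirection
  s <- as.vector(rel %*% a)
  perp <- rel - outer(s, a)
  r <- sqrt(rowSums(perp^2))
  ## reference directions orthogonal to the axis for the azimuth
  ref <- if (abs(a[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * a) * a
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(a[2] * e1[3] - a[3] * e1[2], a[3] * e1[1] - a[1] * e1[3],
          a[1] * e1[2] - a[2] * e1[1])
  theta <- atan2(perp %*% e2, perp %*% e1)[, 1]
  data.frame(s = s, r = r, theta = theta)
}

#' Cell centroid and volume table of a segmentation
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @return data.frame with \code{label}, centroid coordinates in
#'   micrometres and \code{volume_um3}.
#' @export
cellTable <- function(labels) {
  stopifnot(is(labels, "LabelVolume"))
  lab <- labels@labels
  idx <- which(lab > 0)
  if (length(idx) == 0) stop("empty label volume")
  nd <- dim(lab)
  vs <- labels@voxelSize
  l <- lab[idx]
  i1 <- (idx - 1) %% nd[1]
  i2 <- ((idx - 1) %/% nd[1]) %% nd[2]
  i3 <- (idx - 1) %/% (nd[1] * nd[2])
  n <- tabulate(l)
  ids <- which(n > 0)
  cx <- rowsum((i1 + 0.5) * vs[1], l)[, 1] / n[ids] + labels@origin[1]
  cy <- rowsum((i2 + 0.5) * vs[2], l)[, 1] / n[ids] + labels@origin[2]
  cz <- rowsum((i3 + 0.5) * vs[3], l)[, 1] / n[ids] + labels@origin[3]
  data.frame(label = ids, centroid_x = unname(cx), centroid_y = unname(cy),
             centroid_z = unname(cz),
             volume_um3 = n[ids] * prod(vs))
}

#' Assign cells to radial layers
#'
#' Implements radial-coordinate cell typing: cell centroids are expressed
#' in the root-axis cylindrical frame, sorted by radial distance, and split
#' into bands at the largest gaps of the sorted radii (1-D gap clustering).
#' The outermost band receives \code{layerNames[1]} and so on inward; with
#' \code{innerCore = TRUE} one extra innermost band is split off and
#' labelled \code{"inner_core"} (excluded from named-class statistics).
#' Scaling all coordinates uniformly leaves the assignment unchanged.
#'
#' @param cells data.frame from \code{\link{cellTable}}.
#' @param axis a \linkS4class{RootAxis}.
#' @param layerNames layer names outermost first.
#' @param innerCore whether cells inner to the last named layer form a
#'   separate core band.
#' @return \code{cells} with added columns \code{s}, \code{r},
#'   \code{theta}, \code{layer_name}, \code{layer_index} (0 = outermost;
#'   NA for the core).
#' @export
assignCellLayers <- function(cells, axis, layerNames, innerCore = FALSE) {
  stopifnot(is.data.frame(cells), is(axis, "RootAxis"),
            length(layerNames) >= 1)
  nBands <- length(layerNames) + as.integer(innerCore)
  if (nrow(cells) < nBands)
    stop("fewer cells (", nrow(cells), ") than layers (", nBands, ")")
  cc <- cylindricalCoords(as.matrix(cells[, c("centroid_x", "centroid_y",
                                              "centroid_z")]), axis)
  cells$s <- cc$s; cells$r <- cc$r; cells$theta <- cc$theta
  ord <- order(cells$r, decreasing = TRUE)  # outermost first
  rs <- cells$r[ord]
  band <- integer(nrow(cells))
  if (nBands > 1) {
    gaps <- -diff(rs)  # rs decreasing, gaps positive
    cut <- sort(order(gaps, decreasing = TRUE)[seq_len(nBands - 1)])
    band[ord] <- findInterval(seq_along(rs) - 1, cut) # 0-based band index
  }
  names_ <- c(layerNames, if (innerCore) "inner_core")
  cells$layer_name <- names_[band + 1]
  cells$layer_index <- ifelse(cells$layer_name == "inner_core", NA_integer_,
                              band)
  cells
}

#' Classify interface orientation relative to the root axis
#'
#' For every interface patch, the area-weighted mean unit normal is
#' compared with the local cylindrical frame at the patch centroid: the
#' axial direction, the radial direction away from the axis, and their
#' cross product (circumferential). The class is the frame axis with the
#' largest absolute dot product; when the top two magnitudes differ by less
#' than \code{tieMargin} the interface is "unclassified" and excluded from
#' class-level statistics.
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param axis a \linkS4class{RootAxis}.
#' @param tieMargin minimum separation between the top two dot-product
#'   magnitudes (default 0.05).
#' @return the mesh with \code{orientation_class} filled in its interface
#'   table.
#' @export
classifyInterfaceOrientation <- function(mesh, axis, tieMargin = 0.05) {
  stopifnot(is(mesh, "SurfaceMesh"), is(axis, "RootAxis"))
  tn <- .triangleNormalsArea(mesh)
  areas <- .triangleAreas(mesh)
  v <- mesh@vertices
  cent <- (v[mesh@triangles[, 1], , drop = FALSE] +
             v[mesh@triangles[, 2], , drop = FALSE] +
             v[mesh@triangles[, 3], , drop = FALSE]) / 3
  nIf <- nrow(mesh@interfaces)
  sumN <- matrix(0, nIf, 3)
  sumC <- matrix(0, nIf, 3)
  sumA <- numeric(nIf)
  rs <- rowsum(tn, mesh@triInterface, reorder = TRUE)
  ids <- as.integer(rownames(rs))
  sumN[ids, ] <- rs
  sumC[ids, ] <- rowsum(cent * areas, mesh@triInterface, reorder = TRUE)
  sumA[ids] <- rowsum(areas, mesh@triInterface, reorder = TRUE)[, 1]
  a <- axis@axisDirection
  cls <- character(nIf)
  for (i in seq_len(nIf)) {
    ## degenerate (zero-area) patches cannot be oriented
    if (sumA[i] <= 0) { cls[i] <- "unclassified"; next }
    nhat <- sumN[i, ]
    nl <- sqrt(sum(nhat^2))
    centroid <- sumC[i, ] / sumA[i]
    rel <- centroid - axis@axisPoint
    rad <- rel - sum(rel * a) * a
    rl <- sqrt(sum(rad^2))
    if (nl < 1e-12 || rl < 1e-9) { cls[i] <- "unclassified"; next }
    nhat <- nhat / nl
    rhat <- rad / rl
    chat <- c(a[2] * rhat[3] - a[3] * rhat[2],
              a[3] * rhat[1] - a[1] * rhat[3],
              a[1] * rhat[2] - a[2] * rhat[1])
    dots <- abs(c(apical_basal = sum(nhat * a), radial = sum(nhat * rhat),
                  circumferential = sum(nhat * chat)))
    ord <- order(dots, decreasing = TRUE)
    cls[i] <- if (dots[ord[1]] - dots[ord[2]] < tieMargin) "unclassified"
      else names(dots)[ord[1]]
  }
  mesh@interfaces$orientation_class <- cls
  mesh
}

#' Name interface interaction classes from cell layers
#'
#' The interaction class of a cell-cell interface is the alphabetically
#' ordered pair of the two cells' layer names joined with an en dash
#' ("cortex–endodermis"); same-layer pairs collapse to the single layer
#' name ("epidermis"). Exterior interfaces are named "exterior".
#'
#' @param mesh a \linkS4class{SurfaceMesh}.
#' @param cells annotated cell table from \code{\link{assignCellLayers}}.
#' @return the mesh with \code{interaction_class} filled in.
#' @export
nameInteractionClass <- function(mesh, cells) {
  stopifnot(is(mesh, "SurfaceMesh"), "layer_name" %in% names(cells))
  layerOf <- function(lbl) {
    m <- match(lbl, cells$label)
    if (anyNA(m) && any(lbl[is.na(m)] != 0))
      stop("unannotated cell label(s): ",
           paste(setdiff(lbl[is.na(m)], 0), collapse = ", "))
    cells$layer_name[m]
  }
  tab <- mesh@interfaces
  la <- layerOf(tab$cell_a)
  lb <- ifelse(tab$cell_b == 0, NA, layerOf(tab$cell_b))
  cls <- ifelse(tab$cell_b == 0, "exterior",
                ifelse(la == lb, la,
                       paste(pmin(la, lb), pmax(la, lb), sep = "\u2013")))
  mesh@interfaces$interaction_class <- cls
  mesh
}

#' Annotate a sample: axis, layers, orientation and interaction classes
#'
#' Convenience wrapper running \code{\link{estimateRootAxis}},
#' \code{\link{cellTable}} + \code{\link{assignCellLayers}},
#' \code{\link{classifyInterfaceOrientation}} and
#' \code{\link{nameInteractionClass}}.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param mesh a \linkS4class{SurfaceMesh} built from \code{labels}.
#' @param layerNames layer names outermost first.
#' @param innerCore see \code{\link{assignCellLayers}}.
#' @return list with elements \code{mesh} (annotated), \code{cells},
#'   \code{axis}.
#' @export
annotateSample <- function(labels, mesh,
                           layerNames = c("epidermis", "cortex",
                                          "endodermis"),
                           innerCore = FALSE) {
  axis <- estimateRootAxis(labels)
  cells <- assignCellLayers(cellTable(labels), axis, layerNames,
                            innerCore = innerCore)
  mesh <- classifyInterfaceOrientation(mesh, axis)
  mesh <- nameInteractionClass(mesh, cells)
  list(mesh = mesh, cells = cells, axis = axis)
}
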