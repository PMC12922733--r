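#' Gaussian blur in physical units
#'
#' Separable 3D Gaussian smoothing with the kernel width expressed in
#' micrometres: the per-axis sigma in voxels is \code{radius / voxelSize},
#' so anisotropic voxels receive an isotropic physical blur. \code{radius =
#' 0} returns the input unchanged.
#'
#' @param stack a \linkS4class{VoxelGrid}.
#' @param radius Gaussian sigma in micrometres; must be >= 0.
#' @return a \linkS4class{VoxelGrid} of the same shape and metadata.
#' @export
gaussianBlur <- function(stack, radius = 0.5) {
  stopifnot(is(stack, "VoxelGrid"))
  if (radius < 0) stop("blur radius must be >= 0")
  if (radius == 0) return(stack)
  vals <- cpp_gauss_blur(stack@values, dim(stack@values),
                         radius / stack@voxelSize)
  new("VoxelGrid", values = vals, voxelSize = stack@voxelSize,
      origin = stack@origin)
}

#' Segmentation parameters
#'
#' @param blurRadius Gaussian blur sigma in micrometres applied to the wall
#'   channel before seeding and flooding.
#' @param seedQuantile intensity quantile of the blurred stack below which
#'   voxels are candidate seeds (cell interiors and the dark exterior).
#' @param minCellVoxels labels smaller than this voxel count are merged into
#'   their largest-contact neighbour after watershed.
#' @param minSeedVoxels seed components smaller than this are discarded
#'   (suppresses noise-induced minima); defaults to \code{minCellVoxels}.
#' @return a named list of validated parameters.
#' @export
segmentationParams <- function(blurRadius = 0.5, seedQuantile = 0.5,
                               minCellVoxels = 50,
                               minSeedVoxels = minCellVoxels) {
  stopifnot(blurRadius >= 0, seedQuantile > 0, seedQuantile < 1,
            minCellVoxels >= 0, minSeedVoxels >= 0)
  list(blurRadius = blurRadius, seedQuantile = seedQuantile,
       minCellVoxels = as.integer(minCellVoxels),
       minSeedVoxels = as.integer(minSeedVoxels))
}

## 6-neighbour contact counts between labels; returns data.frame(a, b, n)
## with a < b, 0 included for background contacts
.labelContacts <- function(lab) {
  nd <- dim(lab)
  pairs <- list()
  for (axis in 1:3) {
    idxA <- switch(axis,
      lab[-nd[1], , , drop = FALSE], lab[, -nd[2], , drop = FALSE],
      lab[, , -nd[3], drop = FALSE])
    idxB <- switch(axis,
      lab[-1, , , drop = FALSE], lab[, -1, , drop = FALSE],
      lab[, , -1, drop = FALSE])
    d <- which(idxA != idxB)
    if (length(d))
      pairs[[axis]] <- cbind(pmin(idxA[d], idxB[d]), pmax(idxA[d], idxB[d]))
  }
  if (length(pairs) == 0)
    return(data.frame(a = integer(), b = integer(), n = integer()))
  m <- do.call(rbind, pairs)
  key <- paste(m[, 1], m[, 2])
  tab <- table(key)
  ab <- do.call(rbind, strsplit(names(tab), " "))
  data.frame(a = as.integer(ab[, 1]), b = as.integer(ab[, 2]),
             n = as.integer(tab))
}

#' Segment cells by automatically seeded 3D watershed
#'
#' Seeds are the connected components of voxels whose blurred wall intensity
#' lies below the \code{seedQuantile} intensity quantile (cell interiors and
#' the mountant outside the root). Components touching the stack border are
#' treated as exterior background; the remaining seeds flood the
#' wall-intensity landscape by a Meyer-style watershed, so label boundaries
#' settle on the bright wall ridges. Background ends up 0 and cell labels
#' are relabelled consecutively from 1.
#'
#' @param blurred the blurred wall channel (walls bright, interiors dark),
#'   a \linkS4class{VoxelGrid}; apply \code{\link{gaussianBlur}} first or
#'   use \code{\link{segmentCells}}.
#' @param params a list from \code{\link{segmentationParams}}.
#' @return a \linkS4class{LabelVolume}.
#' @export
autoseededWatershed <- function(blurred, params = segmentationParams()) {
  stopifnot(is(blurred, "VoxelGrid"))
  vals <- blurred@values
  nd <- dim(vals)
  thr <- stats::quantile(vals, params$seedQuantile, names = FALSE)
  seeds <- cpp_label_components(array(as.integer(vals < thr), nd), nd,
                                26L, FALSE)
  if (max(seeds) == 0) stop("no cells detected")
  ## components touching the stack border are exterior background
  borderIds <- unique(c(seeds[c(1, nd[1]), , ], seeds[, c(1, nd[2]), ],
                        seeds[, , c(1, nd[3])]))
  borderIds <- borderIds[borderIds > 0]
  sizes <- tabulate(seeds, nbins = max(seeds))
  keep <- which(sizes >= params$minSeedVoxels)
  keep <- setdiff(keep, borderIds)
  if (length(keep) == 0) stop("no cells detected")
  ## remap: background components -> one flooding label, kept seeds -> 2..K+1
  map <- integer(max(seeds))
  map[borderIds] <- 1L
  map[keep] <- seq_along(keep) + 1L
  seeds2 <- array(0L, nd)
  nz <- seeds > 0
  seeds2[nz] <- map[seeds[nz]]
  lab <- cpp_watershed(vals, seeds2, nd)
  lab[lab == 1L] <- 0L
  lab <- lab - 1L
  lab[lab < 0L] <- 0L
  out <- new("LabelVolume", labels = lab, voxelSize = blurred@voxelSize,
             origin = blurred@origin)
  filterSmallLabels(out, params$minCellVoxels)
}

#' Merge undersized labels into their neighbours
#'
#' Labels with fewer than \code{minCellVoxels} voxels are merged into the
#' neighbouring label with the largest shared contact (6-neighbourhood face
#' count), or into background when they touch no other label. Remaining
#' labels are relabelled consecutively from 1. Stands in for the manual
#' inspection step of an interactive workflow.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param minCellVoxels minimum voxel count; 0 is the identity.
#' @return a \linkS4class{LabelVolume}.
#' @export
filterSmallLabels <- function(labels, minCellVoxels) {
  stopifnot(is(labels, "LabelVolume"))
  lab <- labels@labels
  if (minCellVoxels > 0 && max(lab) > 0) {
    repeat {
      sizes <- tabulate(lab, nbins = max(lab))
      small <- which(sizes > 0 & sizes < minCellVoxels)
      if (length(small) == 0) break
      contacts <- .labelContacts(lab)
      victim <- small[which.min(sizes[small])]
      cc <- contacts[(contacts$a == victim & contacts$b != 0) |
                       (contacts$b == victim & contacts$a != 0), ]
      if (nrow(cc) == 0) {
        target <- 0L
      } else {
        nb <- ifelse(cc$a == victim, cc$b, cc$a)
        target <- nb[which.max(cc$n)]
      }
      lab[lab == victim] <- as.integer(target)
    }
  }
  ## relabel consecutively
  ids <- sort(unique(as.vector(lab)))
  ids <- ids[ids > 0]
  if (length(ids) > 0 && !identical(ids, seq_along(ids))) {
    map <- integer(max(ids))
    map[ids] <- seq_along(ids)
    nz <- lab > 0
    lab[nz] <- map[lab[nz]]
  }
  new("LabelVolume", labels = lab, voxelSize = labels@voxelSize,
      origin = labels@origin)
}

#' Blur and segment a wall-channel stack
#'
#' Convenience wrapper: \code{\link{gaussianBlur}} at \code{blurRadius}
#' followed by \code{\link{autoseededWatershed}}.
#'
#' @param stack the raw wall channel, a \linkS4class{VoxelGrid}.
#' @param params a list from \code{\link{segmentationParams}}.
#' @return a \linkS4class{LabelVolume}.
#' @export
segmentCells <- function(stack, params = segmentationParams()) {
  autoseededWatershed(gaussianBlur(stack, params$blurRadius), params)
}

#' Match segmentation labels against a reference
#'
#' Greedy best-overlap matching between two label volumes on the same grid:
#' each reference label is paired with the predicted label sharing the most
#' voxels (each predicted label used at most once), and the
#' intersection-over-union of every matched pair is reported. Used for
#' parameter-recovery validation against the synthetic generator's truth.
#'
#' @param predicted,reference \linkS4class{LabelVolume}s on identical grids.
#' @return data.frame with columns \code{reference}, \code{predicted}
#'   (NA when unmatched) and \code{iou}.
#' @export
matchLabels <- function(predicted, reference) {
  stopifnot(is(predicted, "LabelVolume"), is(reference, "LabelVolume"),
            all(dim(predicted@labels) == dim(reference@labels)))
  p <- as.vector(predicted@labels)
  r <- as.vector(reference@labels)
  nz <- p > 0 | r > 0
  p <- p[nz]; r <- r[nz]
  key <- paste(r, p)
  tab <- table(key)
  rp <- do.call(rbind, strsplit(names(tab), " "))
  ov <- data.frame(r = as.integer(rp[, 1]), p = as.integer(rp[, 2]),
                   n = as.integer(tab))
  sizeR <- tapply(rep(1L, length(r)), r, sum)
  sizeP <- tapply(rep(1L, length(p)), p, sum)
  ov <- ov[ov$r > 0 & ov$p > 0, ]
  ov <- ov[order(-ov$n), ]
  usedP <- integer(0)
  refs <- sort(unique(r[r > 0]))
  res <- data.frame(reference = refs, predicted = NA_integer_,
                    iou = 0)
  for (i in seq_len(nrow(ov))) {
    ri <- ov$r[i]; pi <- ov$p[i]
    j <- match(ri, res$reference)
    if (!is.na(res$predicted[j]) || pi %in% usedP) next
    res$predicted[j] <- pi
    inter <- ov$n[i]
    res$iou[j] <- inter / (sizeR[as.character(ri)] +
                             sizeP[as.character(pi)] - inter)
    usedP <- c(usedP, pi)
  }
  res
}
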