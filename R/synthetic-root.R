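#' Define the geometry of a synthetic root
#'
#' The synthetic sample is a straight cylinder along z: concentric cell
#' layers (outermost first) split into angular sectors and axial segments,
#' emulating the radially symmetric organisation of a root meristem
#' (epidermis, cortex, endodermis, ...). The root is centred in x/y; the
#' number of axial segments per layer is \code{floor(extent_z /
#' axialCellLength)}, with the last segment absorbing any remainder.
#'
#' @param layerRadii outer radius of each layer, micrometres, strictly
#'   decreasing inward. The innermost layer reaches down to
#'   \code{coreRadius}.
#' @param cellsPerRing angular sectors per layer (1 or >= 3).
#' @param axialCellLength axial cell length in micrometres; scalar or one
#'   value per layer.
#' @param stackExtent physical stack size (x, y, z) in micrometres.
#' @param voxelSize voxel edge lengths in micrometres, length 1 or 3.
#' @param layerNames layer names, outermost first.
#' @param sectorOffset angular offset (radians) of sector boundaries, scalar
#'   or per layer. Aligned sectors (the default) give one radial wall patch
#'   per sector pair; offsets diversify circumferential interfaces.
#' @param coreRadius radius of a central core region; cells inside it form a
#'   single "inner_core" cell per axial segment. 0 (default) disables it.
#' @return a \linkS4class{RootGeometry}.
#' @examples
#' geom <- rootGeometry(layerRadii = c(12, 7), cellsPerRing = c(6, 4),
#'                      axialCellLength = 10, stackExtent = c(28, 28, 20),
#'                      voxelSize = 0.5, layerNames = c("epidermis", "cortex"))
#' geom
#' @export
rootGeometry <- function(layerRadii = c(16, 11, 6),
                         cellsPerRing = c(8, 8, 8),
                         axialCellLength = 12,
                         stackExtent = c(36, 36, 48),
                         voxelSize = c(0.25, 0.25, 0.25),
                         layerNames = c("epidermis", "cortex", "endodermis"),
                         sectorOffset = 0,
                         coreRadius = 0) {
  L <- length(layerRadii)
  if (length(axialCellLength) == 1) axialCellLength <- rep(axialCellLength, L)
  if (length(sectorOffset) == 1) sectorOffset <- rep(sectorOffset, L)
  if (length(voxelSize) == 1) voxelSize <- rep(voxelSize, 3)
  new("RootGeometry", layerRadii = as.numeric(layerRadii),
      cellsPerRing = as.integer(cellsPerRing),
      axialCellLength = as.numeric(axialCellLength),
      stackExtent = as.numeric(stackExtent),
      voxelSize = as.numeric(voxelSize),
      layerNames = as.character(layerNames),
      sectorOffset = as.numeric(sectorOffset),
      coreRadius = as.numeric(coreRadius))
}

## per-layer bookkeeping: inner radius, segment count/length, label offsets.
## The core (if any) is appended as an extra pseudo-layer with 1 sector.
.layerPlan <- function(geom) {
  L <- length(geom@layerRadii)
  outer <- geom@layerRadii
  inner <- c(geom@layerRadii[-1], geom@coreRadius)
  nsect <- geom@cellsPerRing
  alen <- geom@axialCellLength
  offs <- geom@sectorOffset
  names <- geom@layerNames
  if (geom@coreRadius > 0) {
    outer <- c(outer, geom@coreRadius)
    inner <- c(inner, 0)
    nsect <- c(nsect, 1L)
    alen <- c(alen, alen[L])
    offs <- c(offs, 0)
    names <- c(names, "inner_core")
  }
  nseg <- pmax(1L, as.integer(floor(geom@stackExtent[3] / alen)))
  base <- cumsum(c(0L, (nsect * nseg)[-length(nsect)]))
  list(outer = outer, inner = inner, nsect = nsect, alen = alen,
       offset = offs, names = names, nseg = nseg, base = base,
       nlayers = length(outer))
}

.segmentBreaks <- function(plan, k, extentZ) {
  ns <- plan$nseg[k]
  z0 <- (seq_len(ns) - 1) * plan$alen[k]
  z1 <- c(z0[-1], extentZ)  # last segment absorbs the remainder
  cbind(z0, z1)
}

#' Rasterise the synthetic root into a label volume
#'
#' Deterministically assigns every voxel whose centre lies inside the
#' outermost radius to a cell determined by its (layer band, angular sector,
#' axial segment); voxels outside are 0. Labels are consecutive from 1.
#'
#' @param geom a \linkS4class{RootGeometry}.
#' @return a \linkS4class{LabelVolume}.
#' @export
generateLabelVolume <- function(geom) {
  stopifnot(is(geom, "RootGeometry"))
  plan <- .layerPlan(geom)
  ## resolvability: voxels must be smaller than the smallest cell dimension
  thick <- plan$outer - plan$inner
  midArc <- 2 * pi * (plan$outer + plan$inner) / 2 / plan$nsect
  minDim <- min(thick, plan$alen, midArc[plan$nsect > 1])
  if (max(geom@voxelSize) > minDim)
    stop("unresolvable geometry: voxel size ", max(geom@voxelSize),
         " um exceeds smallest cell dimension ", signif(minDim, 3), " um")

  nd <- pmax(2L, as.integer(floor(geom@stackExtent / geom@voxelSize)))
  cx <- geom@stackExtent[1] / 2
  cy <- geom@stackExtent[2] / 2
  xs <- (seq_len(nd[1]) - 0.5) * geom@voxelSize[1] - cx
  ys <- (seq_len(nd[2]) - 0.5) * geom@voxelSize[2] - cy
  zs <- (seq_len(nd[3]) - 0.5) * geom@voxelSize[3]

  r <- sqrt(outer(xs^2, ys^2, "+"))
  th <- atan2(rep(ys, each = nd[1]), rep(xs, nd[2]))
  th <- (th + 2 * pi) %% (2 * pi)
  dim(th) <- c(nd[1], nd[2])

  ## layer index per (x, y) column: 0 = outside, 1..nlayers
  layer <- matrix(0L, nd[1], nd[2])
  for (k in seq_len(plan$nlayers))
    layer[r <= plan$outer[k] & r > plan$inner[k]] <- k
  ## voxel columns through the exact centre (r == 0) belong to the deepest
  ## region when it reaches the axis
  if (plan$inner[plan$nlayers] == 0)
    layer[r == 0] <- plan$nlayers

  lab <- array(0L, nd)
  twoPi <- 2 * pi
  planeSize <- nd[1] * nd[2]
  for (k in seq_len(plan$nlayers)) {
    sel <- which(layer == k)
    if (length(sel) == 0) next
    n <- plan$nsect[k]
    sect <- if (n == 1) rep(0L, length(sel)) else {
      a <- (th[sel] - plan$offset[k]) %% twoPi
      pmin(as.integer(floor(a / (twoPi / n))), n - 1L)
    }
    segOfZ <- pmin(as.integer(floor(zs / plan$alen[k])), plan$nseg[k] - 1L)
    for (z in seq_len(nd[3]))
      lab[sel + (z - 1L) * planeSize] <-
        plan$base[k] + segOfZ[z] * n + sect + 1L
  }
  new("LabelVolume", labels = lab, voxelSize = geom@voxelSize,
      origin = c(0, 0, 0))
}

.arcIntersect <- function(a0, a1, b0, b1) {
  ## intersection of arcs [a0,a1) and [b0,b1) on the circle (lengths < 2pi
  ## or full circle); returns matrix of (start, end) rows
  twoPi <- 2 * pi
  if (a1 - a0 >= twoPi - 1e-12) return(matrix(c(b0, b1), ncol = 2))
  if (b1 - b0 >= twoPi - 1e-12) return(matrix(c(a0, a1), ncol = 2))
  a0 <- a0 %% twoPi; a1w <- a0 + ((a1 - a0) %% twoPi)
  b0 <- b0 %% twoPi; b1w <- b0 + ((b1 - b0) %% twoPi)
  out <- NULL
  for (shift in c(-twoPi, 0, twoPi)) {
    lo <- max(a0, b0 + shift)
    hi <- min(a1w, b1w + shift)
    if (hi - lo > 1e-9) out <- rbind(out, c(lo, hi))
  }
  out
}

#' Analytic ground truth for a synthetic root geometry
#'
#' Enumerates the true cells (with analytic centroids and volumes) and every
#' interface patch between adjacent cells, with closed-form areas:
#' apical-basal walls are annular-sector discs, circumferential walls are
#' radial rectangles, and walls between layers are cylindrical patches.
#' Outer surfaces are recorded with \code{cell_b = 0} and class
#' \code{"exterior"}.
#'
#' @param geom a \linkS4class{RootGeometry}.
#' @return a \linkS4class{RootTruth} (spot table empty).
#' @export
groundTruth <- function(geom) {
  stopifnot(is(geom, "RootGeometry"))
  plan <- .layerPlan(geom)
  twoPi <- 2 * pi
  cx <- geom@stackExtent[1] / 2
  cy <- geom@stackExtent[2] / 2

  cellRows <- list()
  for (k in seq_len(plan$nlayers)) {
    n <- plan$nsect[k]
    segBreaks <- .segmentBreaks(plan, k, geom@stackExtent[3])
    for (s in seq_len(plan$nseg[k])) {
      for (q in seq_len(n)) {
        th0 <- plan$offset[k] + (q - 1) * twoPi / n
        th1 <- th0 + twoPi / n
        Ro <- plan$outer[k]; Ri <- plan$inner[k]
        dth <- th1 - th0
        ## centroid of an annular sector
        rbar <- if (Ro^2 - Ri^2 > 0)
          (2 / 3) * (Ro^3 - Ri^3) / (Ro^2 - Ri^2) *
            (sin(dth / 2) / (dth / 2)) else 0
        thm <- (th0 + th1) / 2
        z0 <- segBreaks[s, 1]; z1 <- segBreaks[s, 2]
        cellRows[[length(cellRows) + 1]] <- data.frame(
          label = plan$base[k] + (s - 1L) * n + q,
          layer_name = plan$names[k], layer_index = k - 1L,
          ring_index = k - 1L, sector = q - 1L, axial_index = s - 1L,
          centroid_x = cx + rbar * cos(thm),
          centroid_y = cy + rbar * sin(thm),
          centroid_z = (z0 + z1) / 2,
          volume_um3 = dth / 2 * (Ro^2 - Ri^2) * (z1 - z0))
      }
    }
  }
  cells <- do.call(rbind, cellRows)

  labelOf <- function(k, s, q) plan$base[k] + (s - 1L) * plan$nsect[k] +
    ((q - 1L) %% plan$nsect[k]) + 1L

  ifRows <- list()
  addPatch <- function(a, b, class, geomType, area, p) {
    ifRows[[length(ifRows) + 1]] <<- data.frame(
      cell_a = a, cell_b = b, class = class,
      geom_type = geomType, area_um2 = area,
      p1 = p[1], p2 = p[2], p3 = p[3], p4 = p[4], p5 = p[5])
  }

  for (k in seq_len(plan$nlayers)) {
    n <- plan$nsect[k]
    Ro <- plan$outer[k]; Ri <- plan$inner[k]
    dth <- twoPi / n
    segBreaks <- .segmentBreaks(plan, k, geom@stackExtent[3])
    for (s in seq_len(plan$nseg[k])) {
      z0 <- segBreaks[s, 1]; z1 <- segBreaks[s, 2]
      for (q in seq_len(n)) {
        th0 <- plan$offset[k] + (q - 1) * dth
        me <- labelOf(k, s, q)
        ## apical-basal wall to the next axial segment
        if (s < plan$nseg[k]) {
          up <- labelOf(k, s + 1L, q)
          addPatch(me, up, "apical_basal", "disc",
                   dth / 2 * (Ro^2 - Ri^2), c(z1, th0, th0 + dth, Ri, Ro))
        } else {
          ## top cap is exterior
          addPatch(me, 0L, "exterior", "disc",
                   dth / 2 * (Ro^2 - Ri^2), c(z1, th0, th0 + dth, Ri, Ro))
        }
        if (s == 1)
          addPatch(me, 0L, "exterior", "disc",
                   dth / 2 * (Ro^2 - Ri^2), c(z0, th0, th0 + dth, Ri, Ro))
        ## circumferential wall to the next sector
        if (n >= 3) {
          nb <- labelOf(k, s, q + 1L)
          addPatch(me, nb, "circumferential", "rect",
                   (Ro - Ri) * (z1 - z0), c(th0 + dth, Ri, Ro, z0, z1))
        }
        ## radial wall(s) to the inner layer (or exterior outer wall)
        if (k == 1)
          addPatch(me, 0L, "exterior", "cyl",
                   Ro * dth * (z1 - z0), c(Ro, th0, th0 + dth, z0, z1))
        if (k < plan$nlayers) {
          ki <- k + 1L
          ni <- plan$nsect[ki]
          dthi <- twoPi / ni
          segI <- .segmentBreaks(plan, ki, geom@stackExtent[3])
          for (si in seq_len(plan$nseg[ki])) {
            zo <- c(max(z0, segI[si, 1]), min(z1, segI[si, 2]))
            if (zo[2] - zo[1] <= 1e-9) next
            for (qi in seq_len(ni)) {
              ti0 <- plan$offset[ki] + (qi - 1) * dthi
              arcs <- .arcIntersect(th0, th0 + dth, ti0, ti0 + dthi)
              if (is.null(arcs)) next
              inner <- labelOf(ki, si, qi)
              for (ar in seq_len(nrow(arcs))) {
                w <- arcs[ar, 2] - arcs[ar, 1]
                addPatch(me, inner, "radial", "cyl",
                         Ri * w * (zo[2] - zo[1]),
                         c(Ri, arcs[ar, 1], arcs[ar, 2], zo[1], zo[2]))
              }
            }
          }
        }
      }
    }
  }
  interfaces <- do.call(rbind, ifRows)
  ## canonical pair ordering (exterior stays in cell_b as 0)
  swap <- interfaces$cell_b != 0 & interfaces$cell_a > interfaces$cell_b
  tmp <- interfaces$cell_a[swap]
  interfaces$cell_a[swap] <- interfaces$cell_b[swap]
  interfaces$cell_b[swap] <- tmp
  interfaces$patch_id <- seq_len(nrow(interfaces))
  spots <- data.frame(patch_id = integer(), cell_a = integer(),
                      cell_b = integer(), x = numeric(), y = numeric(),
                      z = numeric())
  new("RootTruth", cells = cells, interfaces = interfaces, spots = spots,
      geometry = geom)
}

#' Render the cell-wall stain channel
#'
#' Produces a wall channel: high intensity on voxels lying within the wall
#' band around any label boundary (including the outer surface), Gaussian
#' blurred, with additive Gaussian noise.
#'
#' @param labels a \linkS4class{LabelVolume}.
#' @param wallThickness physical wall thickness in micrometres; walls are at
#'   least two voxels thick (one on each side of the boundary face).
#' @param blurSigma Gaussian blur sigma in micrometres (imaging PSF proxy).
#' @param noiseSd additive Gaussian noise SD.
#' @param amplitude wall intensity before blur.
#' @param seed integer seed for the noise; NULL leaves the RNG state alone.
#' @return a \linkS4class{VoxelGrid}.
#' @export
renderWallChannel <- function(labels, wallThickness = 0.4, blurSigma = 0.2,
                              noiseSd = 0, amplitude = 100, seed = NULL) {
  stopifnot(is(labels, "LabelVolume"))
  lab <- labels@labels
  vs <- labels@voxelSize
  nd <- dim(lab)
  ## base mask: the two voxels astride every label-change face (6-
  ## neighbourhood), which is symmetric about the true boundary surface;
  ## thicker walls are grown by symmetric face-neighbour dilation
  faceOffs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))
  shift <- function(arr, o, fill = 0L) {
    P <- array(fill, nd + 2L)
    P[1L + seq_len(nd[1]), 1L + seq_len(nd[2]), 1L + seq_len(nd[3])] <- arr
    P[1L + o[1] + seq_len(nd[1]), 1L + o[2] + seq_len(nd[2]),
      1L + o[3] + seq_len(nd[3])]
  }
  wall <- array(FALSE, nd)
  for (i in seq_len(nrow(faceOffs))) {
    S <- shift(lab, faceOffs[i, ])
    wall <- wall | (S != lab)
  }
  dilations <- max(0L, as.integer(round(wallThickness / (2 * min(vs)) - 1)))
  for (d in seq_len(dilations)) {
    grown <- wall
    for (i in seq_len(nrow(faceOffs)))
      grown <- grown | shift(wall, faceOffs[i, ], fill = FALSE)
    wall <- grown
  }
  vals <- array(0, nd)
  vals[wall] <- amplitude
  if (blurSigma > 0)
    vals <- cpp_gauss_blur(vals, nd, blurSigma / vs)
  if (noiseSd > 0) {
    if (!is.null(seed)) set.seed(seed)
    vals <- vals + array(stats::rnorm(prod(nd), 0, noiseSd), nd)
  }
  new("VoxelGrid", values = array(as.numeric(vals), nd),
      voxelSize = vs, origin = labels@origin)
}

## map patch parameter-plane points to 3D; u, v in [0, 1]
.patchPoint <- function(row, u, v, centre) {
  if (row$geom_type == "disc") {
    r <- sqrt(row$p4^2 + u * (row$p5^2 - row$p4^2))
    th <- row$p2 + v * (row$p3 - row$p2)
    cbind(centre[1] + r * cos(th), centre[2] + r * sin(th), row$p1)
  } else if (row$geom_type == "rect") {
    r <- row$p2 + u * (row$p3 - row$p2)
    z <- row$p4 + v * (row$p5 - row$p4)
    cbind(centre[1] + r * cos(row$p1), centre[2] + r * sin(row$p1), z)
  } else {  # cyl
    th <- row$p2 + u * (row$p3 - row$p2)
    z <- row$p4 + v * (row$p5 - row$p4)
    cbind(centre[1] + row$p1 * cos(th), centre[2] + row$p1 * sin(th), z)
  }
}

#' Sample pit-field spot positions on the true interfaces
#'
#' Draws per-patch spot counts from a Poisson law with mean
#' \code{ratePerArea[class] * area} and places spots either uniformly on the
#' patch or by a Thomas parent-offspring cluster process (parents Poisson on
#' the patch, offspring displaced by an in-plane Gaussian of SD
#' \code{clusterSigma} and clamped to the patch). Exterior patches receive
#' no spots. This is the placement stage only; \code{\link{placePitFields}}
#' renders the result into an image.
#'
#' @param truth a \linkS4class{RootTruth}.
#' @param params a \linkS4class{PitFieldParams}.
#' @param seed integer seed; NULL leaves the RNG state alone.
#' @return data.frame of spots (patch_id, cell pair, class, x, y, z).
#' @export
samplePitFieldSpots <- function(truth, params, seed = NULL) {
  stopifnot(is(truth, "RootTruth"), is(params, "PitFieldParams"))
  if (!is.null(seed)) set.seed(seed)
  geom <- truth@geometry
  centre <- c(geom@stackExtent[1] / 2, geom@stackExtent[2] / 2, 0)
  ifc <- truth@interfaces
  out <- list()
  for (i in seq_len(nrow(ifc))) {
    row <- ifc[i, ]
    if (row$class == "exterior") next
    if (!row$class %in% names(params@ratePerArea))
      stop("interface class '", row$class, "' missing from ratePerArea")
    rate <- params@ratePerArea[[row$class]]
    if (params@clusterMode == "uniform") {
      n <- stats::rpois(1, rate * row$area_um2)
      if (n == 0) next
      pts <- .patchPoint(row, stats::runif(n), stats::runif(n), centre)
    } else {
      parentRate <- if (is.na(params@parentsPerArea))
        rate / params@offspringPerParent else params@parentsPerArea
      np <- stats::rpois(1, parentRate * row$area_um2)
      if (np == 0) next
      pu <- stats::runif(np); pv <- stats::runif(np)
      noff <- stats::rpois(np, params@offspringPerParent)
      if (sum(noff) == 0) next
      ## physical extents of the parameter axes, for clamped displacement
      uext <- switch(row$geom_type,
        disc = row$p5 - row$p4, rect = row$p3 - row$p2,
        cyl = row$p1 * (row$p3 - row$p2))
      vext <- switch(row$geom_type,
        disc = (row$p3 - row$p2) * (row$p4 + row$p5) / 2,
        rect = row$p5 - row$p4, cyl = row$p5 - row$p4)
      uu <- rep(pu, noff) + stats::rnorm(sum(noff), 0,
                                         params@clusterSigma / max(uext, 1e-9))
      vv <- rep(pv, noff) + stats::rnorm(sum(noff), 0,
                                         params@clusterSigma / max(vext, 1e-9))
      pts <- .patchPoint(row, pmin(pmax(uu, 0), 1), pmin(pmax(vv, 0), 1),
                         centre)
    }
    out[[length(out) + 1]] <- data.frame(
      patch_id = row$patch_id, cell_a = row$cell_a, cell_b = row$cell_b,
      class = row$class, x = pts[, 1], y = pts[, 2], z = pts[, 3])
  }
  if (length(out) == 0)
    return(data.frame(patch_id = integer(), cell_a = integer(),
                      cell_b = integer(), class = character(), x = numeric(),
                      y = numeric(), z = numeric()))
  do.call(rbind, out)
}

#' Render the plasmodesmata marker channel
#'
#' Samples spot positions with \code{\link{samplePitFieldSpots}}, renders
#' each spot as an isotropic 3D Gaussian of width \code{spotSigma} and peak
#' \code{spotAmplitude}, and adds Gaussian noise. True counts and positions
#' are recorded in the returned truth table; every spot is attributed to the
#' patch that generated it, even if its rendered support bleeds across a
#' neighbouring interface.
#'
#' @param labels a \linkS4class{LabelVolume} giving the image grid.
#' @param truth a \linkS4class{RootTruth} consistent with \code{labels}.
#' @param params a \linkS4class{PitFieldParams}.
#' @param seed integer seed; NULL leaves the RNG state alone.
#' @return list with elements \code{pd} (a \linkS4class{VoxelGrid}) and
#'   \code{truth} (the input truth with spots and per-patch
#'   \code{true_spot_count} filled in).
#' @export
placePitFields <- function(labels, truth, params, seed = NULL) {
  stopifnot(is(labels, "LabelVolume"))
  spots <- samplePitFieldSpots(truth, params, seed = seed)
  nd <- dim(labels@labels)
  vals <- array(0, nd)
  if (nrow(spots) > 0)
    vals <- cpp_render_spots(vals, nd, labels@voxelSize, labels@origin,
                             as.matrix(spots[, c("x", "y", "z")]),
                             params@spotSigma, params@spotAmplitude)
  if (params@noiseSd > 0)
    vals <- vals + array(stats::rnorm(prod(nd), 0, params@noiseSd), nd)
  truth@spots <- spots
  cnt <- table(factor(spots$patch_id,
                      levels = truth@interfaces$patch_id))
  truth@interfaces$true_spot_count <- as.integer(cnt)
  truth@interfaces$cluster_mode <- params@clusterMode
  pd <- new("VoxelGrid", values = array(as.numeric(vals), nd),
            voxelSize = labels@voxelSize, origin = labels@origin)
  list(pd = pd, truth = truth)
}

#' Pit-field placement parameters
#'
#' Defaults give a 4:1:1 expected-count-per-area ratio in favour of
#' apical-basal walls, the qualitative abundance ranking reported for root
#' tissue, with a diffraction-scale spot size.
#'
#' @param ratePerArea named expected spot counts per square micrometre.
#' @param clusterMode "uniform" or "thomas".
#' @param parentsPerArea Thomas parent intensity per square micrometre;
#'   \code{NA} (default) derives it as rate / offspringPerParent so uniform
#'   and thomas modes share the same expected total count.
#' @param offspringPerParent mean offspring per parent.
#' @param clusterSigma offspring dispersion in micrometres.
#' @param spotSigma rendered spot Gaussian SD in micrometres.
#' @param spotAmplitude spot peak intensity.
#' @param noiseSd additive Gaussian noise SD.
#' @return a \linkS4class{PitFieldParams}.
#' @export
pitFieldParams <- function(ratePerArea = c(apical_basal = 0.4, radial = 0.1,
                                           circumferential = 0.1),
                           clusterMode = c("uniform", "thomas"),
                           parentsPerArea = NA_real_,
                           offspringPerParent = 5,
                           clusterSigma = 0.5,
                           spotSigma = 0.15,
                           spotAmplitude = 100,
                           noiseSd = 2) {
  clusterMode <- match.arg(clusterMode)
  new("PitFieldParams", ratePerArea = ratePerArea, clusterMode = clusterMode,
      parentsPerArea = as.numeric(parentsPerArea),
      offspringPerParent = as.numeric(offspringPerParent),
      clusterSigma = as.numeric(clusterSigma),
      spotSigma = as.numeric(spotSigma),
      spotAmplitude = as.numeric(spotAmplitude),
      noiseSd = as.numeric(noiseSd))
}

#' Simulate a complete dual-channel root sample
#'
#' Generates the true segmentation, the wall-stain channel and the
#' plasmodesmata marker channel for one synthetic root. The two channels
#' get independent sub-seeds derived from \code{seed}, so identical
#' arguments reproduce bit-identical stacks.
#'
#' @param geom a \linkS4class{RootGeometry}.
#' @param pit a \linkS4class{PitFieldParams}.
#' @param wallThickness,wallBlurSigma,wallNoiseSd,wallAmplitude wall channel
#'   rendering parameters, see \code{\link{renderWallChannel}}.
#' @param seed integer seed.
#' @return a \linkS4class{SimulatedRoot}.
#' @examples
#' geom <- rootGeometry(layerRadii = c(10, 6), cellsPerRing = c(4, 4),
#'                      axialCellLength = 8, stackExtent = c(24, 24, 16),
#'                      voxelSize = 0.5, layerNames = c("epidermis", "cortex"))
#' sim <- simulateRoot(geom, pitFieldParams(), seed = 1)
#' sim
#' @export
simulateRoot <- function(geom, pit = pitFieldParams(), wallThickness = 0.4,
                         wallBlurSigma = 0.2, wallNoiseSd = 2,
                         wallAmplitude = 100, seed = 1) {
  set.seed(seed)
  subSeeds <- sample.int(.Machine$integer.max - 1, 2)
  labels <- generateLabelVolume(geom)
  truth <- groundTruth(geom)
  wall <- renderWallChannel(labels, wallThickness = wallThickness,
                            blurSigma = wallBlurSigma, noiseSd = wallNoiseSd,
                            amplitude = wallAmplitude, seed = subSeeds[1])
  pd <- placePitFields(labels, truth, pit, seed = subSeeds[2])
  new("SimulatedRoot", wall = wall, pd = pd$pd, labels = labels,
      truth = pd$truth)
}
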