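## Shared small fixtures, built once per test run and memoised.

.fixtureCache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtureCache))
    assign(name, force(expr), envir = .fixtureCache)
  get(name, envir = .fixtureCache)
}

## compact elongated 2-layer root at 0.25 um voxels: 40 cells
smallGeom <- function() rootGeometry(
  layerRadii = c(9, 5), cellsPerRing = c(6, 4), axialCellLength = 8,
  stackExtent = c(22, 22, 32), voxelSize = 0.25,
  layerNames = c("epidermis", "cortex"))

smallLab <- function() memo("smallLab", generateLabelVolume(smallGeom()))
smallTruth <- function() memo("smallTruth", groundTruth(smallGeom()))
smallMesh <- function() memo("smallMesh",
  buildInterfaceMesh(smallLab(), cubeSize = 0.5, smoothPasses = 10))

## analytic interface areas aggregated per cell pair
smallTruthAreas <- function() memo("smallTruthAreas", {
  ti <- truthInterfaces(smallTruth())
  stats::aggregate(area_um2 ~ cell_a + cell_b + class, ti, sum)
})

## a two-cube label volume: cells 1 and 2 sharing a full 10 x 10 um face
twoCubeLabels <- function(h = 0.5) memo(paste0("twoCube", h), {
  n <- as.integer(round(10 / h))
  lab <- array(0L, c(2L * n, n, n))
  lab[seq_len(n), , ] <- 1L
  lab[n + seq_len(n), , ] <- 2L
  new("LabelVolume", labels = lab, voxelSize = rep(h, 3),
      origin = c(0, 0, 0))
})

## dense-matrix brute-force Moran's I oracle (independent of the package's
## edge-list implementation)
bruteMoransI <- function(x, W) {
  n <- length(x)
  d <- x - mean(x)
  (n / sum(W)) * sum(W * outer(d, d)) / sum(d^2)
}

## random connected-ish graph as (x, edges, W) for oracle comparisons
randomGraph <- function(n, pEdge = 0.05, binaryValues = FALSE) {
  repeat {
    all <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    sel <- all[stats::runif(nrow(all)) < pEdge, , drop = FALSE]
    if (nrow(sel) >= 1) break
  }
  W <- matrix(0, n, n)
  W[sel] <- 1
  W <- W + t(W)
  repeat {
    x <- if (binaryValues) stats::rbinom(n, 1, 0.4) else stats::rnorm(n)
    if (stats::var(x) > 0) break
  }
  list(x = x, edges = sel, W = W)
}

## checkerboard values on an n x n grid, column-major like gridRookEdges
checkerboard <- function(n) as.vector((outer(1:n, 1:n, "+")) %% 2)

## left half a / right half b two-block pattern on an n x n grid
twoBlock <- function(n, a = 0, b = 1) {
  as.vector(outer(1:n, 1:n, function(i, j) ifelse(j <= n / 2, a, b)))
}
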