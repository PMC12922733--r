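## flat interface between two cubes; marker spots rendered analytically
flatMesh <- function() buildInterfaceMesh(twoCubeLabels(0.25),
                                          cubeSize = 0.5, smoothPasses = 10)

spotStack <- function(centers, sigma, amplitude, h = 0.1,
                      nd = c(210, 110, 110)) {
  vals <- pdmap:::cpp_render_spots(array(0, nd), as.integer(nd),
                                   rep(h, 3), c(0, 0, 0),
                                   rbind(centers), sigma, amplitude)
  new("VoxelGrid", values = vals, voxelSize = rep(h, 3), origin = c(0, 0, 0))
}

test_that("an all-zero stack projects to all-zero raw intensities", {
  sig <- projectSignal(flatMesh(), spotStack(matrix(numeric(0), 0, 3), 0.2, 0))
  expect_true(all(sig@raw == 0))
  expect_identical(sig@nOutOfBounds, 0L)
})

test_that("projected intensity reaches the Gaussian value at the offset", {
  mesh <- flatMesh()
  sigma <- 0.3; A <- 100
  ## spot 0.2 um from the interface plane (x = 10), inside the band
  pd <- spotStack(c(10.2, 5, 5), sigma, A)
  sig <- projectSignal(mesh, pd, bandHalfwidth = 0.5)
  tab <- interfaceTable(mesh)
  iCC <- tab$interface_id[tab$cell_b != 0]
  vid <- unique(as.vector(triangles(mesh)[mesh@triInterface == iCC, ]))
  v <- vertices(mesh)[vid, ]
  near <- vid[which.min((v[, 2] - 5)^2 + (v[, 3] - 5)^2)]
  ## the nearest vertex samples along its normal through the spot centre
  expect_gte(sig@raw[near], A * exp(-0.2^2 / (2 * sigma^2)) * 0.95)

  ## a spot 1.0 um off-surface is outside the 0.5 um band: < 1% amplitude
  sigmaN <- 0.15
  pdFar <- spotStack(c(11.0, 5, 5), sigmaN, A)
  sigFar <- projectSignal(mesh, pdFar, bandHalfwidth = 0.5)
  vFar <- vertices(mesh)[vid, ]
  nearFar <- vid[which.min((vFar[, 2] - 5)^2 + (vFar[, 3] - 5)^2)]
  expect_lt(sigFar@raw[nearFar], 0.01 * A)
})

test_that("projection scales linearly with the stack", {
  mesh <- flatMesh()
  pd <- spotStack(rbind(c(10, 3, 6), c(10, 7, 4)), 0.3, 50)
  s1 <- projectSignal(mesh, pd)
  pd3 <- new("VoxelGrid", values = 3 * voxelData(pd),
             voxelSize = voxelSize(pd), origin = gridOrigin(pd))
  s3 <- projectSignal(mesh, pd3)
  expect_equal(s3@raw, 3 * s1@raw, tolerance = 1e-12)
})

test_that("mean aggregation is bounded by max aggregation", {
  mesh <- flatMesh()
  pd <- spotStack(c(10, 5, 5), 0.3, 80)
  mx <- projectSignal(mesh, pd, aggregate = "max")
  mn <- projectSignal(mesh, pd, aggregate = "mean")
  expect_true(all(mn@raw <= mx@raw + 1e-12))
})

test_that("background trim decays into inner layers", {
  raw <- c(0, 0.9, 0.9, 2)
  sig <- new("VertexSignal", raw = raw, trimmed = raw,
             binary = as.numeric(raw > 0), maxValue = 1,
             nOutOfBounds = 0L)
  ## f = 1: uniform threshold
  u <- trimBackground(sig, vertexLayers = c(0L, 0L, 2L, 0L), baseTrim = 1,
                      layerDecay = 1)
  expect_equal(u@trimmed, c(0, 0, 0, 2))
  ## f = 0.8: raw 0.9 removed on layer 0 (thr 1) but kept on layer 2
  ## (thr 0.64)
  d <- trimBackground(sig, vertexLayers = c(0L, 0L, 2L, 0L), baseTrim = 1,
                      layerDecay = 0.8)
  expect_equal(d@trimmed, c(0, 0, 0.9, 2))
  ## unannotated vertices fall back to the layer-0 trim with a warning
  expect_warning(
    w <- trimBackground(sig, vertexLayers = c(0L, NA, 2L, 0L),
                        baseTrim = 1, layerDecay = 0.8),
    "without layer annotation")
  expect_equal(w@trimmed, c(0, 0, 0.9, 2))
})

test_that("lowering the trim never removes surviving vertices", {
  raw <- stats::runif(500, 0, 10)
  sig <- new("VertexSignal", raw = raw, trimmed = raw,
             binary = as.numeric(raw > 0), maxValue = 1, nOutOfBounds = 0L)
  lay <- sample(0:2, 500, replace = TRUE)
  nPos <- vapply(seq(5, 0, by = -0.5), function(t0)
    sum(trimBackground(sig, lay, baseTrim = t0)@binary > 0), 0)
  expect_true(all(diff(nPos) >= 0))
})

test_that("binarization sets max value, is idempotent and conservative", {
  sig <- new("VertexSignal", raw = c(0, 0.2, 7.5),
             trimmed = c(0, 0.2, 7.5), binary = c(0, 1, 1), maxValue = 1,
             nOutOfBounds = 0L)
  b <- binarizeSignal(sig, maxValue = 1)
  expect_equal(b@binary, c(0, 1, 1))
  expect_equal(binarizeSignal(b, 1)@binary, b@binary)
  b2 <- binarizeSignal(sig, maxValue = 255)
  expect_equal(b2@binary, c(0, 255, 255))
  expect_identical(sum(b2@binary > 0), sum(b@binary > 0))
})

test_that("binary signal is invariant to joint stack/trim scaling", {
  mesh <- flatMesh()
  pd <- spotStack(rbind(c(10, 4, 4), c(10, 6, 7)), 0.3, 60)
  run <- function(scale) {
    pdS <- new("VoxelGrid", values = scale * voxelData(pd),
               voxelSize = voxelSize(pd), origin = gridOrigin(pd))
    s <- projectSignal(mesh, pdS)
    binarizeSignal(trimBackground(s, baseTrim = 5 * scale,
                                  layerDecay = 1))@binary
  }
  expect_identical(run(1), run(7.3))
})

test_that("vertices outside the stack are sampled as zero and counted", {
  mesh <- flatMesh()
  ## a stack half the size of the mesh extent
  small <- new("VoxelGrid", values = array(1, c(20, 20, 20)),
               voxelSize = c(0.25, 0.25, 0.25), origin = c(0, 0, 0))
  sig <- projectSignal(mesh, small)
  expect_gt(sig@nOutOfBounds, 0L)
  out <- rowSums(sweep(vertices(mesh), 2, c(5, 5, 5)) > 0.6) > 0
  expect_true(all(sig@raw[out] == 0))
})

test_that("vertex layer index takes the deeper owning cell", {
  mesh <- smallMesh()
  ann <- annotateSample(smallLab(), mesh, c("epidermis", "cortex"))
  vl <- vertexLayerIndex(ann$mesh, ann$cells)
  expect_identical(length(vl), nrow(vertices(mesh)))
  expect_true(all(vl %in% c(0L, 1L)))
  ## vertices of the cortex-cortex interfaces are layer 1
  tab <- interfaceTable(ann$mesh)
  ids <- tab$interface_id[tab$interaction_class == "cortex"]
  vid <- unique(as.vector(triangles(mesh)[mesh@triInterface %in% ids, ]))
  expect_true(all(vl[vid] == 1L))
})
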