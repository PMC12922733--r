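test_that("label volume has one cell per (layer, sector, segment)", {
  ## one layer, one sector, two axial segments
  g1 <- rootGeometry(layerRadii = 5, cellsPerRing = 1, axialCellLength = 8,
                     stackExtent = c(12, 12, 16), voxelSize = 0.5,
                     layerNames = "epidermis")
  expect_identical(length(labelIds(generateLabelVolume(g1))), 2L)

  ## 3 layers x 8 sectors x 4 segments = 96 cells
  g96 <- rootGeometry(voxelSize = 0.5)
  expect_identical(length(labelIds(generateLabelVolume(g96))), 96L)

  ## 20-cell fixture: every label is a single 26-connected component
  lv <- smallLab()
  cc <- pdmap:::cpp_label_components(labelData(lv), dim(labelData(lv)),
                                     26L, TRUE)
  expect_identical(max(cc), length(labelIds(lv)))
})

test_that("voxel counts match analytic cylindrical-sector volumes", {
  m <- merge(cellTable(smallLab()), truthCells(smallTruth()),
             by = "label")
  ratio <- m$volume_um3.x / m$volume_um3.y
  expect_true(all(abs(ratio - 1) < 0.10))
})

test_that("unresolvable geometry is rejected", {
  g <- rootGeometry(layerRadii = c(5, 4), cellsPerRing = c(4, 4),
                    axialCellLength = 8, stackExtent = c(12, 12, 16),
                    voxelSize = 1.5, layerNames = c("a", "b"))
  expect_error(generateLabelVolume(g), "unresolvable geometry")
})

test_that("geometry parameters are validated", {
  expect_error(rootGeometry(layerRadii = c(5, 6)), "decreasing")
  expect_error(rootGeometry(layerRadii = c(5, 3), cellsPerRing = c(2, 4),
                            layerNames = c("a", "b")), "2")
  expect_error(rootGeometry(coreRadius = 10), "coreRadius")
})

test_that("wall channel marks exactly the boundary voxels when unblurred", {
  lv <- twoCubeLabels(0.5)
  wall <- renderWallChannel(lv, wallThickness = 0.1, blurSigma = 0,
                            noiseSd = 0, amplitude = 1)
  lab <- labelData(lv)
  nd <- dim(lab)
  ## reference: voxels with a differing 6-neighbour (outside counts as 0)
  P <- array(0L, nd + 2L)
  P[1L + seq_len(nd[1]), 1L + seq_len(nd[2]), 1L + seq_len(nd[3])] <- lab
  ref <- array(FALSE, nd)
  sl <- function(di, dj, dk)
    P[1L + di + seq_len(nd[1]), 1L + dj + seq_len(nd[2]),
      1L + dk + seq_len(nd[3])]
  for (o in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0),
                 c(0,0,1), c(0,0,-1)))
    ref <- ref | (sl(o[1], o[2], o[3]) != lab)
  expect_identical(voxelData(wall) > 0, ref)
})

test_that("wall channel is reproducible and brighter on boundaries", {
  lv <- smallLab()
  w1 <- renderWallChannel(lv, noiseSd = 2, seed = 7)
  w2 <- renderWallChannel(lv, noiseSd = 2, seed = 7)
  expect_identical(voxelData(w1), voxelData(w2))

  boundary <- voxelData(renderWallChannel(lv, wallThickness = 0.1,
                                          blurSigma = 0, noiseSd = 0,
                                          amplitude = 1)) > 0
  v <- voxelData(w1)
  interior <- !boundary & labelData(lv) > 0
  expect_gt(mean(v[boundary]), mean(v[interior]))
})

test_that("pit-field spot counts follow the Poisson law per interface", {
  tr <- smallTruth()
  ## zero rates: no spots, channel is pure noise
  p0 <- pitFieldParams(c(apical_basal = 0, radial = 0, circumferential = 0),
                       noiseSd = 1)
  res <- placePitFields(smallLab(), tr, p0, seed = 1)
  expect_identical(nrow(truthSpots(res$truth)), 0L)
  expect_true(all(truthInterfaces(res$truth)$true_spot_count == 0))
  expect_gt(stats::sd(voxelData(res$pd)), 0)

  ## Monte-Carlo mean of the largest patch's count vs rate * area
  rate <- 0.5
  pp <- pitFieldParams(c(apical_basal = rate, radial = rate,
                         circumferential = rate))
  ti <- truthInterfaces(tr)
  big <- ti$patch_id[which.max(ti$area_um2 *
                                 (ti$class != "exterior"))]
  area <- ti$area_um2[ti$patch_id == big]
  nSeeds <- 200
  counts <- vapply(seq_len(nSeeds), function(s) {
    sp <- samplePitFieldSpots(tr, pp, seed = s)
    sum(sp$patch_id == big)
  }, 0L)
  se <- sqrt(rate * area / nSeeds)
  expect_lt(abs(mean(counts) - rate * area), 3 * se)
})

test_that("every sampled spot lies on its generating patch", {
  tr <- smallTruth()
  geom <- smallGeom()
  sp <- samplePitFieldSpots(tr, pitFieldParams(), seed = 3)
  expect_gt(nrow(sp), 0)
  cx <- geom@stackExtent[1] / 2
  r <- sqrt((sp$x - cx)^2 + (sp$y - cx)^2)
  expect_true(all(r <= max(geom@layerRadii) + 1e-6))
  expect_true(all(sp$z >= 0 & sp$z <= geom@stackExtent[3]))
  ## spots on a radial (cylindrical) patch sit at the layer boundary radius
  rad <- sp$class == "radial"
  expect_true(all(abs(r[rad] - geom@layerRadii[2]) < 1e-6))
})

test_that("rendered spot count equals the truth table count", {
  res <- placePitFields(smallLab(), smallTruth(), pitFieldParams(),
                        seed = 5)
  expect_identical(nrow(truthSpots(res$truth)),
                   as.integer(sum(truthInterfaces(res$truth)$true_spot_count)))
  ## rendered intensity integrates to count * amplitude * (2 pi sigma^2)^1.5
  p <- pitFieldParams(noiseSd = 0)
  res0 <- placePitFields(smallLab(), smallTruth(), p, seed = 5)
  total <- sum(voxelData(res0$pd)) * prod(voxelSize(res0$pd))
  expected <- nrow(truthSpots(res0$truth)) * p@spotAmplitude *
    (2 * pi * p@spotSigma^2)^1.5
  expect_lt(abs(total / expected - 1), 0.05)
})

test_that("missing interface class in the rate map is an error", {
  p <- pitFieldParams()
  p@ratePerArea <- c(apical_basal = 1)  # bypass constructor validation
  expect_error(samplePitFieldSpots(smallTruth(), p), "missing")
})

test_that("simulateRoot is bit-identical under a fixed seed", {
  geom <- rootGeometry(layerRadii = 6, cellsPerRing = 4,
                       axialCellLength = 8, stackExtent = c(16, 16, 16),
                       voxelSize = 0.5, layerNames = "epidermis")
  s1 <- simulateRoot(geom, pitFieldParams(), seed = 11)
  s2 <- simulateRoot(geom, pitFieldParams(), seed = 11)
  expect_identical(voxelData(s1@wall), voxelData(s2@wall))
  expect_identical(voxelData(s1@pd), voxelData(s2@pd))
  expect_identical(truthSpots(s1), truthSpots(s2))
  s3 <- simulateRoot(geom, pitFieldParams(), seed = 12)
  expect_false(identical(voxelData(s3@pd), voxelData(s1@pd)))
})
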