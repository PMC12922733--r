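mkSignal <- function(binary, maxValue = 1)
  new("VertexSignal", raw = binary, trimmed = binary,
      binary = as.numeric(binary > 0) * maxValue, maxValue = maxValue,
      nOutOfBounds = 0L)

test_that("Total Signal integrates binary coverage over the patch", {
  mesh <- buildInterfaceMesh(twoCubeLabels(0.5), cubeSize = 0.5,
                             smoothPasses = 0)
  tab <- interfaceTable(mesh)
  iCC <- tab$interface_id[tab$cell_b != 0]
  A <- tab$area_um2[iCC]
  nv <- nrow(vertices(mesh))

  ## nothing positive -> 0; everything positive -> the interface area
  expect_equal(unname(totalSignal(mesh, mkSignal(rep(0, nv)), iCC)), 0)
  expect_equal(unname(totalSignal(mesh, mkSignal(rep(1, nv)), iCC)), A,
               tolerance = 1e-12)

  ## half the patch positive -> A/2 within vertex-area discretisation
  v <- vertices(mesh)
  half <- as.numeric(v[, 2] < 5)
  S <- unname(totalSignal(mesh, mkSignal(half), iCC))
  expect_lt(abs(S / (A / 2) - 1), 0.15)

  expect_error(totalSignal(mesh, mkSignal(rep(1, nv)), 999L), "empty")
})

test_that("Signal Density is S over A", {
  expect_identical(signalDensity(0, 10), 0)
  expect_identical(signalDensity(10, 10), 1)
  expect_identical(signalDensity(25, 100), 0.25)
  expect_error(signalDensity(1, 0), "> 0")
})

test_that("sample normalization yields percentages summing to 100", {
  q <- data.frame(total_signal = c(1, 1, 2),
                  signal_density = c(0.1, 0.1, 0.2))
  out <- normalizeSample(q)
  expect_equal(out$pct_total_signal, c(25, 25, 50))
  expect_equal(out$pct_signal_density, c(25, 25, 50))
  one <- normalizeSample(data.frame(total_signal = 7, signal_density = 1))
  expect_equal(one$pct_total_signal, 100)
  expect_error(normalizeSample(data.frame(total_signal = c(0, 0),
                                          signal_density = c(0, 0))),
               "no signal")
})

test_that("Moran's I matches its printed anchor patterns", {
  ## even checkerboard with rook adjacency: exactly -1
  for (n in c(4, 8)) {
    I <- moransI(checkerboard(n), gridRookEdges(n, n))
    expect_identical(I, -1)
  }
  ## two-block half/half: (n-2)/(n-1), increasing toward +1
  vals <- vapply(c(4, 8, 16), function(n)
    moransI(twoBlock(n), gridRookEdges(n, n)), 0)
  expect_equal(vals, (c(4, 8, 16) - 2) / (c(4, 8, 16) - 1),
               tolerance = 1e-12)
  expect_true(all(diff(vals) > 0))
  ## the anchor values are invariant to which two values are used
  expect_equal(moransI(twoBlock(8, a = 3, b = 9), gridRookEdges(8, 8)),
               6 / 7, tolerance = 1e-12)
})

test_that("Moran's I equals the brute-force double loop on random graphs", {
  set.seed(404)
  for (rep in 1:25) {
    g <- randomGraph(sample(5:60, 1), pEdge = 0.15)
    expect_equal(moransI(g$x, g$edges), bruteMoransI(g$x, g$W),
                 tolerance = 1e-12)
  }
})

test_that("constant values have no defined Moran's I", {
  e <- gridRookEdges(3, 3)
  I <- moransI(rep(1, 9), e)
  expect_true(is.na(I))
  expect_identical(attr(I, "reason"), "no variance")
  expect_error(moransI(1, matrix(integer(0), 0, 2)), "at least 2")
  expect_error(moransI(c(1, 2), cbind(1L, 1L)), "self loops")
})

test_that("permutation mean of I approaches the randomization expectation", {
  set.seed(77)
  g <- randomGraph(40, pEdge = 0.12, binaryValues = TRUE)
  n <- length(g$x)
  nPerm <- 2000
  d0 <- g$x - mean(g$x)
  den <- sum(d0^2)
  W <- 2 * nrow(g$edges)
  Is <- vapply(seq_len(nPerm), function(i) {
    p <- sample.int(n)
    d <- (g$x[p] - mean(g$x))
    (n / W) * 2 * sum(d[g$edges[, 1]] * d[g$edges[, 2]]) / den
  }, 0)
  se <- stats::sd(Is) / sqrt(nPerm)
  expect_lt(abs(mean(Is) - (-1 / (n - 1))), 3 * se)
})

test_that("per-interface Moran's I flags patches without variance", {
  mesh <- buildInterfaceMesh(twoCubeLabels(0.5), cubeSize = 0.5,
                             smoothPasses = 0)
  nv <- nrow(vertices(mesh))
  allOn <- moransIInterfaces(mesh, mkSignal(rep(1, nv)))
  expect_true(all(is.na(allOn)))
  v <- vertices(mesh)
  patchy <- moransIInterfaces(mesh, mkSignal(as.numeric(v[, 3] < 5)))
  expect_true(all(!is.na(patchy)))
  ## segregated half/half pattern on a flat patch is strongly positive
  expect_true(all(patchy > 0.5))
})

test_that("quantifyInterfaces joins metrics and propagates a silent sample", {
  lv <- smallLab()
  mesh <- smallMesh()
  ann <- annotateSample(lv, mesh, c("epidermis", "cortex"))
  nv <- nrow(vertices(ann$mesh))
  set.seed(9)
  sig <- mkSignal(stats::rbinom(nv, 1, 0.3))
  out <- quantifyInterfaces(ann$mesh, sig)
  expect_true(all(out$cell_b != 0))
  expect_true(all(out$area_um2 >= 3))
  expect_equal(sum(out$pct_total_signal), 100, tolerance = 1e-9)
  expect_equal(out$signal_density, out$total_signal / out$area_um2)

  ## an all-zero marker channel propagates the normalization error
  zero <- mkSignal(rep(0, nv))
  expect_error(quantifyInterfaces(ann$mesh, zero), "no signal")
})
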