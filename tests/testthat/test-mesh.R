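singleCubeLabels <- function(h = 0.5, side = 10, pad = 4L) {
  n <- as.integer(round(side / h))
  lab <- array(0L, c(n + 2L * pad, n + 2L * pad, n + 2L * pad))
  lab[pad + seq_len(n), pad + seq_len(n), pad + seq_len(n)] <- 1L
  new("LabelVolume", labels = lab, voxelSize = rep(h, 3),
      origin = c(0, 0, 0))
}

test_that("a 10 um cube cell meshes to ~600 um^2 with one exterior patch", {
  mesh <- buildInterfaceMesh(singleCubeLabels(), cubeSize = 0.5,
                             smoothPasses = 10)
  tab <- interfaceTable(mesh)
  expect_identical(nrow(tab), 1L)
  expect_identical(tab$cell_b, 0L)
  expect_lt(abs(tab$area_um2 / 600 - 1), 0.05)
})

test_that("smoothing reduces the staircase area", {
  ## a slanted (cylindrical) surface has staircase excess before smoothing
  raw <- buildInterfaceMesh(smallLab(), cubeSize = 0.5, smoothPasses = 0)
  smooth <- smallMesh()
  expect_gt(sum(interfaceTable(raw)$area_um2),
            sum(interfaceTable(smooth)$area_um2))
})

test_that("two cubes sharing a face give one cell-cell interface of ~100 um^2", {
  mesh <- buildInterfaceMesh(twoCubeLabels(0.5), cubeSize = 0.5,
                             smoothPasses = 10)
  tab <- interfaceTable(mesh)
  cc <- tab[tab$cell_b != 0, ]
  expect_identical(nrow(cc), 1L)
  expect_identical(c(cc$cell_a, cc$cell_b), c(1L, 2L))
  expect_lt(abs(cc$area_um2 / 100 - 1), 0.05)
})

test_that("interface patches partition each cell surface exactly", {
  mesh <- smallMesh()
  tab <- interfaceTable(mesh)
  areas <- cellMeshArea(mesh)
  for (cl in as.integer(names(areas))) {
    partSum <- sum(tab$area_um2[tab$cell_a == cl | tab$cell_b == cl])
    expect_equal(partSum, unname(areas[as.character(cl)]),
                 tolerance = 1e-12)
  }
  ## every triangle belongs to exactly one interface
  expect_identical(length(mesh@triInterface), nrow(triangles(mesh)))
  ## canonical pair ordering
  cc <- tab[tab$cell_b != 0, ]
  expect_true(all(cc$cell_a < cc$cell_b))
  expect_identical(anyDuplicated(paste(tab$cell_a, tab$cell_b)), 0L)
})

test_that("mesh areas match the analytic geometry within 7%", {
  agg <- smallTruthAreas()
  tab <- extractInterfaces(smallMesh())
  mm <- merge(tab, agg, by = c("cell_a", "cell_b"))
  mm <- mm[mm$class != "exterior" & mm$area_um2.y >= 3, ]
  expect_gt(nrow(mm), 20)
  expect_true(all(abs(mm$area_um2.x / mm$area_um2.y - 1) < 0.07))

  ## the fine mesh carries >= 4x the vertices of the coarse mesh
  meshF <- memo("smallMeshF",
                buildInterfaceMesh(smallLab(), cubeSize = 0.2,
                                   smoothPasses = 10))
  expect_gte(nrow(vertices(meshF)), 4 * nrow(vertices(smallMesh())))
})

test_that("interface areas agree between cube sizes 0.2 and 0.5", {
  ## evaluated on a finely rasterised root so both meshes resolve the
  ## geometry (at coarse voxels the residual is label quantisation, not
  ## mesh resolution)
  geomF <- rootGeometry(layerRadii = c(9, 5), cellsPerRing = c(6, 4),
                        axialCellLength = 8, stackExtent = c(22, 22, 32),
                        voxelSize = 0.125,
                        layerNames = c("epidermis", "cortex"))
  lvF <- generateLabelVolume(geomF)
  tabC <- extractInterfaces(buildInterfaceMesh(lvF, 0.5, 10))
  tabF <- extractInterfaces(buildInterfaceMesh(lvF, 0.2, 10))
  mm <- merge(tabC, tabF, by = c("cell_a", "cell_b"))
  mm <- mm[mm$cell_b != 0 & mm$area_um2.x >= 3, ]
  expect_gt(nrow(mm), 20)
  expect_true(all(abs(mm$area_um2.x / mm$area_um2.y - 1) < 0.05))
})

test_that("area filter keeps the boundary value and is monotone", {
  tab <- data.frame(cell_a = 1:3, cell_b = 2:4,
                    area_um2 = c(2.9, 3.0, 3.1))
  kept <- filterInterfaces(tab, minArea = 3)
  expect_identical(nrow(kept), 2L)
  expect_true(3.0 %in% kept$area_um2)
  expect_identical(filterInterfaces(tab, 0), tab)
  counts <- vapply(seq(0, 4, by = 0.5),
                   function(a) nrow(filterInterfaces(tab, a)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("empty or surface-less label volumes are rejected", {
  empty <- new("LabelVolume", labels = array(0L, c(4, 4, 4)),
               voxelSize = c(1, 1, 1), origin = c(0, 0, 0))
  expect_error(buildInterfaceMesh(empty), "empty label volume")
})

test_that("vertex normals point from cell_a to cell_b", {
  mesh <- buildInterfaceMesh(twoCubeLabels(0.5), cubeSize = 0.5,
                             smoothPasses = 0)
  tab <- interfaceTable(mesh)
  iCC <- tab$interface_id[tab$cell_b != 0]
  sel <- mesh@triInterface == iCC
  vid <- unique(as.vector(triangles(mesh)[sel, ]))
  v <- vertices(mesh)[vid, ]
  ## patch-interior vertices (border vertices blend exterior normals);
  ## interface plane is x = 10 with cell 1 on the low-x side
  interior <- vid[v[, 2] > 1 & v[, 2] < 9 & v[, 3] > 1 & v[, 3] < 9]
  nrm <- vertexNormals(mesh)[interior, ]
  expect_true(all(nrm[, 1] > 0.9))
})
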