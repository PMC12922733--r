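test_that("root axis is recovered, translation- and rotation-equivariant", {
  lv <- smallLab()
  ax <- estimateRootAxis(lv)
  expect_gt(sum(ax@axisDirection * c(0, 0, 1)), 0.999)

  ## translating the volume leaves the direction unchanged
  shifted <- new("LabelVolume", labels = labelData(lv),
                 voxelSize = voxelSize(lv), origin = c(5, -3, 10))
  ax2 <- estimateRootAxis(shifted)
  expect_equal(ax2@axisDirection, ax@axisDirection, tolerance = 1e-9)

  ## rotating 90 degrees about x: (y, z) -> (z, -y); axis moves to y
  lab <- labelData(lv)
  nd <- dim(lab)
  rot <- aperm(lab, c(1, 3, 2))[, , rev(seq_len(nd[2]))]
  lvR <- new("LabelVolume", labels = rot,
             voxelSize = voxelSize(lv)[c(1, 3, 2)], origin = c(0, 0, 0))
  axR <- estimateRootAxis(lvR)
  ang <- acos(abs(sum(axR@axisDirection * c(0, 1, 0)))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("a near-spherical volume has no dominant axis", {
  n <- 20
  cs <- seq_len(n) - (n + 1) / 2
  ball <- array(0L, c(n, n, n))
  r2 <- outer(outer(cs^2, cs^2, "+"), cs^2, "+")
  ball[r2 <= 8^2] <- 1L
  lv <- new("LabelVolume", labels = ball, voxelSize = c(1, 1, 1),
            origin = c(0, 0, 0))
  expect_error(estimateRootAxis(lv), "no dominant axis")
})

test_that("layer assignment matches the generator and its invariances", {
  lv <- smallLab()
  ax <- estimateRootAxis(lv)
  cells <- assignCellLayers(cellTable(lv), ax, c("epidermis", "cortex"))
  truth <- truthCells(smallTruth())
  m <- merge(cells, truth[, c("label", "layer_name")], by = "label")
  expect_identical(mean(m$layer_name.x == m$layer_name.y), 1)

  ## one layer requested: everything gets it
  one <- assignCellLayers(cellTable(lv), ax, "epidermis")
  expect_true(all(one$layer_name == "epidermis"))

  ## uniform scaling leaves assignments unchanged
  ct <- cellTable(lv)
  ct[, c("centroid_x", "centroid_y", "centroid_z")] <-
    2 * ct[, c("centroid_x", "centroid_y", "centroid_z")]
  ax2 <- new("RootAxis", axisPoint = 2 * ax@axisPoint,
             axisDirection = ax@axisDirection)
  sc <- assignCellLayers(ct, ax2, c("epidermis", "cortex"))
  expect_identical(sc$layer_name, cells$layer_name)

  expect_error(assignCellLayers(ct[1, ], ax, c("a", "b")), "fewer cells")
})

## a hand-built single-patch mesh: a unit square with a given normal
planarPatchMesh <- function(normal = c(0, 0, 1), centre = c(5, 0, 0)) {
  ## orthonormal frame around the normal
  n <- normal / sqrt(sum(normal^2))
  ref <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * n) * n
  u <- u / sqrt(sum(u^2))
  w <- c(n[2] * u[3] - n[3] * u[2], n[3] * u[1] - n[1] * u[3],
         n[1] * u[2] - n[2] * u[1])
  v <- rbind(centre - u - w, centre + u - w, centre + u + w,
             centre - u + w)
  new("SurfaceMesh", vertices = v,
      triangles = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
      triInterface = c(1L, 1L),
      interfaces = data.frame(interface_id = 1L, cell_a = 1L, cell_b = 2L,
                              area_um2 = 4),
      cubeSize = 1, smoothPasses = 0L)
}

test_that("orientation classes follow the patch normal", {
  axis <- new("RootAxis", axisPoint = c(0, 0, 0),
              axisDirection = c(0, 0, 1))
  classOf <- function(normal, centre = c(5, 0, 0))
    interfaceTable(classifyInterfaceOrientation(
      planarPatchMesh(normal, centre), axis))$orientation_class
  expect_identical(classOf(c(0, 0, 1)), "apical_basal")
  expect_identical(classOf(c(1, 0, 0)), "radial")          # away from axis
  expect_identical(classOf(c(0, 1, 0)), "circumferential")
  ## normal halfway between axial and radial: ambiguous
  expect_identical(classOf(c(1, 0, 1)), "unclassified")
})

test_that("synthetic interface orientations match the generator classes", {
  mesh <- smallMesh()
  ax <- estimateRootAxis(smallLab())
  mesh <- classifyInterfaceOrientation(mesh, ax)
  agg <- smallTruthAreas()
  ## dominant truth class per pair
  best <- do.call(rbind, lapply(
    split(agg, paste(agg$cell_a, agg$cell_b)),
    function(d) d[which.max(d$area_um2), ]))
  mm <- merge(interfaceTable(mesh), best, by = c("cell_a", "cell_b"))
  mm <- mm[mm$class != "exterior" & mm$area_um2.x >= 3, ]
  expect_gte(mean(mm$orientation_class == mm$class), 0.95)
})

test_that("interaction classes are layer-pair names, order-invariant", {
  mesh <- smallMesh()
  ann <- annotateSample(smallLab(), mesh, c("epidermis", "cortex"))
  tab <- interfaceTable(ann$mesh)
  expect_setequal(unique(tab$interaction_class),
                  c("epidermis", "cortex", "cortex–epidermis",
                    "exterior"))
  ## same-layer pair collapses to the layer name
  ep <- tab[tab$interaction_class == "epidermis", ][1, ]
  truth <- truthCells(smallTruth())
  expect_identical(
    truth$layer_name[match(c(ep$cell_a, ep$cell_b), truth$label)],
    c("epidermis", "epidermis"))

  ## reversing the cell order in the annotation table changes nothing
  ann2 <- ann
  cellsRev <- ann$cells[rev(seq_len(nrow(ann$cells))), ]
  mesh2 <- nameInteractionClass(classifyInterfaceOrientation(
    smallMesh(), ann$axis), cellsRev)
  expect_identical(interfaceTable(mesh2)$interaction_class,
                   tab$interaction_class)

  ## unannotated cell is an error
  expect_error(nameInteractionClass(smallMesh(), ann$cells[-1, ]),
               "unannotated")
})

test_that("circumferential interfaces stay within a ring, radial between rings", {
  mesh <- smallMesh()
  ann <- annotateSample(smallLab(), mesh, c("epidermis", "cortex"))
  tab <- interfaceTable(ann$mesh)
  tab <- tab[tab$cell_b != 0 & tab$area_um2 >= 3 &
               tab$orientation_class != "unclassified", ]
  truth <- truthCells(smallTruth())
  ringOf <- function(l) truth$ring_index[match(l, truth$label)]
  sameRing <- ringOf(tab$cell_a) == ringOf(tab$cell_b)
  expect_true(all(sameRing[tab$orientation_class == "circumferential"]))
  expect_true(all(!sameRing[tab$orientation_class == "radial"]))
})
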