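test_that("woodpecker mesh carries all five regions, closed brain, and passes the audit", {
  m <- test_wood_mesh()
  expect_setequal(unique(m$elem_region),
                  c("beak", "hyoid", "skull", "flesh", "brain"))
  counts <- table(m$elem_region)
  expect_true(all(counts > 0))
  expect_true(audit_jacobians(m))
  expect_true(all(m$elem_area > 0))
  # triangles are a small minority
  expect_lt(nrow(m$tris) / n_elements(m), 0.05)
  # brain is interior: no brain element touches the outer boundary
  ib <- which(m$elem_region == "brain")
  brain_nodes <- unique(c(m$quads[ib[ib <= nrow(m$quads)], ]))
  expect_length(intersect(brain_nodes, m$boundary_nodes), 0)
  # reference point 117 mm below the head CM
  expect_equal(m$cm[2] - m$ref_point[2], 0.117)
})

test_that("region areas match the analytic outline areas within 1% at default resolution", {
  m <- build_simplified_woodpecker(element_size = 1e-3)
  ra <- region_areas(m)
  expect_true(all(abs(ra$mesh_area / ra$analytic_area - 1) < 0.01))
  h <- build_simplified_human(element_size = 5e-3)
  rh <- region_areas(h)
  expect_true(all(abs(rh$mesh_area / rh$analytic_area - 1) < 0.01))
})

test_that("geometric scaling of the builder is exact similarity", {
  m1 <- build_simplified_woodpecker(element_size = 2e-3)
  m05 <- build_simplified_woodpecker(scale = 0.5, element_size = 2e-3)
  expect_equal(m05$nodes, m1$nodes * 0.5, tolerance = 1e-14)
  expect_equal(sum(m05$elem_area), 0.25 * sum(m1$elem_area), tolerance = 1e-12)
  expect_equal(m05$cm[2] - m05$ref_point[2], 0.117 * 0.5)
})

test_that("feature ablation is a label-only edit of identical topology", {
  base <- build_simplified_woodpecker(element_size = 3e-3)
  noh <- build_simplified_woodpecker(element_size = 3e-3, include_hyoid = FALSE)
  expect_identical(base$nodes, noh$nodes)
  expect_identical(base$quads, noh$quads)
  expect_identical(base$tris, noh$tris)
  changed <- which(base$elem_region != noh$elem_region)
  expect_setequal(changed, which(base$elem_region == "hyoid"))
  expect_true(all(noh$elem_region[changed] == "flesh"))
  nob <- build_simplified_woodpecker(element_size = 3e-3,
                                     include_hyoid = FALSE,
                                     include_beak = FALSE)
  expect_identical(base$quads, nob$quads)
  expect_false(any(nob$elem_region %in% c("hyoid", "beak")))
})

test_that("human mesh nests brain inside subarachnoid inside skull", {
  h <- test_human_mesh()
  expect_setequal(unique(h$elem_region),
                  c("skull", "face", "neck", "subarachnoid", "brain"))
  expect_true(audit_jacobians(h))
  nodes_of <- function(rg) {
    iq <- which(h$elem_region[seq_len(nrow(h$quads))] == rg)
    unique(as.integer(h$quads[iq, ]))
  }
  bn <- nodes_of("brain"); sa <- nodes_of("subarachnoid"); sk <- nodes_of("skull")
  # brain shares nodes with the subarachnoid layer but never with skull
  expect_gt(length(intersect(bn, sa)), 0)
  expect_length(intersect(bn, sk), 0)
  expect_length(intersect(bn, h$boundary_nodes), 0)
  expect_length(intersect(sa, h$boundary_nodes), 0)
  expect_equal(h$cm[2] - h$ref_point[2], 0.191)
})

test_that("human head at one-tenth scale has approximately the woodpecker brain area", {
  w <- test_wood_mesh()
  h01 <- scale_head(test_human_mesh(), 0.1, lever_arm = w$lever_arm)
  bw <- sum(w$elem_area[w$elem_region == "brain"])
  bh <- sum(h01$elem_area[h01$elem_region == "brain"])
  expect_equal(bh / bw, 1, tolerance = 0.20)
})

test_that("halving the element size roughly quadruples the element count", {
  n1 <- n_elements(build_simplified_woodpecker(element_size = 2e-3))
  n2 <- n_elements(build_simplified_woodpecker(element_size = 1e-3))
  expect_gt(n2 / n1, 2.8)
  expect_lt(n2 / n1, 5.5)
})

test_that("scale_head is identity at factor 1 and exact similarity otherwise", {
  m <- test_wood_mesh()
  m1 <- scale_head(m, 1)
  expect_equal(m1$nodes, m$nodes)
  m25 <- scale_head(m, 0.25, lever_arm = 0.117)
  expect_equal(sum(m25$elem_area), sum(m$elem_area) / 16, tolerance = 1e-12)
  # scaling is about the CM: CM itself is unchanged
  expect_equal(m25$cm, m$cm)
  expect_equal(m25$ref_point, m$cm - c(0, 0.117))
  # 2D mass scales with the square of the factor
  lib <- material_library()
  expect_equal(sum(assemble_lumped_mass(m25, lib)),
               sum(assemble_lumped_mass(m, lib)) / 16, tolerance = 1e-12)
})

test_that("too-coarse meshing fails naming the unresolvable region", {
  expect_error(build_simplified_human(element_size = 12e-3), "subarachnoid")
})

test_that("mesh exports are well-formed", {
  m <- patch_mesh(2, 2, 1, 1)
  f <- tempfile(fileext = ".vtk")
  write_vtk(m, f, cell_data = list(x = rep(1, 4)))
  lines <- readLines(f)
  expect_true(any(grepl("DATASET UNSTRUCTURED_GRID", lines)))
  expect_true(any(grepl("CELLS 4 20", lines)))
  stem <- tempfile()
  write_mesh_text(m, stem)
  nd <- read.csv(paste0(stem, "_nodes.csv"))
  expect_equal(nrow(nd), 9)
  el <- read.csv(paste0(stem, "_elements.csv"))
  expect_equal(el$region, rep("brain", 4))
})
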