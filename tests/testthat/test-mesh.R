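test_that("mesher honours the requested element count and populates sets", {
  p <- globe_params()
  for (res in c(200, 1000)) {
    m <- generate_mesh(p, resolution = res)
    expect_lt(abs(nrow(m$conn) / res - 1), 0.2)
    s <- m$sets
    expect_gt(nrow(s$inner_faces), 0)
    expect_gt(nrow(s$outer_faces), 0)
    expect_gt(length(s$airpuff_idx), 0)
    expect_gt(length(s$sagittal_nodes), 0)
    expect_gt(length(s$axial_nodes), 0)
    # the air-puff patch is a subset of the outer surface
    expect_true(all(s$airpuff_idx %in% seq_len(nrow(s$outer_faces))))
    # the posterior pole node lies on the sagittal section (and axial plane)
    expect_true(s$pole_node %in% s$sagittal_nodes)
    expect_true(s$pole_node %in% s$axial_nodes)
    expect_equal(m$nodes[s$pole_node, ], c(-9, 0, 0), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # sagittal nodes lie on the symmetry plane
    expect_lt(max(abs(m$nodes[s$sagittal_nodes, 3])), 1e-9)
  }
})

test_that("all elements have positive jacobians, including collapsed poles", {
  m <- generate_mesh(globe_params(), resolution = 300)
  expect_gt(min(scleraAPDI:::.min_detJ(m$nodes, m$conn)), 0)
})

test_that("at least two elements span the wall and coarse meshes error", {
  m <- generate_mesh(globe_params(), resolution = 200)
  expect_gte(m$divisions$ns, 2)
  expect_error(generate_mesh(globe_params(), resolution = 200, ns = 1),
               "meshing error")
})

test_that("mesh volume matches the cross-section quadrature oracle", {
  p <- globe_params()
  cs <- build_globe_cross_section(p)
  V_exact <- cross_section_volume(cs)
  m <- generate_mesh(p, resolution = 400)
  expect_lt(abs(mesh_volume(m) / V_exact - 1), 0.01)
  # refinement converges further
  m2 <- generate_mesh(p, resolution = 1600)
  expect_lt(abs(mesh_volume(m2) / V_exact - 1),
            abs(mesh_volume(m) / V_exact - 1))
})

test_that("2x refinement in each direction grows the count 4-8x", {
  m1 <- generate_mesh(globe_params(), resolution = 250)
  m2 <- generate_mesh(globe_params(), resolution = 250 * 4)
  ratio <- nrow(m2$conn) / nrow(m1$conn)
  expect_gte(ratio, 3.2)
  expect_lte(ratio, 8)
  expect_gt(min(scleraAPDI:::.min_detJ(m2$nodes, m2$conn)), 0)
})

test_that("axial coordinate map is anchored at the equator and posterior pole", {
  m <- generate_mesh(globe_params(AL = 18), resolution = 300)
  ax <- compute_axial_coordinates(m)
  expect_equal(ax$x_f, 9)
  sclera <- m$region == "sclera"
  # posterior-most element centroids approach x_f
  expect_gt(max(ax$x[sclera]), 0.9 * ax$x_f)
  expect_lt(max(ax$x[sclera]), ax$x_f)
  # elements straddling the equator have |x| small relative to the globe
  expect_lt(min(abs(ax$x[sclera])), 0.5)
  # anterior scleral elements have negative x, cornea is the most anterior
  expect_lt(min(ax$x), 0)
  expect_equal(ax$x[which.min(ax$x)],
               ax$x[m$region == "cornea"][which.min(ax$x[m$region == "cornea"])])
})

test_that("circle-limit geometry gives x_f = AL/2 = 9", {
  m <- tiny_sphere_mesh()
  ax <- compute_axial_coordinates(m)
  expect_equal(ax$x_f, 9.5)  # AL/2 for the 19-mm sphere
  expect_lt(max(ax$x), ax$x_f)
  expect_gt(max(ax$x), 0.9 * ax$x_f)
})

test_that("vtk export writes a well-formed quadratic-hex file", {
  m <- generate_mesh(globe_params(), resolution = 200)
  f <- tempfile(fileext = ".vtk")
  write_mesh_vtk(m, f)
  lines <- readLines(f)
  expect_equal(lines[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("^POINTS", lines)))
  expect_true(any(grepl(sprintf("^CELLS %d", nrow(m$conn)), lines)))
  expect_equal(sum(lines == "25"), nrow(m$conn))
  unlink(f)
})

test_that("the half model spans the full upper-lower range and solves", {
  m <- generate_mesh(globe_params(), resolution = 200, model = "half")
  expect_lt(abs(nrow(m$conn) / 200 - 1), 0.2)
  expect_gt(min(scleraAPDI:::.min_detJ(m$nodes, m$conn)), 0)
  # azimuth reaches below the axial plane: some nodes have negative y
  expect_lt(min(m$nodes[, 2]), -1)
  expect_gte(min(m$nodes[, 3]), -1e-9)   # still one side of the sagittal plane
  # no axial-plane constraint in the half model
  b <- boundary_conditions(m)
  ring <- setdiff(which(abs(m$nodes[, 2]) < 1e-9 & abs(m$nodes[, 3]) > 1),
                  m$sets$pole_node)
  expect_false(any((3L * ring - 1L) %in% b$dofs))
  # the half model agrees with the quarter model on the baseline response
  f <- material_field(m)
  sf <- stress_free_iterate(m, f, b, iop_mmhg = 18)
  sol <- run_airpuff(sf)
  out <- compute_output_params(
    extract_sagittal_profile(sol, 1),
    extract_sagittal_profile(sol, nrow(sol$steps) - 1))
  quarter <- tiny_globe_forward()
  expect_equal(out$AD, quarter$outputs$AD, tolerance = 0.06)
})
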