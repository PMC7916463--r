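test_that("material table carries the literature property values exactly", {
  mt <- material_table()
  expect_identical(mt$fat$optical$mu_a, 3)
  expect_identical(mt$fat$optical$mu_s_prime, 950)
  expect_identical(mt$gland$optical$mu_a, 6)
  expect_identical(mt$gland$optical$mu_s_prime, 1100)
  expect_identical(mt$fat$thermo$c, 2348)
  expect_identical(mt$fat$thermo$lambda_37, 0.21)
  expect_identical(mt$fat$thermo$rho, 911)
  expect_identical(mt$fat$thermo$q_met, 400)
  expect_identical(mt$fat$thermo$omega_b0, 2e-4)
  expect_identical(mt$gland$thermo$c, 2960)
  expect_identical(mt$gland$thermo$lambda_37, 0.48)
  expect_identical(mt$gland$thermo$rho, 1041)
  expect_identical(mt$gland$thermo$q_met, 700)
  expect_identical(mt$gland$thermo$omega_b0, 5e-4)
  bl <- blood_properties()
  expect_identical(bl$rho_b, 1050)
  expect_identical(bl$c_b, 3617)
})

test_that("derived optical quantities follow the diffusion-approximation formulas", {
  set.seed(7)
  for (i in 1:20) {
    mua <- runif(1, 0.1, 200)
    mus <- runif(1, 0, 2000)
    op <- optical_properties(mua, mus)
    expect_equal(op$mu_tr, mua + mus)
    expect_equal(op$D, 1 / (3 * (mua + mus)))
    expect_equal(op$mu_eff, sqrt(3 * mua * (mua + mus)))
  }
  # absorption-only limit
  op0 <- optical_properties(10, 0)
  expect_equal(op0$mu_eff, sqrt(3) * 10)
  expect_error(optical_properties(-1, 10), "mu_a")
})

test_that("default breast phantom hosts a resolved 2x2 seed array around P1", {
  ph <- build_breast_phantom()
  ax <- ph$seeds$axes
  expect_equal(nrow(ax), 4L)
  # pairwise centre-to-centre distances: 5 mm sides, 7.07 mm diagonals
  dd <- as.numeric(dist(ax))
  expect_equal(sort(dd), sort(c(5e-3, 5e-3, 5e-3, 5e-3,
                                sqrt(2) * 5e-3, sqrt(2) * 5e-3)))
  # the four seeds are disjoint single-voxel columns on the 1 mm grid
  seed_xy <- which(apply(ph$labels == "seed", c(1, 2), any), arr.ind = TRUE)
  expect_equal(nrow(seed_xy), 4L)
  # each column spans the seed length
  nz <- sum(ph$labels[seed_xy[1, 1], seed_xy[1, 2], ] == "seed")
  expect_equal(nz * ph$spacing, 0.015, tolerance = 0.1)
  # P1 sits at the centroid of the array
  expect_equal(ph$probes$P1, c(0.03, 0.03, 0.03))
  expect_true(ph$labels[probe_index(ph, "P1")[1],
                        probe_index(ph, "P1")[2],
                        probe_index(ph, "P1")[3]] != "seed")
})

test_that("zero-seed phantom keeps the fat/gland layering and a central P1", {
  cfg <- breast_phantom_config(seed_rows = 0, seed_cols = 0)
  ph0 <- build_breast_phantom(cfg)
  expect_setequal(unique(as.vector(ph0$labels)), c("fat", "gland"))
  expect_equal(ph0$probes$P1, c(0.03, 0.03, 0.03))
  # relabeling with seeds leaves every non-seed voxel unchanged
  ph <- build_breast_phantom()
  keep <- ph$labels != "seed"
  expect_identical(ph$labels[keep], ph0$labels[keep])
  # fat layer along the beam axis
  expect_true(all(ph0$labels[, , 1:10] == "fat"))
  expect_true(all(ph0$labels[, , 11:60] == "gland"))
})

test_that("voxelized seed volume approaches the analytic cylinder volume", {
  cfg <- small_seed_config(spacing = 2.5e-4)
  ph <- build_breast_phantom(cfg)
  vox_vol <- sum(ph$labels == "seed") * ph$spacing^3
  analytic <- pi * (1e-3 / 2)^2 * 0.015
  expect_lt(abs(vox_vol - analytic) / analytic, 0.15)
})

test_that("impossible seed geometries are rejected", {
  # array wider than the block
  cfg <- breast_phantom_config(seed_spacing = 0.08)
  expect_error(build_breast_phantom(cfg), "bounds")
  # spacing coarser than the seed diameter
  cfg <- breast_phantom_config(spacing = 2e-3)
  expect_error(build_breast_phantom(cfg), "resolution")
  # seed axis falling between voxel centres must not vanish silently
  cfg <- breast_phantom_config(block = c(0.045, 0.045, 0.045))
  expect_error(build_breast_phantom(cfg), "vanish")
  # seeds must sit in the gland layer
  cfg <- breast_phantom_config(fat_thickness = 0.025)
  expect_error(build_breast_phantom(cfg), "gland")
})

test_that("water model reproduces the bench geometry", {
  ph <- build_water_model()
  # cubic seed of side 0.5 cm -> volume 0.125 cm^3 (exact on an aligned grid)
  v_seed <- sum(ph$labels == "seed") * ph$spacing^3
  expect_equal(v_seed, 0.125e-6, tolerance = 0.05)
  # water volume close to the configured 0.5 mL
  v_water <- sum(ph$labels == "water") * ph$spacing^3
  expect_equal(v_water, 0.5e-6, tolerance = 0.1)
  expect_true(all(c("bottom", "P1") %in% names(ph$probes)))
  # bottom probe lies in/on the seed
  bi <- probe_index(ph, "bottom")
  expect_equal(unname(ph$labels[bi[1], bi[2], bi[3]]), "seed")

  # water-only configuration has no seed voxels
  ph0 <- build_water_model(water_model_config(cube_side = 0))
  expect_setequal(unique(as.vector(ph0$labels)), c("air", "water"))

  # container arithmetic
  expect_equal(water_column_height(0.5e-6, 0.0045), 0.00786, tolerance = 1e-3)
  expect_error(build_water_model(water_model_config(cube_side = 0.02)),
               "geometry error")
})

test_that("probe lookup and property-field expansion are consistent", {
  ph <- build_breast_phantom()
  expect_error(probe_index(ph, "nope"), "unknown probe")
  expect_error(probe_index(ph, c(1, 1, 1)), "outside")
  f <- phantom_fields(ph)
  n <- prod(ph$dims)
  expect_true(all(lengths(f) == n))
  labs <- as.vector(ph$labels)
  expect_equal(unique(f$rho_c[labs == "gland"]), 1041 * 2960)
  expect_equal(unique(f$qmet[labs == "fat"]), 400)
  expect_equal(unique(f$perf0[labs == "gland"]), 1050 * 3617 * 5e-4)
  expect_equal(unique(f$perf0[labs == "seed"]), 0)
  expect_equal(unique(f$lambda37[labs == "seed"]), 0.16)
})

test_that("phantom VTK export round-trips dimensions and label counts", {
  ph <- build_breast_phantom(small_seed_config())
  p <- tempfile(fileext = ".vtk")
  write_phantom_vtk(ph, p)
  lines <- readLines(p)
  expect_equal(lines[5], sprintf("DIMENSIONS %d %d %d", ph$dims[1],
                                 ph$dims[2], ph$dims[3]))
  codes <- as.integer(lines[-(1:10)])
  expect_equal(length(codes), prod(ph$dims))
  expect_equal(sum(codes == match("seed", sort(unique(as.vector(ph$labels))))),
               sum(ph$labels == "seed"))
})
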