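test_that("grid construction matches analytic sphere volume and set algebra", {
  # single inclusion sphere r = 5 at spacing 0.5: count * 0.125 ~ 4/3 pi r^3
  g <- build_grid(sphere_spec(c(0, 0, 0), 5), spec = grid_spec(0.5, 0))
  expect_equal(g$n_points * 0.125, 4 / 3 * pi * 125,
               tolerance = 0.02)

  # congruent exclusion removes everything
  g0 <- build_grid(sphere_spec(c(0, 0, 0), 5),
                   exclusion = sphere_spec(c(0, 0, 0), 5,
                                           role = "exclusion"),
                   spec = grid_spec(0.5, 0))
  expect_equal(g0$n_points, 0)

  # disjoint inclusion spheres add up
  s1 <- sphere_spec(c(0, 0, 0), 3)
  s2 <- sphere_spec(c(100, 0, 0), 4)
  g12 <- build_grid(list(s1, s2), spec = grid_spec(1, 0))
  g1 <- build_grid(s1, spec = grid_spec(1, 0))
  g2 <- build_grid(s2, spec = grid_spec(1, 0))
  expect_equal(g12$n_points, g1$n_points + g2$n_points)

  expect_error(build_grid(list()), "inclusion")
})

test_that("pocket volume removes clashes at vdW + padding", {
  g <- build_grid(sphere_spec(c(0, 0, 0), 6), spec = grid_spec(0.5, 1.09))

  # no protein atoms: candidate volume unchanged
  pk0 <- pocket_volume(g, NULL)
  expect_equal(pk0$volume, g$n_points * 0.125)

  # a single carbon at the centre carves ~ 4/3 pi (1.7 + 1.09)^3
  atom <- mol_structure(data.frame(
    name = "C", element = "C", chain = "A", res_num = 1L, res_name = "GLY",
    x = 0, y = 0, z = 0, is_hetero = FALSE
  ), id = "one-atom")
  pk1 <- pocket_volume(g, atom)
  removed <- pk0$volume - pk1$volume
  expect_equal(removed, 4 / 3 * pi * (1.70 + 1.09)^3, tolerance = 0.03)

  # hydrogens do not clash
  h <- atom
  h$atoms$element <- "H"
  h$atoms$vdw <- 1.2
  expect_equal(pocket_volume(g, h)$volume, pk0$volume)
})

test_that("hollow-shell fixtures reproduce their closed-form volumes", {
  fx <- make_pocket_fixture("sphere_core")
  expect_equal(fx$accessible_radius, 9 - 1.7 - 1.09)
  expect_equal(fx$analytic_volume, 4 / 3 * pi * (9 - 1.7 - 1.09)^3)

  g <- build_grid(fx$inclusion, spec = grid_spec(1.0, fx$padding))
  pk <- pocket_volume(g, fx$structure)
  expect_equal(pk$volume, fx$analytic_volume, tolerance = 0.03)

  fb <- make_pocket_fixture("box_core", wall_atom_spacing = 0.7)
  gb <- build_grid(fb$inclusion, spec = grid_spec(0.5, fb$padding))
  pkb <- pocket_volume(gb, fb$structure)
  expect_equal(pkb$volume, fb$analytic_volume, tolerance = 0.04)

  # coarse walls would leak: the generator refuses
  err <- tryCatch(make_pocket_fixture(wall_atom_spacing = 5), error = identity)
  expect_s3_class(err, "ligmodes_usage_error")
  expect_match(conditionMessage(err), "leak")
})

test_that("volume is monotone in padding and in protein size", {
  fx <- make_pocket_fixture()
  g <- build_grid(fx$inclusion, spec = grid_spec(1.0, 0))
  vols <- vapply(c(0, 0.5, 1.09, 2), function(p) {
    pocket_volume(g, fx$structure, grid_spec(1.0, p))$volume
  }, 1.0)
  expect_false(is.unsorted(rev(vols)))

  half <- fx$structure
  half$atoms <- half$atoms[seq_len(nrow(half$atoms) %/% 2), ]
  expect_gte(pocket_volume(g, half, grid_spec(1.0, 1.09))$volume,
             pocket_volume(g, fx$structure, grid_spec(1.0, 1.09))$volume)
})

test_that("ligand occupancy counts lattice points within the search radius", {
  # pocket = free sphere; ligand atom exactly on an interior lattice point
  g <- build_grid(sphere_spec(c(0, 0, 0), 6), spec = grid_spec(1, 0))
  pk <- pocket_volume(g, NULL)
  lig1 <- matrix(c(0, 0, 0), 1)
  occ <- ligand_occupied_volume(pk, lig1, search_radius = 1.6)
  # direct enumeration of unit-lattice offsets within 1.6 of the origin:
  # centre (1) + face neighbours at 1 (6) + edge neighbours at sqrt(2) (12)
  offsets <- as.matrix(expand.grid(-2:2, -2:2, -2:2))
  n_expected <- sum(sqrt(rowSums(offsets^2)) <= 1.6)
  expect_equal(n_expected, 19)
  expect_equal(occ$n_points, n_expected)
  expect_equal(occ$ligand_volume, n_expected)

  # monotone non-decreasing in search radius, saturating at pocket volume
  radii <- c(0.5, 1.0, 1.6, 2.5, 4, 1000)
  vols <- vapply(radii, function(r) {
    ligand_occupied_volume(pk, lig1, r)$ligand_volume
  }, 1.0)
  expect_false(is.unsorted(vols))
  expect_equal(vols[length(vols)], pk$volume)

  # far-away ligand occupies nothing
  far <- ligand_occupied_volume(pk, matrix(c(500, 0, 0), 1), 1.6)
  expect_equal(far$ligand_volume, 0)

  err <- tryCatch(
    ligand_occupied_volume(pk, data.frame(element = "H", x = 0, y = 0, z = 0)),
    error = identity
  )
  expect_s3_class(err, "ligmodes_usage_error")
})

test_that("common pocket is the arithmetic mean of cross-occupancies", {
  expect_equal(common_pocket(100, 50), 75)
  expect_equal(common_pocket(42.5, 42.5), 42.5)
  expect_error(common_pocket(-1, 5), ">= 0")

  # composition with occupancy results
  g <- build_grid(sphere_spec(c(0, 0, 0), 5), spec = grid_spec(1, 0))
  pk <- pocket_volume(g, NULL)
  o1 <- ligand_occupied_volume(pk, matrix(c(0, 0, 0), 1), 1.6)
  o2 <- ligand_occupied_volume(pk, matrix(c(2, 0, 0), 1), 2.5)
  expect_equal(common_pocket(o1, o2),
               (o1$ligand_volume + o2$ligand_volume) / 2)
})

test_that("volumes are stable under joint rigid motion up to lattice phase", {
  fx <- make_pocket_fixture()
  spec <- grid_spec(1.0, fx$padding)
  pk <- pocket_volume(build_grid(fx$inclusion, spec = spec), fx$structure, spec)

  set.seed(41)
  r <- random_rotation()
  shift <- rnorm(3, sd = 15)
  moved <- transform_structure(fx$structure, r, shift)
  incl_moved <- sphere_spec(as.numeric(r %*% fx$inclusion$center + shift),
                            fx$inclusion$radius)
  pk_moved <- pocket_volume(build_grid(incl_moved, spec = spec), moved, spec)
  expect_equal(pk_moved$volume, pk$volume, tolerance = 0.05)
})

test_that("flood fill keeps only the component holding the seed", {
  s1 <- sphere_spec(c(0, 0, 0), 4)
  s2 <- sphere_spec(c(50, 0, 0), 4)
  g <- build_grid(list(s1, s2), spec = grid_spec(1, 0))
  pk <- pocket_volume(g, NULL)
  only1 <- connected_component(pk, c(0, 0, 0))
  g1 <- build_grid(s1, spec = grid_spec(1, 0))
  expect_equal(only1$n_points, g1$n_points)
})

test_that("grids dump as PDB pseudo-atom files", {
  g <- build_grid(sphere_spec(c(0, 0, 0), 3), spec = grid_spec(1, 0))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_grid_pdb(g, f)
  expect_equal(nrow(read_structure(f)$atoms), g$n_points)
})
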