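test_that("surface tension closed forms and error handling", {
  # constant (0, 0, 100) bar over L_z = 200 A: gamma = 100 mN/m exactly
  tr <- generate_pressure_trace(c(0, 0, 100), sigma = 0, n_samples = 50,
                                L_z = 200, seed = 1)
  st <- surface_tension(tr)
  expect_equal(st$gamma, 100, tolerance = 1e-12)
  expect_equal(st$se, 0, tolerance = 1e-12)

  # isotropic trace: gamma = 0 within error
  iso <- generate_pressure_trace(c(200, 200, 200), sigma = 30,
                                 n_samples = 5000, L_z = 150, seed = 2)
  sti <- surface_tension(iso, block_count = 5)
  expect_lt(abs(sti$gamma), 3 * sti$se)

  expect_error(surface_tension(tr, block_count = 100), "blocks")
})

test_that("the surface-pressure identity holds for every emitted result", {
  expect_equal(surface_pressure(40.05), 0, tolerance = 1e-12)
  expect_equal(surface_pressure(0), 80.1)
  expect_equal(surface_pressure(30), 20.1, tolerance = 1e-12)
  for (seed in 1:5) {
    tr <- generate_pressure_trace(c(0, 0, 20 * seed), sigma = 25,
                                  n_samples = 400, L_z = 200, seed = seed)
    st <- surface_tension(tr)
    expect_equal(st$pi, st$gamma_water_vacuum - 2 * st$gamma, tolerance = 1e-12)
  }
  # overridable clean-interface constant
  st <- surface_tension(generate_pressure_trace(c(0, 0, 0), 1, 100, 200, 3),
                        gamma_water_vacuum = 72)
  expect_equal(st$pi, 72 - 2 * st$gamma, tolerance = 1e-12)
})

test_that("gamma estimator is unbiased across many seeds", {
  gammas <- vapply(1:60, function(s) {
    surface_tension(generate_pressure_trace(c(0, 0, 100), sigma = 60,
                                            n_samples = 800, L_z = 200,
                                            seed = s))$gamma
  }, numeric(1))
  se <- stats::sd(gammas) / sqrt(length(gammas))
  expect_lt(abs(mean(gammas) - 100), 3 * se)
})

test_that("area per molecule reproduces the monolayer arithmetic", {
  expect_equal(area_per_molecule(c(67, 67, 200), 64), 70.140625)
  expect_equal(area_per_molecule(c(44, 44, 200), 64), 30.25)
  expect_equal(area_per_molecule(c(1, 1, 1), 1), 1)
  expect_error(area_per_molecule(c(10, 10, 10), 0), ">= 1")
  mono <- build_monolayer_slab(n_chl = 16, S_A_per_mol = 70, seed = 1,
                               water = list(thickness = 10, density = 0.005,
                                            min_dist = 2.5))
  expect_equal(area_per_molecule(mono$configuration, 16), 70, tolerance = 1e-9)
})

test_that("tilt angles follow the leaflet convention", {
  # hand-built: one upright molecule per leaflet, one in-plane molecule
  mk_chl <- function(c3, c25, mol) {
    list(names = c("C3", "C25", "O1", "H1"),
         coords = rbind(c3, c25, c3 + c(0, 0, -0.5), c3 + c(0, 0, -1)),
         mol = rep(mol, 4))
  }
  a <- mk_chl(c(10, 10, 70), c(10, 10, 87), 1L)    # upper, axis along -z: upright
  b <- mk_chl(c(20, 10, 70), c(3, 10, 70), 2L)     # upper, in-plane
  cfg <- configuration(c(a$names, b$names), rbind(a$coords, b$coords),
                       c(40, 40, 120), molecule_ids = c(a$mol, b$mol))
  ta <- tilt_angles(cfg, infer_topology(cfg), midplane = 60)
  expect_equal(unname(ta$theta_z[1]), 0, tolerance = 1e-9)
  expect_equal(unname(ta$theta_z[2]), 90, tolerance = 1e-9)

  # zero-length axis errors, naming the molecule
  z <- mk_chl(c(5, 5, 70), c(5, 5, 70), 3L)
  zc <- configuration(z$names, z$coords, c(40, 40, 120), molecule_ids = z$mol)
  expect_error(tilt_angles(zc, infer_topology(zc), midplane = 60),
               "zero-length")
})

test_that("generated monolayers recover their planted mean tilt within 2 degrees", {
  mono <- build_monolayer_slab(n_chl = 256L, S_A_per_mol = 70, tilt_mean = 30,
                               tilt_kappa = 60, seed = 8,
                               water = list(thickness = 10, density = 0,
                                            min_dist = 2.5))
  ta <- tilt_angles(mono$configuration, mono$topology)
  expect_lt(abs(mean(ta$theta_z) - 30), 2)
  # and against the generator's own ground truth, angle by angle
  expect_equal(sort(unname(ta$theta_z)), sort(mono$tilt_true), tolerance = 1e-9)
})

test_that("dipole angles and the Jacobian-corrected isotropic limit", {
  # a water with both hydrogens pointing along -outward-normal measures 180
  w <- water_with_bisector(c(10, 10, 80), c(0, 0, -1))
  cfg <- configuration(c("OW", "HW1", "HW2"), w, c(40, 40, 120),
                       molecule_ids = rep(1L, 3))
  da <- dipole_angles(cfg, infer_topology(cfg), "water", midplane = 60)
  expect_equal(unname(da$theta_z[1]), 180, tolerance = 1e-9)

  # constructed ensemble peaked at 102 degrees shows its mode there
  n <- 2000
  ang <- with_seed(4, pmin(pmax(stats::rnorm(n, 102, 4), 1), 179))
  phis <- with_seed(5, stats::runif(n, 0, 2 * pi))
  coords <- do.call(rbind, lapply(seq_len(n), function(k) {
    th <- ang[k] * pi / 180
    dir <- c(sin(th) * cos(phis[k]), sin(th) * sin(phis[k]), cos(th))
    water_with_bisector(c(10 + (k %% 5), 10 + (k %% 7), 80), dir)
  }))
  ens <- configuration(rep(c("OW", "HW1", "HW2"), n), coords, c(40, 40, 120),
                       molecule_ids = rep(seq_len(n), each = 3))
  de <- dipole_angles(ens, infer_topology(ens), "water", midplane = 60,
                      bin_width = 4)
  expect_equal(peak_angle(de$distribution), 102)
  # density integrates to one
  expect_equal(sum(de$distribution$density) * 4, 1, tolerance = 1e-6)

  # isotropic orientations: flat under the sin(theta) Jacobian correction
  n <- 6000
  u <- with_seed(6, stats::runif(n, -1, 1))
  ph <- with_seed(7, stats::runif(n, 0, 2 * pi))
  coords <- do.call(rbind, lapply(seq_len(n), function(k) {
    s <- sqrt(1 - u[k]^2)
    water_with_bisector(c(10, 10, 80), c(s * cos(ph[k]), s * sin(ph[k]), u[k]))
  }))
  iso <- configuration(rep(c("OW", "HW1", "HW2"), n), coords, c(40, 40, 120),
                       molecule_ids = rep(seq_len(n), each = 3))
  di <- dipole_angles(iso, infer_topology(iso), "water", midplane = 60,
                      bin_width = 10, jacobian = "sin")
  expect_lt(max(abs(di$distribution$density * 180 - 1)), 0.2)

  # cholesterol hydroxyl vector
  ch <- configuration(c("C3", "C25", "O1", "H1"),
                      rbind(c(5, 5, 70), c(5, 5, 87), c(5, 5, 69), c(5, 5, 68.2)),
                      c(40, 40, 120), molecule_ids = rep(1L, 4))
  dc <- dipole_angles(ch, infer_topology(ch), "chol_oh", midplane = 60)
  expect_equal(unname(dc$theta_z[1]), 180, tolerance = 1e-9)  # O->H along -z, outward +z
})

test_that("interfacial water selection uses an inclusive minimum-image cutoff", {
  # two waters at 6.9 and exactly 7.0 A from a hydroxyl oxygen, one beyond
  chl <- rbind(c(10, 10, 52), c(10, 10, 69), c(10, 10, 51), c(10, 10, 50.2))
  w1 <- water_with_bisector(c(10, 10, 44.1), c(0, 0, 1))   # 6.9 from O1
  w2 <- water_with_bisector(c(10, 10, 44.0), c(0, 0, 1))   # 7.0 exactly
  w3 <- water_with_bisector(c(10, 10, 42.0), c(0, 0, 1))   # 9.0
  # and one reached only through the periodic x boundary: raw dx 33, image 7
  w4 <- water_with_bisector(c(37, 10, 51), c(0, 0, 1))
  chl[3, 1] <- 4  # hydroxyl O at x = 4 -> |37 - 4 - 40| = 7 via the image
  w1[, 1] <- 4; w2[, 1] <- 4; w3[, 1] <- 4
  cfg <- configuration(
    c("C3", "C25", "O1", "H1", rep(c("OW", "HW1", "HW2"), 4)),
    rbind(chl, w1, w2, w3, w4),
    c(40, 40, 120),
    molecule_ids = c(rep(1L, 4), rep(2:5, each = 3))
  )
  topo <- infer_topology(cfg)
  sel <- select_interfacial_water(cfg, topo, cutoff = 7)
  expect_true(all(c(2L, 3L) %in% sel))   # 6.9 and the inclusive 7.0
  expect_false(4L %in% sel)              # 9.0 is out
  expect_true(5L %in% sel)               # periodic image at exactly 7.0
  expect_error(select_interfacial_water(
    subset_configuration(cfg, 5:16), infer_topology(subset_configuration(cfg, 5:16)),
    7), "cholesterol")
})

test_that("interfacial selection ranking is stable across 5-10 A cutoffs", {
  mono <- build_monolayer_slab(n_chl = 16, S_A_per_mol = 70, seed = 3,
                               water = list(thickness = 24, density = 0.022,
                                            min_dist = 2.5), box_z = 120)
  cfg <- mono$configuration; topo <- mono$topology
  z <- cfg$coords[topo$water$O, 3]
  mid <- mean(z)
  depth <- -abs(z - mid)  # deeper = more negative
  prev <- NULL
  for (cut in c(5, 6, 7, 8, 10)) {
    sel <- select_interfacial_water(cfg, topo, cut)
    isel <- topo$water$mol %in% sel
    # selected waters sit nearer the interfaces (further from the midplane)
    # than unselected ones, at every cutoff in the 5-10 A range
    expect_lt(mean(depth[isel]), mean(depth[!isel]))
    if (!is.null(prev)) expect_true(all(prev %in% sel))  # nested in cutoff
    prev <- sel
  }
})
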