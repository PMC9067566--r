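test_that("cell and brute neighbour searches return identical graphs", {
  for (seed in 1:10) {
    cfg <- with_seed(seed, {
      n <- sample(80:200, 1)
      box <- c(stats::runif(1, 14, 30), stats::runif(1, 14, 30),
               stats::runif(1, 25, 60))
      configuration(rep("OW", n),
                    cbind(stats::runif(n) * box[1], stats::runif(n) * box[2],
                          stats::runif(n) * box[3]),
                    box, molecule_ids = seq_len(n))
    })
    gb <- neighbor_list(cfg, 3.5, "brute")
    gc <- neighbor_list(cfg, 3.5, "cell")
    key <- function(g) {
      p <- g$pairs[order(g$pairs$i, g$pairs$j), ]
      rownames(p) <- NULL
      p
    }
    expect_equal(key(gc), key(gb), tolerance = 1e-12)
  }
})

test_that("neighbour cutoff is inclusive and preconditions are checked", {
  cfg <- configuration(c("OW", "OW", "OW"),
                       rbind(c(1, 1, 1), c(4.5, 1, 1), c(1, 4.4, 1)),
                       c(50, 50, 50), molecule_ids = 1:3)
  g <- neighbor_list(cfg, 3.5, "brute")  # distances exactly 3.5 and 3.4
  expect_identical(nrow(g$pairs), 2L)
  expect_true(any(abs(g$pairs$r - 3.5) < 1e-12))
  small <- configuration(c("OW", "OW"), rbind(c(1, 1, 1), c(3, 3, 3)),
                         c(8, 8, 8), molecule_ids = 1:2,
                         periodic = c(TRUE, TRUE, TRUE))
  expect_error(neighbor_list(small, 4.5, "cell"), "brute")
  expect_error(neighbor_list(cfg, -1), "positive")
})

test_that("q_0 is 1 and zero-neighbour molecules are flagged undefined", {
  cfg <- configuration(rep("OW", 3),
                       rbind(c(5, 5, 5), c(7, 5, 5), c(40, 40, 40)),
                       c(50, 50, 50), molecule_ids = 1:3,
                       periodic = c(FALSE, FALSE, FALSE))
  g <- neighbor_list(cfg, 3, "brute")
  q0 <- steinhardt_q(cfg, g, 0)
  expect_equal(q0$q[1:2], c(1, 1), tolerance = 1e-12)
  expect_true(is.na(q0$q[3]))
  q6 <- steinhardt_q(cfg, g, 6)
  expect_true(is.na(q6$q[3]))
})

test_that("q6 matches the independent spherical-harmonic oracle values", {
  ic <- build_ice_lattice("Ic", c(2, 2, 2))
  g <- neighbor_list(ic, 3.5, "brute")
  q6 <- steinhardt_q(ic, g, 6)
  expect_equal(unname(q6$q), rep(Q_REF$tet_q6, 64), tolerance = 1e-10)
  q4 <- steinhardt_q(ic, g, 4)
  expect_equal(unname(q4$q), rep(Q_REF$tet_q4, 64), tolerance = 1e-10)

  fcc <- fcc_cluster_config()
  gf <- neighbor_list(fcc, 3.0, "brute")
  qf <- steinhardt_q(fcc, gf, 6)
  expect_equal(qf$q[1], Q_REF$fcc_q6, tolerance = 1e-10)
  expect_equal(steinhardt_q(fcc, gf, 4)$q[1], Q_REF$fcc_q4, tolerance = 1e-10)
})

test_that("q_l is invariant under rotation, translation and relabelling", {
  base <- fcc_cluster_config()
  g <- neighbor_list(base, 3.0, "brute")
  q_ref <- steinhardt_q(base, g, 6)$q[1]
  for (seed in 1:8) {
    R <- with_seed(seed, random_rotation_oracle())
    rot <- configuration(base$atom_names,
                         sweep(base$coords, 2, c(25, 25, 25), "-") %*% t(R) + 25,
                         base$box, molecule_ids = base$molecule_ids,
                         periodic = base$periodic)
    gr <- neighbor_list(rot, 3.0, "brute")
    expect_equal(steinhardt_q(rot, gr, 6)$q[1], q_ref, tolerance = 1e-8)
  }
  # rigid translation with periodic re-wrap plus atom relabelling
  ic <- build_ice_lattice("Ic", c(2, 2, 2))
  gi <- neighbor_list(ic, 3.5, "brute")
  qi <- sort(steinhardt_q(ic, gi, 6)$q)
  perm <- with_seed(5, sample(n_atoms(ic)))
  shifted <- configuration(
    ic$atom_names[perm],
    sweep(ic$coords[perm, ], 2, c(3.1, -2.2, 4.4), "+") %% ic$box[1],
    ic$box, molecule_ids = seq_along(perm), periodic = ic$periodic
  )
  gs <- neighbor_list(shifted, 3.5, "brute")
  expect_equal(sort(steinhardt_q(shifted, gs, 6)$q), qi, tolerance = 1e-8)
})

test_that("local averaging is the identity on a uniform lattice and pulls defects in", {
  ih <- build_ice_lattice("Ih", c(2, 2, 2))
  g <- neighbor_list(ih, 3.5, "brute")
  q <- steinhardt_q(ih, g, 6)
  qb <- local_average_q(q, g)
  # uniform lattice: all averaged values still share a single value
  expect_lt(diff(range(qb$q)), 1e-9)

  # displace one atom: its averaged value moves toward the lattice value
  coords <- ih$coords
  coords[1, ] <- coords[1, ] + c(0.45, -0.3, 0.25)
  pert <- configuration(ih$atom_names, coords, ih$box,
                        molecule_ids = ih$molecule_ids, periodic = ih$periodic)
  gp <- neighbor_list(pert, 3.5, "brute")
  qp <- steinhardt_q(pert, gp, 6)
  qbp <- local_average_q(qp, gp)
  lattice_val <- qb$q[1]
  expect_lt(abs(qbp$q[1] - lattice_val), abs(qp$q[1] - lattice_val))

  # averaging twice is not averaging once
  qbb <- local_average_q(qb, g)
  expect_false(isTRUE(all.equal(qbb$q, qb$q)))

  # graph mismatch is an error
  g2 <- neighbor_list(ih, 3.2, "brute")
  expect_error(local_average_q(q, g2), "not computed on this")
})

test_that("classification separates generated ice from generated liquid", {
  # zero-noise fixtures: any calibrated midpoint separates perfectly
  ih <- build_ice_lattice("Ih", c(2, 2, 2))
  gi <- neighbor_list(ih, 3.5, "brute")
  qi <- local_average_q(steinhardt_q(ih, gi, 6), gi)
  liq <- build_liquid_slab(420, c(22, 22, 40), min_dist = 2.5, seed = 2,
                           z_range = c(4, 36))
  lo <- water_oxygen_config(liq)
  gl <- neighbor_list(lo$config, 3.5, "brute")
  ql <- local_average_q(steinhardt_q(lo$config, gl, 6), gl)
  thr <- calibrate_threshold(qi, ql)
  ice_lab <- classify_ice(qi, thr)
  liq_lab <- classify_ice(ql, thr)
  expect_true(all(ice_lab$ice_like))          # 100% of ideal ice
  expect_lte(mean(liq_lab$ice_like), 0.01)    # <= 1% of the liquid

  # a threshold just under 1 labels (almost) nothing in a noisy lattice
  ihn <- build_ice_lattice("Ih", c(2, 2, 2), noise_sigma = 0.12, seed = 5)
  gn <- neighbor_list(ihn, 3.5, "brute")
  qn <- local_average_q(steinhardt_q(ihn, gn, 6), gn)
  expect_lte(sum(classify_ice(qn, 0.999)$ice_like), 1L)

  expect_error(classify_ice(qn, 1.5), "\\(0, 1\\)")
})

test_that("threshold calibration is reproducible and detects overlap", {
  make_qs <- function() {
    ihn <- build_ice_lattice("Ih", c(2, 2, 2), noise_sigma = 0.12, seed = 31)
    gn <- neighbor_list(ihn, 3.5, "brute")
    qi <- local_average_q(steinhardt_q(ihn, gn, 6), gn)
    liq <- build_liquid_slab(380, c(22, 22, 40), seed = 32, z_range = c(4, 36))
    lo <- water_oxygen_config(liq)
    gl <- neighbor_list(lo$config, 3.5, "brute")
    ql <- local_average_q(steinhardt_q(lo$config, gl, 6), gl)
    list(qi = qi, ql = ql)
  }
  a <- make_qs(); b <- make_qs()
  expect_identical(calibrate_threshold(a$qi, a$ql),
                   calibrate_threshold(b$qi, b$ql))

  # overlapping distributions error with both percentiles reported
  expect_error(calibrate_threshold(c(0.3, 0.4, 0.5), c(0.35, 0.45, 0.55)),
               "overlap")

  # held-out fixtures: misclassification below 1%
  thr <- calibrate_threshold(a$qi, a$ql)
  ihn2 <- build_ice_lattice("Ih", c(2, 2, 2), noise_sigma = 0.12, seed = 77)
  g2 <- neighbor_list(ihn2, 3.5, "brute")
  q2 <- local_average_q(steinhardt_q(ihn2, g2, 6), g2)
  liq2 <- build_liquid_slab(380, c(22, 22, 40), seed = 78, z_range = c(4, 36))
  lo2 <- water_oxygen_config(liq2)
  gl2 <- neighbor_list(lo2$config, 3.5, "brute")
  ql2 <- local_average_q(steinhardt_q(lo2$config, gl2, 6), gl2)
  ice_ok <- classify_ice(q2, thr)$ice_like
  nb2 <- q2$n_neighbors
  expect_lte(mean(!ice_ok[nb2 >= 4]), 0.01)
  expect_lte(mean(classify_ice(ql2, thr)$ice_like), 0.01)
})
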