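random_config <- function(n, seed, periodic = c(TRUE, TRUE, FALSE)) {
  with_seed(seed, {
    box <- c(stats::runif(2, 15, 40), stats::runif(1, 30, 80))
    configuration(
      sample(c("OW", "HW1", "HW2"), n, replace = TRUE),
      cbind(stats::runif(n, 0, box[1]), stats::runif(n, 0, box[2]),
            stats::runif(n, 0, box[3])),
      box, molecule_ids = seq_len(n), periodic = periodic
    )
  })
}

test_that("configuration invariants are enforced", {
  expect_error(configuration("OW", matrix(1, 1, 3), c(10, 10, 0)), "positive")
  expect_error(configuration("OW", matrix(Inf, 1, 3), c(10, 10, 10)), "finite")
  expect_error(configuration(c("OW", "HW1"), matrix(1, 1, 3), c(10, 10, 10)),
               "names must equal")
  expect_error(configuration("OW", matrix(1, 1, 3), c(10, 10, 10),
                             molecule_ids = -1L), "non-negative")
})

shift_frame <- function(cfg, dz) {
  configuration(cfg$atom_names, cfg$coords + dz, cfg$box,
                molecule_ids = cfg$molecule_ids, periodic = cfg$periodic)
}

test_that("trajectory frames must align and times must increase", {
  a <- random_config(5, 1)
  b <- shift_frame(a, 0.3)
  expect_s3_class(trajectory(list(a, b), times = c(0, 1)), "trajectory")
  expect_error(trajectory(list(a, b), times = c(1, 1)), "strictly increasing")
  c3 <- random_config(6, 3)
  expect_error(trajectory(list(a, c3)), "identical atom count")
})

test_that("extended-XYZ round-trips exactly and enforces its dialect", {
  for (seed in 1:6) {
    cfg <- random_config(20, seed)
    path <- withr::local_tempfile(fileext = ".xyz")
    write_configuration(cfg, path, "xyz_ext")
    back <- read_configuration(path, "xyz_ext")
    expect_equal(back$coords, cfg$coords, tolerance = 1e-9)
    expect_equal(back$box, cfg$box, tolerance = 1e-9)
    expect_identical(back$atom_names, cfg$atom_names)
    expect_identical(back$molecule_ids, cfg$molecule_ids)
    expect_identical(back$periodic, cfg$periodic)
  }

  # 3-atom literal fixture with an explicit cubic lattice
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c(
    "3",
    'Lattice="10 0 0 0 10 0 0 0 10" Properties=species:S:1:pos:R:3 pbc="T T T"',
    "OW 1.0 2.0 3.0", "HW1 1.5 2.0 3.0", "HW2 1.0 2.5 3.0"
  ), path)
  cfg <- read_configuration(path, "xyz_ext")
  expect_equal(cfg$box, c(10, 10, 10))
  expect_equal(cfg$coords[1, ], c(1, 2, 3))

  # plain XYZ without a box is rejected, naming the line
  writeLines(c("1", "no lattice here", "OW 0 0 0"), path)
  expect_error(read_configuration(path, "xyz_ext"), "line 2.*Lattice")

  # triclinic lattices are rejected
  writeLines(c(
    "1", 'Lattice="10 1 0 0 10 0 0 0 10"', "OW 0 0 0"
  ), path)
  expect_error(read_configuration(path, "xyz_ext"), "triclinic")

  # malformed coordinate names its line
  writeLines(c(
    "1", 'Lattice="10 0 0 0 10 0 0 0 10"', "OW 0 xx 0"
  ), path)
  expect_error(read_configuration(path, "xyz_ext"), "line 3")
})

test_that("GRO converts nm to angstrom and round-trips to format precision", {
  path <- withr::local_tempfile(fileext = ".gro")
  writeLines(c(
    "one water",
    "    1",
    "    1SOL     OW    1   1.000   0.250   2.000",
    "   3.00000   3.00000   3.00000"
  ), path)
  cfg <- read_configuration(path, "gro")
  expect_equal(cfg$coords[1, ], c(10, 2.5, 20))
  expect_equal(cfg$box, c(30, 30, 30))

  for (seed in 1:4) {
    cfg <- random_config(30, seed)
    p2 <- withr::local_tempfile(fileext = ".gro")
    write_configuration(cfg, p2, "gro")
    back <- read_configuration(p2, "gro")
    # GRO stores nm to 3 decimals: 0.005 angstrom round-trip granularity
    expect_true(max(abs(back$coords - cfg$coords)) <= 0.005 + 1e-12)
    expect_identical(back$atom_names, cfg$atom_names)
    expect_identical(back$molecule_ids, cfg$molecule_ids)
  }

  # the slab box of the monolayer setup survives the nm conversion
  slabish <- configuration(c("OW", "HW1", "HW2"), matrix(1:9, 3, 3, byrow = TRUE),
                           box = c(67, 67, 200), molecule_ids = c(1L, 1L, 1L))
  p3 <- withr::local_tempfile(fileext = ".gro")
  write_configuration(slabish, p3, "gro")
  expect_equal(read_configuration(p3, "gro")$box, c(67, 67, 200),
               tolerance = 1e-9)

  # triclinic GRO box rejected
  writeLines(c(
    "t", "    1", "    1SOL     OW    1   1.000   1.000   1.000",
    "   3.0   3.0   3.0   0.5   0.0   0.0   0.0   0.0   0.0"
  ), path)
  expect_error(read_configuration(path, "gro"), "triclinic")
})

test_that("writing refuses an empty configuration", {
  empty <- configuration(character(0), matrix(numeric(0), 0, 3), c(10, 10, 10),
                         molecule_ids = integer(0))
  expect_error(write_configuration(empty, tempfile(), "xyz_ext"), "no atoms")
})

test_that("a full-scale water slab survives the write/read cycle", {
  slab <- build_liquid_slab(4752L, c(67, 67, 200), min_dist = 2.5, seed = 42,
                            z_range = c(80, 120))
  expect_identical(n_atoms(slab), 3L * 4752L)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_configuration(slab, path, "xyz_ext")
  back <- read_configuration(path, "xyz_ext")
  expect_equal(back$coords, slab$coords, tolerance = 1e-9)
  expect_identical(back$molecule_ids, slab$molecule_ids)
})

test_that("trajectory I/O preserves frames and times", {
  base <- random_config(8, 1)
  frames <- lapply(c(0, 0.4, 1.1), function(dz) shift_frame(base, dz))
  traj <- trajectory(frames, times = c(0, 0.5, 1.25))
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$times, traj$times)
  expect_equal(back$frames[[2]]$coords, traj$frames[[2]]$coords,
               tolerance = 1e-9)
})

test_that("topology inference classifies and validates molecules", {
  w <- configuration(c("OW", "HW1", "HW2"), matrix(0:8 / 10, 3, 3), c(9, 9, 9),
                     molecule_ids = c(1L, 1L, 1L))
  topo <- infer_topology(w)
  expect_identical(nrow(topo$water), 1L)
  expect_identical(topo$water$O, 1L)

  ch <- configuration(c("C3", "C25", "O1", "H1"), matrix(1:12, 4, 3), c(9, 9, 9),
                      molecule_ids = rep(2L, 4))
  topo <- infer_topology(ch)
  expect_identical(nrow(topo$chol), 1L)
  expect_true(topo$chol$axis_tail != topo$chol$axis_head)

  bad <- configuration(c("OW", "HW1"), matrix(1:6, 2, 3), c(9, 9, 9),
                       molecule_ids = c(7L, 7L))
  expect_error(infer_topology(bad), "molecule 7")

  unk <- configuration("XX", matrix(1, 1, 3), c(9, 9, 9), molecule_ids = 3L)
  expect_error(infer_topology(unk, strict = TRUE), "unrecognised")
  topo <- infer_topology(unk, strict = FALSE)
  expect_identical(topo$other, 1L)
})

test_that("tabular series round-trip, dialect sniffing and column checks", {
  df <- data.frame(time = 0:4, P_xx = rnorm(5), P_zz = rnorm(5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_series(df, path)
  back <- read_series(path, columns = c("time", "P_zz"))
  expect_equal(back$data$P_zz, df$P_zz, tolerance = 1e-12)
  expect_error(read_series(path, columns = "nope"), "nope")

  # whitespace dialect
  p2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("a b", "1 2", "3 4"), p2)
  expect_equal(read_series(p2)$data$b, c(2, 4))

  # header-only file gives an empty series
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b", p3)
  s <- read_series(p3)
  expect_identical(nrow(s$data), 0L)
  expect_identical(names(s$data), c("a", "b"))
})

test_that("minimum image respects per-axis periodicity flags", {
  box <- c(10, 10, 50)
  d <- c(6, -6, 30)
  expect_equal(minimum_image(d, box, c(TRUE, TRUE, FALSE)), c(-4, 4, 30))
  expect_equal(minimum_image(d, box, c(FALSE, FALSE, FALSE)), d)
  m <- matrix(c(6, -6, 30, 1, 2, 3), 2, 3, byrow = TRUE)
  out <- minimum_image(m, box, c(TRUE, TRUE, TRUE))
  expect_equal(out[1, ], c(-4, 4, -20))
  expect_equal(out[2, ], c(1, 2, 3))
})
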