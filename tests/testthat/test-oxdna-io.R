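test_that("topology reader parses the hand-written duplex fixture", {
  dir <- duplex_fixture_dir()
  topo <- read_topology(file.path(dir, "duplex.top"))
  expect_equal(topo$n_nucleotides, 8L)
  expect_equal(topo$n_strands, 2L)
  expect_equal(nchar(topo$sequences), c(4L, 4L))
  expect_equal(topo$sequences, c("ACGT", "ACGT"))
  # chain ends carry -1 neighbors
  expect_equal(topo$neighbor3[c(1, 5)], c(-1L, -1L))
  expect_equal(topo$neighbor5[c(4, 8)], c(-1L, -1L))
})

test_that("topology reader rejects malformed files with line numbers", {
  empty <- tempfile(fileext = ".top")
  file.create(empty)
  expect_error(read_topology(empty), "empty")

  bad_header <- tempfile(fileext = ".top")
  writeLines(c("eight 2", "1 A -1 -1"), bad_header)
  expect_error(read_topology(bad_header), ":1:.*two integers")

  bad_base <- tempfile(fileext = ".top")
  writeLines(c("2 1", "1 A -1 1", "1 X 0 -1"), bad_base)
  expect_error(read_topology(bad_base), ":3:.*non-ACGT")

  asym <- tempfile(fileext = ".top")
  writeLines(c("2 1", "1 A -1 1", "1 C 1 -1"), asym)
  expect_error(read_topology(asym), "asymmetric")

  wrong_count <- tempfile(fileext = ".top")
  writeLines(c("3 1", "1 A -1 1", "1 C 0 -1"), wrong_count)
  expect_error(read_topology(wrong_count), "expected 3 nucleotide rows")
})

test_that("topology write-read round trip is the byte-identical canonical form", {
  dir <- duplex_fixture_dir()
  path1 <- file.path(dir, "duplex.top")
  topo <- read_topology(path1)
  path2 <- tempfile(fileext = ".top")
  write_topology(topo, path2)
  expect_identical(readLines(path2), readLines(path1))
  expect_equal(read_topology(path2), topo)
})

test_that("trajectory reader accepts 15- and 9-column rows with equal positions", {
  dir <- duplex_fixture_dir()
  topo <- read_topology(file.path(dir, "duplex.top"))
  t15 <- read_trajectory(file.path(dir, "duplex15.dat"), topo)
  t9 <- read_trajectory(file.path(dir, "duplex9.dat"), topo)
  expect_equal(n_frames(t15), 1L)
  expect_false(is.null(t15$velocities))
  expect_equal(t15$velocities[1, , 1], c(0.01, 0.02, 0.03))
  expect_null(t9$velocities)
  expect_identical(t15$positions, t9$positions)
})

test_that("trajectory reader rejects truncated and corrupt frames", {
  dir <- duplex_fixture_dir()
  topo <- read_topology(file.path(dir, "duplex.top"))
  lines <- readLines(file.path(dir, "duplex9.dat"))

  trunc <- tempfile(fileext = ".dat")
  writeLines(c(lines, lines[1:6]), trunc)  # second frame has too few rows
  expect_error(read_trajectory(trunc, topo), "frame 2 truncated")

  nonnum <- tempfile(fileext = ".dat")
  bad <- lines; bad[5] <- sub("^[0-9.]+", "oops", bad[5])
  writeLines(bad, nonnum)
  expect_error(read_trajectory(nonnum, topo), "frame 1")

  backwards <- tempfile(fileext = ".dat")
  writeLines(c(sub("t = 0", "t = 5", lines), lines), backwards)
  expect_error(read_trajectory(backwards, topo), "decreasing time")
})

test_that("trajectory write-read is a fixed point within 1e-6", {
  set.seed(4)
  pos <- array(rnorm(8 * 3 * 3, sd = 3), c(8, 3, 3))
  traj <- make_trajectory(pos)
  path <- tempfile(fileext = ".dat")
  write_trajectory(traj, path)
  dir <- duplex_fixture_dir()
  topo <- read_topology(file.path(dir, "duplex.top"))
  back <- read_trajectory(path, topo)
  expect_equal(back$positions, traj$positions, tolerance = 1e-6)
  expect_equal(back$base_vectors, traj$base_vectors, tolerance = 1e-6)
  expect_equal(back$times, traj$times, tolerance = 1e-6)
  # write(read(write(x))) reproduces the file byte for byte
  path2 <- tempfile(fileext = ".dat")
  write_trajectory(back, path2)
  expect_identical(readLines(path2), readLines(path))
})

test_that("empty trajectories and invalid orientation vectors are handled", {
  dir <- duplex_fixture_dir()
  topo <- read_topology(file.path(dir, "duplex.top"))
  empty <- tempfile(fileext = ".dat")
  file.create(empty)
  expect_equal(n_frames(read_trajectory(empty, topo)), 0L)

  traj <- make_trajectory(array(rnorm(8 * 3), c(8, 3, 1)))
  traj$base_vectors[1, , 1] <- c(2, 0, 0)  # non-unit base vector
  expect_error(write_trajectory(traj, tempfile()), "unit norm")
})

test_that("unit conversions follow the published constants and invert exactly", {
  u <- oxdna_units()
  expect_equal(convert_units(1, "length"), 0.8518)
  expect_equal(convert_units(5e-8, "rate"), 1.4e4, tolerance = 0.005)
  expect_equal(convert_units(1, "time"), 3.03e-12)
  # round trip is the identity to 1e-12 relative
  for (kind in c("length", "time", "force", "stiffness", "rate")) {
    x <- c(0.1, 1, 57.3)
    expect_equal(convert_units(convert_units(x, kind, from = "sim"), kind, from = "si"),
                 x, tolerance = 1e-12)
  }
  # rate factor is the length factor over the time factor
  expect_equal(convert_units(1, "rate"),
               convert_units(1, "length") / convert_units(1, "time"))
  expect_error(convert_units(1, "volume"), "unknown unit kind")
})

test_that("force-unit default is consistent with the printed trap stiffness", {
  # 0.2 simulation stiffness units must equal 11.42 pN/nm within 0.5%
  expect_equal(convert_units(0.2, "stiffness", from = "sim"), 11.42,
               tolerance = 0.005)
})
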