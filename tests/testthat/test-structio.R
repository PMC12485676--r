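test_that("toy dimer reads back identically after writing (round trip)", {
  m <- toy_dimer()
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(m$atoms))
  expect_identical(m2$atoms$elety, m$atoms$elety)
  expect_identical(m2$atoms$resno, m$atoms$resno)
  expect_identical(m2$atoms$chain, m$atoms$chain)
  # PDB coordinates carry three decimals
  expect_lt(max(abs(coords(m2) - coords(m))), 5e-4)
  expect_identical(m2$chains$role, m$chains$role)
  expect_identical(m2$chains$assoc, m$chains$assoc)
  expect_setequal(unique(m2$chains$role[m2$chains$role != "ligand"]),
                  c("alpha", "beta"))
  # read(write(read(write(x)))) is stable
  f2 <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("a 39-dimer lattice survives the >62-chain relettering scheme", {
  lat <- make_toy_lattice()$model
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(lat, f)
  m2 <- read_structure(f)
  expect_equal(dimer_count(m2), 39)
  expect_identical(m2$chains$pf, lat$chains$pf)
  expect_identical(m2$chains$ring, lat$chains$ring)
})

test_that("box geometry is preserved through PDB headers and CRYST1", {
  tl <- tailed_lattice()$model
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(tl, f)
  expect_true(any(startsWith(readLines(f, n = 400), "CRYST1")))
  m2 <- read_structure(f)
  expect_equal(m2$box$mode, "axial_periodic")
  expect_equal(m2$box$axial_length, tl$box$axial_length)
})

test_that("degenerate structure files are rejected with clear errors", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("HEADER    EMPTY", "END"), f)
  expect_error(read_structure(f), "parse|empty|ATOM")
  expect_error(read_structure(tempfile()), "not found")
  m <- toy_dimer()
  m$atoms$x[1] <- 12345.0
  expect_error(write_structure(m, withr::local_tempfile()), "mmCIF")
})

test_that("ligand name dialects normalize to one internal code", {
  m <- make_toy_dimer(1, beta_nucleotide = "GCP")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  txt <- readLines(f)
  m2 <- read_structure(f)
  expect_true(all(m2$atoms$resid[m2$atoms$chain == "LB"] == "GCP"))
})

test_that("trajectories round-trip through text and DCD formats", {
  m <- toy_dimer()
  set.seed(4)
  xyz <- t(replicate(7, as.numeric(t(coords(m))) + rnorm(3 * n_atoms(m), 0, 0.2)))
  tr <- mt_trajectory(m, xyz, frame_interval = 0.5)
  ft <- withr::local_tempfile(fileext = ".traj")
  write_trajectory(tr, ft, "multipdb")
  tr2 <- read_trajectory(m, ft, "multipdb")
  expect_equal(n_frames(tr2), 7)
  expect_equal(tr2$xyz, round(tr$xyz, 3), ignore_attr = TRUE)
  # the text dialect is also readable by a second, independent parser
  p <- bio3d::read.pdb(ft, multi = TRUE, verbose = FALSE)
  expect_equal(nrow(p$xyz), 7)
  expect_equal(max(abs(as.matrix(p$xyz) - round(tr$xyz, 3))), 0)

  fd <- withr::local_tempfile(fileext = ".dcd")
  write_trajectory(tr, fd)
  tr3 <- read_trajectory(m, fd)   # parsed by bio3d::read.dcd
  expect_equal(n_frames(tr3), 7)
  expect_lt(max(abs(tr3$xyz - tr$xyz)), 1e-4)  # float32 storage
})

test_that("truncated trajectory frames raise an error naming the frame", {
  m <- toy_dimer()
  xyz <- rbind(as.numeric(t(coords(m))), as.numeric(t(coords(m))))
  tr <- mt_trajectory(m, xyz)
  ft <- withr::local_tempfile(fileext = ".traj")
  write_trajectory(tr, ft, "multipdb")
  lines <- readLines(ft)
  # drop some atoms of frame 2
  cut <- utils::tail(which(startsWith(lines, "ATOM")), 5)
  writeLines(lines[-cut], ft)
  expect_error(read_trajectory(m, ft, "multipdb"), "frame 2")
  # file ending inside a MODEL block
  last_end <- max(which(startsWith(lines, "ENDMDL")))
  writeLines(lines[seq_len(last_end - 3)], ft)
  expect_error(read_trajectory(m, ft, "multipdb"), "truncated frame 2")
})

test_that("streaming iteration matches eager loading", {
  m <- toy_dimer()
  set.seed(5)
  xyz <- t(replicate(6, as.numeric(t(coords(m))) + rnorm(3 * n_atoms(m), 0, 0.3)))
  tr <- mt_trajectory(m, xyz)
  ft <- withr::local_tempfile(fileext = ".traj")
  write_trajectory(tr, ft, "multipdb")
  eager <- read_trajectory(m, ft, "multipdb")
  means <- numeric(0)
  n <- stream_frames(ft, m, function(i, mm) means[i] <<- mean(mm))
  expect_equal(n, 6)
  expect_equal(means, vapply(seq_len(6), function(i)
    mean(frame_coords(eager, i)), numeric(1)))
})

test_that("run metadata is carried but never computed on", {
  md <- md_run_metadata(engine = "NAMD", force_field = "CHARMM36",
                        ionic_strength_mM = 50, timestep_fs = 4,
                        trajectory_lengths_ns = c(260, 330),
                        nucleotide_state = "GDP")
  m <- toy_dimer()
  m$metadata <- md
  expect_identical(m$metadata$nucleotide_state, "GDP")
  expect_error(md_run_metadata(nucleotide_state = "ATP"))
})
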