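# Structure and time-series IO, atom selection, superposition.

write_test_pdb <- function(path, xyz, chain = "A", b = NULL, resno = NULL) {
  n <- nrow(xyz)
  if (is.null(b)) b <- rep(50, n)
  if (is.null(resno)) resno <- seq_len(n)
  if (length(chain) == 1L) chain <- rep(chain, n)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(xyz)), resno = resno,
                   resid = rep("ALA", n), elety = rep("CA", n), chain = chain,
                   b = b, o = rep(1, n))
  path
}

test_that("identical files load into identical structures with equal pLDDT", {
  d <- withr::local_tempdir()
  xyz <- matrix(rnorm(30, sd = 5), 10, 3)
  p <- write_test_pdb(file.path(d, "a.pdb"), xyz, b = rep(77.5, 10))
  files <- c(p, file.copy2 <- file.path(d, "b.pdb"), file.path(d, "c.pdb"))
  file.copy(p, files[2]); file.copy(p, files[3])
  ens <- load_ensemble(files)
  expect_equal(n_structures(ens), 3)
  expect_equal(ens$xyz[[1]], ens$xyz[[2]])
  expect_equal(ens$xyz[[1]], ens$xyz[[3]])
  expect_equal(ens$mean_plddt, rep(77.5, 3))
})

test_that("schema harmonization intersects atoms; chain selection works", {
  d <- withr::local_tempdir()
  xyz_a <- matrix(rnorm(30), 10, 3)
  xyz_ab <- rbind(xyz_a, matrix(rnorm(15), 5, 3))
  write_test_pdb(file.path(d, "onlyA.pdb"), xyz_a)
  write_test_pdb(file.path(d, "withB.pdb"), xyz_ab,
                 chain = rep(c("A", "B"), c(10, 5)),
                 resno = c(1:10, 1:5))
  ens <- load_ensemble(file.path(d, c("onlyA.pdb", "withB.pdb")),
                       selection = "chain A and name CA")
  expect_equal(n_structures(ens), 2)
  expect_equal(nrow(ens$atoms), 10)
  expect_true(all(ens$atoms$chain == "A"))
})

test_that("structures missing the selection are dropped with a warning", {
  d <- withr::local_tempdir()
  write_test_pdb(file.path(d, "a.pdb"), matrix(rnorm(30), 10, 3), chain = "A")
  write_test_pdb(file.path(d, "b.pdb"), matrix(rnorm(30), 10, 3), chain = "B")
  expect_warning(
    ens <- load_ensemble(file.path(d, c("a.pdb", "b.pdb")), selection = "chain A"),
    "dropping"
  )
  expect_equal(n_structures(ens), 1)
  expect_error(suppressWarnings(
    load_ensemble(file.path(d, "a.pdb"), selection = "chain Q")),
    "matches no atoms")
})

test_that("synthetic ensemble coordinates survive a PDB round-trip", {
  d <- withr::local_tempdir()
  truth <- make_ensemble(d, n_states = 2, structures_per_state = 3,
                         chain_length = 12, noise_sigma = 0.2, seed = 42)
  ens <- load_ensemble(truth$file, selection = "name CA")
  expect_equal(n_structures(ens), 6)
  # regenerate the exact coordinates that were written
  ideal <- attr(truth, "ideal")
  withr::with_seed(42, {
    for (i in seq_len(6)) {
      s <- truth$state[i]
      xyz <- ideal[[s]] + matrix(rnorm(3 * 12, sd = 0.2), 12, 3)
      expect_lt(max(abs(ens$xyz[[i]] - xyz)), 1e-3) # PDB precision
    }
  })
})

test_that("selection mini-language resolves compound expressions", {
  atoms <- data.frame(chain = rep(c("A", "B"), each = 6),
                      resid = rep(1:6, 2), resname = "ALA",
                      name = rep(c("CA", "CB", "CA"), 4), b = 0)
  expect_equal(select_atoms(atoms, "all"), 1:12)
  expect_equal(select_atoms(atoms, "chain B"), 7:12)
  expect_equal(select_atoms(atoms, "resid 2:4 and name CA"),
               intersect(which(atoms$resid %in% 2:4), which(atoms$name == "CA")))
  expect_equal(select_atoms(atoms, "not chain A"), 7:12)
  expect_equal(select_atoms(atoms, "(chain A and resid 1) or (chain B and resid 6)"),
               c(1, 12))
  expect_error(select_atoms(atoms, "resid x"), "syntax")
  expect_error(select_atoms(atoms, "chain A and"), "syntax|argument")
})

test_that("superposition is exact for self and rigid copies", {
  withr::with_seed(7, {
    xyz <- matrix(rnorm(60, sd = 4), 20, 3)
    expect_equal(superpose(xyz, xyz)$rmsd, 0)
    moved <- random_rigid(xyz, seed = 11)
    expect_lt(superpose(moved, xyz)$rmsd, 1e-8)
  })
})

test_that("superposition RMSD matches the quaternion oracle and is symmetric", {
  # fixed 4-point toy coordinate sets
  P <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0.3, 0.2, 1.1), 4, 3, byrow = TRUE)
  Q <- matrix(c(0.1, -0.1, 0, 1.2, 0.1, 0, -0.1, 0.9, 0.2, 0.2, 0.4, 0.9),
              4, 3, byrow = TRUE)
  r_kabsch <- superpose(P, Q)$rmsd
  expect_equal(r_kabsch, quaternion_rmsd(P, Q), tolerance = 1e-6)
  expect_equal(r_kabsch, superpose(Q, P)$rmsd, tolerance = 1e-8)
  # symmetry + rigid invariance on random pairs
  for (s in 1:5) {
    withr::with_seed(s, {
      A <- matrix(rnorm(30), 10, 3); B <- matrix(rnorm(30), 10, 3)
    })
    expect_equal(superpose(A, B)$rmsd, superpose(B, A)$rmsd, tolerance = 1e-8)
    expect_equal(superpose(random_rigid(A, s + 50), B)$rmsd,
                 superpose(A, B)$rmsd, tolerance = 1e-8)
  }
})

test_that("degenerate superposition inputs are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(superpose(line, line), "collinear")
  tri <- matrix(rnorm(9), 3, 3)
  expect_error(superpose(tri, tri, fit_selection = 1:2), "at least 3")
})

test_that("time series load, preserve trajectory boundaries, and round-trip", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "t1.dat"); f2 <- file.path(d, "t2.csv")
  m1 <- matrix(round(rnorm(30), 6), 10, 3)
  writeLines(c("# a b c", apply(m1, 1, paste, collapse = " ")), f1)
  ts1 <- load_timeseries(f1)
  expect_equal(dim(ts1$trajectories[[1]]), c(10, 3))
  expect_equal(ts1$column_names, c("a", "b", "c"))
  expect_equal(unname(ts1$trajectories[[1]]), unname(m1))

  m2 <- matrix(rnorm(60), 20, 3)
  write.table(m2, f2, sep = ",", row.names = FALSE, col.names = FALSE)
  ts2 <- load_timeseries(c(f1, f2))
  expect_length(ts2$trajectories, 2)
  expect_equal(nrow(ts2$trajectories[[1]]), 10)
  expect_equal(nrow(ts2$trajectories[[2]]), 20)

  # write/read round-trip
  out <- file.path(d, c("o1.dat", "o2.dat"))
  write_timeseries(ts2, out, digits = 12)
  back <- load_timeseries(out)
  expect_equal(back$trajectories, ts2$trajectories, tolerance = 1e-10)
  expect_equal(back$column_names, ts2$column_names)
})

test_that("malformed time series are rejected", {
  d <- withr::local_tempdir()
  f1 <- file.path(d, "a.dat"); f2 <- file.path(d, "b.dat"); f3 <- file.path(d, "c.dat")
  writeLines(c("1 2", "3 4"), f1)
  writeLines(c("1 2 3", "4 5 6"), f2)
  expect_error(load_timeseries(c(f1, f2)), "disagree")
  writeLines(c("1 x", "2 3"), f3)
  expect_error(load_timeseries(f3))
  writeLines("1 2", f3)
  expect_error(load_timeseries(f3), "2 frames")
})
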