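# Reference picking, RMSD filter, pair enumeration, CoV ranking,
# regular-space clustering.

test_that("reference is the highest-pLDDT structure, ties to the first", {
  xyz <- replicate(3, matrix(rnorm(15), 5, 3), simplify = FALSE)
  expect_equal(select_reference(toy_structure_ensemble(xyz, c(70, 90, 80))), 2)
  expect_equal(select_reference(toy_structure_ensemble(xyz, c(80, 80, 80))), 1)
  expect_warning(
    ref <- select_reference(toy_structure_ensemble(xyz, c(0, 0, 0))),
    "pLDDT")
  expect_equal(ref, 1)
})

test_that("RMSD filter keeps rigid copies and respects the cutoff", {
  withr::with_seed(1, {
    base <- matrix(rnorm(30, sd = 3), 10, 3)
    ens <- toy_structure_ensemble(
      list(base, sweep(base, 2, c(10, -4, 2), "+"), base + rnorm(30, sd = 2)),
      plddt = c(90, 50, 50))
  })
  all_kept <- rmsd_filter(ens, cutoff = 1e9)
  expect_equal(n_structures(all_kept), 3)
  # a purely translated copy has zero RMSD at any cutoff
  tight <- rmsd_filter(ens, cutoff = 1e-6)
  expect_true(all(c("s1", "s2") %in% tight$source_ids))
  expect_false("s3" %in% tight$source_ids)
})

test_that("RMSD filter separates synthetic states at a cutoff between them", {
  d <- withr::local_tempdir()
  truth <- make_ensemble(d, n_states = 2, structures_per_state = 10,
                         hinge_angles_deg = c(0, 40), noise_sigma = 0.2,
                         plddt_by_state = c(90, 60), seed = 5)
  ens <- load_ensemble(truth$file, selection = "name CA")
  ref <- select_reference(ens) # state 1 has the higher pLDDT
  expect_equal(truth$state[ref], 1)
  rms <- attr(rmsd_filter(ens, cutoff = 1e9, reference_index = ref), "rmsd")
  mid <- (max(rms[truth$state == 1]) + min(rms[truth$state == 2])) / 2
  expect_gt(min(rms[truth$state == 2]), max(rms[truth$state == 1]))
  filt <- rmsd_filter(ens, cutoff = mid, reference_index = ref)
  expect_equal(n_structures(filt), 10) # exactly the state-1 structures
  expect_true(all(grepl("state1", filt$source_ids)))
})

test_that("RMSD filter is monotone in the cutoff", {
  d <- withr::local_tempdir()
  truth <- make_ensemble(d, n_states = 2, structures_per_state = 8,
                         noise_sigma = 0.4, seed = 2)
  ens <- load_ensemble(truth$file, selection = "name CA")
  cutoffs <- c(0.3, 0.8, 1.5, 3, 8)
  kept <- lapply(cutoffs, function(cc) rmsd_filter(ens, cutoff = cc)$source_ids)
  for (i in seq_along(cutoffs)[-1]) {
    expect_true(all(kept[[i - 1]] %in% kept[[i]]))
  }
})

test_that("pair enumeration counts match brute force with the separation rule", {
  xyz <- list(cbind(3.8 * (0:9), 0, 0))
  ens <- toy_structure_ensemble(xyz)
  expect_equal(nrow(enumerate_pair_features(ens, "all", 0)), choose(10, 2))
  # 10 consecutive residues, min separation 3
  specs <- enumerate_pair_features(ens, "all", 3)
  brute <- 0
  for (i in 1:9) for (j in (i + 1):10) if (j - i >= 3) brute <- brute + 1
  expect_equal(nrow(specs), brute)
  expect_equal(brute, 28)
  expect_true(all(specs$atom_i < specs$atom_j))
  # 3 residues with min_sep 3 leave nothing
  ens3 <- toy_structure_ensemble(list(cbind(3.8 * (0:2), 0, 0)))
  expect_equal(nrow(enumerate_pair_features(ens3, "all", 3)), 0)
  ens1 <- toy_structure_ensemble(list(cbind(0, 0, 0)))
  expect_error(enumerate_pair_features(ens1, "all", 0), "fewer than 2")
})

test_that("pairs across chains are always allowed", {
  atoms <- data.frame(chain = rep(c("A", "B"), each = 2), resid = c(1, 2, 1, 2),
                      resname = "ALA", name = "CA", b = 0)
  ens <- structure(list(xyz = list(matrix(rnorm(12), 4, 3)), atoms = atoms,
                        source_ids = "s1", mean_plddt = 50),
                   class = "StructureEnsemble")
  specs <- enumerate_pair_features(ens, "all", 5)
  # same-chain pairs are filtered (sep < 5), all 4 cross-chain pairs remain
  expect_equal(nrow(specs), 4)
})

test_that("CoV equals population variance over mean, with stated examples", {
  fm <- structure(list(
    values = cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(5, 5, 5)),
    specs = data.frame(atom_i = 1:3, atom_j = 4:6, label = c("a", "b", "c")),
    source_ids = paste0("s", 1:3)), class = "FeatureMatrix")
  st <- feature_stats(fm)
  # column {1,2,3}: mean 2, population variance 2/3, CoV 1/3
  expect_equal(st$variance[1], 2 / 3, tolerance = 1e-12)
  expect_equal(st$cov[1], 1 / 3, tolerance = 1e-12)
  # b = 2a doubles the CoV and therefore outranks a
  expect_equal(st$cov[2], 2 * st$cov[1], tolerance = 1e-12)
  # constant column: zero variance, zero CoV, ranked last
  expect_equal(st$cov[3], 0)
  rk <- rank_by_cov(fm, top_m = 2)
  expect_equal(colnames(rk$matrix$values), c("b", "a"))
  expect_equal(rk$stats$rank, c(2, 1, 3))
  # sd/mean variant
  expect_equal(feature_stats(fm, "sd")$cov[1], sqrt(2 / 3) / 2, tolerance = 1e-12)
})

test_that("CoV ranking is deterministic and invariant to structure order", {
  withr::with_seed(3, {
    v <- matrix(runif(60, 1, 10), 10, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
  })
  fm <- structure(list(values = v,
                       specs = data.frame(atom_i = 1:6, atom_j = 7:12,
                                          label = colnames(v)),
                       source_ids = paste0("s", 1:10)), class = "FeatureMatrix")
  r1 <- rank_by_cov(fm, top_m = 3)
  r2 <- rank_by_cov(fm, top_m = 3)
  expect_identical(r1$stats, r2$stats)
  perm <- c(4, 1, 9, 10, 2, 3, 8, 6, 5, 7)
  fm_p <- fm; fm_p$values <- v[perm, ]; fm_p$source_ids <- fm$source_ids[perm]
  expect_equal(rank_by_cov(fm_p, top_m = 3)$stats, r1$stats)
  expect_warning(rank_by_cov(fm, top_m = 99), "keeping all")
})

test_that("regular-space clustering reproduces the hand-simulated 1D pass", {
  x <- matrix(0:10, ncol = 1)
  cl <- regular_space_cluster(x, d_min = 2.5)
  expect_equal(cl$center_indices, c(1, 4, 7, 10)) # values 0, 3, 6, 9
  expect_equal(regular_space_cluster(matrix(rep(1, 5), 5, 1), 0.5)$n_centers, 1)
  withr::with_seed(4, y <- matrix(rnorm(20), 10, 2))
  expect_equal(regular_space_cluster(y, 0)$n_centers, 10)
})

test_that("regular-space clustering matches the brute-force oracle", {
  for (s in 1:50) {
    withr::with_seed(s, {
      n <- sample(2:50, 1)
      p <- sample(1:4, 1)
      v <- matrix(rnorm(n * p), n, p)
      d_min <- runif(1, 0, 2.5)
    })
    cl <- regular_space_cluster(v, d_min)
    expect_identical(cl$center_indices, brute_force_rsc(v, d_min))
  }
})

test_that("cluster invariants hold: center separation and point coverage", {
  for (s in 1:100) {
    withr::with_seed(1000 + s, {
      n <- sample(2:40, 1)
      v <- matrix(rnorm(n * 3), n, 3)
      d_min <- runif(1, 0.1, 3)
    })
    cl <- regular_space_cluster(v, d_min)
    cm <- v[cl$center_indices, , drop = FALSE]
    if (cl$n_centers > 1) {
      cd <- as.matrix(dist(cm))
      expect_gt(min(cd[upper.tri(cd)]), d_min)
    }
    near <- apply(v, 1, function(r) min(sqrt(colSums((t(cm) - r)^2))))
    expect_true(all(near <= d_min + 1e-12))
  }
})

test_that("d_min bisection hits the target center range", {
  grid <- matrix(seq(0, 1, length.out = 100), ncol = 1)
  got <- suggest_d_min(grid, c(5, 20))
  expect_gte(got$n_centers, 5)
  expect_lte(got$n_centers, 20)
  expect_equal(regular_space_cluster(grid, got$d_min)$n_centers, got$n_centers)
  # exact target at n distinct points needs a near-zero threshold
  pts <- matrix(c(0, 1, 2, 3), ncol = 1)
  exact <- suggest_d_min(pts, c(4, 4))
  expect_equal(exact$n_centers, 4)
  expect_lt(exact$d_min, 1)
  expect_warning(suggest_d_min(matrix(c(0, 5, 9), ncol = 1), c(5, 20)),
                 "unreachable")
})
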