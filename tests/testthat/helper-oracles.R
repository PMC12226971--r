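# Independent oracles and small fixture builders shared across tests.

# Quaternion (Horn) superposition oracle: optimal RMSD between two centered
# point sets from the largest eigenvalue of the 4x4 key matrix. Independent
# of the SVD-based Kabsch implementation under test.
quaternion_rmsd <- function(P, Q) {
  P <- sweep(P, 2, colMeans(P))
  Q <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(P, Q) # 3x3 correlation
  S <- matrix(0, 4, 4)
  S[1, 1] <- M[1, 1] + M[2, 2] + M[3, 3]
  S[1, 2] <- S[2, 1] <- M[2, 3] - M[3, 2]
  S[1, 3] <- S[3, 1] <- M[3, 1] - M[1, 3]
  S[1, 4] <- S[4, 1] <- M[1, 2] - M[2, 1]
  S[2, 2] <- M[1, 1] - M[2, 2] - M[3, 3]
  S[2, 3] <- S[3, 2] <- M[1, 2] + M[2, 1]
  S[2, 4] <- S[4, 2] <- M[3, 1] + M[1, 3]
  S[3, 3] <- -M[1, 1] + M[2, 2] - M[3, 3]
  S[3, 4] <- S[4, 3] <- M[2, 3] + M[3, 2]
  S[4, 4] <- -M[1, 1] - M[2, 2] + M[3, 3]
  lambda <- max(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lambda) / nrow(P)
  sqrt(max(msd, 0))
}

# Brute-force regular-space single pass, written as a plain double loop.
brute_force_rsc <- function(v, d_min) {
  v <- as.matrix(v)
  centers <- 1L
  for (i in seq_len(nrow(v))[-1]) {
    new_center <- TRUE
    for (c in centers) {
      if (sqrt(sum((v[i, ] - v[c, ])^2)) <= d_min) {
        new_center <- FALSE
        break
      }
    }
    if (new_center) centers <- c(centers, i)
  }
  centers
}

# Plug-in mutual information evaluated as an explicit scalar sum over the
# cells of a joint count table (bits).
mi_from_counts <- function(counts) {
  n <- sum(counts)
  p <- counts / n
  px <- rowSums(p)
  py <- colSums(p)
  total <- 0
  for (i in seq_len(nrow(p))) {
    for (j in seq_len(ncol(p))) {
      if (p[i, j] > 0) {
        total <- total + p[i, j] * log2(p[i, j] / (px[i] * py[j]))
      }
    }
  }
  total
}

# Expand a joint count table into paired label vectors.
labels_from_counts <- function(counts) {
  x <- integer(0); y <- integer(0)
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      x <- c(x, rep(i, counts[i, j]))
      y <- c(y, rep(j, counts[i, j]))
    }
  }
  list(x = x, y = y)
}

# Random rigid transform of coordinates (proper rotation + translation).
random_rigid <- function(xyz, seed) {
  withr::with_seed(seed, {
    A <- matrix(rnorm(9), 3, 3)
    qr_d <- qr(A)
    R <- qr.Q(qr_d)
    if (det(R) < 0) R[, 1] <- -R[, 1]
    t <- rnorm(3, sd = 5)
    sweep(xyz %*% R, 2, t, "+")
  })
}

# Small in-memory StructureEnsemble (no files) for unit tests.
toy_structure_ensemble <- function(xyz_list, plddt = NULL, n_res = NULL) {
  n <- nrow(xyz_list[[1]])
  atoms <- data.frame(chain = "A", resid = seq_len(n), resname = "ALA",
                      name = "CA", b = 0, stringsAsFactors = FALSE)
  if (is.null(plddt)) plddt <- rep(0, length(xyz_list))
  structure(list(xyz = xyz_list, atoms = atoms,
                 source_ids = paste0("s", seq_along(xyz_list)),
                 mean_plddt = plddt),
            class = "StructureEnsemble")
}

# Two-trajectory double-well fixture: one short trajectory per well, so both
# states are sampled without requiring barrier crossings.
two_well_ts <- function(n_frames = 8000L, seed = 1L) {
  dw <- potential("double_well_1d", barrier = 8)
  a <- langevin_trajectory(dw, n_steps = n_frames * 5L, step_size = 5e-3,
                           seed = seed, x0 = -1, stride = 5L)
  b <- langevin_trajectory(dw, n_steps = n_frames * 5L, step_size = 5e-3,
                           seed = seed + 1L, x0 = 1, stride = 5L)
  list(
    ts = timeseries(list(a$ts$trajectories[[1]], b$ts$trajectories[[1]]),
                    dt = a$ts$dt, column_names = "x"),
    labels = c(a$labels, b$labels)
  )
}

# Compact two-state pipeline config (writes the synthetic ensemble under
# `root/structs` and points the run at `root/run`).
make_pipeline_config <- function(root, seed = 1L) {
  struct_dir <- file.path(root, "structs")
  make_ensemble(struct_dir, n_states = 2, structures_per_state = 20,
                hinge_angles_deg = c(0, 30), noise_sigma = 0.3,
                plddt_by_state = c(90, 70), seed = seed)
  list(
    output_dir = file.path(root, "run"),
    seed = seed,
    io = list(structures = file.path(struct_dir, "*.pdb"), selection = "name CA"),
    filter = list(cutoff = 50),
    features = list(selection = "name CA", min_residue_separation = 3),
    cluster = list(target_centers = c(2, 2)),
    dynamics = list(mode = "toy", n_steps = 6000, step_size = 0.05,
                    temperature = 0.15, kappa = 2),
    amino = list(k_max = 5, n_bins = 30),
    spib = list(lag_steps = 30, n_initial_states = 6, max_epochs = 25)
  )
}
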