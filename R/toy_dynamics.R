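# Synthetic fixtures: analytic multi-well potentials sampled with overdamped
# Langevin dynamics, and multi-state bead-chain structural ensembles with
# known labels. Every downstream stage of the pipeline is testable against
# these constructed ground truths without a folding model or an MD engine.

#' Analytic toy potentials
#'
#' Three bounded-below forms with finite gradients on the sampling domain:
#'
#' * `harmonic`: `U = kappa/2 * |x - center|^2` in any dimension; stationary
#'   variance per coordinate is `kT / kappa` (closed form used in tests).
#' * `double_well_1d`: `U = barrier * (x^2 - 1)^2`; minima at `x = -1, +1`,
#'   barrier height `barrier` (in kT when `temperature = 1`).
#' * `triple_well_2d`: three inverted Gaussian wells plus harmonic
#'   confinement. The default geometry has a "fast" well pair (A, B)
#'   separated by a low barrier and a "slow" well C behind a high barrier,
#'   giving a constructed timescale separation: at short lag times a state
#'   model resolves all three wells, while at lags beyond the A-B
#'   interconversion time A and B merge.
#'
#' @param form one of `"harmonic"`, `"double_well_1d"`, `"triple_well_2d"`
#' @param ... parameters overriding the defaults: `kappa`, `center`
#'   (harmonic); `barrier` (double well); `wells` (k x 2 matrix), `depths`,
#'   `sigma`, `confinement` (triple well)
#' @return a `PotentialSpec`: list with `form`, `params`, `minima` (k x dim),
#'   `dim`
#' @export
potential <- function(form = c("harmonic", "double_well_1d", "triple_well_2d"),
                      ...) {
  form <- match.arg(form)
  dots <- list(...)
  take <- function(name, default) if (!is.null(dots[[name]])) dots[[name]] else default
  if (form == "harmonic") {
    center <- take("center", 0)
    params <- list(kappa = take("kappa", 1), center = as.numeric(center))
    minima <- matrix(params$center, nrow = 1)
    dim <- length(params$center)
  } else if (form == "double_well_1d") {
    params <- list(barrier = take("barrier", 8))
    minima <- matrix(c(-1, 1), ncol = 1)
    dim <- 1L
  } else {
    params <- list(
      wells = take("wells", rbind(A = c(-1, 0), B = c(1, 0), C = c(0, 2.2))),
      depths = take("depths", c(5, 5, 8)),
      sigma = take("sigma", 0.55),
      confinement = take("confinement", 1.0)
    )
    minima <- params$wells
    dim <- 2L
  }
  structure(list(form = form, params = params, minima = minima, dim = dim),
            class = "PotentialSpec")
}

#' Evaluate a toy potential
#' @param pot a `PotentialSpec`
#' @param x numeric matrix of positions (rows) or a single position vector
#' @return numeric vector of energies (kT units at `temperature = 1`)
#' @export
potential_energy <- function(pot, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = pot$dim)
  p <- pot$params
  switch(pot$form,
    harmonic = 0.5 * p$kappa * rowSums(sweep(x, 2, p$center)^2),
    double_well_1d = p$barrier * (x[, 1]^2 - 1)^2,
    triple_well_2d = {
      u <- 0.5 * p$confinement * rowSums(x^2)
      for (j in seq_len(nrow(p$wells))) {
        r2 <- rowSums(sweep(x, 2, p$wells[j, ])^2)
        u <- u - p$depths[j] * exp(-r2 / (2 * p$sigma^2))
      }
      u
    }
  )
}

#' Assign positions to the basin of the nearest potential minimum
#' @param pot a `PotentialSpec`
#' @param x positions (matrix rows or vector)
#' @return integer well labels (row index into `pot$minima`)
#' @export
well_labels <- function(pot, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = pot$dim)
  d2 <- vapply(seq_len(nrow(pot$minima)), function(j) {
    rowSums(sweep(x, 2, pot$minima[j, ])^2)
  }, numeric(nrow(x)))
  if (nrow(pot$minima) == 1L) return(rep(1L, nrow(x)))
  max.col(-d2)
}

#' Sample a toy potential with overdamped Langevin dynamics
#'
#' Euler-Maruyama integration of `dx = -grad U dt + sqrt(2 kT dt) dW`
#' (Brownian dynamics, no inertia). Positions are emitted every `stride`
#' steps as a CV time series together with per-frame ground-truth well labels
#' (nearest-minimum basin). Identical seeds give byte-identical output.
#'
#' @param pot a `PotentialSpec`
#' @param n_steps number of integration steps
#' @param step_size integration step (must keep the scheme stable; the
#'   integrator aborts with advice if the trajectory diverges)
#' @param temperature kT (energy units of the potential)
#' @param seed RNG seed
#' @param x0 start position (default: first minimum)
#' @param stride save every `stride`-th frame (default 1)
#' @param domain_bound abort threshold on `|x|` (default 1e3)
#' @return list with `ts` (a one-trajectory `TimeSeries`, `dt = step_size *
#'   stride`) and `labels` (integer ground-truth well per saved frame)
#' @export
langevin_trajectory <- function(pot, n_steps, step_size, temperature = 1,
                                seed = 1L, x0 = NULL, stride = 1L,
                                domain_bound = 1e3) {
  stopifnot(inherits(pot, "PotentialSpec"), n_steps >= 1, step_size > 0)
  if (is.null(x0)) x0 <- pot$minima[1, ]
  stopifnot(length(x0) == pot$dim)
  form_code <- match(pot$form, c("harmonic", "double_well_1d", "triple_well_2d")) - 1L
  noise <- withr::with_seed(seed,
    matrix(stats::rnorm(n_steps * pot$dim), ncol = pot$dim))
  pos <- .langevin_integrate(form_code, pot$params, as.numeric(x0), noise,
                             step_size, temperature, as.integer(stride),
                             domain_bound)
  cn <- if (pot$dim == 1L) "x" else c("x", "y")[seq_len(pot$dim)]
  colnames(pos) <- cn
  list(
    ts = timeseries(list(pos), dt = step_size * stride, column_names = cn),
    labels = well_labels(pot, pos)
  )
}

#' Simulate harmonic CV-space exploration around seed structures
#'
#' Stand-in for the short-MD stage of the pipeline: for each cluster-center
#' CV vector, an overdamped Langevin trajectory is run in CV space under a
#' harmonic potential centered on that seed, emulating local conformational
#' sampling around each seed structure. One trajectory per center; columns
#' keep the CV names of `centers`.
#'
#' @param centers numeric matrix (centers x CVs) of seed CV values
#' @param n_steps steps per trajectory
#' @param step_size integration step
#' @param temperature kT, sets the sampling spread `sqrt(kT / kappa)`
#' @param kappa restoring-force constant per CV
#' @param seed RNG seed (each center derives its own sub-seed)
#' @param stride save every `stride`-th frame
#' @return a `TimeSeries` with one trajectory per center
#' @export
simulate_cv_watch <- function(centers, n_steps = 5000L, step_size = 0.05,
                              temperature = 1, kappa = 1, seed = 1L,
                              stride = 1L) {
  centers <- as.matrix(centers)
  trajs <- vector("list", nrow(centers))
  for (i in seq_len(nrow(centers))) {
    pot <- potential("harmonic", kappa = kappa, center = as.numeric(centers[i, ]))
    tr <- langevin_trajectory(pot, n_steps = n_steps, step_size = step_size,
                              temperature = temperature, seed = seed + i - 1L,
                              stride = stride)
    trajs[[i]] <- tr$ts$trajectories[[1]]
  }
  cn <- colnames(centers)
  if (is.null(cn)) cn <- paste0("cv", seq_len(ncol(centers)))
  timeseries(trajs, dt = step_size * stride, column_names = cn,
             traj_ids = paste0("seed", seq_len(nrow(centers))))
}

#' Generate a synthetic multi-state structural ensemble
#'
#' Writes Calpha-only bead-chain PDB files emulating a structurally diverse
#' ensemble with known state labels. A straight chain (3.8 A spacing) is bent
#' at a central hinge by a state-specific angle; intra-state variation is
#' isotropic Gaussian coordinate noise. The per-state pLDDT value is stored
#' in the B-factor column, as AlphaFold2 does.
#'
#' @param dir output directory for the PDB files (created if missing)
#' @param n_states number of conformational states (default 2)
#' @param structures_per_state structures written per state (default 50)
#' @param chain_length beads in the chain (default 20)
#' @param hinge_angles_deg per-state hinge angle in degrees (default
#'   `seq(0, by = 30)`)
#' @param noise_sigma intra-state Gaussian noise sigma in Angstrom
#'   (default 0.3); a warning is issued when it approaches a quarter of the
#'   inter-state displacement and states may overlap
#' @param plddt_by_state per-state pLDDT written to the B-factor column
#'   (default `90, 80, 70, ...`)
#' @param seed RNG seed
#' @return data.frame (the ground-truth table) with columns `file`, `state`;
#'   attribute `"ideal"` holds the noise-free per-state coordinate sets
#' @export
make_ensemble <- function(dir, n_states = 2L, structures_per_state = 50L,
                          chain_length = 20L, hinge_angles_deg = NULL,
                          noise_sigma = 0.3, plddt_by_state = NULL,
                          seed = 1L) {
  stopifnot(n_states >= 1L, structures_per_state >= 1L, chain_length >= 4L)
  if (is.null(hinge_angles_deg)) hinge_angles_deg <- seq(0, by = 30, length.out = n_states)
  if (is.null(plddt_by_state)) plddt_by_state <- pmax(90 - 10 * (seq_len(n_states) - 1), 40)
  stopifnot(length(hinge_angles_deg) == n_states,
            length(plddt_by_state) == n_states)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  L <- chain_length
  base <- cbind(3.8 * (seq_len(L) - 1), 0, 0)
  hinge <- ceiling(L / 2)
  ideal <- lapply(seq_len(n_states), function(s) {
    th <- hinge_angles_deg[s] * pi / 180
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                3, 3, byrow = TRUE)
    xyz <- base
    tail_idx <- (hinge + 1L):L
    xyz[tail_idx, ] <- sweep(sweep(xyz[tail_idx, , drop = FALSE], 2, base[hinge, ]) %*% t(R),
                             2, base[hinge, ], "+")
    xyz
  })

  # smallest displacement between distinct ideal states
  if (n_states > 1L) {
    disp <- min(vapply(utils::combn(n_states, 2, simplify = FALSE), function(p) {
      max(sqrt(rowSums((ideal[[p[1]]] - ideal[[p[2]]])^2)))
    }, numeric(1)))
    if (noise_sigma >= disp / 4) {
      warning("noise_sigma (", noise_sigma, " A) is >= a quarter of the ",
              "smallest inter-state displacement (", round(disp, 2),
              " A); states may overlap", call. = FALSE)
    }
  }

  files <- character(0)
  states <- integer(0)
  withr::with_seed(seed, {
    for (s in seq_len(n_states)) {
      for (r in seq_len(structures_per_state)) {
        xyz <- ideal[[s]]
        if (noise_sigma > 0) xyz <- xyz + matrix(stats::rnorm(3 * L, sd = noise_sigma), L, 3)
        f <- file.path(dir, sprintf("state%d_rep%03d.pdb", s, r))
        bio3d::write.pdb(file = f,
                         xyz = as.numeric(t(xyz)),
                         resno = seq_len(L),
                         resid = rep("ALA", L),
                         elety = rep("CA", L),
                         chain = rep("A", L),
                         b = rep(plddt_by_state[s], L),
                         o = rep(1, L))
        files <- c(files, f)
        states <- c(states, s)
      }
    }
  })
  out <- data.frame(file = files, state = states, stringsAsFactors = FALSE)
  attr(out, "ideal") <- ideal
  out
}

#' Generate groups of redundant CV time series with known membership
#'
#' Emulates the redundancy structure of monitored pairwise distances: a few
#' independent underlying motions, each reported by several noisy copies
#' (neighboring residue pairs track the same motion). Used to benchmark
#' redundancy removal: the ground truth is one representative per group.
#'
#' @param n_frames frames (default 5000)
#' @param n_groups independent underlying signals (default 3)
#' @param copies_per_group noisy copies per signal (default 5)
#' @param noise_sd copy noise as a fraction of the unit signal sd
#'   (default 0.1)
#' @param seed RNG seed
#' @return a `TimeSeries` with one trajectory and columns named
#'   `g<group>_<copy>`
#' @export
make_redundant_cvs <- function(n_frames = 5000L, n_groups = 3L,
                               copies_per_group = 5L, noise_sd = 0.1,
                               seed = 1L) {
  stopifnot(n_frames >= 2L, n_groups >= 1L, copies_per_group >= 1L)
  X <- withr::with_seed(seed, {
    base <- matrix(stats::rnorm(n_frames * n_groups), n_frames, n_groups)
    do.call(cbind, lapply(seq_len(n_groups), function(g) {
      vapply(seq_len(copies_per_group), function(j) {
        base[, g] + stats::rnorm(n_frames, sd = noise_sd)
      }, numeric(n_frames))
    }))
  })
  cn <- paste0("g", rep(seq_len(n_groups), each = copies_per_group), "_",
               rep(seq_len(copies_per_group), n_groups))
  timeseries(list(X), column_names = cn)
}
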