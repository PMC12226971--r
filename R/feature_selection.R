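# Feature selection: reference picking, RMSD filtering, pairwise-distance
# enumeration, coefficient-of-variance ranking, regular-space clustering.

#' Pick the reference structure of an ensemble
#'
#' The structure with the highest mean pLDDT (mean B-factor over the selected
#' atoms) is the default reference for RMSD filtering; ties are broken by the
#' lowest input index. If no structure carries pLDDT information (all
#' B-factors zero) the first structure is used with a warning.
#'
#' @param ensemble a `StructureEnsemble`
#' @return integer structure index (1-based)
#' @export
select_reference <- function(ensemble) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  p <- ensemble$mean_plddt
  if (length(p) == 0L) stop("empty ensemble", call. = FALSE)
  if (all(p == 0)) {
    warning("all B-factors are zero; no pLDDT information, using the first ",
            "structure as reference", call. = FALSE)
    return(1L)
  }
  which.max(p) # returns the first maximum: ties break to the lowest index
}

#' Filter an ensemble by RMSD to a reference structure
#'
#' Every structure is rigidly superposed onto the reference (Kabsch over
#' `fit_selection`) and kept when its RMSD is at most `cutoff`. The reference
#' always survives and input order is preserved. Used to exclude unfolded or
#' unrealistic members of a generated ensemble before feature analysis.
#'
#' @param ensemble a `StructureEnsemble`
#' @param cutoff RMSD cutoff in Angstrom (> 0)
#' @param reference_index structure index of the reference; default
#'   [select_reference()]
#' @param fit_selection selection expression evaluated on the ensemble schema
#'   (default: all schema atoms)
#' @return the filtered `StructureEnsemble`, with attribute `"rmsd"` holding
#'   the per-structure RMSD values of the input ensemble
#' @export
rmsd_filter <- function(ensemble, cutoff, reference_index = NULL,
                        fit_selection = "all") {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0) {
    stop("cutoff must be a single positive number (Angstrom)", call. = FALSE)
  }
  if (is.null(reference_index)) reference_index <- select_reference(ensemble)
  n <- n_structures(ensemble)
  stopifnot(reference_index >= 1L, reference_index <= n)
  fit_idx <- select_atoms(ensemble$atoms, fit_selection)
  ref <- ensemble$xyz[[reference_index]]
  rmsd <- vapply(seq_len(n), function(i) {
    if (i == reference_index) return(0)
    superpose(ensemble$xyz[[i]], ref, fit_selection = fit_idx)$rmsd
  }, numeric(1))
  keep <- rmsd <= cutoff
  keep[reference_index] <- TRUE
  out <- .subset_ensemble(ensemble, which(keep))
  attr(out, "rmsd") <- rmsd
  attr(out, "kept") <- which(keep)
  out
}

#' Enumerate pairwise-distance feature definitions
#'
#' All unordered atom pairs from a selection whose residue separation is at
#' least `min_residue_separation` (pairs on different chains are always
#' allowed). Small separations are excluded by default because neighboring
#' residues are trivially rigid and carry no conformational signal.
#'
#' @param ensemble a `StructureEnsemble` (its schema defines atom indices)
#' @param selection selection expression (default `"name CA"`)
#' @param min_residue_separation minimum `|resid_i - resid_j|` on the same
#'   chain (default 3)
#' @return data.frame of class `FeatureSpec` with columns `atom_i`, `atom_j`
#'   (schema indices, `atom_i < atom_j`) and `label`
#'   (`chain:resid:name-chain:resid:name`)
#' @export
enumerate_pair_features <- function(ensemble, selection = "name CA",
                                    min_residue_separation = 3L) {
  stopifnot(inherits(ensemble, "StructureEnsemble"))
  atoms <- ensemble$atoms
  idx <- select_atoms(atoms, selection)
  if (length(idx) < 2L) {
    stop("selection resolves to fewer than 2 atoms; no pairs to enumerate",
         call. = FALSE)
  }
  pairs <- utils::combn(idx, 2L)
  i <- pairs[1, ]; j <- pairs[2, ]
  same_chain <- atoms$chain[i] == atoms$chain[j]
  sep <- abs(atoms$resid[i] - atoms$resid[j])
  keep <- !same_chain | sep >= min_residue_separation
  i <- i[keep]; j <- j[keep]
  lab <- function(k) paste(atoms$chain[k], atoms$resid[k], atoms$name[k], sep = ":")
  labels <- if (length(i)) paste0(lab(i), "-", lab(j)) else character(0)
  out <- data.frame(atom_i = i, atom_j = j, label = labels,
                    stringsAsFactors = FALSE)
  class(out) <- c("FeatureSpec", "data.frame")
  out
}

#' Compute a structures x features distance matrix
#'
#' Evaluates each pairwise-distance feature on every structure. Distances are
#' rigid-body invariant, so no prior superposition is required.
#'
#' @param ensemble a `StructureEnsemble`
#' @param specs a `FeatureSpec` data.frame from [enumerate_pair_features()]
#' @return a `FeatureMatrix`: list with `values` (structures x features,
#'   Angstrom), `specs`, `source_ids`
#' @export
compute_feature_matrix <- function(ensemble, specs) {
  stopifnot(inherits(ensemble, "StructureEnsemble"), nrow(specs) >= 1L)
  vals <- vapply(ensemble$xyz, function(xyz) {
    sqrt(rowSums((xyz[specs$atom_i, , drop = FALSE] -
                  xyz[specs$atom_j, , drop = FALSE])^2))
  }, numeric(nrow(specs)))
  vals <- if (nrow(specs) == 1L) matrix(vals, ncol = 1L) else t(vals)
  colnames(vals) <- specs$label
  structure(list(values = vals, specs = specs, source_ids = ensemble$source_ids),
            class = "FeatureMatrix")
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat("FeatureMatrix:", nrow(x$values), "structures x", ncol(x$values), "features\n")
  invisible(x)
}

#' Per-feature spread statistics
#'
#' The coefficient of variance used for ranking is defined as
#' `CoV = variance / mean` (population variance, units of Angstrom) — not the
#' conventional dimensionless `sd/mean`, which is available via
#' `cov_type = "sd"`.
#'
#' @param fm a `FeatureMatrix`
#' @param cov_type `"variance"` (variance/mean, default) or `"sd"` (sd/mean)
#' @return data.frame with `label`, `mean`, `variance`, `cov`
#' @export
feature_stats <- function(fm, cov_type = c("variance", "sd")) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  cov_type <- match.arg(cov_type)
  v <- fm$values
  n <- nrow(v)
  mu <- colMeans(v)
  va <- colMeans(v^2) - mu^2       # population variance (divide by N)
  va <- pmax(va, 0)                 # guard tiny negative round-off
  covv <- switch(cov_type, variance = va / mu, sd = sqrt(va) / mu)
  data.frame(label = fm$specs$label, mean = mu, variance = va, cov = covv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank features by coefficient of variance and keep the top m
#'
#' Features are sorted by CoV descending (ties broken by label, lexicographic)
#' and the top `top_m` columns are retained. The default
#' `top_m = min(ceiling(0.05 * n_features), 200)` keeps roughly the top 5% of
#' all features without exceeding a few hundred, which keeps Euclidean
#' distances in the downstream clustering informative.
#'
#' @param fm a `FeatureMatrix`
#' @param top_m number of features to keep (default as above)
#' @param cov_type see [feature_stats()]
#' @return list with `matrix` (the restricted `FeatureMatrix`) and `stats`
#'   (full feature statistics with a `rank` column)
#' @export
rank_by_cov <- function(fm, top_m = NULL, cov_type = c("variance", "sd")) {
  stopifnot(inherits(fm, "FeatureMatrix"))
  cov_type <- match.arg(cov_type)
  nf <- ncol(fm$values)
  if (is.null(top_m)) top_m <- min(ceiling(0.05 * nf), 200L)
  if (top_m < 1L) stop("top_m must be >= 1", call. = FALSE)
  if (top_m > nf) {
    warning("top_m (", top_m, ") exceeds the number of features (", nf,
            "); keeping all features", call. = FALSE)
    top_m <- nf
  }
  st <- feature_stats(fm, cov_type)
  ord <- order(-st$cov, st$label, method = "radix")
  st$rank <- NA_integer_
  st$rank[ord] <- seq_len(nf)
  keep <- ord[seq_len(top_m)]
  restricted <- structure(
    list(values = fm$values[, keep, drop = FALSE],
         specs = fm$specs[keep, , drop = FALSE],
         source_ids = fm$source_ids),
    class = "FeatureMatrix"
  )
  list(matrix = restricted, stats = st)
}

.fm_values <- function(x) {
  if (inherits(x, "FeatureMatrix")) x$values else as.matrix(x)
}

#' Regular-space clustering
#'
#' Single deterministic pass over the structures in input order: a structure
#' becomes a new cluster center iff its Euclidean distance in feature space
#' to every existing center is strictly greater than `d_min`. The first
#' structure is always a center. Afterwards every structure is assigned to
#' its nearest center. This yields centers that are pairwise more than
#' `d_min` apart while every structure lies within `d_min` of some center —
#' a diverse, non-redundant set of seed structures.
#'
#' @param x a `FeatureMatrix` or numeric matrix (rows = structures)
#' @param d_min distance threshold (>= 0), in feature-space units (Angstrom)
#' @return a `ClusterResult`: list with `center_indices`, `assignments`
#'   (per-structure center index into `center_indices`), `d_min`, `n_centers`
#' @export
regular_space_cluster <- function(x, d_min) {
  v <- .fm_values(x)
  if (!is.numeric(d_min) || length(d_min) != 1L || d_min < 0) {
    stop("d_min must be a single non-negative number", call. = FALSE)
  }
  n <- nrow(v)
  if (n < 1L) stop("need at least one structure", call. = FALSE)
  centers <- 1L
  if (n > 1L) {
    for (i in 2L:n) {
      d2 <- colSums((t(v[centers, , drop = FALSE]) - v[i, ])^2)
      if (all(d2 > d_min^2)) centers <- c(centers, i)
    }
  }
  cmat <- v[centers, , drop = FALSE]
  assignments <- vapply(seq_len(n), function(i) {
    which.min(colSums((t(cmat) - v[i, ])^2))
  }, integer(1))
  structure(
    list(center_indices = centers, assignments = assignments,
         d_min = d_min, n_centers = length(centers)),
    class = "ClusterResult"
  )
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("ClusterResult:", x$n_centers, "centers (d_min =", x$d_min, ")\n")
  invisible(x)
}

#' Suggest a regular-space distance threshold for a target center count
#'
#' Bisects `d_min` until the number of regular-space centers falls inside
#' `target_centers = c(lo, hi)` (5 to 20 centers is a practical range for
#' seeding short MD runs) or the iteration budget is exhausted. When the
#' target is unreachable (fewer distinct structures than `lo`) the best
#' effort is returned with a warning.
#'
#' @param x a `FeatureMatrix` or numeric matrix
#' @param target_centers integer range `c(lo, hi)`
#' @param max_iter bisection iterations (default 30)
#' @return list with `d_min`, `n_centers`, `cluster` (the `ClusterResult`)
#' @export
suggest_d_min <- function(x, target_centers = c(5L, 20L), max_iter = 30L) {
  v <- .fm_values(x)
  lo_t <- target_centers[1]; hi_t <- target_centers[2]
  stopifnot(lo_t >= 1L, hi_t >= lo_t)
  n_distinct <- nrow(unique(v))
  # upper bound: diameter of the bounding box guarantees a single center
  hi <- sqrt(sum((apply(v, 2, max) - apply(v, 2, min))^2))
  if (hi == 0) hi <- 1
  lo <- 0
  best <- NULL
  d <- hi / 2
  for (iter in seq_len(max_iter)) {
    cl <- regular_space_cluster(v, d)
    k <- cl$n_centers
    if (is.null(best) || abs(k - (lo_t + hi_t) / 2) <
        abs(best$n_centers - (lo_t + hi_t) / 2)) {
      best <- list(d_min = d, n_centers = k, cluster = cl)
    }
    if (k >= lo_t && k <= hi_t) {
      return(list(d_min = d, n_centers = k, cluster = cl))
    }
    if (k < lo_t) hi <- d else lo <- d   # too few centers -> shrink d_min
    d <- (lo + hi) / 2
  }
  if (n_distinct < lo_t) {
    warning("only ", n_distinct, " distinct structures; target of at least ",
            lo_t, " centers is unreachable", call. = FALSE)
  } else {
    warning("bisection did not reach the target center count in ", max_iter,
            " iterations; returning best effort (", best$n_centers, " centers)",
            call. = FALSE)
  }
  best
}

#' Write a CSV report of feature statistics
#' @param stats data.frame from [rank_by_cov()]/[feature_stats()]
#' @param path output CSV path
#' @export
write_feature_report <- function(stats, path) {
  ord <- if ("rank" %in% names(stats)) order(stats$rank) else seq_len(nrow(stats))
  utils::write.csv(stats[ord, , drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Export cluster-center structures as PDB files
#'
#' Writes one PDB per regular-space center, named after the structure's
#' source id, for use as seeds of short MD simulations.
#'
#' @param ensemble the `StructureEnsemble` that was clustered
#' @param cluster a `ClusterResult` on the same structures
#' @param dir output directory (created if missing)
#' @return character vector of written paths
#' @export
export_centers <- function(ensemble, cluster, dir) {
  stopifnot(inherits(ensemble, "StructureEnsemble"), inherits(cluster, "ClusterResult"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atoms <- ensemble$atoms
  paths <- character(0)
  for (ci in cluster$center_indices) {
    id <- gsub("[^A-Za-z0-9._-]", "_", ensemble$source_ids[ci])
    path <- file.path(dir, paste0(sub("\\.pdb$", "", id), "_center.pdb"))
    bio3d::write.pdb(file = path,
                     xyz = as.numeric(t(ensemble$xyz[[ci]])),
                     resno = atoms$resid, resid = atoms$resname,
                     elety = atoms$name, chain = atoms$chain,
                     b = atoms$b, o = rep(1, nrow(atoms)))
    paths <- c(paths, path)
  }
  paths
}
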