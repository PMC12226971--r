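# AMINO: prune redundant CVs using a mutual-information distance and
# k-medoid clustering, keeping one representative CV per correlated group.

#' Discretize a time series into equal-width bins
#'
#' Per CV, frames from all trajectories are pooled, the range `[min, max]` is
#' split into `n_bins` equal-width bins and every frame is mapped to its bin
#' index (0-based; the last bin is right-closed). Redundancy between CVs is a
#' static property, so trajectory boundaries are irrelevant here.
#'
#' @param ts a `TimeSeries` or numeric matrix (frames x CVs)
#' @param n_bins number of bins per CV (>= 2, default 50)
#' @return a `DiscretizedSeries`: list with `labels` (frames x CVs integer
#'   matrix of bin indices in `[0, n_bins)`), `n_bins`, `edges` (per-CV bin
#'   edges), `column_names`
#' @export
discretize <- function(ts, n_bins = 50L) {
  if (!is.numeric(n_bins) || n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  n_bins <- as.integer(n_bins)
  x <- if (inherits(ts, "TimeSeries")) ts_pool(ts) else as.matrix(ts)
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("cv", seq_len(ncol(x)))
  labels <- matrix(0L, nrow(x), ncol(x))
  edges <- vector("list", ncol(x))
  constant <- character(0)
  for (j in seq_len(ncol(x))) {
    lo <- min(x[, j]); hi <- max(x[, j])
    if (hi == lo) {
      constant <- c(constant, cn[j])
      edges[[j]] <- c(lo, lo)
      next # all frames stay in bin 0
    }
    e <- seq(lo, hi, length.out = n_bins + 1L)
    b <- floor((x[, j] - lo) / (hi - lo) * n_bins)
    labels[, j] <- as.integer(pmin(b, n_bins - 1L)) # right-close the last bin
    edges[[j]] <- e
  }
  if (length(constant)) {
    warning("constant CV(s) mapped to a single bin: ",
            paste(constant, collapse = ", "), call. = FALSE)
  }
  colnames(labels) <- cn
  structure(list(labels = labels, n_bins = n_bins, edges = edges,
                 column_names = cn),
            class = "DiscretizedSeries")
}

#' Plug-in mutual information between two discrete label sequences
#'
#' `I(X;Y) = sum p(x,y) log2[p(x,y) / (p(x) p(y))]` from the empirical joint
#' frequencies, in bits.
#'
#' @param x,y integer label vectors of equal length
#' @return mutual information in bits (>= 0 up to round-off)
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  joint <- table(x, y) / length(x)
  px <- rowSums(joint); py <- colSums(joint)
  nz <- joint > 0
  outer_p <- outer(px, py)
  sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
}

.joint_entropy <- function(x, y) {
  p <- as.numeric(table(x, y)) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mutual-information distance between two discrete label sequences
#'
#' `D(X,Y) = 1 - I(X;Y) / H(X,Y)` — a symmetric dissimilarity in `[0, 1]`
#' with `D(X,X) = 0` and `D = 1` for independent variables. Two constant
#' signals (joint entropy zero) are defined as identical, `D = 0`, with a
#' warning.
#'
#' @param x,y integer label vectors of equal length
#' @return distance in `[0, 1]`
#' @export
mi_distance <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  h <- .joint_entropy(x, y)
  if (h == 0) {
    warning("both signals are constant (zero joint entropy); defining D = 0",
            call. = FALSE)
    return(0)
  }
  d <- 1 - mutual_information(x, y) / h
  min(max(d, 0), 1)
}

#' Pairwise MI-distance matrix of a discretized series
#' @param disc a `DiscretizedSeries`
#' @return symmetric n_CV x n_CV matrix with zero diagonal
#' @export
mi_distance_matrix <- function(disc) {
  stopifnot(inherits(disc, "DiscretizedSeries"))
  L <- disc$labels
  n <- ncol(L)
  D <- matrix(0, n, n, dimnames = list(disc$column_names, disc$column_names))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- mi_distance(L[, i], L[, j])
    }
  }
  D
}

# Seeded k-medoids: k-medoids++ initialization followed by PAM-style swap
# local search. Deterministic given the seed.
.kmedoids <- function(D, k, seed) {
  n <- nrow(D)
  stopifnot(k >= 1L, k <= n)
  meds <- withr::with_seed(seed, {
    m <- which.min(colSums(D)) # most central point first
    while (length(m) < k) {
      d2 <- apply(D[m, , drop = FALSE], 2, min)^2
      if (sum(d2) == 0) {
        # all remaining points coincide with a medoid: take any non-medoid
        cand <- setdiff(seq_len(n), m)
        m <- c(m, cand[1])
      } else {
        m <- c(m, sample.int(n, 1L, prob = d2))
      }
    }
    m
  })
  cost <- function(meds) sum(apply(D[meds, , drop = FALSE], 2, min))
  best <- cost(meds)
  repeat {
    improved <- FALSE
    for (mi in seq_along(meds)) {
      for (o in setdiff(seq_len(n), meds)) {
        trial <- meds
        trial[mi] <- o
        ct <- cost(trial)
        if (ct < best - 1e-12) {
          meds <- trial
          best <- ct
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  meds <- sort(meds)
  assign <- apply(D[meds, , drop = FALSE], 2, which.min)
  list(medoids = meds, cluster = assign, cost = best)
}

#' Reduce a redundant CV set to representative medoids (AMINO)
#'
#' Monitored pairwise distances are typically heavily redundant (neighbors of
#' an informative residue pair track the same motion). This routine bins the
#' time series, computes the pairwise MI distance `1 - I/H`, runs k-medoid
#' clustering for every `k` in `[1, k_max]`, and picks `k` with the
#' distortion-jump criterion: with distortion `d_k` = mean squared MI
#' distance of each CV to its nearest medoid, the selected `k` maximizes
#' `d_k^(-p) - d_(k-1)^(-p)` (transform power `p = 1` for this scalar
#' distortion, `d_0^(-p) := 0`). Zero-distortion solutions (exact duplicate
#' groups) select the smallest such `k`. In practice this reduces a few
#' hundred CVs to fewer than 20.
#'
#' @param ts a `TimeSeries` or numeric matrix (frames x CVs)
#' @param k_max largest candidate number of representatives (default 20)
#' @param n_bins histogram bins for the MI estimate (default 50)
#' @param seed RNG seed for the medoid initialization
#' @return an `AminoResult`: list with `selected` (medoid CV names), `k`,
#'   `distance_matrix`, `distortion` (per candidate k), `jump`, `groups`
#'   (per-CV medoid assignment at the chosen k)
#' @export
amino_reduce <- function(ts, k_max = 20L, n_bins = 50L, seed = 1L) {
  x <- if (inherits(ts, "TimeSeries")) ts_pool(ts) else as.matrix(ts)
  n_cv <- ncol(x)
  if (n_cv < 2L) stop("need at least 2 CVs", call. = FALSE)
  if (k_max < 1L) stop("k_max must be >= 1", call. = FALSE)
  if (k_max > n_cv) {
    warning("k_max (", k_max, ") exceeds the number of CVs (", n_cv,
            "); clamping", call. = FALSE)
    k_max <- n_cv
  }
  disc <- discretize(x, n_bins)
  D <- mi_distance_matrix(disc)

  fits <- vector("list", k_max)
  distortion <- numeric(k_max)
  for (k in seq_len(k_max)) {
    fits[[k]] <- .kmedoids(D, k, seed = seed + k)
    distortion[k] <- mean(apply(D[fits[[k]]$medoids, , drop = FALSE], 2, min)^2)
  }
  inv <- ifelse(distortion > 0, 1 / distortion, Inf)
  jump <- inv - c(0, inv[-k_max])
  if (any(distortion == 0)) {
    k_best <- which(distortion == 0)[1] # smallest k that already separates all groups
  } else {
    k_best <- which.max(jump)
  }
  fit <- fits[[k_best]]
  structure(
    list(selected = disc$column_names[fit$medoids],
         k = k_best,
         distance_matrix = D,
         distortion = distortion,
         jump = jump,
         groups = stats::setNames(disc$column_names[fit$medoids][fit$cluster],
                                  disc$column_names),
         seed = seed),
    class = "AminoResult"
  )
}

#' @export
print.AminoResult <- function(x, ...) {
  cat("AminoResult: kept", x$k, "of", ncol(x$distance_matrix), "CVs:\n  ",
      paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' Restrict a time series to a subset of CV columns
#' @param ts a `TimeSeries`
#' @param columns CV names to keep (e.g. `AminoResult$selected`)
#' @return a `TimeSeries` with the selected columns
#' @export
ts_select <- function(ts, columns) {
  stopifnot(inherits(ts, "TimeSeries"))
  missing <- setdiff(columns, ts$column_names)
  if (length(missing)) {
    stop("unknown CV name(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  timeseries(lapply(ts$trajectories, function(m) m[, columns, drop = FALSE]),
             dt = ts$dt, column_names = columns, traj_ids = ts$traj_ids)
}
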