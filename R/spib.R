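# State Predictive Information Bottleneck (SPIB).
#
# A stochastic encoder maps a CV vector x_t to a low-dimensional Gaussian
# latent z; a decoder predicts the state label at t + lag from z. Training
# minimizes
#     E[-log p_decoder(label_{t+lag} | z)] + beta * KL(q(z|x) || r(z))
# with r(z) a learnable mixture-of-Gaussians prior (one component per live
# state). Every refinement interval, frames are relabeled to the argmax
# decoded state of their own encoded mean; empty states are dropped. The
# procedure converges to a set of metastable states whose granularity is
# controlled by the lag: lags longer than a pair's interconversion time merge
# those states.
#
# The network is small (2 tanh hidden layers), so forward/backward passes are
# plain matrix algebra with hand-derived gradients and Adam updates; the
# gradients are verified against finite differences in the test suite.

#' SPIB configuration
#'
#' @param lag_steps prediction horizon in frames (the key granularity knob:
#'   larger lags average out fast dynamics and yield fewer states)
#' @param latent_dim latent dimensionality (default 2, giving a plottable
#'   plane)
#' @param beta bottleneck trade-off > 0 (default 0.01)
#' @param n_initial_states initial k-means states (default 10; refinement
#'   prunes downward)
#' @param refinement_interval epochs between relabeling passes (default 1)
#' @param convergence_tol max fraction of frames changing label to count as
#'   stable (default 0.01)
#' @param patience consecutive stable relabelings required (default 10)
#' @param max_epochs training epoch cap (default 40)
#' @param seed RNG seed (all stochasticity flows through it)
#' @param hidden encoder hidden width (default 64)
#' @param learning_rate Adam step size (default 3e-3)
#' @param batch_size minibatch size (default 500)
#' @param epoch_samples prediction pairs sampled per epoch (default 10000;
#'   capped at the number of available pairs)
#' @param warmup_epochs epochs trained before the first relabeling pass
#'   (default 5)
#' @return a `SpibConfig` list
#' @export
spib_config <- function(lag_steps, latent_dim = 2L, beta = 0.01,
                        n_initial_states = 10L, refinement_interval = 1L,
                        convergence_tol = 0.01, patience = 10L,
                        max_epochs = 40L, seed = 1L, hidden = 64L,
                        learning_rate = 3e-3, batch_size = 500L,
                        epoch_samples = 10000L, warmup_epochs = 5L) {
  stopifnot(lag_steps >= 1L, latent_dim >= 1L, beta > 0, n_initial_states >= 1L,
            refinement_interval >= 1L, convergence_tol > 0, max_epochs >= 1L)
  structure(list(
    lag_steps = as.integer(lag_steps), latent_dim = as.integer(latent_dim),
    beta = beta, n_initial_states = as.integer(n_initial_states),
    refinement_interval = as.integer(refinement_interval),
    convergence_tol = convergence_tol, patience = as.integer(patience),
    max_epochs = as.integer(max_epochs), seed = as.integer(seed),
    hidden = as.integer(hidden), learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    epoch_samples = as.integer(epoch_samples),
    warmup_epochs = as.integer(warmup_epochs)
  ), class = "SpibConfig")
}

#' Initial state labels by k-means in CV space
#'
#' Pooled frames are standardized and clustered with seeded k-means. When the
#' data have fewer distinct frames than requested states, the empty clusters
#' collapse and a warning reports the reduced count.
#'
#' @param ts a `TimeSeries`
#' @param n_initial_states requested number of initial states (>= 1)
#' @param seed RNG seed
#' @return a `StateLabels`: list with `labels` (per-trajectory integer
#'   vectors), `n_states`
#' @export
init_labels <- function(ts, n_initial_states = 10L, seed = 1L) {
  stopifnot(inherits(ts, "TimeSeries"), n_initial_states >= 1L)
  X <- ts_pool(ts)
  if (n_initial_states > nrow(X)) {
    stop("n_initial_states exceeds the number of frames", call. = FALSE)
  }
  sdv <- apply(X, 2, stats::sd)
  Xs <- scale(X, center = TRUE, scale = ifelse(sdv > 0, sdv, 1))
  k <- n_initial_states
  n_unique <- nrow(unique(Xs))
  if (n_unique < k) {
    warning(k - n_unique, " initial state(s) collapse: only ", n_unique,
            " distinct frames", call. = FALSE)
    k <- n_unique
  }
  lab <- if (k == 1L) {
    rep(1L, nrow(X))
  } else {
    withr::with_seed(seed, {
      # exact k-means convergence is irrelevant for an initialization that
      # SPIB refinement immediately reworks; silence the iteration warning
      suppressWarnings(
        stats::kmeans(Xs, centers = k, nstart = 5L, iter.max = 200L,
                      algorithm = "Lloyd")$cluster)
    })
  }
  .relist_labels(as.integer(lab), ts, max(lab))
}

.relist_labels <- function(pooled, ts, n_states) {
  lens <- vapply(ts$trajectories, nrow, integer(1))
  ends <- cumsum(lens)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  structure(list(
    labels = lapply(seq_along(lens), function(i) pooled[starts[i]:ends[i]]),
    n_states = n_states
  ), class = "StateLabels")
}

# ---------------------------------------------------------------------------
# network internals
# ---------------------------------------------------------------------------

.spib_init_par <- function(D, H, d, K) {
  rn <- function(a, b) matrix(stats::rnorm(a * b, sd = sqrt(2 / (a + b))), a, b)
  list(W1 = rn(D, H), b1 = numeric(H),
       W2 = rn(H, H), b2 = numeric(H),
       Wmu = rn(H, d), bmu = numeric(d),
       ls = rep(log(0.3), d),
       Wd = rn(d, K), bd = numeric(K),
       M = matrix(stats::rnorm(K * d, sd = 0.5), K, d))
}

.spib_encode <- function(par, X) {
  A1 <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
  A2 <- tanh(sweep(A1 %*% par$W2, 2, par$b2, "+"))
  sweep(A2 %*% par$Wmu, 2, par$bmu, "+")
}

.softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

# deterministic decode of frame labels from encoder means; chunked to bound
# peak memory on long trajectories
.spib_decode_labels <- function(par, X, chunk = 200000L) {
  n <- nrow(X)
  out <- integer(n)
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    MU <- .spib_encode(par, X[s:e, , drop = FALSE])
    LOGIT <- sweep(MU %*% par$Wd, 2, par$bd, "+")
    out[s:e] <- max.col(LOGIT, ties.method = "first")
  }
  out
}

# forward + hand-derived gradients for one minibatch
.spib_step <- function(par, X, Y, EPS, beta) {
  B <- nrow(X); K <- ncol(par$Wd); d <- ncol(par$Wmu)
  A1 <- tanh(sweep(X %*% par$W1, 2, par$b1, "+"))
  A2 <- tanh(sweep(A1 %*% par$W2, 2, par$b2, "+"))
  MU <- sweep(A2 %*% par$Wmu, 2, par$bmu, "+")
  S <- exp(par$ls)
  Z <- MU + sweep(EPS, 2, S, "*")
  LOGIT <- sweep(Z %*% par$Wd, 2, par$bd, "+")
  P <- .softmax_rows(LOGIT)
  ce <- -mean(log(pmax(P[cbind(seq_len(B), Y)], 1e-300)))

  # mixture prior: uniform weights, unit variance
  rZ <- rowSums(Z^2); rM <- rowSums(par$M^2)
  C <- -(outer(rZ, rM, "+") - 2 * Z %*% t(par$M)) / 2 -
    d / 2 * log(2 * pi) - log(K)
  cmax <- apply(C, 1, max)
  lr <- cmax + log(rowSums(exp(C - cmax)))
  G <- exp(C - lr) # responsibilities, B x K
  lq <- rowSums(matrix(-0.5 * log(2 * pi) - rep(par$ls, each = B) -
                         0.5 * EPS^2, B, d))
  kl <- mean(lq - lr)
  loss <- ce + beta * kl

  onehot <- matrix(0, B, K); onehot[cbind(seq_len(B), Y)] <- 1
  dLOG <- (P - onehot) / B
  gWd <- crossprod(Z, dLOG); gbd <- colSums(dLOG)
  dZ <- dLOG %*% t(par$Wd) + (beta / B) * (Z - G %*% par$M)
  gM <- (beta / B) * (colSums(G) * par$M - crossprod(G, Z))
  gls <- -beta + colSums(dZ * EPS) * S
  gWmu <- crossprod(A2, dZ); gbmu <- colSums(dZ)
  dA2 <- (dZ %*% t(par$Wmu)) * (1 - A2^2)
  gW2 <- crossprod(A1, dA2); gb2 <- colSums(dA2)
  dA1 <- (dA2 %*% t(par$W2)) * (1 - A1^2)
  gW1 <- crossprod(X, dA1); gb1 <- colSums(dA1)

  list(loss = loss, ce = ce, kl = kl,
       grads = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
                    Wmu = gWmu, bmu = gbmu, ls = gls,
                    Wd = gWd, bd = gbd, M = gM))
}

.adam_new <- function(par) {
  list(m = lapply(par, function(p) p * 0), v = lapply(par, function(p) p * 0),
       t = 0L)
}

.adam_update <- function(par, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t; bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    par[[nm]] <- par[[nm]] - lr * (st$m[[nm]] / bc1) /
      (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(par = par, st = st)
}

# drop decoder columns / prior components of dead states, remapping labels
.spib_prune <- function(par, adam, y, alive) {
  par$Wd <- par$Wd[, alive, drop = FALSE]
  par$bd <- par$bd[alive]
  par$M <- par$M[alive, , drop = FALSE]
  for (f in c("m", "v")) {
    adam[[f]]$Wd <- adam[[f]]$Wd[, alive, drop = FALSE]
    adam[[f]]$bd <- adam[[f]]$bd[alive]
    adam[[f]]$M <- adam[[f]]$M[alive, , drop = FALSE]
  }
  list(par = par, adam = adam, y = match(y, alive))
}

# ---------------------------------------------------------------------------

#' Train a State Predictive Information Bottleneck model
#'
#' Prediction pairs `(x_t, label_{t + lag_steps})` are formed within each
#' trajectory only — never across trajectory boundaries. Training alternates
#' minibatch gradient steps on the variational objective with periodic
#' relabeling of all frames to the argmax decoded state of their own encoded
#' mean; empty states are dropped as they arise. Training stops when the
#' fraction of frames changing label stays below `convergence_tol` for
#' `patience` consecutive relabelings, or at `max_epochs`.
#'
#' @param ts a `TimeSeries`
#' @param cfg a `SpibConfig`
#' @param init optional initial `StateLabels` (default: [init_labels()] with
#'   `cfg$n_initial_states` and `cfg$seed`)
#' @return list with `model` (a `SpibModel`) and `labels` (converged
#'   `StateLabels` including per-frame latent coordinates)
#' @export
train_spib <- function(ts, cfg, init = NULL) {
  stopifnot(inherits(ts, "TimeSeries"), inherits(cfg, "SpibConfig"))
  lens <- vapply(ts$trajectories, nrow, integer(1))
  if (cfg$lag_steps >= min(lens)) {
    stop("lag_steps (", cfg$lag_steps, ") must be smaller than the shortest ",
         "trajectory (", min(lens), " frames)", call. = FALSE)
  }
  if (is.null(init)) init <- init_labels(ts, cfg$n_initial_states, cfg$seed)
  stopifnot(inherits(init, "StateLabels"))

  X <- ts_pool(ts)
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd)
  x_sd[x_sd == 0] <- 1
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")

  y <- unlist(init$labels, use.names = FALSE)
  alive0 <- sort(unique(y))
  y <- match(y, alive0)
  K <- length(alive0)

  # within-trajectory prediction pairs
  ends <- cumsum(lens); starts <- c(1L, utils::head(ends, -1L) + 1L)
  src <- unlist(lapply(seq_along(lens), function(i) {
    starts[i]:(ends[i] - cfg$lag_steps)
  }), use.names = FALSE)
  tgt <- src + cfg$lag_steps
  n_pairs <- length(src)
  epoch_samples <- min(cfg$epoch_samples, n_pairs)

  history <- list(loss = numeric(0), label_change = numeric(0),
                  n_states = integer(0))
  d <- cfg$latent_dim

  out <- withr::with_seed(cfg$seed, {
    par <- .spib_init_par(ncol(Xs), cfg$hidden, d, K)
    adam <- .adam_new(par)
    stable <- 0L
    prev_y <- y
    collapsed <- FALSE

    for (epoch in seq_len(cfg$max_epochs)) {
      idx <- sample.int(n_pairs, epoch_samples)
      epoch_loss <- 0
      n_batches <- ceiling(epoch_samples / cfg$batch_size)
      for (b in seq_len(n_batches)) {
        take <- idx[((b - 1L) * cfg$batch_size + 1L):
                      min(b * cfg$batch_size, epoch_samples)]
        Xb <- Xs[src[take], , drop = FALSE]
        Yb <- y[tgt[take]]
        EPS <- matrix(stats::rnorm(length(take) * d), length(take), d)
        step <- .spib_step(par, Xb, Yb, EPS, cfg$beta)
        if (!is.finite(step$loss)) {
          stop("SPIB loss became non-finite at epoch ", epoch,
               " (ce = ", signif(step$ce, 4), ", kl = ", signif(step$kl, 4),
               "); try a smaller learning_rate or larger beta", call. = FALSE)
        }
        upd <- .adam_update(par, step$grads, adam, cfg$learning_rate)
        par <- upd$par; adam <- upd$st
        epoch_loss <- epoch_loss + step$loss / n_batches
      }
      history$loss <- c(history$loss, epoch_loss)

      relabel_due <- epoch > cfg$warmup_epochs &&
        (epoch - cfg$warmup_epochs) %% cfg$refinement_interval == 0L
      if (relabel_due) {
        new_y <- .spib_decode_labels(par, Xs)
        changed <- mean(new_y != prev_y)
        counts <- tabulate(new_y, nbins = ncol(par$Wd))
        alive <- which(counts > 0L)
        if (length(alive) < ncol(par$Wd)) {
          pr <- .spib_prune(par, adam, new_y, alive)
          par <- pr$par; adam <- pr$adam; new_y <- pr$y
        }
        y <- new_y
        prev_y <- new_y
        history$label_change <- c(history$label_change, changed)
        history$n_states <- c(history$n_states, ncol(par$Wd))
        if (ncol(par$Wd) == 1L) {
          collapsed <- TRUE
          break
        }
        stable <- if (changed < cfg$convergence_tol) stable + 1L else 0L
        if (stable >= cfg$patience) break
      }
    }
    list(par = par, y = y, collapsed = collapsed)
  })

  if (out$collapsed) {
    warning("all frames collapsed into a single state", call. = FALSE)
  }
  par <- out$par
  final_y <- .spib_decode_labels(par, Xs)
  counts <- tabulate(final_y, nbins = ncol(par$Wd))
  alive <- which(counts > 0L)
  if (length(alive) < ncol(par$Wd)) {
    pr <- .spib_prune(par, .adam_new(par), final_y, alive)
    par <- pr$par; final_y <- pr$y
  }
  n_states <- ncol(par$Wd)
  latent <- .spib_encode(par, Xs)

  model <- structure(list(
    par = par, x_mean = x_mean, x_sd = x_sd,
    column_names = ts$column_names, latent_dim = d,
    n_states = n_states, cfg = cfg, history = history
  ), class = "SpibModel")

  labels <- .relist_labels(final_y, ts, n_states)
  labels$latent <- lapply(seq_along(lens), function(i) {
    latent[starts[i]:ends[i], , drop = FALSE]
  })
  list(model = model, labels = labels)
}

#' @export
print.SpibModel <- function(x, ...) {
  cat("SpibModel:", x$n_states, "states, lag", x$cfg$lag_steps, "frames,",
      length(x$column_names), "input CVs, latent dim", x$latent_dim, "\n")
  invisible(x)
}

#' Project CV vectors through a trained SPIB model
#'
#' Deterministic projection via the encoder mean; the decoder supplies a
#' state posterior. Any structure with the model's CVs can be projected,
#' including ones never seen in training (e.g. feature-matrix rows of the
#' original ensemble).
#'
#' @param model a `SpibModel`
#' @param x numeric matrix (rows = observations), `FeatureMatrix`, or
#'   `TimeSeries`; columns are matched to the training CVs by name when
#'   available
#' @return list with `latent` (n x latent_dim), `posterior` (n x n_states),
#'   `state` (argmax integer labels)
#' @export
spib_project <- function(model, x) {
  stopifnot(inherits(model, "SpibModel"))
  v <- if (inherits(x, "TimeSeries")) ts_pool(x) else .fm_values(x)
  if (!is.null(colnames(v))) {
    missing <- setdiff(model$column_names, colnames(v))
    if (length(missing)) {
      stop("input lacks the model's CV column(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    v <- v[, model$column_names, drop = FALSE]
  } else if (ncol(v) != length(model$column_names)) {
    stop("input has ", ncol(v), " columns but the model expects ",
         length(model$column_names), " CVs (",
         paste(model$column_names, collapse = ", "), ")", call. = FALSE)
  }
  Xs <- sweep(sweep(v, 2, model$x_mean), 2, model$x_sd, "/")
  MU <- .spib_encode(model$par, Xs)
  P <- .softmax_rows(sweep(MU %*% model$par$Wd, 2, model$par$bd, "+"))
  list(latent = MU, posterior = P, state = max.col(P, ties.method = "first"))
}

#' Converged state count as a function of the lag time
#'
#' Trains an independent SPIB model per lag (same seed and config otherwise)
#' and reports the converged number of states. Longer lags average out fast
#' interconversions, so the count is expected to fall (or hold) as the lag
#' grows.
#'
#' @param ts a `TimeSeries`
#' @param cfg a `SpibConfig` (its `lag_steps` is overridden per run)
#' @param lags integer vector of lags (frames)
#' @return data.frame with columns `lag`, `n_states`, `seed`
#' @export
state_count_scan <- function(ts, cfg, lags) {
  stopifnot(length(lags) >= 1L)
  res <- lapply(lags, function(l) {
    cl <- cfg
    cl$lag_steps <- as.integer(l)
    fit <- train_spib(ts, cl)
    data.frame(lag = l, n_states = fit$model$n_states, seed = cl$seed)
  })
  do.call(rbind, res)
}

#' Best-permutation agreement between two labelings
#'
#' Fraction of observations on which `pred` equals `truth` after optimally
#' matching predicted label ids to true ids (exhaustive over permutations of
#' the smaller label set; intended for small state counts).
#'
#' @param pred,truth integer label vectors of equal length
#' @return agreement fraction in `[0, 1]`
#' @export
match_labels <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  tp <- table(pred, truth)
  pu <- rownames(tp); tu <- colnames(tp)
  if (length(pu) > 8L && length(tu) > 8L) {
    stop("label matching supports at most 8 states on one side", call. = FALSE)
  }
  # assign each pred label to one truth label injectively, maximizing matches
  swap <- length(pu) > length(tu)
  A <- if (swap) t(tp) else tp # rows = smaller side
  rows <- nrow(A); cols <- ncol(A)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(cols))) {
    s <- sum(A[cbind(seq_len(rows), p[seq_len(rows)])])
    if (s > best) best <- s
  }
  best / length(pred)
}
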