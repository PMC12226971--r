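# SPIB: initialization, gradients, training behavior, projection.

test_that("k-means initialization separates well-separated blobs", {
  withr::with_seed(1, {
    blob1 <- matrix(rnorm(600, mean = 0, sd = 0.3), 300, 2)
    blob2 <- matrix(rnorm(600, mean = 5, sd = 0.3), 300, 2)
  })
  ts <- timeseries(list(rbind(blob1, blob2)), column_names = c("u", "v"))
  init <- init_labels(ts, n_initial_states = 2, seed = 1)
  truth <- rep(1:2, each = 300)
  expect_gte(match_labels(unlist(init$labels), truth), 0.99)
  # one state is allowed (degenerate but useful)
  one <- init_labels(ts, n_initial_states = 1, seed = 1)
  expect_equal(one$n_states, 1)
  expect_true(all(unlist(one$labels) == 1))
  # identical frames collapse requested states
  same <- timeseries(list(matrix(1, 50, 2)), column_names = c("u", "v"))
  expect_warning(ic <- init_labels(same, n_initial_states = 2, seed = 1),
                 "collapse")
  expect_equal(ic$n_states, 1)
  expect_error(init_labels(ts, n_initial_states = 601), "exceeds")
})

test_that("analytic gradients agree with finite differences", {
  set.seed(13)
  B <- 6; D <- 3; H <- 4; d <- 2; K <- 3
  par <- cvstates:::.spib_init_par(D, H, d, K)
  X <- matrix(rnorm(B * D), B, D)
  Y <- sample.int(K, B, replace = TRUE)
  EPS <- matrix(rnorm(B * d), B, d)
  beta <- 0.05
  st <- cvstates:::.spib_step(par, X, Y, EPS, beta)
  for (nm in names(st$grads)) {
    g <- st$grads[[nm]]
    for (i in seq_len(min(length(g), 5))) {
      e <- 1e-6
      p_hi <- par; p_hi[[nm]][i] <- p_hi[[nm]][i] + e
      p_lo <- par; p_lo[[nm]][i] <- p_lo[[nm]][i] - e
      num <- (cvstates:::.spib_step(p_hi, X, Y, EPS, beta)$loss -
                cvstates:::.spib_step(p_lo, X, Y, EPS, beta)$loss) / (2 * e)
      expect_equal(g[i], num, tolerance = 1e-4)
    }
  }
})

test_that("training on a two-well system recovers both wells", {
  fix <- two_well_ts(n_frames = 6000, seed = 31)
  cfg <- spib_config(lag_steps = 5, n_initial_states = 6, seed = 1,
                     max_epochs = 30)
  fit <- suppressWarnings(train_spib(fix$ts, cfg))
  expect_equal(fit$model$n_states, 2)
  expect_gte(match_labels(unlist(fit$labels$labels), fix$labels), 0.95)
  # decoder outputs valid probability vectors on random inputs
  withr::with_seed(2, rand <- matrix(rnorm(50), 50, 1))
  proj <- spib_project(fit$model, rand)
  expect_true(all(abs(rowSums(proj$posterior) - 1) < 1e-6))
  expect_true(all(proj$posterior >= 0))
})

test_that("training is bit-reproducible for identical seed and config", {
  fix <- two_well_ts(n_frames = 3000, seed = 7)
  cfg <- spib_config(lag_steps = 5, n_initial_states = 4, seed = 3,
                     max_epochs = 15, patience = 3)
  f1 <- suppressWarnings(train_spib(fix$ts, cfg))
  f2 <- suppressWarnings(train_spib(fix$ts, cfg))
  expect_identical(f1$model$par, f2$model$par)
  expect_identical(f1$labels$labels, f2$labels$labels)
  expect_identical(f1$labels$latent, f2$labels$latent)
})

test_that("prediction pairs never span trajectory boundaries", {
  # two single-well trajectories; concatenating them across the time axis
  # would fabricate one well-to-well transition
  fix <- two_well_ts(n_frames = 4000, seed = 17)
  cfg <- spib_config(lag_steps = 10, n_initial_states = 4, seed = 5,
                     max_epochs = 25)
  fwd <- suppressWarnings(train_spib(fix$ts, cfg))
  rev_ts <- timeseries(rev(fix$ts$trajectories), dt = fix$ts$dt,
                       column_names = fix$ts$column_names)
  bwd <- suppressWarnings(train_spib(rev_ts, cfg))
  expect_equal(fwd$model$n_states, 2)
  expect_equal(bwd$model$n_states, 2)
  # same partition of frames regardless of file order
  lab_fwd <- unlist(fwd$labels$labels)
  lab_bwd_reordered <- unlist(rev(bwd$labels$labels))
  expect_gte(match_labels(lab_bwd_reordered, lab_fwd), 0.99)
})

test_that("projection is self-consistent and separates the well minima", {
  fix <- two_well_ts(n_frames = 5000, seed = 23)
  cfg <- spib_config(lag_steps = 5, n_initial_states = 6, seed = 2,
                     max_epochs = 30)
  fit <- suppressWarnings(train_spib(fix$ts, cfg))
  # re-projecting the training frames reproduces the converged labels
  proj <- spib_project(fit$model, ts_pool(fix$ts))
  agree <- mean(proj$state == unlist(fit$labels$labels))
  expect_gte(agree, 0.99)
  # duplicated frames project identically
  tri <- matrix(rep(0.37, 3), 3, 1)
  p3 <- spib_project(fit$model, tri)
  expect_equal(p3$latent[1, ], p3$latent[2, ])
  expect_equal(p3$posterior[1, ], p3$posterior[3, ])
  # the two well minima land in two distinct states
  minima <- matrix(c(-1, 1), 2, 1)
  pm <- spib_project(fit$model, minima)
  expect_equal(length(unique(pm$state)), 2)
  expect_equal(ncol(pm$latent), 2)
})

test_that("projection validates the CV schema", {
  fix <- two_well_ts(n_frames = 2000, seed = 3)
  cfg <- spib_config(lag_steps = 5, n_initial_states = 3, seed = 1,
                     max_epochs = 10, patience = 2)
  fit <- suppressWarnings(train_spib(fix$ts, cfg))
  bad <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("y", "z")))
  expect_error(spib_project(fit$model, bad), "x")
  expect_error(spib_project(fit$model, matrix(rnorm(10), 5, 2)), "expects")
})

test_that("lag validation and scan determinism", {
  fix <- two_well_ts(n_frames = 500, seed = 9)
  expect_error(train_spib(fix$ts, spib_config(lag_steps = 500, seed = 1)),
               "lag_steps")
  cfg <- spib_config(lag_steps = 5, n_initial_states = 3, seed = 4,
                     max_epochs = 8, patience = 2, epoch_samples = 500)
  scan <- suppressWarnings(state_count_scan(fix$ts, cfg, lags = c(5, 5)))
  expect_equal(scan$n_states[1], scan$n_states[2])
})
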