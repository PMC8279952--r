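test_that("dyad classification tallies molecules correctly", {
  mols <- list(list(plus = c("M"), minus = c("U")),
               list(plus = rep("M", 5), minus = rep("M", 5)))
  r <- classify_dyads(mols)
  expect_equal(r$counts$n_MU, 1)
  expect_equal(r$counts$n_MM, 5)
  expect_equal(r$n_rejected, 0)

  # ambiguous calls skip the dyad; strand-length mismatch rejects molecule
  r2 <- classify_dyads(list(list(plus = c("M", "N"), minus = c("U", "M")),
                            list(plus = "M", minus = c("M", "M"))))
  expect_equal(r2$counts$n_MU, 1)
  expect_equal(r2$n_skipped_dyads, 1)
  expect_equal(r2$n_rejected, 1)
})

test_that("dyad classification equals a brute-force tally on random calls", {
  set.seed(101)
  mols <- lapply(1:50, function(i) {
    k <- sample(1:8, 1)
    list(plus = sample(c("M", "U", "N"), k, replace = TRUE,
                       prob = c(0.45, 0.45, 0.1)),
         minus = sample(c("M", "U", "N"), k, replace = TRUE,
                        prob = c(0.45, 0.45, 0.1)))
  })
  r <- classify_dyads(mols)
  want <- c(UU = 0, MU = 0, UM = 0, MM = 0)
  for (mol in mols) for (j in seq_along(mol$plus)) {
    if (mol$plus[j] %in% c("M", "U") && mol$minus[j] %in% c("M", "U"))
      want[paste0(mol$plus[j], mol$minus[j])] <-
        want[paste0(mol$plus[j], mol$minus[j])] + 1
  }
  expect_equal(as.numeric(r$counts[c("n_UU", "n_MU", "n_UM", "n_MM")]),
               unname(want))
})

test_that("dyad log2 fold changes follow the closed form", {
  a <- dyad_count_table("a", "x", 10, 20, 30, 40)
  expect_equal(unname(dyad_log2fc(a[1, ], a[1, ], pseudo = 0)), rep(0, 4))

  s <- dyad_count_table("s", "x", 20, 0, 0, 80)
  r <- dyad_count_table("r", "x", 5, 0, 0, 95)
  fc <- dyad_log2fc(s[1, ], r[1, ], pseudo = 0)
  expect_equal(unname(fc["UU"]), 2)

  z <- dyad_count_table("z", "x", 0, 0, 0, 0)
  expect_error(dyad_log2fc(z[1, ], r[1, ]), "total is zero")
})

test_that("transition law reproduces hand-computed evolutions", {
  # absorbing limit: perfect maintenance keeps MM
  par1 <- kinetic_params(mu = 1, delta_n = 0)
  expect_equal(unname(transition_step(c(0, 0, 0, 1), par1)), c(0, 0, 0, 1))

  # no maintenance, no de novo: MM -> (1/2)MU + (1/2)UM -> 1/4,1/4,1/2 UU
  par0 <- kinetic_params(mu = 0, delta_n = 0)
  p1 <- transition_step(c(0, 0, 0, 1), par0)
  expect_equal(unname(p1), c(0, 0.5, 0.5, 0))
  p2 <- transition_step(p1, par0)
  expect_equal(unname(p2), c(0.5, 0.25, 0.25, 0))

  expect_error(transition_step(c(0.5, 0.5, 0.5, 0.5), par0), "distribution")
})

test_that("the per-strand marginal obeys its algebraic recursion", {
  set.seed(102)
  for (i in 1:20) {
    par <- kinetic_params(mu = runif(1), delta_n = runif(1),
                          delta_p = runif(1), lam = runif(1))
    p <- as.numeric(rmultinom(1, 100, rep(0.25, 4))) / 100
    f <- strand_marginal(p)
    p2 <- transition_step(p, par)
    f_pred <- (f * (1 - par$lam) * (1 + par$mu) +
                 (1 - f * (1 - par$lam)) * (par$delta_p + par$delta_n)) / 2
    expect_equal(strand_marginal(p2), f_pred, tolerance = 1e-12)
    # simplex preservation
    expect_equal(sum(p2), 1, tolerance = 1e-12)
    expect_true(all(p2 >= -1e-12))
  }
})

test_that("symmetric parameters preserve MU = UM exactly", {
  par <- kinetic_params(mu = 0.7, delta_n = 0.1, delta_p = 0.05, lam = 0.02)
  p <- c(0.4, 0.15, 0.15, 0.3)
  for (i in 1:10) {
    p <- transition_step(p, par)
    expect_equal(unname(p["MU"]), unname(p["UM"]), tolerance = 1e-14)
  }
})

test_that("stationary marginal: closed form, iteration and corner cases", {
  s <- stationary_marginal(kinetic_params(mu = 0.9, delta_n = 0.05))
  expect_equal(s$f_star, 1 / 3, tolerance = 1e-10)
  expect_equal(strand_marginal(s$p_star), 1 / 3, tolerance = 1e-9)

  expect_equal(stationary_marginal(kinetic_params(0.5, 0))$f_star, 0)

  # iteration from an arbitrary start reaches the closed form
  par <- kinetic_params(mu = 0.8, delta_n = 0.2)
  p <- c(0.1, 0.2, 0.3, 0.4)
  for (i in 1:500) p <- transition_step(p, par)
  expect_equal(strand_marginal(p), 0.2 / (1 - 0.8 + 0.2), tolerance = 1e-10)

  corner <- stationary_marginal(kinetic_params(mu = 1, delta_n = 0))
  expect_false(corner$unique)
})

test_that("observation matrix is the per-strand error product", {
  expect_equal(observation_matrix(0, 0), diag(4), ignore_attr = TRUE)
  O <- observation_matrix(0.01, 0.02)
  expect_equal(O["UU", "MM"], 1e-4)
  expect_equal(O["MM", "UU"], 4e-4)
  expect_equal(unname(rowSums(O)), rep(1, 4))
  set.seed(103)
  for (i in 1:5) {
    Oi <- observation_matrix(runif(1), runif(1))
    expect_equal(unname(rowSums(Oi)), rep(1, 4), tolerance = 1e-12)
  }
})

test_that("log-likelihood matches the closed-form multinomial at one point", {
  cnt <- c(10, 20, 30, 40)
  tc <- dyad_time_course("t0", 0,
                         dyad_count_table("t0", "x", cnt[1], cnt[2],
                                          cnt[3], cnt[4]))
  par <- kinetic_params(0.5, 0.1, e = 0, c = 0, p0 = cnt / sum(cnt))
  want <- lgamma(101) - sum(lgamma(cnt + 1)) + sum(cnt * log(cnt / 100))
  expect_equal(dyad_loglik(par, tc), want)

  empty <- dyad_time_course(character(0), integer(0),
                            dyad_count_table(character(0), character(0),
                                             numeric(0), numeric(0),
                                             numeric(0), numeric(0)))
  expect_equal(dyad_loglik(par, empty), 0)

  # impossible observation with zero error rates
  par_imp <- kinetic_params(0, 0, e = 0, c = 0, p0 = c(1, 0, 0, 0))
  expect_equal(dyad_loglik(par_imp, tc), -Inf)
})

test_that("generating parameters beat perturbed ones in likelihood", {
  truth <- kinetic_params(0.9, 0.15, e = 0.005, c = 0.005)
  ok <- 0
  for (s in 1:5) {
    tc <- simulate_time_course(truth, c(0, 6, 30), n_dyads = 50000, seed = s)
    ll_true <- dyad_loglik(truth, tc)
    pert <- kinetic_params(0.7, 0.35, e = 0.005, c = 0.005)
    if (ll_true >= dyad_loglik(pert, tc)) ok <- ok + 1
  }
  expect_gte(ok, 5)
})

test_that("fit recovers generating parameters and respects boundaries", {
  truth <- kinetic_params(0.95, 0.2, e = 0.005, c = 0.005)
  tc <- simulate_time_course(truth, c(0, 6, 30), n_dyads = 50000, seed = 7)
  fit <- fit_kinetics(tc, seed = 1, n_starts = 4)
  expect_lt(abs(fit$params$mu - 0.95), 0.03)
  expect_lt(abs(fit$params$delta_n - 0.2), 0.03)

  # all-UU data drives the de novo rate to the zero boundary
  uu <- dyad_time_course(c("a", "b"), c(0, 6),
                         dyad_count_table(c("a", "b"), "x", c(1000, 1000),
                                          c(0, 0), c(0, 0), c(0, 0)))
  fit0 <- fit_kinetics(uu, seed = 1, n_starts = 4, e = 0, c = 0)
  expect_lt(fit0$params$delta_n, 1e-3)

  # grid search never beats the optimizer
  grid <- expand.grid(mu = seq(0, 1, length.out = 41),
                      delta_n = seq(0, 1, length.out = 41))
  grid_ll <- max(vapply(seq_len(nrow(grid)), function(i)
    dyad_loglik(kinetic_params(grid$mu[i], grid$delta_n[i], e = 0.005,
                               c = 0.005, p0 = fit$params$p0), tc),
    numeric(1)))
  expect_gte(fit$loglik + 1e-6, grid_ll)
})

test_that("a single timepoint refuses a joint mu/delta_n fit", {
  tc1 <- dyad_time_course("t0", 0,
                          dyad_count_table("t0", "x", 50, 20, 20, 10))
  expect_error(fit_kinetics(tc1, seed = 1), "not jointly identifiable")
  # but a constrained fit runs
  fitc <- fit_kinetics(tc1, fixed = list(delta_n = 0.1), seed = 1,
                       n_starts = 2)
  expect_true(is.finite(fitc$loglik))
})

test_that("fits are deterministic given the seed", {
  truth <- kinetic_params(0.8, 0.1, e = 0.005, c = 0.005)
  tc <- simulate_time_course(truth, c(0, 6, 30), n_dyads = 20000, seed = 3)
  f1 <- fit_kinetics(tc, seed = 5, n_starts = 3)
  f2 <- fit_kinetics(tc, seed = 5, n_starts = 3)
  expect_identical(f1$params$mu, f2$params$mu)
  expect_identical(f1$starts, f2$starts)
})

test_that("bootstrap confidence intervals bracket the generating values", {
  truth <- kinetic_params(0.9, 0.15, e = 0.005, c = 0.005)
  tc <- simulate_time_course(truth, c(0, 6, 30), n_dyads = 20000, seed = 9)
  fit <- fit_kinetics(tc, seed = 4, n_starts = 3, n_boot = 8)
  expect_equal(rownames(fit$ci), c("mu", "delta_n"))
  expect_true(all(fit$ci[, 1] <= fit$ci[, 2]))
  expect_gte(truth$mu, fit$ci["mu", 1] - 0.05)
  expect_lte(truth$mu, fit$ci["mu", 2] + 0.05)
})
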