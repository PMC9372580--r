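test_that("ICC ratios follow their defining formulas", {
  expect_identical(icc_adj(1, 0), 1)
  expect_equal(icc_cond(1, 1, 2), 0.25)
  expect_identical(icc_adj(0, 1), 0)
  expect_identical(icc_cond(0, 1, 1), 0)
  expect_error(icc_adj(-1, 1), ">= 0")
  expect_error(icc_adj(0, 0), "denominator")
  expect_error(icc_cond(0, 0, 0), "denominator")
})

test_that("conditional ICC is the R2 gap", {
  expect_equal(icc_cond_from_r2(0.521, 1.000), 0.479)
  expect_equal(icc_cond_from_r2(0.681, 1.000), 0.319)
  expect_identical(icc_cond_from_r2(0, 1), 1)
  expect_error(icc_cond_from_r2(0.6, 0.5), "exceed")
  expect_error(icc_cond_from_r2(-0.1, 0.5), "0, 1")
})

test_that("variance-partition R2 and the ICC identity hold", {
  expect_equal(r2_nakagawa(2, 1, 1), c(r2m = 0.5, r2c = 0.75))
  # no fixed variance: r2m = 0 and r2c = icc_adj
  r0 <- r2_nakagawa(0, 3, 1)
  expect_identical(unname(r0["r2m"]), 0)
  expect_equal(unname(r0["r2c"]), icc_adj(3, 1))
  expect_error(r2_nakagawa(0, 0, 0), "degenerate")
  # identity r2m + icc_cond = r2c on random variance triples
  set.seed(42)
  for (i in 1:100) {
    v <- runif(3, 0, 10)
    r2 <- r2_nakagawa(v[1], v[2], v[3])
    expect_lt(abs(r2[["r2m"]] + icc_cond(v[2], v[3], v[1]) - r2[["r2c"]]),
              1e-6)
    expect_lte(icc_cond(v[2], v[3], v[1]), icc_adj(v[2], v[3]) + 1e-12)
  }
})

test_that("effect classification applies the two-step rule", {
  expect_identical(classify_effect(1e-4, 1.000, 0.465), "very strong")
  expect_identical(classify_effect(0.035, 1.000, 0.859), "moderate")
  expect_identical(classify_effect(0.011, 0.528, 0.525), "negligible")
  expect_identical(classify_effect(0.20, 1.000, 0.465), "negligible")
  expect_identical(classify_effect(0.01, 0.80, 0.60), "strong")
  expect_identical(classify_effect(0.01, 0.99, 0.95), "small")
  expect_identical(classify_effect(NA, 0.9, 0.5), NA_character_)
})

test_that("variance components agree with a brute-force ML oracle", {
  # independent oracle: Gaussian ML with GLS-profiled fixed effects,
  # optimized over the two variance components on the log scale
  ml_oracle <- function(d) {
    X <- stats::model.matrix(~ run, d)
    Z <- stats::model.matrix(~ factor(session_id) - 1, d)
    y <- d$value; n <- length(y)
    nll <- function(par) {
      V <- exp(par[2]) * diag(n) + exp(par[1]) * tcrossprod(Z)
      ch <- chol(V)
      solve_V <- function(b) backsolve(ch, forwardsolve(t(ch), b))
      beta <- solve(crossprod(X, solve_V(X)), crossprod(X, solve_V(y)))
      r <- y - X %*% beta
      0.5 * (2 * sum(log(diag(ch))) + sum(r * solve_V(r)) + n * log(2 * pi))
    }
    opt <- optim(c(0, 0), nll, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 5000))
    c(var_random = exp(opt$par[1]), var_residual = exp(opt$par[2]))
  }
  set.seed(9)
  d <- data.frame(session_id = rep(c("A", "B"), each = 3),
                  run = rep(c("First", "Last", "First"), 2),
                  value = c(10.2, 11.1, 10.6, 14.8, 15.9, 15.1))
  fit <- fit_metric_model(d, fixed = "run_only", family = "normal")
  oracle <- ml_oracle(d)
  expect_lt(abs(fit$var_random - oracle[["var_random"]]), 1e-3)
  expect_lt(abs(fit$var_residual - oracle[["var_residual"]]), 1e-3)
})

test_that("the family race picks the generating family", {
  dl <- simulate_metrics_table(10, 6, mean = 30, sigma2_id = 0.04,
                               sigma2_res = 0.25, family = "lognormal",
                               seed = 2)
  fl <- fit_metric_model(dl, "run_leg", "auto")
  expect_identical(fl$family, "lognormal")
  expect_identical(names(which.min(fl$aic_table)), "lognormal")
  dn <- simulate_metrics_table(10, 6, mean = 40, sigma2_id = 4,
                               sigma2_res = 1, seed = 3)
  fn <- fit_metric_model(dn, "run_leg", "auto")
  expect_identical(fn$family, "normal")
  # explicit non-positive responses exclude the positive-only families
  dneg <- dn; dneg$value <- dneg$value - 100
  expect_error(fit_metric_model(dneg, "run_leg", "lognormal"), "positive")
  fneg <- fit_metric_model(dneg, "run_leg", "auto")
  expect_identical(fneg$family, "normal")
})

test_that("emmeans reproduce raw cell means on balanced normal data", {
  d <- simulate_metrics_table(8, 5, mean = 40, sigma2_id = 1,
                              sigma2_res = 1, run_effect = 2,
                              leg_effect = -1, seed = 6)
  fit <- fit_metric_model(d, "run_leg", "normal")
  raw <- aggregate(value ~ run + leg, d, mean)
  em <- fit$emmeans
  for (i in seq_len(nrow(raw))) {
    got <- em$emmean[em$run == raw$run[i] & em$leg == raw$leg[i]]
    expect_equal(got, raw$value[i], tolerance = 1e-6)
  }
  # Last - First contrast direction
  dd <- fit$emmean_diff
  expect_true(all(grepl("Last - First", dd$contrast)))
})

test_that("fitted ICCs obey their structural invariants", {
  d <- simulate_metrics_table(12, 8, run_effect = 3, leg_effect = 2, seed = 8)
  fit <- fit_metric_model(d, "run_leg", "normal")
  expect_gte(fit$icc_adj, fit$icc_cond)
  expect_lt(abs(fit$r2m + fit$icc_cond - fit$r2c), 1e-6)
  expect_true(all(c(fit$r2m, fit$r2c, fit$icc_adj, fit$icc_cond) >= 0))
  expect_true(all(c(fit$r2m, fit$r2c, fit$icc_adj, fit$icc_cond) <= 1))
  expect_lte(fit$r2m, fit$r2c)
  expect_false(fit$singular)
  expect_lt(fit$p[["run"]], 0.05)
})

test_that("the CV decomposition maps variances to percent dispersion", {
  fake <- structure(list(family = "normal", var_random = 4, var_residual = 0,
                         var_fixed = 1, grand_mean = 20),
                    class = "ski_mixed_fit")
  cv <- cv_decomposition(fake)
  expect_equal(unname(cv["cv_random"]), 10)
  expect_identical(unname(cv["cv_intra"]), 0)
  expect_equal(unname(cv["cv_syst"]), 5)
  fake$grand_mean <- -1
  expect_error(cv_decomposition(fake), "positive")
  # recovery on simulated tables: mean CV within 20% of closed form
  cvs <- vapply(1:6, function(i) {
    d <- simulate_metrics_table(25, 10, mean = 40, sigma2_id = 9,
                                sigma2_res = 4, seed = 700 + i)
    cv_decomposition(fit_metric_model(d, "run_leg", "normal"))
  }, numeric(3))
  expect_lt(abs(mean(cvs["cv_random", ]) - 100 * 3 / 40) / (100 * 3 / 40),
            0.20)
  expect_lt(abs(mean(cvs["cv_intra", ]) - 100 * 2 / 40) / (100 * 2 / 40),
            0.20)
})

test_that("simulated tables are balanced and seeded", {
  d <- simulate_metrics_table(5, 4, seed = 1)
  expect_identical(nrow(d), 5L * 4L * 2L * 2L)
  expect_identical(d, simulate_metrics_table(5, 4, seed = 1))
  counts <- table(d$session_id, d$run, d$leg)
  expect_true(all(counts == 4))
  # injected effects shift the right cells
  d2 <- simulate_metrics_table(200, 20, sigma2_id = 0, sigma2_res = 0.01,
                               run_effect = 5, interaction_effect = 3,
                               seed = 2)
  cell <- aggregate(value ~ run + leg, d2, mean)
  base <- cell$value[cell$run == "First" & cell$leg == "IL"]
  expect_equal(cell$value[cell$run == "Last" & cell$leg == "IL"] - base, 5,
               tolerance = 0.05)
  expect_equal(cell$value[cell$run == "Last" & cell$leg == "OL"] - base, 8,
               tolerance = 0.05)
})
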