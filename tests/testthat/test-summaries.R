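test_that("subgroup membership and counts follow the thresholds", {
  d <- trial_data(y = c(0.1, 0.2, 0.3, 0.4), u = c(1, 1, 0, 0),
                  x = c(0.1, 0.6, 0.4, 0.9))
  s <- summarize_subgroups(d, nested_design(c(0.5, 1.0)))
  expect_equal(s$nt, c(1, 2))
  expect_equal(s$nc, c(1, 2))
  # degenerate nesting: everything below the first threshold
  d2 <- tiny_trial()
  d2$x <- d2$x / 10
  s2 <- summarize_subgroups(d2, nested_design(c(0.25, 0.5, 1)))
  expect_equal(s2$mean_t, rep(s2$mean_t[1], 3))
  expect_equal(s2$var_c, rep(s2$var_c[1], 3))
})

test_that("subgroup summaries match a brute-force recomputation", {
  set.seed(42)
  d <- trial_data(y = rnorm(60), u = rbinom(60, 1, 0.5), x = runif(60))
  des <- nested_design(c(0.3, 0.6, 0.9))
  s <- summarize_subgroups(d, des)
  for (k in 1:3) {
    sel <- d$x <= des$thresholds[k]
    yt <- d$y[sel & d$u == 1]; yc <- d$y[sel & d$u == 0]
    expect_equal(s$nt[k], length(yt))
    expect_equal(s$mean_t[k], mean(yt))
    expect_equal(s$var_t[k], var(yt))
    expect_equal(s$var_c[k], var(yc))
    expect_equal(s$pooled_var[k],
                 ((length(yt) - 1) * var(yt) + (length(yc) - 1) * var(yc)) /
                   (length(yt) + length(yc) - 2))
    expect_equal(s$delta_hat[k], mean(yt) - mean(yc))
  }
})

test_that("pooled t statistic matches hand computation", {
  d <- trial_data(y = c(1, 2, 3, 0, 1, 2), u = c(1, 1, 1, 0, 0, 0),
                  x = rep(0.5, 6))
  s <- summarize_subgroups(d, nested_design(1))
  st <- t_statistic(s)
  expect_equal(st$values, 1 / sqrt(2 / 3))   # pooled variance 1
  expect_equal(st$df, 4)
  # identical arms give zero
  d0 <- trial_data(y = c(1, 2, 3, 1, 2, 3), u = c(1, 1, 1, 0, 0, 0),
                   x = rep(0.5, 6))
  expect_equal(t_statistic(summarize_subgroups(d0, nested_design(1)))$values, 0)
  # full-population statistic equals the classical two-sample t-test
  dd <- simulate_trial(alt_step_spec(n = 40), seed = 5)
  sfull <- summarize_subgroups(dd, nested_design(1))
  tt <- t.test(dd$y[dd$u == 1], dd$y[dd$u == 0], var.equal = TRUE,
               alternative = "greater")
  expect_equal(t_statistic(sfull)$values, unname(tt$statistic))
})

test_that("known-variance z statistic evaluates and scales correctly", {
  s <- data.frame(nt = 100, nc = 100, delta_hat = 0.2)
  expect_equal(z_statistic(s, 1, 1)$values, 0.2 / sqrt(0.02))
  expect_equal(z_statistic(s, 2, 2)$values, 0.5 * z_statistic(s, 1, 1)$values)
  s0 <- data.frame(nt = 10, nc = 15, delta_hat = 0)
  expect_equal(z_statistic(s0, 1.3, 0.7)$values, 0)
})

test_that("regression statistic agrees with lm and the normal equations", {
  set.seed(7)
  d <- trial_data(y = rnorm(30) + 0.5 * (u <- rbinom(30, 1, 0.5)),
                  u = u, x = runif(30))
  des <- nested_design(1)
  st <- regression_statistic(d, des)
  fit <- summary(lm(y ~ u + x, data = as.data.frame(d)))
  expect_equal(st$values, unname(fit$coefficients["u", "t value"]))
  expect_equal(st$df, 27)   # n - 3 fitted parameters
  # independent normal-equations oracle
  X <- cbind(1, d$u, d$x)
  beta <- solve(crossprod(X), crossprod(X, d$y))
  s2 <- sum((d$y - X %*% beta)^2) / (30 - 3)
  se1 <- sqrt(s2 * solve(crossprod(X))[2, 2])
  expect_equal(st$values, beta[2] / se1)
  expect_equal(st$information, 1 / se1^2)
  # with the biomarker uncorrelated with the arm, close to the plain t-test
  big <- simulate_trial(model_spec(beta1 = 0.3, n_per_group = 2000), seed = 9)
  treg <- regression_statistic(big, des)$values
  tt <- t_statistic(summarize_subgroups(big, des))$values
  expect_equal(treg, tt, tolerance = 0.02)
})

test_that("regression statistic flags singular subgroups", {
  d <- trial_data(y = rnorm(10), u = rep(1, 10), x = runif(10))  # one arm
  expect_true(is.na(regression_statistic(d, nested_design(1))$values))
  d2 <- trial_data(y = rnorm(10), u = rep(0:1, 5), x = rep(0.2, 10))
  expect_true(is.na(regression_statistic(d2, nested_design(1))$values))
})

test_that("disjoint subsets partition the population with harmonic weights", {
  d <- simulate_trial(null_step_spec(n = 60), seed = 13)
  des <- quartile_design()
  dp <- disjoint_pvalues(d, des)
  s <- summarize_subgroups(d, des)
  expect_equal(cumsum(dp$nt), s$nt)
  expect_equal(cumsum(dp$nc), s$nc)
  expect_equal(dp$w, 1 / (1 / dp$nt + 1 / dp$nc))
  # balanced subset of 20 per arm has weight 10
  db <- trial_data(y = rnorm(40), u = rep(0:1, 20), x = runif(40))
  expect_equal(disjoint_pvalues(db, nested_design(1))$w, 10)
})

test_that("subset p-values are uniform under the global null", {
  # prognostic effect only: each disjoint subset still has a null contrast
  spec <- null_step_spec(delta = 1.5, n = 40)
  des <- nested_design(c(0.5, 1))
  p1 <- p2 <- numeric(800)
  for (r in 1:800) {
    d <- simulate_trial(spec, seed = 5000 + r)
    dp <- disjoint_pvalues(d, des)
    p1[r] <- dp$p[1]; p2[r] <- dp$p[2]
  }
  expect_gt(stats::ks.test(p1, "punif")$p.value, 0.001)
  expect_gt(stats::ks.test(p2, "punif")$p.value, 0.001)
})

test_that("inverse normal combination has the stated algebra and covariance", {
  expect_equal(inverse_normal_statistics(0.2, 3)$values, qnorm(0.8))
  z <- qnorm(1 - c(0.1, 0.3))
  expect_equal(inverse_normal_statistics(c(0.1, 0.3), c(2, 2))$values[2],
               sum(z) / sqrt(2))
  expect_warning(inverse_normal_statistics(c(1e-300, 1), c(1, 1)), "infinite")
  # empirical covariance over independent uniforms: sqrt(I_j / I_k)
  set.seed(17)
  w <- c(4, 8)
  C1 <- C2 <- numeric(20000)
  for (r in 1:20000) {
    st <- inverse_normal_statistics(runif(2), w)
    C1[r] <- st$values[1]; C2[r] <- st$values[2]
  }
  expect_equal(cor(C1, C2), sqrt(w[1] / sum(w)), tolerance = 0.02)
  expect_equal(sd(C1), 1, tolerance = 0.02)
  expect_equal(sd(C2), 1, tolerance = 0.02)
})

test_that("single-stage combination reproduces the subgroup t-test p-value", {
  d <- simulate_trial(alt_step_spec(n = 30), seed = 3)
  des <- nested_design(1)
  dp <- disjoint_pvalues(d, des)
  st <- inverse_normal_statistics(dp$p, dp$w)
  tt <- t.test(d$y[d$u == 1], d$y[d$u == 0], var.equal = TRUE,
               alternative = "greater")
  expect_equal(1 - pnorm(st$values), tt$p.value)
})

test_that("cumulative t statistics on nested subgroups are positively correlated", {
  spec <- null_step_spec(delta = 0, n = 80)
  des <- nested_design(c(0.5, 1))
  t1 <- t2 <- numeric(3000)
  for (r in 1:3000) {
    d <- simulate_trial(spec, seed = 20000 + r)
    tv <- t_statistic(summarize_subgroups(d, des))$values
    t1[r] <- tv[1]; t2[r] <- tv[2]
  }
  expect_gt(cor(t1, t2), 0.6)   # theory: ~sqrt(1/2) = 0.707
})

test_that("general subgroup summaries handle intersections and match brute force", {
  d <- simulate_trial(null_step_spec(n = 50), seed = 23)
  gs <- general_subgroups(list(c(-Inf, 0.4), c(-Inf, 1), c(0.4, 1)),
                          labels = c("low", "all", "high"))
  g <- general_subgroup_summary(d, gs)
  # nested: intersection of low with all is low itself
  expect_equal(g$intersections$nt[1, 2], g$summary$nt[1])
  expect_equal(g$intersections$var_c[1, 2], g$summary$var_c[1])
  # disjoint: low and high share nobody
  expect_equal(g$intersections$nt[1, 3] + g$intersections$nc[1, 3], 0)
  # random interval unions against per-subject brute force
  set.seed(8)
  for (r in 1:10) {
    lo <- sort(runif(4))
    sets <- list(rbind(c(lo[1], lo[2]), c(lo[3], lo[4])), c(lo[2], lo[3]))
    masks <- subgroup_membership(d$x, general_subgroups(sets))
    brute1 <- (d$x > lo[1] & d$x <= lo[2]) | (d$x > lo[3] & d$x <= lo[4])
    brute2 <- d$x > lo[2] & d$x <= lo[3]
    expect_identical(masks[, 1], brute1)
    expect_identical(masks[, 2], brute2)
  }
})
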