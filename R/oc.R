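# Monte-Carlo engine for family-wise error rate (FWER), disjunctive power and
# sample-size computations. Replicates are independent tasks seeded by a
# counter-based substream of the root seed, so any replicate is reproducible
# in isolation and results do not depend on execution order.

#' Define a simulation scenario
#'
#' @param model A [model_spec()] (data-generating mechanism).
#' @param design A [nested_design()]; if omitted, \code{K} equally spaced
#'   quantile-based thresholds \eqn{q_k = k/K} are used, so the last test is
#'   the full-population test.
#' @param K Number of equally spaced thresholds (used when \code{design} is
#'   missing).
#' @param procedures Character vector of procedure names, see
#'   [run_procedure()].
#' @param replicates Number of Monte-Carlo replicates.
#' @param seed Root integer seed.
#' @param alpha One-sided family-wise level (used when \code{design} is
#'   missing).
#' @param boundary Boundary family, \code{"pocock"} (default) or \code{"obf"}.
#' @return An object of class \code{"oc_scenario"}.
#' @export
scenario <- function(model, design = NULL, K = NULL,
                     procedures = c("sidak", "t_gs", "adjusted_t",
                                    "inverse_normal"),
                     replicates = 10000, seed = 1, alpha = 0.025,
                     boundary = c("pocock", "obf")) {
  stopifnot(inherits(model, "model_spec"))
  boundary <- match.arg(boundary)
  if (is.null(design)) {
    if (is.null(K)) stop("supply either 'design' or 'K'")
    design <- nested_design(seq_len(K) / K, alpha = alpha)
  }
  procedures <- match.arg(procedures, PROCEDURES, several.ok = TRUE)
  stopifnot(replicates >= 1)
  structure(list(model = model, design = design, procedures = procedures,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 boundary = boundary),
            class = "oc_scenario")
}

# Common critical value for statistics with product correlation
# rho_jk = g_j / g_k, cached on the normalized g rounded to 4 decimals (the
# boundary depends on counts and variance estimates only through g, so this
# key subsumes count- and SD-ratio-based keys; the induced boundary error,
# ~1e-4, is orders of magnitude below Monte-Carlo noise). The solve runs on
# the rounded vector itself, so cached and fresh paths agree exactly.
cached_pocock_c <- function(g, alpha, cache) {
  K <- length(g)
  if (K == 1) return(stats::qnorm(1 - alpha))
  # enforce monotonicity (sampling noise can invert the SD-ratio part) and
  # drop duplicated information levels: a duplicate coordinate is the same
  # statistic and does not change the common-boundary tail probability
  gg <- round(cummax(g / g[K]), 4)
  gg <- gg[c(gg[-1] > gg[-K], TRUE)]   # strict after rounding: no rho = 1
  if (length(gg) == 1) return(stats::qnorm(1 - alpha))
  key <- paste(gg, collapse = ",")
  hit <- cache$store[[key]]
  if (!is.null(hit)) return(hit)
  cc <- solve_pocock_markov(gg, alpha, state = cache)
  cache$warm <- cc
  cache$store[[key]] <- cc
  cc
}

# Rejection indicators for one simulated replicate, all requested procedures.
replicate_rejections <- function(y, u, x, des, procs, boundary, cache) {
  K <- des$K; alpha <- des$alpha
  b <- bin_sufficient_stats(y, u, x, des$thresholds)
  m <- nested_moments(b)
  ok <- !m$degenerate
  rej <- matrix(FALSE, length(procs), K, dimnames = list(procs, NULL))
  need_t <- any(procs %in% c("sidak", "z_gs", "t_gs", "adjusted_t"))
  if (need_t) {
    se <- sqrt(m$pooled_var * (1 / m$nt + 1 / m$nc))
    tstat <- ifelse(ok, m$delta_hat / se, NA_real_)
    df <- m$nt + m$nc - 2
  }
  for (pr in procs) {
    if (pr == "full_population") {
      n1 <- sum(u); n0 <- length(u) - n1
      y1 <- y[u == 1L]; y0 <- y[u == 0L]
      v <- ((n1 - 1) * stats::var(y1) + (n0 - 1) * stats::var(y0)) /
        (n1 + n0 - 2)
      tt <- (mean(y1) - mean(y0)) / sqrt(v * (1 / n1 + 1 / n0))
      rej[pr, K] <- tt > stats::qt(1 - alpha, n1 + n0 - 2)
      next
    }
    if (pr == "sidak") {
      ac <- sidak_level(alpha, K)
      rej[pr, ] <- ok & !is.na(tstat) & tstat > stats::qt(1 - ac, df)
      next
    }
    if (pr %in% c("z_gs", "t_gs")) {
      if (!any(ok)) next
      r <- (1 / m$nt + 1 / m$nc)[ok]
      cc <- cached_pocock_c(1 / sqrt(r), alpha, cache)
      bnd <- if (pr == "z_gs") cc else
        stats::qt(stats::pnorm(cc), df[ok])
      rej[pr, ok] <- !is.na(tstat[ok]) & tstat[ok] > bnd
      next
    }
    if (pr == "adjusted_t") {
      if (!any(ok)) next
      r <- (1 / m$nt + 1 / m$nc)[ok]
      # corr entry (j<k) = (s_j / s_k) * sqrt(r_k / r_j) = g_j / g_k with
      # g = s / sqrt(r); g is generically increasing over nested subgroups.
      cc <- cached_pocock_c(sqrt(m$pooled_var[ok]) / sqrt(r), alpha, cache)
      bnd <- stats::qt(stats::pnorm(cc), df[ok])
      rej[pr, ok] <- !is.na(tstat[ok]) & tstat[ok] > bnd
      next
    }
    if (pr == "inverse_normal") {
      bm_t <- moments_from_sums(b$n_t, b$s1_t, b$s2_t)
      bm_c <- moments_from_sums(b$n_c, b$s1_c, b$s2_c)
      pv <- pooled_variance(b$n_t, b$n_c, bm_t$var, bm_c$var)
      degb <- b$n_t < 2L | b$n_c < 2L | !is.finite(pv) | pv <= 0
      dfb <- b$n_t + b$n_c - 2
      tb <- ifelse(degb, NA_real_, (bm_t$mean - bm_c$mean) /
                     sqrt(pv * (1 / b$n_t + 1 / b$n_c)))
      z <- ifelse(degb, 0, stats::qnorm(stats::pt(tb, dfb)))
      w <- ifelse(degb, 0, 1 / (1 / b$n_t + 1 / b$n_c))
      Iu <- cumsum(w)
      usable <- Iu > 0
      if (!any(usable)) next
      Cstat <- ifelse(usable, cumsum(sqrt(w) * z) / sqrt(pmax(Iu, 1e-300)), NA_real_)
      cc <- cached_pocock_c(sqrt(Iu[usable]), alpha, cache)
      rej[pr, usable] <- !is.na(Cstat[usable]) & Cstat[usable] > cc
      next
    }
    if (pr == "regression") {
      vals <- dfs <- info <- rep(NA_real_, K)
      for (k in seq_len(K)) {
        sel <- x <= des$thresholds[k]
        n <- sum(sel)
        if (n < 4) next
        uu <- u[sel]; xx <- x[sel]; yy <- y[sel]
        if (sum(uu) < 1 || sum(1 - uu) < 1 || stats::var(xx) == 0) next
        X <- cbind(1, uu, xx)
        qx <- qr(X)
        if (qx$rank < 3) next
        cf <- qr.coef(qx, yy)
        res <- yy - X %*% cf
        v1 <- (sum(res^2) / (n - 3)) * chol2inv(qr.R(qx))[2, 2]
        if (!is.finite(v1) || v1 <= 0) next
        vals[k] <- cf[2] / sqrt(v1); dfs[k] <- n - 3; info[k] <- 1 / v1
      }
      okr <- !is.na(vals)
      if (!any(okr)) next
      cc <- cached_pocock_c(sqrt(cummax(info[okr])), alpha, cache)
      bnd <- stats::qt(stats::pnorm(cc), dfs[okr])
      rej[pr, okr] <- vals[okr] > bnd
      next
    }
  }
  list(rej = rej, n_degenerate = sum(!ok))
}

# Shared engine: per-procedure disjunctive rejection rate, per-hypothesis
# rates, degenerate-subgroup counts.
oc_engine <- function(sc) {
  spec <- sc$model; des <- sc$design
  procs <- sc$procedures
  R <- sc$replicates
  n <- spec$n_per_group
  u <- rep(c(1L, 0L), each = n)
  if (sc$boundary != "pocock")
    stop("the Monte-Carlo engine supports Pocock-type (common) boundaries; ",
         "use run_procedure() for O'Brien-Fleming analyses")
  cache <- new.env(parent = emptyenv())
  cache$store <- new.env(hash = TRUE, parent = emptyenv())
  cache$warm <- NULL
  any_rej <- matrix(0, R, length(procs), dimnames = list(NULL, procs))
  hyp_rej <- matrix(0, length(procs), des$K, dimnames = list(procs, NULL))
  n_degen <- 0L
  for (r in seq_len(R)) {
    sim <- with_private_seed(substream_seed(sc$seed, r), {
      x <- stats::runif(2L * n)
      eps <- stats::rnorm(2L * n, sd = spec$sigma)
      list(x = x, eps = eps)
    })
    f <- if (spec$beta2 != 0 || spec$beta3 != 0)
      effect_function(spec, sim$x) else 0
    y <- spec$beta0 + spec$beta1 * u + spec$beta2 * f + spec$beta3 * u * f +
      sim$eps
    out <- replicate_rejections(y, u, sim$x, des, procs, sc$boundary, cache)
    any_rej[r, ] <- rowSums(out$rej) > 0
    hyp_rej <- hyp_rej + out$rej
    n_degen <- n_degen + out$n_degenerate
  }
  est <- colMeans(any_rej)
  structure(list(table = data.frame(procedure = procs, estimate = est,
                                    mc_se = sqrt(est * (1 - est) / R),
                                    row.names = NULL),
                 per_hypothesis = hyp_rej / R,
                 n_degenerate = n_degen, replicates = R, seed = sc$seed,
                 design = des, model = sc$model),
            class = "oc_result")
}

#' @export
print.oc_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo operating characteristics (%d replicates, seed %d)\n",
              x$replicates, x$seed))
  print(cbind(x$table, data.frame(round(x$per_hypothesis, 4))), row.names = FALSE)
  if (x$n_degenerate > 0)
    cat(sprintf("Degenerate subgroup events: %d\n", x$n_degenerate))
  invisible(x)
}

#' Estimate the family-wise error rate by simulation
#'
#' Proportion of replicates in which at least one null hypothesis is
#' rejected, under a global-null scenario (no treatment effect anywhere:
#' \code{beta1 = beta3 = 0}; a prognostic effect \code{beta2} is allowed and
#' is exactly what stresses the group-sequential boundary assumptions).
#'
#' @param sc An [scenario()] object whose model satisfies the global null.
#' @return An \code{"oc_result"} with one row per procedure: FWER estimate
#'   and Monte-Carlo standard error, plus per-hypothesis rejection rates.
#' @export
estimate_fwer <- function(sc) {
  stopifnot(inherits(sc, "oc_scenario"))
  if (sc$model$beta1 != 0 || sc$model$beta3 != 0)
    stop("FWER scenarios require beta1 = beta3 = 0 (global null); ",
         "got beta1 = ", sc$model$beta1, ", beta3 = ", sc$model$beta3)
  oc_engine(sc)
}

#' Estimate disjunctive power by simulation
#'
#' Probability of rejecting at least one of the K hypotheses under an
#' alternative. The single full-population t-test is always included for
#' comparison.
#'
#' @param sc An [scenario()] object.
#' @return An \code{"oc_result"}.
#' @export
estimate_power <- function(sc) {
  stopifnot(inherits(sc, "oc_scenario"))
  if (!"full_population" %in% sc$procedures)
    sc$procedures <- c(sc$procedures, "full_population")
  oc_engine(sc)
}

#' Analytic sample size for the single full-population t-test
#'
#' Smallest per-group \eqn{n} such that the one-sided two-sample pooled
#' t-test at level \eqn{\alpha} attains the target power against a
#' standardized effect \eqn{d}: power is the upper tail of the noncentral t
#' distribution with \eqn{2n - 2} degrees of freedom and noncentrality
#' \eqn{d \sqrt{n/2}} at the central t quantile.
#'
#' @param effect_size Standardized effect \eqn{d > 0}.
#' @param alpha One-sided level.
#' @param power Target power in (0, 1).
#' @return Smallest integer per-group sample size meeting the target.
#' @examples
#' analytic_two_sample_n(0.5)   # 86
#' @export
analytic_two_sample_n <- function(effect_size, alpha = 0.025, power = 0.9) {
  stopifnot(effect_size > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  pw <- function(n) stats::pt(stats::qt(1 - alpha, 2 * n - 2), 2 * n - 2,
                              ncp = effect_size * sqrt(n / 2),
                              lower.tail = FALSE)
  za <- stats::qnorm(1 - alpha); zb <- stats::qnorm(power)
  n <- max(2, floor(2 * (za + zb)^2 / effect_size^2) - 2)
  while (pw(n) < power) n <- n + 1
  while (n > 2 && pw(n - 1) >= power) n <- n - 1
  n
}

#' Simulation-based sample-size search for a multiple testing procedure
#'
#' Integer bisection for the smallest per-group \eqn{n} whose estimated
#' disjunctive power reaches the target. All candidate sizes reuse the same
#' per-replicate random substreams (common random numbers), so the power
#' curve is monotone up to Monte-Carlo noise at the search boundary.
#'
#' A two-stage search keeps the number of full-replicate candidates small: a
#' coarse bisection at \code{pilot_replicates} locates the approximate
#' solution, and the full-replicate bisection then runs on a narrow bracket
#' around it (re-widened automatically if the pilot was off).
#'
#' @param model A [model_spec()] template; its \code{n_per_group} is
#'   overridden during the search.
#' @param procedure Single procedure name.
#' @param target_power Target disjunctive power.
#' @param n_bracket Integer vector \code{c(lo, hi)}; the search errors if the
#'   estimated power does not straddle the target over this bracket.
#' @param K Number of equally spaced quantile thresholds.
#' @param replicates Replicates per candidate size at the final stage.
#' @param seed Root seed; all candidate sizes share per-replicate substreams.
#' @param alpha One-sided family-wise level.
#' @param pilot_replicates Replicates for the coarse first-stage bisection;
#'   set to \code{NULL} to bisect the full bracket at full replicates.
#' @param pilot_margin Half-width of the refined bracket around the pilot
#'   solution.
#' @return A list: \code{n} (smallest adequate size), \code{power} and
#'   \code{mc_se} at \code{n}, \code{power_below} at \code{n - 1}, and the
#'   \code{evaluations} table of all full-replicate candidates tried.
#' @export
sample_size_search <- function(model, procedure, target_power = 0.9,
                               n_bracket, K = 4, replicates = 10000,
                               seed = 1, alpha = 0.025,
                               pilot_replicates = max(1000L, replicates %/% 10L),
                               pilot_margin = 6L) {
  stopifnot(inherits(model, "model_spec"), length(n_bracket) == 2,
            n_bracket[1] < n_bracket[2])
  procedure <- match.arg(procedure, PROCEDURES)
  make_power_at <- function(R) {
    evals <- new.env(parent = emptyenv())
    function(n) {
      key <- as.character(n)
      if (!is.null(evals[[key]])) return(evals[[key]])
      m <- model; m$n_per_group <- as.integer(n)
      sc <- scenario(m, K = K, procedures = procedure,
                     replicates = R, seed = seed, alpha = alpha)
      res <- oc_engine(sc)
      p <- res$table$estimate[res$table$procedure == procedure]
      evals[[key]] <- p
      p
    }
  }
  bisect <- function(power_at, lo, hi) {
    while (hi - lo > 1L) {
      mid <- (lo + hi) %/% 2L
      if (power_at(mid) >= target_power) hi <- mid else lo <- mid
    }
    hi
  }
  lo <- as.integer(n_bracket[1]); hi <- as.integer(n_bracket[2])
  power_at <- make_power_at(replicates)
  if (!is.null(pilot_replicates) && pilot_replicates < replicates) {
    pilot_at <- make_power_at(as.integer(pilot_replicates))
    if (pilot_at(lo) >= target_power || pilot_at(hi) < target_power)
      stop(sprintf("bracket [%d, %d] does not straddle the target power %.3f",
                   lo, hi, target_power))
    n_pilot <- bisect(pilot_at, lo, hi)
    lo2 <- max(lo, n_pilot - as.integer(pilot_margin))
    hi2 <- min(hi, n_pilot + as.integer(pilot_margin))
    while (hi2 < hi && power_at(hi2) < target_power)
      hi2 <- min(hi, hi2 + 2L * as.integer(pilot_margin))
    while (lo2 > lo && power_at(lo2) >= target_power)
      lo2 <- max(lo, lo2 - 2L * as.integer(pilot_margin))
    lo <- lo2; hi <- hi2
  }
  p_lo <- power_at(lo); p_hi <- power_at(hi)
  if (p_lo >= target_power || p_hi < target_power)
    stop(sprintf("bracket [%d, %d] does not straddle the target power %.3f ",
                 lo, hi, target_power),
         sprintf("(power %.4f and %.4f)", p_lo, p_hi))
  n_star <- bisect(power_at, lo, hi)
  p_n <- power_at(n_star)
  p_below <- power_at(n_star - 1L)
  evals <- environment(power_at)$evals
  ns <- sort(as.integer(ls(evals)))
  list(n = n_star, power = p_n,
       mc_se = sqrt(p_n * (1 - p_n) / replicates),
       power_below = p_below,
       evaluations = data.frame(
         n = ns, power = vapply(as.character(ns), function(k) evals[[k]], 0),
         row.names = NULL))
}

#' Scenario grids of the simulation study
#'
#' Factorial scenario grids for the main operating-characteristic figures:
#' FWER under step-function or linear prognostic effects, disjunctive power
#' under step or linear predictive effects, and the misspecification
#' scenarios (monotonically increasing effects and an intermediate-peak
#' effect). Defaults: \eqn{n = 80} per group, \eqn{K \in \{2, 4, 8\}}
#' quantile-based thresholds, \eqn{\gamma \in \{0.2, 0.5, 0.8\}} for step
#' shapes, prognostic effects \eqn{\Delta \in [0, 3]}, predictive effects in
#' \eqn{[0, 1]} standard deviations, \eqn{\sigma = 1}, one-sided
#' \eqn{\alpha = 0.025}.
#'
#' @param figure One of \code{"fwer_step"}, \code{"fwer_linear"},
#'   \code{"power_step"}, \code{"power_linear"}, \code{"misspec"}.
#' @param n Per-group sample size.
#' @param replicates Replicates per scenario.
#' @param seed Root seed.
#' @param procedures Procedures to evaluate.
#' @param delta_grid,effect_grid Overrides for the prognostic / predictive
#'   effect grids.
#' @return A named list of [scenario()] objects.
#' @export
scenario_grid <- function(figure = c("fwer_step", "fwer_linear", "power_step",
                                     "power_linear", "misspec"),
                          n = 80, replicates = 10000, seed = 1,
                          procedures = c("sidak", "t_gs", "adjusted_t",
                                         "inverse_normal"),
                          delta_grid = seq(0, 3, by = 0.5),
                          effect_grid = seq(0, 1, by = 0.25)) {
  figure <- match.arg(figure)
  Ks <- c(2, 4, 8); gammas <- c(0.2, 0.5, 0.8)
  out <- list()
  add <- function(name, spec, K)
    out[[name]] <<- scenario(spec, K = K, procedures = procedures,
                             replicates = replicates, seed = seed)
  if (figure == "fwer_step") {
    for (K in Ks) for (g in gammas) for (d in delta_grid)
      add(sprintf("K%d_gamma%g_delta%g", K, g, d),
          model_spec(beta2 = d, shape = "step-decreasing", gamma = g,
                     n_per_group = n), K)
  } else if (figure == "fwer_linear") {
    for (K in Ks) for (d in delta_grid)
      add(sprintf("K%d_delta%g", K, d),
          model_spec(beta2 = d, shape = "linear-decreasing",
                     n_per_group = n), K)
  } else if (figure == "power_step") {
    for (K in Ks) for (g in gammas) for (e in effect_grid)
      add(sprintf("K%d_gamma%g_effect%g", K, g, e),
          model_spec(beta3 = e, shape = "step-decreasing", gamma = g,
                     n_per_group = n), K)
  } else if (figure == "power_linear") {
    for (K in Ks) for (e in effect_grid)
      add(sprintf("K%d_effect%g", K, e),
          model_spec(beta3 = e, shape = "linear-decreasing",
                     n_per_group = n), K)
  } else {
    shapes <- c("step-increasing", "linear-increasing", "intermediate-peak")
    for (K in Ks) for (sh in shapes) for (d in delta_grid)
      add(sprintf("K%d_%s_delta%g", K, sh, d),
          model_spec(beta2 = d, shape = sh,
                     gamma = if (sh != "linear-increasing") 0.5,
                     n_per_group = n), K)
  }
  out
}
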