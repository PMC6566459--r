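# Single-pass per-bin sufficient statistics. Bins are the disjoint subsets
# (q_{k-1}, q_k] with q_0 = -Inf; subjects above q_K fall in bin K + 1 and are
# excluded from every subgroup. Returns per-arm counts, sums and sums of
# squares per bin; cumulative sums over bins give the nested summaries.
bin_sufficient_stats <- function(y, u, x, thresholds) {
  K <- length(thresholds)
  bin <- findInterval(x, thresholds, left.open = TRUE) + 1L
  idx <- bin + (K + 1L) * u                      # 1..K+1 control, K+2..2K+2 treatment
  nb <- 2L * (K + 1L)
  cnt <- tabulate(idx, nbins = nb)
  agg <- rowsum(cbind(y, y * y), idx)
  s1 <- s2 <- numeric(nb)
  rows <- as.integer(rownames(agg))
  s1[rows] <- agg[, 1]; s2[rows] <- agg[, 2]
  list(K = K,
       n_c = cnt[1:K], n_t = cnt[(K + 2L):(2L * K + 1L)],
       s1_c = s1[1:K], s1_t = s1[(K + 2L):(2L * K + 1L)],
       s2_c = s2[1:K], s2_t = s2[(K + 2L):(2L * K + 1L)])
}

moments_from_sums <- function(n, s1, s2) {
  m <- ifelse(n > 0, s1 / n, NA_real_)
  v <- ifelse(n > 1, pmax((s2 - n * m^2), 0) / (n - 1), NA_real_)
  list(mean = m, var = v)
}

#' Per-subgroup summary statistics for a nested design
#'
#' Computes, for every nested subpopulation \eqn{S^+(q_k) = \{i : x_i \le q_k\}},
#' the per-arm sample sizes, means and unbiased sample variances, the pooled
#' variance, and the estimated treatment effect
#' \eqn{\hat\delta(q_k) = \bar y_t(q_k) - \bar y_c(q_k)}. Variances are
#' computed from the members of \eqn{S^+(q_k)} only.
#'
#' @param data A [trial_data()] object.
#' @param design A [nested_design()].
#' @return A data frame of class \code{"subgroup_summary"} with one row per
#'   threshold and columns \code{threshold, nt, nc, mean_t, mean_c, var_t,
#'   var_c, pooled_var, delta_hat, degenerate}. A row is flagged degenerate
#'   when either arm has fewer than 2 members or the pooled variance is not
#'   strictly positive; downstream procedures decide how to handle it.
#' @examples
#' d <- simulate_trial(model_spec(n_per_group = 40), seed = 1)
#' summarize_subgroups(d, nested_design(c(0.5, 1)))
#' @export
summarize_subgroups <- function(data, design) {
  stopifnot(inherits(design, "nested_design"))
  data <- as_trial_data(data)
  b <- bin_sufficient_stats(data$y, data$u, data$x, design$thresholds)
  m <- nested_moments(b)
  out <- data.frame(threshold = design$thresholds,
                    nt = m$nt, nc = m$nc,
                    mean_t = m$mean_t, mean_c = m$mean_c,
                    var_t = m$var_t, var_c = m$var_c,
                    pooled_var = m$pooled_var,
                    delta_hat = m$delta_hat)
  out$degenerate <- m$degenerate
  class(out) <- c("subgroup_summary", "data.frame")
  out
}

# Cumulative (nested) moments from per-bin sufficient statistics; plain list
# version used on the simulation hot path.
nested_moments <- function(b) {
  nt <- cumsum(b$n_t); nc <- cumsum(b$n_c)
  mt <- moments_from_sums(nt, cumsum(b$s1_t), cumsum(b$s2_t))
  mc <- moments_from_sums(nc, cumsum(b$s1_c), cumsum(b$s2_c))
  pooled <- pooled_variance(nt, nc, mt$var, mc$var)
  list(nt = nt, nc = nc, mean_t = mt$mean, mean_c = mc$mean,
       var_t = mt$var, var_c = mc$var, pooled_var = pooled,
       delta_hat = mt$mean - mc$mean,
       degenerate = nt < 2L | nc < 2L | !is.finite(pooled) | pooled <= 0)
}

pooled_variance <- function(nt, nc, var_t, var_c) {
  df <- nt + nc - 2
  ifelse(df > 0 & nt > 0 & nc > 0,
         (ifelse(nt > 1, (nt - 1) * var_t, 0) +
          ifelse(nc > 1, (nc - 1) * var_c, 0)) / df,
         NA_real_)
}

as_trial_data <- function(data) {
  if (inherits(data, "trial_data")) return(data)
  if (is.data.frame(data) && all(c("y", "u", "x") %in% names(data)))
    return(trial_data(data$y, data$u, data$x))
  stop("'data' must be a trial_data object or a data frame with columns y, u, x")
}

#' Vector of per-subgroup test statistics
#'
#' Light-weight container pairing statistic values with their degrees of
#' freedom (where applicable) and a method tag.
#'
#' @param values Numeric vector of statistics (\code{NA} where degenerate).
#' @param df Degrees of freedom per statistic, or \code{NA} for normal-scale
#'   statistics.
#' @param method Character tag.
#' @param information Optional information vector (reciprocal contrast
#'   variances or cumulative combination weights).
#' @return An object of class \code{"stat_vector"}.
#' @export
stat_vector <- function(values, df = NA_real_, method = "t",
                        information = NULL) {
  structure(list(values = as.numeric(values),
                 df = rep_len(as.numeric(df), length(values)),
                 method = method, information = information),
            class = "stat_vector")
}

#' @export
print.stat_vector <- function(x, ...) {
  cat(sprintf("Subgroup test statistics (%s):\n", x$method))
  print(data.frame(value = x$values, df = x$df))
  invisible(x)
}

#' Two-sample pooled t statistics per subgroup
#'
#' \eqn{T(q_k) = \hat\delta(q_k) / \sqrt{s_p^2(q_k) (1/n_t + 1/n_c)}} with
#' \eqn{n_t + n_c - 2} degrees of freedom, using the pooled within-subgroup
#' variance. Degenerate rows yield \code{NA}.
#'
#' @param summary A [summarize_subgroups()] result (or any data frame with
#'   columns \code{nt, nc, pooled_var, delta_hat}).
#' @return A [stat_vector()] with method \code{"t"}.
#' @export
t_statistic <- function(summary) {
  ok <- summary$nt >= 2 & summary$nc >= 2 &
    is.finite(summary$pooled_var) & summary$pooled_var > 0
  se <- sqrt(summary$pooled_var * (1 / summary$nt + 1 / summary$nc))
  v <- ifelse(ok, summary$delta_hat / se, NA_real_)
  stat_vector(v, df = summary$nt + summary$nc - 2, method = "t")
}

#' Known-variance z statistics per subgroup
#'
#' \eqn{Z(q_k) = \hat\delta(q_k) / \sqrt{\sigma_t^2/n_t + \sigma_c^2/n_c}}
#' for known arm standard deviations.
#'
#' @param summary A [summarize_subgroups()] result.
#' @param sigma_t,sigma_c Known arm standard deviations (scalars or per-subgroup
#'   vectors), strictly positive.
#' @return A [stat_vector()] with method \code{"z"} and \code{df = NA}.
#' @export
z_statistic <- function(summary, sigma_t, sigma_c) {
  stopifnot(all(sigma_t > 0), all(sigma_c > 0))
  ok <- summary$nt >= 1 & summary$nc >= 1
  se <- sqrt(sigma_t^2 / summary$nt + sigma_c^2 / summary$nc)
  v <- ifelse(ok, summary$delta_hat / se, NA_real_)
  stat_vector(v, df = NA_real_, method = "z")
}

#' Covariate-adjusted regression test statistics per subgroup
#'
#' Fits the linear model \eqn{Y = \beta_0' + \beta_1' U + \beta_2' X + \epsilon'}
#' by least squares within each subpopulation \eqn{S^+(q_k)} and tests the
#' treatment coefficient: the statistic is
#' \eqn{\hat\beta_1' / \widehat{SE}(\hat\beta_1')} on
#' \eqn{n_t + n_c - 3} degrees of freedom. Adjusting for the biomarker as a
#' covariate absorbs a (linear) prognostic effect that the plain t-test leaves
#' in the residual variance. The information \eqn{1/\widehat{Var}(\hat\beta_1')}
#' drives the correlation of the statistics across nested subgroups.
#'
#' @param data A [trial_data()] object.
#' @param design A [nested_design()].
#' @return A [stat_vector()] with method \code{"regression"}, degrees of
#'   freedom \eqn{n_k - 3}, and the per-subgroup information in
#'   \code{$information}. Subgroups with fewer than 4 subjects, a missing arm
#'   or constant biomarker are degenerate (\code{NA}).
#' @export
regression_statistic <- function(data, design) {
  stopifnot(inherits(design, "nested_design"))
  data <- as_trial_data(data)
  K <- design$K
  vals <- dfs <- info <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    sel <- data$x <= design$thresholds[k]
    n <- sum(sel)
    if (n < 4) next
    u <- data$u[sel]; x <- data$x[sel]; y <- data$y[sel]
    if (sum(u) < 1 || sum(1 - u) < 1 || stats::var(x) == 0) next
    X <- cbind(1, u, x)
    qx <- qr(X)
    if (qx$rank < 3) next
    cf <- qr.coef(qx, y)
    res <- y - X %*% cf
    s2 <- sum(res^2) / (n - 3)
    XtX_inv <- chol2inv(qr.R(qx))
    v1 <- s2 * XtX_inv[2, 2]
    if (!is.finite(v1) || v1 <= 0) next
    vals[k] <- cf[2] / sqrt(v1)
    dfs[k] <- n - 3
    info[k] <- 1 / v1
  }
  stat_vector(vals, df = dfs, method = "regression", information = info)
}

#' Stage-wise p-values and weights on disjoint biomarker subsets
#'
#' Splits the population into the disjoint subsets
#' \eqn{S^+(q_{k-1}, q_k] = \{i : q_{k-1} < x_i \le q_k\}} (with
#' \eqn{q_0 = -\infty}) and computes in each subset the one-sided upper-tail
#' p-value of the two-sample pooled t-test together with the combination
#' weight \eqn{w_k = [1/n_c + 1/n_t]^{-1}}, the reciprocal contrast-variance
#' factor of the subset. Under the global null with normal data, the subset
#' p-values are independent and uniform, which is what makes the inverse
#' normal combination exact.
#'
#' @param data A [trial_data()] object.
#' @param design A [nested_design()].
#' @return A list of class \code{"disjoint_pvalues"} with components \code{p},
#'   \code{w}, \code{statistic}, \code{df}, \code{nt}, \code{nc},
#'   \code{degenerate} (all length \eqn{K}).
#' @export
disjoint_pvalues <- function(data, design) {
  stopifnot(inherits(design, "nested_design"))
  data <- as_trial_data(data)
  b <- bin_sufficient_stats(data$y, data$u, data$x, design$thresholds)
  mt <- moments_from_sums(b$n_t, b$s1_t, b$s2_t)
  mc <- moments_from_sums(b$n_c, b$s1_c, b$s2_c)
  pooled <- pooled_variance(b$n_t, b$n_c, mt$var, mc$var)
  degen <- b$n_t < 2L | b$n_c < 2L | !is.finite(pooled) | pooled <= 0
  tstat <- ifelse(degen, NA_real_,
                  (mt$mean - mc$mean) /
                    sqrt(pooled * (1 / b$n_t + 1 / b$n_c)))
  df <- b$n_t + b$n_c - 2
  p <- ifelse(degen, NA_real_, stats::pt(tstat, df, lower.tail = FALSE))
  w <- ifelse(b$n_t > 0 & b$n_c > 0, 1 / (1 / b$n_t + 1 / b$n_c), NA_real_)
  structure(list(p = p, w = w, statistic = tstat, df = df,
                 nt = b$n_t, nc = b$n_c, degenerate = degen),
            class = "disjoint_pvalues")
}

#' Weighted inverse normal combination statistics
#'
#' Combines independent stage-wise p-values into the cumulative statistics
#' \deqn{C(q_k) = \frac{\sum_{m \le k} \sqrt{w_m}\, \Phi^{-1}(1 - p_m)}
#'                     {\sqrt{\sum_{j \le k} w_j}}}
#' which have unit variance under independent uniform p-values and the
#' group-sequential correlation \eqn{\sqrt{I_j / I_k}} with cumulative
#' information \eqn{I_k = \sum_{m \le k} w_m}.
#'
#' @param p Vector of p-values in (0, 1) (\code{NA} allowed for degenerate
#'   stages, which are skipped with their weight).
#' @param w Positive weights, same length.
#' @return A [stat_vector()] with method \code{"inverse-normal"},
#'   \code{df = NA} and cumulative information in \code{$information}.
#' @export
inverse_normal_statistics <- function(p, w) {
  stopifnot(length(p) == length(w))
  if (any(w[!is.na(w)] <= 0)) stop("weights must be strictly positive")
  if (any(p[!is.na(p)] <= 0 | p[!is.na(p)] >= 1))
    warning("p-values at 0 or 1 produce infinite combination statistics")
  use <- !is.na(p) & !is.na(w)
  z <- ifelse(use, stats::qnorm(1 - p), 0)
  wz <- ifelse(use, sqrt(w) * z, 0)
  Iu <- cumsum(ifelse(use, w, 0))
  vals <- ifelse(Iu > 0, cumsum(wz) / sqrt(Iu), NA_real_)
  stat_vector(vals, df = NA_real_, method = "inverse-normal", information = Iu)
}

#' Summaries for general subgroups, including pairwise intersections
#'
#' Computes per-set arm counts, means and variances as in
#' [summarize_subgroups()], plus the arm counts and variances on every
#' pairwise intersection \eqn{B_k \cap B_{k'}} — the ingredients of the
#' general-subgroup covariance of the test statistics.
#'
#' @param data A [trial_data()] object.
#' @param groups A [general_subgroups()] object.
#' @return A list of class \code{"general_summary"}: \code{summary} (a
#'   \code{"subgroup_summary"}-shaped data frame, one row per set) and
#'   \code{intersections}, a list of K x K matrices \code{nt, nc, var_t,
#'   var_c}.
#' @export
general_subgroup_summary <- function(data, groups) {
  stopifnot(inherits(groups, "general_subgroups"))
  data <- as_trial_data(data)
  K <- groups$K
  masks <- subgroup_membership(data$x, groups)
  one <- function(sel) {
    nt <- sum(sel & data$u == 1L); nc <- sum(sel & data$u == 0L)
    yt <- data$y[sel & data$u == 1L]; yc <- data$y[sel & data$u == 0L]
    vt <- if (nt > 1) stats::var(yt) else NA_real_
    vc <- if (nc > 1) stats::var(yc) else NA_real_
    c(nt = nt, nc = nc,
      mean_t = if (nt > 0) mean(yt) else NA_real_,
      mean_c = if (nc > 0) mean(yc) else NA_real_,
      var_t = vt, var_c = vc)
  }
  per <- t(vapply(seq_len(K), function(k) one(masks[, k]), numeric(6)))
  summ <- data.frame(label = groups$labels, per)
  summ$pooled_var <- pooled_variance(summ$nt, summ$nc, summ$var_t, summ$var_c)
  summ$delta_hat <- summ$mean_t - summ$mean_c
  summ$degenerate <- summ$nt < 2L | summ$nc < 2L |
    !is.finite(summ$pooled_var) | summ$pooled_var <= 0
  inter <- list(nt = matrix(0, K, K), nc = matrix(0, K, K),
                var_t = matrix(NA_real_, K, K), var_c = matrix(NA_real_, K, K))
  for (k in seq_len(K)) for (kk in seq_len(K)) {
    sel <- masks[, k] & masks[, kk]
    s <- one(sel)
    inter$nt[k, kk] <- s["nt"]; inter$nc[k, kk] <- s["nc"]
    inter$var_t[k, kk] <- s["var_t"]; inter$var_c[k, kk] <- s["var_c"]
  }
  structure(list(summary = summ, intersections = inter, K = K,
                 labels = groups$labels),
            class = "general_summary")
}
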