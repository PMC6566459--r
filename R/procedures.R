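# The decision procedures. All tests are one-sided (H1: delta > 0) and
# single-step: a hypothesis is rejected when its statistic exceeds its
# multiplicity-adjusted critical value. Because every procedure's rejection
# region for a sub-family of hypotheses contains the corresponding region for
# any super-family, weak control under the global null extends to strong
# family-wise error control by the closed testing principle.

PROCEDURES <- c("sidak", "z_gs", "t_gs", "adjusted_t", "regression",
                "inverse_normal", "full_population")

new_decision_result <- function(table, procedure, alpha, family,
                                attained_alpha = NA_real_, degenerate = 0L,
                                diagnostics = list()) {
  structure(list(table = table, procedure = procedure, alpha = alpha,
                 family = family, attained_alpha = attained_alpha,
                 any_reject = any(table$reject, na.rm = TRUE),
                 n_degenerate = degenerate, diagnostics = diagnostics),
            class = "decision_result")
}

#' @export
print.decision_result <- function(x, digits = 4, ...) {
  cat(sprintf("Procedure: %s (one-sided alpha = %g, %s boundaries)\n",
              x$procedure, x$alpha, x$family))
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  cat(sprintf("Any rejection: %s", x$any_reject))
  if (is.finite(x$attained_alpha))
    cat(sprintf("   (attained boundary level %.6f)", x$attained_alpha))
  cat("\n")
  if (x$n_degenerate > 0)
    cat(sprintf("Degenerate subgroups encountered: %d\n", x$n_degenerate))
  invisible(x)
}

#' Run a multiplicity-adjusted subgroup testing procedure
#'
#' Tests the one-sided null hypotheses \eqn{H_{0k}: \delta(q_k) \le 0} on the
#' nested subpopulations \eqn{S^+(q_k)} with one of the procedures:
#' \describe{
#'   \item{\code{"sidak"}}{t statistics against per-subgroup t quantiles at
#'     the Sidak-adjusted level; conservative, ignores the positive
#'     correlation of nested statistics.}
#'   \item{\code{"z_gs"}}{t statistics against normal-scale group-sequential
#'     boundaries from the equal-variance covariance ("z-test"; can be liberal
#'     at small samples since the t scale is ignored).}
#'   \item{\code{"t_gs"}}{the same boundaries mapped to the t scale by
#'     quantile substitution ("t-test"; can be liberal under strong
#'     unadjusted prognostic effects, which perturb the covariance).}
#'   \item{\code{"adjusted_t"}}{boundaries from the variance-adjusted plug-in
#'     covariance, then quantile substitution; controls the family-wise error
#'     under minimal assumptions.}
#'   \item{\code{"regression"}}{biomarker-adjusted regression statistics
#'     against information-covariance boundaries with \eqn{n_k - 3}
#'     quantile substitution.}
#'   \item{\code{"inverse_normal"}}{weighted inverse normal combination of
#'     disjoint-subset p-values against normal-scale boundaries from the
#'     cumulative-weight information covariance (the combination statistics
#'     are exactly standard normal under the null).}
#'   \item{\code{"full_population"}}{the single unadjusted t-test on all
#'     subjects at level \eqn{\alpha}, for comparison.}
#' }
#'
#' @param name Procedure name, see Details.
#' @param data A [trial_data()] object (or data frame with y, u, x).
#' @param design A [nested_design()].
#' @param boundary Boundary family for the group-sequential procedures:
#'   \code{"pocock"} (common critical value, default) or \code{"obf"}.
#' @param covariance_form Plug-in covariance form for \code{"adjusted_t"},
#'   see [variance_adjusted_covariance()].
#' @param alpha Optional override of the design's level.
#' @param algorithm MVN integration algorithm, see [mvn_tail_probability()].
#' @param mode \code{"analysis"} (degenerate subgroups raise an error asking
#'   the user to merge thresholds) or \code{"simulation"} (degenerate
#'   hypotheses are counted and treated as not rejected).
#' @return A \code{"decision_result"}: per-hypothesis table with columns
#'   \code{threshold, nt, nc, statistic, df, boundary, reject}, plus the
#'   attained boundary level and diagnostics.
#' @examples
#' d <- simulate_trial(model_spec(beta1 = 1, n_per_group = 60), seed = 7)
#' run_procedure("adjusted_t", d, nested_design(c(0.25, 0.5, 0.75, 1)))
#' @export
run_procedure <- function(name, data, design,
                          boundary = c("pocock", "obf"),
                          covariance_form = c("simplified", "general"),
                          alpha = NULL, algorithm = "auto",
                          mode = c("analysis", "simulation")) {
  name <- match.arg(name, PROCEDURES)
  boundary <- match.arg(boundary)
  covariance_form <- match.arg(covariance_form)
  mode <- match.arg(mode)
  stopifnot(inherits(design, "nested_design"))
  data <- as_trial_data(data)
  if (is.null(alpha)) alpha <- design$alpha
  summ <- summarize_subgroups(data, design)
  K <- design$K
  diagnostics <- list()

  if (name == "full_population") {
    n1 <- sum(data$u == 1L); n0 <- sum(data$u == 0L)
    if (n1 < 2 || n0 < 2) stop("both arms need at least 2 subjects")
    v <- ((n1 - 1) * stats::var(data$y[data$u == 1L]) +
          (n0 - 1) * stats::var(data$y[data$u == 0L])) / (n1 + n0 - 2)
    tt <- (mean(data$y[data$u == 1L]) - mean(data$y[data$u == 0L])) /
      sqrt(v * (1 / n1 + 1 / n0))
    df <- n1 + n0 - 2
    bnd <- stats::qt(1 - alpha, df)
    tab <- data.frame(threshold = NA_real_, nt = n1, nc = n0,
                      statistic = tt, df = df, boundary = bnd,
                      reject = !is.na(tt) & tt > bnd)
    return(new_decision_result(tab, name, alpha, "single", alpha))
  }

  degen <- summ$degenerate
  if (name %in% c("sidak", "z_gs", "t_gs", "adjusted_t")) {
    st <- t_statistic(summ)
    stat <- st$values; df <- st$df
  } else if (name == "regression") {
    st <- regression_statistic(data, design)
    stat <- st$values; df <- st$df
    degen <- degen | is.na(stat)
  } else if (name == "inverse_normal") {
    dp <- disjoint_pvalues(data, design)
    if (any(dp$degenerate)) degen_sets <- sum(dp$degenerate) else degen_sets <- 0L
    st <- inverse_normal_statistics(dp$p, dp$w)
    stat <- st$values; df <- rep(NA_real_, K)
    degen <- is.na(stat)
    diagnostics$degenerate_subsets <- degen_sets
  }

  if (any(degen)) {
    if (mode == "analysis")
      stop("degenerate subgroup(s) at threshold(s) ",
           paste(format(design$thresholds[degen]), collapse = ", "),
           ": fewer than 2 subjects per arm or zero variance; ",
           "merge or raise thresholds")
    diagnostics$degenerate_hypotheses <- which(degen)
  }
  ok <- !degen
  if (!any(ok)) {
    tab <- data.frame(threshold = design$thresholds, nt = summ$nt,
                      nc = summ$nc, statistic = stat, df = df,
                      boundary = NA_real_, reject = FALSE)
    return(new_decision_result(tab, name, alpha, "none", NA_real_,
                               sum(degen), diagnostics))
  }

  bnd <- rep(NA_real_, K)
  attained <- NA_real_
  family <- "sidak"
  if (name == "sidak") {
    ac <- sidak_level(alpha, K)   # level fixed by the pre-specified design
    bnd[ok] <- stats::qt(1 - ac, df[ok])
  } else {
    sig <- switch(name,
      z_gs = , t_gs = equal_variance_covariance(summ$nt[ok], summ$nc[ok]),
      adjusted_t = variance_adjusted_covariance(summ[ok, , drop = FALSE],
                                                form = covariance_form),
      regression = {
        info <- st$information[ok]
        if (is.unsorted(info)) {
          if (mode == "analysis")
            warning("realized regression information not monotone over ",
                    "nested subgroups; monotonized")
          diagnostics$info_monotonized <- TRUE
          info <- cummax(info)
        }
        information_covariance(info)
      },
      inverse_normal = information_covariance(st$information[ok]))
    bs <- if (boundary == "pocock") {
      pocock_common_critical_value(sig, alpha, algorithm)
    } else {
      info <- switch(name,
        z_gs = , t_gs = , adjusted_t = 1 / (1 / summ$nt[ok] + 1 / summ$nc[ok]),
        regression = cummax(st$information[ok]),
        inverse_normal = st$information[ok])
      obf_critical_values(sig, info, alpha, algorithm)
    }
    family <- bs$family
    attained <- bs$attained_alpha
    cn <- bs$c_normal
    bnd[ok] <- switch(name,
      z_gs = cn,
      t_gs = , adjusted_t = quantile_substitution(cn, df[ok]),
      regression = quantile_substitution(cn, df[ok]),
      inverse_normal = cn)
  }
  tab <- data.frame(threshold = design$thresholds, nt = summ$nt, nc = summ$nc,
                    statistic = stat, df = df, boundary = bnd,
                    reject = ok & !is.na(stat) & !is.na(bnd) & stat > bnd)
  new_decision_result(tab, name, alpha, family, attained, sum(degen),
                      diagnostics)
}

#' Multiplicity-adjusted p-values
#'
#' For each hypothesis, the smallest significance level at which the chosen
#' procedure rejects it, found by monotone bisection on \eqn{\alpha}. By
#' construction the adjusted p-value is coherent with the test: rejection at
#' level \eqn{\alpha} holds exactly when the adjusted p-value is
#' \eqn{\le \alpha} (up to root-finding tolerance). For the Sidak procedure
#' the result agrees with the closed form \eqn{1 - (1 - p_{raw})^K}.
#'
#' @inheritParams run_procedure
#' @param tol Bisection tolerance on the level scale.
#' @return Numeric vector of adjusted p-values (one per hypothesis;
#'   \code{NA} for degenerate hypotheses in simulation mode).
#' @examples
#' d <- simulate_trial(model_spec(beta1 = 0.8, n_per_group = 50), seed = 3)
#' adjusted_pvalues("sidak", d, nested_design(c(0.5, 1)))
#' @export
adjusted_pvalues <- function(name, data, design,
                             boundary = c("pocock", "obf"),
                             covariance_form = c("simplified", "general"),
                             algorithm = "auto",
                             mode = c("analysis", "simulation"),
                             tol = 1e-8) {
  name <- match.arg(name, PROCEDURES)
  boundary <- match.arg(boundary)
  covariance_form <- match.arg(covariance_form)
  mode <- match.arg(mode)
  run_at <- function(a) run_procedure(name, data, design, boundary = boundary,
                                      covariance_form = covariance_form,
                                      alpha = a, algorithm = algorithm,
                                      mode = mode)
  base <- run_at(design$alpha)
  Kh <- nrow(base$table)
  out <- rep(NA_real_, Kh)
  eps <- 1e-10
  for (k in seq_len(Kh)) {
    if (is.na(base$table$statistic[k])) next
    lo <- eps; hi <- 1 - eps
    if (!run_at(hi)$table$reject[k]) { out[k] <- 1; next }
    if (run_at(lo)$table$reject[k]) { out[k] <- lo; next }
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (run_at(mid)$table$reject[k]) hi <- mid else lo <- mid
    }
    out[k] <- hi
  }
  out
}

#' Test general (non-nested) subgroups with a common adjusted boundary
#'
#' Pooled t statistics for each interval-union subgroup are compared against
#' multiplicity-adjusted critical values derived from the plug-in
#' general-subgroup covariance: either the Pocock-type common value (default)
#' or a user-supplied vector of normal-scale critical values, which is
#' validated against the level-\eqn{\alpha} condition. Normal-scale values
#' are mapped to the t scale per subgroup by quantile substitution.
#'
#' @param data A [trial_data()] object.
#' @param groups A [general_subgroups()] object (e.g. from
#'   [stepp_tail_subgroups()]).
#' @param alpha One-sided family-wise level.
#' @param critical_values Optional vector of normal-scale critical values,
#'   one per subgroup, satisfying the level-\eqn{\alpha} condition.
#' @param algorithm MVN integration algorithm.
#' @return A \code{"decision_result"} with one row per subgroup.
#' @export
run_general_procedure <- function(data, groups, alpha = 0.025,
                                  critical_values = NULL,
                                  algorithm = "auto") {
  stopifnot(inherits(groups, "general_subgroups"))
  data <- as_trial_data(data)
  gs <- general_subgroup_summary(data, groups)
  summ <- gs$summary
  if (any(summ$degenerate))
    stop("degenerate subgroup(s): ",
         paste(summ$label[summ$degenerate], collapse = ", "),
         "; merge or drop them")
  st <- t_statistic(summ)
  sig <- general_covariance(gs)
  if (is.null(critical_values)) {
    bs <- pocock_common_critical_value(sig, alpha, algorithm)
    cn <- bs$c_normal
    attained <- bs$attained_alpha
    family <- "pocock"
  } else {
    stopifnot(length(critical_values) == gs$K)
    attained <- mvn_tail_probability(sig, critical_values, algorithm)
    if (attained > alpha + 1e-6)
      stop(sprintf("supplied critical values attain level %.6f > alpha = %g",
                   attained, alpha))
    cn <- critical_values
    family <- "custom"
  }
  bnd <- quantile_substitution(cn, st$df)
  tab <- data.frame(subgroup = summ$label, nt = summ$nt, nc = summ$nc,
                    statistic = st$values, df = st$df,
                    c_normal = cn, boundary = bnd,
                    reject = !is.na(st$values) & st$values > bnd)
  new_decision_result(tab, "general_t", alpha, family, attained)
}
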