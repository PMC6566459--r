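# Correlation matrices of the per-subgroup test statistics. Nested subgroups
# share all subjects of the smaller subgroup, which induces the
# group-sequential correlation sqrt(I_j / I_k); prognostic biomarker effects
# make the within-subgroup variances differ, which perturbs that structure and
# is what the variance-adjusted forms capture.

new_covariance_matrix <- function(m, labels = NULL) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == ncol(m))
  if (!is.null(labels)) dimnames(m) <- list(labels, labels)
  class(m) <- c("covariance_matrix", class(m))
  m
}

#' Equal-variance (group-sequential) correlation of nested statistics
#'
#' Under a common outcome variance across subgroups, the correlation between
#' the cumulative statistics of nested subgroups \eqn{j \subset k} is
#' \deqn{\sqrt{\frac{1/n_t(q_k) + 1/n_c(q_k)}{1/n_t(q_j) + 1/n_c(q_j)}}}
#' — the classical information ratio \eqn{\sqrt{I_j / I_k}}; it does not
#' depend on the variances themselves.
#'
#' @param nt,nc Per-subgroup arm counts, nondecreasing in the nesting order.
#'   Alternatively \code{nt} may be a [summarize_subgroups()] result, in which
#'   case \code{nc} is ignored.
#' @return A \code{"covariance_matrix"} (correlation matrix, unit diagonal).
#' @examples
#' equal_variance_covariance(c(40, 80), c(40, 80))
#' @export
equal_variance_covariance <- function(nt, nc = NULL) {
  if (is.data.frame(nt)) { nc <- nt$nc; nt <- nt$nt }
  stopifnot(length(nt) == length(nc), all(nt > 0), all(nc > 0))
  if (is.unsorted(nt) || is.unsorted(nc))
    stop("arm counts must be nondecreasing over nested subgroups")
  r <- 1 / nt + 1 / nc                      # contrast-variance factor, decreasing
  K <- length(r)
  m <- sqrt(outer(r, r, function(a, b) pmin(a, b) / pmax(a, b)))
  # pmin/pmax formulation keeps (j,k) = sqrt(r_k / r_j) for j < k and a unit
  # diagonal even when consecutive subgroups coincide.
  new_covariance_matrix(m)
}

#' Variance-adjusted correlation of nested statistics (plug-in)
#'
#' When an unadjusted prognostic biomarker effect makes the outcome variance
#' differ across nested subgroups, the equal-variance correlation is wrong.
#' The general form uses per-arm variances of the smaller subgroup in the
#' numerator:
#' \deqn{\frac{\sigma_t^2(q_j)/n_t(q_k) + \sigma_c^2(q_j)/n_c(q_k)}
#'   {\sqrt{\sigma_t^2(q_j)/n_t(q_j) + \sigma_c^2(q_j)/n_c(q_j)}
#'    \sqrt{\sigma_t^2(q_k)/n_t(q_k) + \sigma_c^2(q_k)/n_c(q_k)}}}
#' for \eqn{q_j < q_k}. Assuming equal variances across arms within a
#' subgroup it simplifies to the equal-variance entry multiplied by
#' \eqn{\sigma(q_j)/\sigma(q_k)} with pooled within-subgroup SDs; the
#' simplified form is the default. In practice the subgroup variances are
#' unknown and the sample estimates are plugged in.
#'
#' @param summary A [summarize_subgroups()] result.
#' @param form \code{"simplified"} (pooled SD ratio, default) or
#'   \code{"general"} (per-arm variances).
#' @return A \code{"covariance_matrix"}.
#' @export
variance_adjusted_covariance <- function(summary,
                                         form = c("simplified", "general")) {
  form <- match.arg(form)
  nt <- summary$nt; nc <- summary$nc
  stopifnot(all(nt > 0), all(nc > 0))
  K <- length(nt)
  if (form == "simplified") {
    s <- sqrt(summary$pooled_var)
    if (any(!is.finite(s) | s <= 0))
      stop("all subgroup pooled variances must be positive")
    base <- equal_variance_covariance(nt, nc)
    # entry (j,k), j < k in nesting order, is scaled by s_j / s_k
    ratio <- matrix(1, K, K)
    for (j in seq_len(K)) for (k in seq_len(K)) {
      lo <- min(j, k); hi <- max(j, k)
      if (j != k) ratio[j, k] <- s[lo] / s[hi]
    }
    m <- unclass(base) * ratio
  } else {
    vt <- summary$var_t; vc <- summary$var_c
    if (any(!is.finite(vt) | !is.finite(vc)))
      stop("all per-arm subgroup variances must be available")
    m <- matrix(1, K, K)
    for (j in seq_len(K)) for (k in seq_len(K)) {
      if (j == k) next
      lo <- min(j, k); hi <- max(j, k)
      num <- vt[lo] / nt[hi] + vc[lo] / nc[hi]
      den <- sqrt(vt[lo] / nt[lo] + vc[lo] / nc[lo]) *
             sqrt(vt[hi] / nt[hi] + vc[hi] / nc[hi])
      m[j, k] <- num / den
    }
  }
  repair_correlation(new_covariance_matrix(m))
}

#' Correlation from an information sequence
#'
#' \eqn{\mathrm{Corr}(Z_j, Z_k) = \sqrt{I_j / I_k}} for \eqn{j < k}, where
#' \eqn{I_k} is the (estimated) information of subgroup \eqn{k}: the
#' reciprocal variance of the treatment-effect estimate for the regression
#' procedure, or the cumulative combination weight for the inverse normal
#' procedure.
#'
#' @param information Strictly positive, nondecreasing vector.
#' @return A \code{"covariance_matrix"}.
#' @export
information_covariance <- function(information) {
  stopifnot(is.numeric(information), all(is.finite(information)),
            all(information > 0))
  if (is.unsorted(information))
    stop("'information' must be nondecreasing over nested subgroups")
  m <- sqrt(outer(information, information, function(a, b) pmin(a, b) / pmax(a, b)))
  new_covariance_matrix(m)
}

#' Correlation of test statistics for general (non-nested) subgroups
#'
#' For arbitrary interval-union subgroups \eqn{B_k} the covariance between
#' the z statistics is driven by the shared subjects in \eqn{B_k \cap B_{k'}}:
#' \deqn{\frac{\sigma_t^2(B_\cap) n_t(B_\cap) / (n_t(B_k) n_t(B_{k'}))
#'       + \sigma_c^2(B_\cap) n_c(B_\cap) / (n_c(B_k) n_c(B_{k'}))}
#'  {\sqrt{\sigma_t^2(B_k)/n_t(B_k) + \sigma_c^2(B_k)/n_c(B_k)}
#'   \sqrt{\sigma_t^2(B_{k'})/n_t(B_{k'}) + \sigma_c^2(B_{k'})/n_c(B_{k'})}}}
#' Disjoint subgroups are uncorrelated; nested ones recover the
#' variance-adjusted nested formula. Sample estimates are plugged in.
#'
#' @param gsummary A [general_subgroup_summary()] result.
#' @return A \code{"covariance_matrix"}.
#' @export
general_covariance <- function(gsummary) {
  stopifnot(inherits(gsummary, "general_summary"))
  s <- gsummary$summary; X <- gsummary$intersections
  K <- gsummary$K
  if (any(s$degenerate))
    stop("degenerate subgroup(s): ",
         paste(s$label[s$degenerate], collapse = ", "))
  den <- sqrt(s$var_t / s$nt + s$var_c / s$nc)
  m <- matrix(1, K, K)
  for (k in seq_len(K)) for (kk in seq_len(K)) {
    if (k == kk) next
    nti <- X$nt[k, kk]; nci <- X$nc[k, kk]
    if (nti + nci == 0) { m[k, kk] <- 0; next }
    vti <- if (nti > 1) X$var_t[k, kk] else 0
    vci <- if (nci > 1) X$var_c[k, kk] else 0
    num <- vti * nti / (s$nt[k] * s$nt[kk]) + vci * nci / (s$nc[k] * s$nc[kk])
    m[k, kk] <- num / (den[k] * den[kk])
  }
  repair_correlation(new_covariance_matrix(m, gsummary$labels))
}

# Plug-in correlation matrices can be slightly non-PSD in finite samples.
# Clip negative eigenvalues at zero and re-standardize to unit diagonal,
# warning when the repair actually changes anything.
repair_correlation <- function(m) {
  cls <- class(m)
  mm <- unclass(m)
  mm <- (mm + t(mm)) / 2
  ev <- eigen(mm, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    warning("plug-in correlation matrix not positive semidefinite; ",
            "clipping negative eigenvalues")
    vals <- pmax(ev$values, 0)
    mm <- ev$vectors %*% (vals * t(ev$vectors))
    d <- sqrt(diag(mm))
    mm <- mm / outer(d, d)
    diag(mm) <- 1
  }
  class(mm) <- cls
  mm
}
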