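#' Nested subpopulation design
#'
#' An ordered set of biomarker thresholds \eqn{q_1 < \dots < q_K} defining the
#' nested biomarker-positive subpopulations \eqn{S^+(q_k) = \{i : x_i \le q_k\}},
#' together with the one-sided significance level. When \eqn{q_K} equals the
#' maximal biomarker value the last test is the full-population test.
#'
#' @param thresholds Strictly increasing numeric vector of thresholds.
#' @param alpha One-sided family-wise significance level in (0, 1).
#' @return An object of class \code{"nested_design"}.
#' @examples
#' nested_design(c(0.25, 0.5, 0.75, 1), alpha = 0.025)
#' @export
nested_design <- function(thresholds, alpha = 0.025) {
  stopifnot(is.numeric(thresholds), length(thresholds) >= 1L,
            all(is.finite(thresholds)))
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("'thresholds' must be strictly increasing")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie in (0, 1)")
  structure(list(thresholds = as.numeric(thresholds),
                 K = length(thresholds), alpha = alpha),
            class = "nested_design")
}

#' @export
print.nested_design <- function(x, ...) {
  cat(sprintf("Nested subpopulation design: K = %d thresholds (%s), one-sided alpha = %g\n",
              x$K, paste(format(x$thresholds), collapse = ", "), x$alpha))
  invisible(x)
}

#' General (non-nested) subgroups as unions of biomarker intervals
#'
#' Each subgroup \eqn{B_k} is a finite union of half-open intervals
#' \eqn{(l, h]} on the biomarker scale; \code{-Inf} and \code{Inf} endpoints
#' are allowed, so \eqn{\{x \le q\}} is \code{(-Inf, q]} and \eqn{\{x > q\}}
#' is \code{(q, Inf]}. Intersections of two subgroups are computed exactly on
#' the interval representation.
#'
#' @param sets A list; each element is a 2-column matrix (or a length-2 vector)
#'   of interval endpoints \code{cbind(lower, upper)} with \code{lower < upper}.
#' @param labels Optional character labels, one per set.
#' @return An object of class \code{"general_subgroups"}.
#' @examples
#' gs <- general_subgroups(list(c(-Inf, 0.5), c(0.5, Inf), c(-Inf, Inf)),
#'                         labels = c("low", "high", "all"))
#' gs
#' @export
general_subgroups <- function(sets, labels = NULL) {
  stopifnot(is.list(sets), length(sets) >= 1L)
  sets <- lapply(sets, function(s) {
    if (is.null(dim(s))) s <- matrix(as.numeric(s), ncol = 2, byrow = TRUE)
    s <- matrix(as.numeric(s), ncol = 2)
    if (any(s[, 1] >= s[, 2]))
      stop("interval lower endpoints must be strictly below upper endpoints")
    s[order(s[, 1]), , drop = FALSE]
  })
  if (is.null(labels))
    labels <- paste0("B", seq_along(sets))
  stopifnot(length(labels) == length(sets))
  structure(list(sets = sets, K = length(sets), labels = as.character(labels)),
            class = "general_subgroups")
}

#' @export
print.general_subgroups <- function(x, ...) {
  cat(sprintf("General subgroups: K = %d interval-union sets\n", x$K))
  for (k in seq_len(x$K)) {
    iv <- apply(x$sets[[k]], 1, function(r) sprintf("(%g, %g]", r[1], r[2]))
    cat(sprintf("  %s: %s\n", x$labels[k], paste(iv, collapse = " U ")))
  }
  invisible(x)
}

# Membership of biomarker values in one interval-union set (half-open (l, h]).
interval_membership <- function(x, intervals) {
  m <- rep(FALSE, length(x))
  for (r in seq_len(nrow(intervals)))
    m <- m | (x > intervals[r, 1] & x <= intervals[r, 2])
  m
}

# Exact intersection of two interval unions, again as an interval union
# (possibly with zero rows).
intersect_intervals <- function(a, b) {
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b))) {
      lo <- max(a[i, 1], b[j, 1]); hi <- min(a[i, 2], b[j, 2])
      if (lo < hi) out <- rbind(out, c(lo, hi))
    }
  out
}

#' Subject membership masks for a subgroup design
#'
#' @param x Biomarker values.
#' @param design A [nested_design()] or [general_subgroups()] object.
#' @return A logical matrix with one column per subgroup.
#' @export
subgroup_membership <- function(x, design) {
  if (inherits(design, "nested_design")) {
    out <- vapply(design$thresholds, function(q) x <= q, logical(length(x)))
  } else if (inherits(design, "general_subgroups")) {
    out <- vapply(design$sets, function(s) interval_membership(x, s),
                  logical(length(x)))
  } else stop("'design' must be a nested_design or general_subgroups object")
  matrix(out, nrow = length(x), ncol = design$K)
}

#' Tail-oriented STEPP subgroups
#'
#' Builds the \eqn{2K - 1} subgroups of the tail-oriented subpopulation
#' treatment effect pattern plot (STEPP) construction: the \eqn{K}
#' left-to-right cumulative sets \eqn{\{x \le q_k\}} (with the largest
#' threshold taken as \eqn{+\infty}, so the full population is included once)
#' and the \eqn{K - 1} right-to-left cumulative sets \eqn{\{x > q_k\}},
#' \eqn{k < K}. Useful when it is unclear whether low or high biomarker values
#' carry the treatment benefit.
#'
#' @param thresholds Strictly increasing thresholds; the last may be
#'   \code{Inf} (it is treated as \code{Inf} regardless, so that the largest
#'   set is the full population).
#' @return A [general_subgroups()] object with \code{2 * K - 1} sets.
#' @examples
#' stepp_tail_subgroups(c(0.25, 0.5, Inf))
#' @export
stepp_tail_subgroups <- function(thresholds) {
  stopifnot(is.numeric(thresholds), length(thresholds) >= 1L)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("'thresholds' must be strictly increasing")
  K <- length(thresholds)
  q <- thresholds
  q[K] <- Inf
  left <- lapply(q, function(qk) c(-Inf, qk))
  right <- if (K > 1) lapply(q[-K], function(qk) c(qk, Inf)) else list()
  labels <- c(paste0("le_", format(thresholds)),
              if (K > 1) paste0("gt_", format(thresholds[-K])))
  labels[K] <- "full"
  general_subgroups(c(left, right), labels = labels)
}
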