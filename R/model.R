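#' Specify the outcome-generating model for a biomarker trial
#'
#' Defines the linear model
#' \deqn{Y_i = \beta_0 + \beta_1 U_i + \beta_2 f(X_i) + \beta_3 U_i f(X_i) + \epsilon_i}
#' for a two-arm parallel-group trial with a continuous baseline biomarker
#' \eqn{X_i \in [0,1]}, arm indicator \eqn{U_i} (1 = treatment, 0 = control) and
#' normal errors \eqn{\epsilon_i \sim N(0, \sigma^2)}. The single shape function
#' \eqn{f} carries both the prognostic effect (through \eqn{\beta_2}) and the
#' predictive effect (through \eqn{\beta_3}).
#'
#' Available shapes for \eqn{f}:
#' \describe{
#'   \item{\code{"step-decreasing"}}{\eqn{f(x) = 1} for \eqn{x \le \gamma}, else 0:
#'     the effect is confined to the biomarker-low ("biomarker positive") tail.}
#'   \item{\code{"step-increasing"}}{the complement \eqn{1 - f(x)} of the above;
#'     a misspecified direction for threshold subgroups of the form \eqn{x \le q}.}
#'   \item{\code{"linear-decreasing"}}{\eqn{f(x) = 1 - x}.}
#'   \item{\code{"linear-increasing"}}{\eqn{f(x) = x} (misspecified direction).}
#'   \item{\code{"intermediate-peak"}}{indicator of the central band
#'     \eqn{(0.5 - \gamma/2,\, 0.5 + \gamma/2]}, so the largest effects occur at
#'     intermediate biomarker values while the band keeps prevalence \eqn{\gamma}.}
#' }
#'
#' @param beta0 Intercept (outcome units).
#' @param beta1 Main treatment effect.
#' @param beta2 Prognostic coefficient (effect of the biomarker on the outcome
#'   in both arms).
#' @param beta3 Predictive coefficient (treatment-by-biomarker interaction).
#' @param shape Shape of the biomarker effect function \eqn{f}; see Details.
#' @param gamma True cutoff in \[0, 1\]; required for the step and
#'   intermediate-peak shapes, ignored otherwise.
#' @param sigma Residual standard deviation, strictly positive.
#' @param n_per_group Number of subjects per arm (the trial has
#'   \code{2 * n_per_group} subjects).
#' @return An object of class \code{"model_spec"}.
#' @seealso [simulate_trial()], [effect_function()]
#' @examples
#' spec <- model_spec(beta3 = 1, shape = "step-decreasing", gamma = 0.5,
#'                    n_per_group = 80)
#' spec
#' @export
model_spec <- function(beta0 = 0, beta1 = 0, beta2 = 0, beta3 = 0,
                       shape = c("step-decreasing", "step-increasing",
                                 "linear-decreasing", "linear-increasing",
                                 "intermediate-peak"),
                       gamma = NULL, sigma = 1, n_per_group) {
  shape <- match.arg(shape)
  for (b in list(beta0, beta1, beta2, beta3))
    stopifnot(is.numeric(b), length(b) == 1L, is.finite(b))
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number")
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L ||
      n_per_group < 1 || n_per_group != round(n_per_group))
    stop("'n_per_group' must be a positive integer")
  # the cutoff only matters when the biomarker effect enters the outcome
  needs_gamma <- shape %in% c("step-decreasing", "step-increasing",
                              "intermediate-peak") &&
    (beta2 != 0 || beta3 != 0)
  if (needs_gamma && is.null(gamma))
    stop("shape '", shape, "' requires a cutoff 'gamma'")
  if (!is.null(gamma)) {
    if (!is.numeric(gamma) || length(gamma) != 1L || gamma < 0 || gamma > 1)
      stop("'gamma' must lie in [0, 1]")
  }
  if (shape %in% c("linear-decreasing", "linear-increasing")) gamma <- NULL
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 shape = shape, gamma = gamma, sigma = sigma,
                 n_per_group = as.integer(n_per_group)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Trial outcome model: y = b0 + b1*u + b2*f(x) + b3*u*f(x) + eps\n")
  cat(sprintf("  beta: (%g, %g, %g, %g)   sigma: %g\n",
              x$beta0, x$beta1, x$beta2, x$beta3, x$sigma))
  cat(sprintf("  shape: %s%s   n per group: %d\n", x$shape,
              if (!is.null(x$gamma)) sprintf(" (gamma = %g)", x$gamma) else "",
              x$n_per_group))
  invisible(x)
}

#' Evaluate the biomarker effect function of a model specification
#'
#' Computes \eqn{f(x)} for the shape held by a [model_spec()]; vectorized in
#' \code{x}. Step shapes use inclusive membership at the cutoff
#' (\eqn{x \le \gamma}), matching the threshold-subgroup convention.
#'
#' @param spec A \code{"model_spec"}.
#' @param x Biomarker values in \[0, 1\].
#' @return Numeric vector \eqn{f(x)} of the same length as \code{x}.
#' @examples
#' spec <- model_spec(shape = "step-decreasing", gamma = 0.5, n_per_group = 10)
#' effect_function(spec, c(0.3, 0.7))
#' @export
effect_function <- function(spec, x) {
  stopifnot(inherits(spec, "model_spec"), is.numeric(x))
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("biomarker values must lie in [0, 1] for model evaluation")
  if (is.null(spec$gamma) &&
      spec$shape %in% c("step-decreasing", "step-increasing",
                        "intermediate-peak"))
    stop("shape '", spec$shape, "' requires a cutoff 'gamma'")
  switch(spec$shape,
    "step-decreasing"   = as.numeric(x <= spec$gamma),
    "step-increasing"   = as.numeric(x > spec$gamma),
    "linear-decreasing" = 1 - x,
    "linear-increasing" = x,
    "intermediate-peak" = as.numeric(x > 0.5 - spec$gamma / 2 &
                                     x <= 0.5 + spec$gamma / 2))
}

#' Container for subject-level trial data
#'
#' @param y Outcome vector.
#' @param u Arm indicator vector (1 = treatment, 0 = control).
#' @param x Biomarker vector. Generated data lie in \[0, 1\]; user data may be
#'   on any scale (thresholds are then on the same scale).
#' @return A data frame of class \code{"trial_data"} with columns
#'   \code{y}, \code{u}, \code{x}.
#' @export
trial_data <- function(y, u, x) {
  if (length(y) != length(u) || length(y) != length(x))
    stop("'y', 'u' and 'x' must have equal lengths")
  if (anyNA(y) || anyNA(u) || anyNA(x))
    stop("trial data must not contain missing values")
  if (!all(u %in% c(0, 1)))
    stop("arm indicator 'u' must contain only 0 (control) and 1 (treatment)")
  structure(data.frame(y = as.numeric(y), u = as.integer(u),
                       x = as.numeric(x)),
            class = c("trial_data", "data.frame"))
}

# Deterministic per-replicate substream seed: a counter-based affine map on the
# Mersenne prime 2^31 - 1, so replicate r is reproducible in isolation and
# seeds stay valid 32-bit integers.
substream_seed <- function(root_seed, r) {
  m <- 2147483647
  as.integer((as.numeric(root_seed) %% m + (1000003 * (as.numeric(r) %% m)) %% m) %% m)
}

# Run expr with a private RNG state; caller's .Random.seed is untouched.
with_private_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate a two-arm trial with a uniformly distributed biomarker
#'
#' Draws \code{2 * n_per_group} subjects: exactly \code{n_per_group} per arm
#' (fixed allocation, so only the biomarker sampling drives subgroup
#' imbalance), biomarker values i.i.d. uniform on \[0, 1\] independent of the
#' arm, and outcomes from the model held by \code{spec}. The same
#' \code{(spec, seed)} pair always yields bit-identical data; the caller's RNG
#' state is left untouched.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed.
#' @return A [trial_data()] object with \code{2 * n_per_group} rows.
#' @examples
#' d <- simulate_trial(model_spec(beta2 = 1, shape = "step-decreasing",
#'                                gamma = 0.5, n_per_group = 40), seed = 1)
#' table(d$u)
#' @export
simulate_trial <- function(spec, seed) {
  stopifnot(inherits(spec, "model_spec"))
  n <- spec$n_per_group
  with_private_seed(seed, {
    u <- rep(c(1L, 0L), each = n)
    x <- stats::runif(2 * n)
    f <- if (spec$beta2 != 0 || spec$beta3 != 0) effect_function(spec, x) else 0
    y <- spec$beta0 + spec$beta1 * u + spec$beta2 * f + spec$beta3 * u * f +
      stats::rnorm(2 * n, sd = spec$sigma)
    trial_data(y, u, x)
  })
}

#' Write / read a model specification as JSON
#'
#' @param spec A [model_spec()].
#' @param path File path.
#' @return \code{write_model_spec} returns \code{path} invisibly;
#'   \code{read_model_spec} returns a \code{"model_spec"}.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "model_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  model_spec(beta0 = v$beta0, beta1 = v$beta1, beta2 = v$beta2,
             beta3 = v$beta3, shape = v$shape,
             gamma = if (!is.null(v$gamma)) v$gamma,
             sigma = v$sigma, n_per_group = v$n_per_group)
}
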