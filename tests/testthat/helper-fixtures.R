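# Shared fixtures, built in code.

null_step_spec <- function(delta = 2, gamma = 0.5, n = 80)
  model_spec(beta2 = delta, shape = "step-decreasing", gamma = gamma,
             n_per_group = n)

alt_step_spec <- function(effect = 1, gamma = 0.5, n = 80)
  model_spec(beta3 = effect, shape = "step-decreasing", gamma = gamma,
             n_per_group = n)

quartile_design <- function(alpha = 0.025)
  nested_design(c(0.25, 0.5, 0.75, 1), alpha = alpha)

# Small deterministic dataset with both arms represented in every quartile
# subgroup; used where exact hand-checkable structure matters.
tiny_trial <- function() {
  trial_data(
    y = c(1.2, 0.4, 2.2, 1.1, 0.3, -0.5, 0.9, 1.8, 0.0, 0.7, 1.4, -0.2,
          2.0, 0.6, 1.0, -1.1),
    u = rep(c(1L, 0L), 8),
    x = c(0.05, 0.10, 0.20, 0.22, 0.30, 0.40, 0.45, 0.48,
          0.55, 0.60, 0.70, 0.72, 0.80, 0.85, 0.90, 0.95))
}
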