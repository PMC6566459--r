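# CSV readers/writers, analysis reports and fixture generation.

#' Read subject-level trial data from CSV
#'
#' Expects named columns \code{y} (outcome), \code{u} (arm indicator, 0/1)
#' and \code{x} (biomarker); any column order; an optional \code{subject_id}
#' column is ignored. The biomarker need not lie in \[0, 1\] — analysis
#' thresholds are interpreted on the same (native) scale.
#'
#' @param path CSV file path.
#' @return A [trial_data()] object.
#' @export
read_trial_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  missing_cols <- setdiff(c("y", "u", "x"), names(d))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  for (cl in c("y", "u", "x")) {
    bad <- which(is.na(d[[cl]]))
    if (length(bad))
      stop(sprintf("missing values in column '%s' at row(s) %s", cl,
                   paste(utils::head(bad, 5), collapse = ", ")))
  }
  bad_u <- which(!d$u %in% c(0, 1))
  if (length(bad_u))
    stop("arm indicator 'u' must be 0 or 1; offending row(s): ",
         paste(utils::head(bad_u, 5), collapse = ", "))
  trial_data(d$y, d$u, d$x)
}

#' Write trial data to CSV
#'
#' @param data A [trial_data()] object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  data <- as_trial_data(data)
  out <- data.frame(subject_id = seq_len(nrow(data)), y = data$y,
                    u = data$u, x = data$x)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis or simulation report to CSV
#'
#' Writes the per-hypothesis decision table (or the per-procedure operating
#' characteristics table with its Monte-Carlo standard errors) as tidy CSV at
#' full precision, followed by \code{#}-prefixed metadata footer lines
#' (procedure, level, attained boundary level, seed, package version) that
#' make the run reproducible; \code{read.csv(..., comment.char = "#")}
#' ignores the footer.
#'
#' @param result A \code{"decision_result"} or \code{"oc_result"}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_report <- function(result, path) {
  if (inherits(result, "decision_result")) {
    tab <- result$table
    meta <- c(sprintf("procedure: %s", result$procedure),
              sprintf("alpha: %g", result$alpha),
              sprintf("boundary_family: %s", result$family),
              sprintf("attained_alpha: %.8f", result$attained_alpha),
              sprintf("any_reject: %s", result$any_reject),
              sprintf("degenerate_subgroups: %d", result$n_degenerate))
  } else if (inherits(result, "oc_result")) {
    tab <- cbind(result$table,
                 stats::setNames(data.frame(result$per_hypothesis),
                                 paste0("reject_rate_h",
                                        seq_len(ncol(result$per_hypothesis)))))
    meta <- c(sprintf("replicates: %d", result$replicates),
              sprintf("seed: %d", result$seed),
              sprintf("alpha: %g", result$design$alpha),
              sprintf("thresholds: %s",
                      paste(result$design$thresholds, collapse = " ")),
              sprintf("degenerate_events: %d", result$n_degenerate))
  } else stop("'result' must be a decision_result or oc_result")
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  con <- file(path, open = "at")
  on.exit(close(con))
  writeLines(c("", paste("#", meta),
               paste("# nestsub version:",
                     as.character(utils::packageVersion("nestsub")))), con)
  invisible(path)
}

#' Generate seeded example datasets
#'
#' Writes four small CSV datasets with a JSON manifest of their generating
#' parameters: a global-null trial with a prognostic step effect, a
#' step-model alternative, a linear-trend alternative, and a
#' degenerate-subgroup case (a threshold so low that the first subgroup has
#' fewer than 2 subjects per arm). All datasets are synthetic and regenerate
#' bit-identically from the same seed.
#'
#' @param out_dir Writable directory (created if absent).
#' @param seed Root seed.
#' @return Invisibly, the named list of file paths.
#' @export
generate_fixtures <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    null_prognostic = model_spec(beta2 = 2, shape = "step-decreasing",
                                 gamma = 0.5, n_per_group = 80),
    step_alternative = model_spec(beta3 = 1, shape = "step-decreasing",
                                  gamma = 0.5, n_per_group = 80),
    linear_alternative = model_spec(beta3 = 1, shape = "linear-decreasing",
                                    n_per_group = 80),
    degenerate_subgroup = model_spec(n_per_group = 12))
  paths <- list()
  manifest <- list()
  for (nm in names(specs)) {
    s <- substream_seed(seed, match(nm, names(specs)))
    d <- simulate_trial(specs[[nm]], seed = s)
    p <- file.path(out_dir, paste0(nm, ".csv"))
    write_trial_csv(d, p)
    paths[[nm]] <- p
    manifest[[nm]] <- c(unclass(specs[[nm]]), list(seed = s, file = basename(p),
      note = if (nm == "degenerate_subgroup")
        "analyze with a first threshold near 0.01 to trigger degenerate handling"))
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(paths)
}
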