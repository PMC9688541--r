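diagnosis_levels_before <- c("UWS", "MCS-")
diagnosis_levels_after <- c("UWS", "MCS-", "MCS+")
etiology_levels <- c("TBI", "ABI", "CVD")

#' Label a patient's consciousness-recovery outcome
#'
#' A patient counts as *improved* when the diagnosis moved up the
#' consciousness hierarchy between the pre-experiment assessment and the
#' three-month follow-up: UWS to MCS-, UWS to MCS+, or MCS- to MCS+.
#' Staying in UWS or MCS- is *not improved*. `nontraumatic` flags NTBI
#' etiology (acquired brain injury or cerebrovascular disease, as opposed
#' to traumatic brain injury).
#'
#' @param record A patient record (row of [load_patient_table()]), or a
#'   diagnosis string when `after` is given.
#' @param after Diagnosis at follow-up (when `record` is the
#'   pre-experiment diagnosis string).
#' @param etiology Optional etiology string (TBI, ABI or CVD).
#' @return List with `improved` and (when etiology is known) `nontraumatic`.
#' @examples
#' label_outcome("UWS", "MCS+")$improved   # TRUE
#' label_outcome("MCS-", "MCS-")$improved  # FALSE
#' @export
label_outcome <- function(record, after = NULL, etiology = NULL) {
  if (is.list(record)) {
    before <- record$diagnosis_before
    after <- record$diagnosis_after
    etiology <- record$etiology
  } else before <- record
  if (!before %in% diagnosis_levels_before)
    stop_param("unknown pre-experiment diagnosis '", before,
               "' (expected UWS or MCS-)")
  if (!after %in% diagnosis_levels_after)
    stop_param("unknown follow-up diagnosis '", after,
               "' (expected UWS, MCS- or MCS+)")
  rank <- c(UWS = 1L, `MCS-` = 2L, `MCS+` = 3L)
  out <- list(improved = rank[[after]] > rank[[before]])
  if (!is.null(etiology)) {
    if (!etiology %in% etiology_levels)
      stop_param("unknown etiology '", etiology, "'")
    out$nontraumatic <- etiology %in% c("ABI", "CVD")
  }
  out
}

#' Summarise a patient cohort
#'
#' Outcome and etiology counts (via [label_outcome()]) plus the age summary
#' (mean and n-1-denominator SD).
#'
#' @param records Patient table from [load_patient_table()].
#' @return Object of class `cohort_summary`: `n`, `n_improved`,
#'   `n_not_improved`, `n_tbi`, `n_ntbi`, `n_tbi_improved`, `age_mean`,
#'   `age_sd`.
#' @export
summarize_cohort <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop_param("records must contain at least one patient")
  if (nrow(records) < 2L) stop_param("at least two records needed for SD")
  lab <- lapply(seq_len(nrow(records)), function(i)
    label_outcome(as.list(records[i, ])))
  improved <- vapply(lab, `[[`, logical(1), "improved")
  ntbi <- vapply(lab, `[[`, logical(1), "nontraumatic")
  structure(list(n = nrow(records),
                 n_improved = sum(improved),
                 n_not_improved = sum(!improved),
                 n_tbi = sum(!ntbi), n_ntbi = sum(ntbi),
                 n_tbi_improved = sum(!ntbi & improved),
                 age_mean = mean(records$age), age_sd = sd(records$age)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> n = %d: %d improved / %d not improved; %d TBI (%d improved) / %d NTBI\n",
              x$n, x$n_improved, x$n_not_improved, x$n_tbi,
              x$n_tbi_improved, x$n_ntbi))
  cat(sprintf("  age %.2f +/- %.2f years\n", x$age_mean, x$age_sd))
  invisible(x)
}

#' Two-sample Student's t-test between patient groups
#'
#' Two-sided pooled-variance Student's t-test by default (`welch = TRUE`
#' switches to the Welch variant). Degenerate inputs -- both groups with
#' zero variance -- are flagged explicitly instead of returning NaN.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param names Length-2 character vector of group names.
#' @param welch Use the Welch (unequal-variance) test.
#' @return Object of class `group_comparison`: group names, sizes, means,
#'   SDs, `t`, `df`, `p` (two-sided), `degenerate` flag, and a slot
#'   `p_fdr` filled by [run_study_statistics()].
#' @export
group_ttest <- function(values_a, values_b, names = c("A", "B"),
                        welch = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2)
    stop_param("each group needs at least two values")
  degenerate <- sd(values_a) == 0 && sd(values_b) == 0
  if (degenerate) {
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    t_stat <- if (same) 0 else Inf * sign(mean(values_a) - mean(values_b))
    p <- if (same) 1 else 0
    df <- length(values_a) + length(values_b) - 2
  } else {
    tt <- t.test(values_a, values_b, var.equal = !welch)
    t_stat <- unname(tt$statistic)
    df <- unname(tt$parameter)
    p <- tt$p.value
  }
  structure(list(groups = names,
                 n = c(length(values_a), length(values_b)),
                 means = c(mean(values_a), mean(values_b)),
                 sds = c(sd(values_a), sd(values_b)),
                 t = t_stat, df = df, p = p, p_fdr = NA_real_,
                 alpha = 0.05, degenerate = degenerate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (n=%d, mean %.4f) vs %s (n=%d, mean %.4f)\n",
              x$groups[1], x$n[1], x$means[1],
              x$groups[2], x$n[2], x$means[2]))
  cat(sprintf("  t = %.4f, df = %g, p = %.5g%s%s\n", x$t, x$df, x$p,
              if (!is.na(x$p_fdr)) sprintf(", FDR-adjusted p = %.5g", x$p_fdr)
              else "",
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotonicity-enforced); adjusted values are
#' never below the raw ones.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
fdr_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop_param("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Fit a Gaussian to a set of accuracies
#'
#' Descriptive sample mean and (n-1) SD, as used for the per-group density
#' plots; `density(grid)` evaluates the fitted normal density.
#'
#' @param values Numeric vector, length >= 2.
#' @return Object of class `gaussian_fit`: `mean`, `sd`, `n`, `degenerate`
#'   (TRUE when `sd` is 0) and a `density` function.
#' @export
fit_gaussian <- function(values) {
  if (length(values) < 2) stop_param("need at least two values")
  m <- mean(values); s <- sd(values)
  structure(list(mean = m, sd = s, n = length(values),
                 degenerate = s == 0,
                 density = function(x) dnorm(x, m, s)),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> N(mean = %.4f, sd = %.4f), n = %d%s\n",
              x$mean, x$sd, x$n,
              if (x$degenerate) " [degenerate: zero variance]" else ""))
  invisible(x)
}

#' Correlation between CRS-R score and P300 detection accuracy
#'
#' Pearson linear correlation between per-patient CRS-R totals (at the
#' three-month follow-up by default) and detection accuracies, with the
#' least-squares line.
#'
#' @param records Patient table ([load_patient_table()]).
#' @param accuracies One detection accuracy per record, in the same order.
#' @param which_score `"after"` (three-month follow-up, the default) or
#'   `"before"`.
#' @return Object of class `correlation_result`: `r`, `n`, `slope`,
#'   `intercept`, `which_score`.
#' @export
accuracy_crsr_correlation <- function(records, accuracies,
                                      which_score = c("after", "before")) {
  which_score <- match.arg(which_score)
  if (nrow(records) != length(accuracies))
    stop_param("one accuracy per record is required")
  if (nrow(records) < 3) stop_param("need at least three patients")
  score <- records[[paste0("crsr_", which_score, "_total")]]
  if (sd(score) == 0 || sd(accuracies) == 0)
    stop_param("zero variance in scores or accuracies")
  fit <- lm(accuracies ~ score)
  structure(list(r = cor(score, accuracies), n = length(accuracies),
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 which_score = which_score),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> Pearson r = %.6f (n = %d, CRS-R %s); fit: acc = %.4f + %.4f * score\n",
              x$r, x$n, x$which_score, x$intercept, x$slope))
  invisible(x)
}

#' The full cohort-level statistical analysis for one detector
#'
#' Runs the four group comparisons -- detection accuracy and F1, each
#' improved-vs-not-improved and TBI-vs-NTBI -- as pooled two-sided Student's
#' t-tests with Benjamini-Hochberg FDR adjustment across that family of
#' four, fits per-group Gaussians to the accuracies, and computes the
#' Pearson correlation between follow-up CRS-R totals and accuracy.
#'
#' @param records Patient table ([load_patient_table()]).
#' @param accuracies Named or ordered per-patient detection accuracies
#'   (percent or fraction, used as given).
#' @param f1 Per-patient F1 scores, same order.
#' @param method `"cnn"` or `"bayesian"` (labelling only).
#' @param which_score CRS-R assessment used for the correlation.
#' @return Object of class `p300_study` with elements `method`,
#'   `comparisons` (named list of four [group_ttest()] results with
#'   `p_fdr` filled), `gaussians` (per-group fits), `correlation`,
#'   `summary` (a [summarize_cohort()]).
#' @export
run_study_statistics <- function(records, accuracies, f1,
                                 method = c("cnn", "bayesian"),
                                 which_score = "after") {
  method <- match.arg(method)
  if (!is.null(names(accuracies))) {
    miss <- setdiff(records$patient_id, names(accuracies))
    if (length(miss))
      stop_param("missing accuracy for patient(s): ",
                 paste(miss, collapse = ", "))
    accuracies <- accuracies[records$patient_id]
  }
  if (!is.null(names(f1))) f1 <- f1[records$patient_id]
  if (nrow(records) != length(accuracies) || nrow(records) != length(f1))
    stop_param("accuracies and f1 must cover every patient")
  lab <- lapply(seq_len(nrow(records)), function(i)
    label_outcome(as.list(records[i, ])))
  imp <- vapply(lab, `[[`, logical(1), "improved")
  ntbi <- vapply(lab, `[[`, logical(1), "nontraumatic")

  cmp <- list(
    accuracy_outcome = group_ttest(accuracies[imp], accuracies[!imp],
                                   c("improved", "not improved")),
    f1_outcome = group_ttest(f1[imp], f1[!imp],
                             c("improved", "not improved")),
    accuracy_etiology = group_ttest(accuracies[!ntbi], accuracies[ntbi],
                                    c("TBI", "NTBI")),
    f1_etiology = group_ttest(f1[!ntbi], f1[ntbi], c("TBI", "NTBI")))
  adj <- fdr_adjust(vapply(cmp, `[[`, numeric(1), "p"))
  for (i in seq_along(cmp)) cmp[[i]]$p_fdr <- adj[i]

  gaussians <- list(
    improved = fit_gaussian(accuracies[imp]),
    not_improved = fit_gaussian(accuracies[!imp]),
    tbi = fit_gaussian(accuracies[!ntbi]),
    ntbi = fit_gaussian(accuracies[ntbi]))

  structure(list(method = method, comparisons = cmp, gaussians = gaussians,
                 correlation = accuracy_crsr_correlation(
                   records, accuracies, which_score),
                 summary = summarize_cohort(records)),
            class = "p300_study")
}

#' @export
print.p300_study <- function(x, ...) {
  cat(sprintf("<p300_study> method: %s\n", x$method))
  print(x$summary)
  for (nm in names(x$comparisons)) {
    cat(sprintf("- %s:\n", nm))
    print(x$comparisons[[nm]])
  }
  print(x$correlation)
  invisible(x)
}

#' Plot the per-group Gaussian fits of a study report
#'
#' Fitted normal densities of detection accuracy for improved vs not
#' improved (or TBI vs NTBI) patients.
#'
#' @param x A `p300_study`.
#' @param grouping `"outcome"` or `"etiology"`.
#' @param ... Passed to [graphics::curve()].
#' @export
plot.p300_study <- function(x, grouping = c("outcome", "etiology"), ...) {
  grouping <- match.arg(grouping)
  g <- if (grouping == "outcome")
    x$gaussians[c("improved", "not_improved")]
  else x$gaussians[c("tbi", "ntbi")]
  rng <- range(g[[1]]$mean + c(-4, 4) * g[[1]]$sd,
               g[[2]]$mean + c(-4, 4) * g[[2]]$sd)
  xs <- seq(rng[1], rng[2], length.out = 400)
  ys <- cbind(g[[1]]$density(xs), g[[2]]$density(xs))
  graphics::matplot(xs, ys, type = "l", lty = 1,
                    col = c("firebrick", "forestgreen"),
                    xlab = "P300 detection accuracy", ylab = "density",
                    main = sprintf("Gaussian fits by %s (%s)", grouping,
                                   x$method), ...)
  graphics::legend("topleft", names(g), lty = 1,
                   col = c("firebrick", "forestgreen"), bty = "n")
  invisible(x)
}

#' Serialise a study report to JSON
#'
#' @param study A `p300_study`.
#' @param path Output file.
#' @export
write_study_json <- function(study, path) {
  strip <- function(cmpr) cmpr[setdiff(names(cmpr), "density")]
  out <- list(
    method = study$method,
    summary = unclass(study$summary),
    comparisons = lapply(study$comparisons, unclass),
    gaussians = lapply(study$gaussians, function(g)
      list(mean = g$mean, sd = g$sd, n = g$n, degenerate = g$degenerate)),
    correlation = unclass(study$correlation))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
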