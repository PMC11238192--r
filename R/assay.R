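#' Relative expression by the 2^-ddCt method
#'
#' Fold change of the target gene in a treated sample relative to a
#' control sample, each normalized to a reference gene:
#' `2^-[(Ct_target - Ct_ref)_treated - (Ct_target - Ct_ref)_control]`.
#'
#' @param treated,control Numeric length-2 vectors
#'   `c(ct_target, ct_reference)`.
#' @return Positive fold change; 1 when treated equals control.
#' @examples
#' ddct_fold_change(c(21, 20), c(20, 20))  # 0.5
#' @export
ddct_fold_change <- function(treated, control) {
  stopifnot(length(treated) == 2L, length(control) == 2L,
            all(is.finite(treated)), all(is.finite(control)))
  2^-((treated[1] - treated[2]) - (control[1] - control[2]))
}

#' Relative-suppression screen for allele selectivity
#'
#' An ASO passes when the mutant allele is suppressed by more than
#' `threshold` relative to the wild-type allele, i.e. when the ratio of
#' mutant to wild-type residual expression is at most `1 - threshold`
#' (default threshold 0.75, ratio <= 0.25).
#'
#' @param mut_fold,wt_fold Residual expression fold changes (> 0).
#' @param threshold Required relative suppression, in (0, 1).
#' @return List with `ratio` (`mut_fold / wt_fold`), `pass` and
#'   `threshold`.
#' @export
screen_selective <- function(mut_fold, wt_fold, threshold = 0.75) {
  if (any(c(mut_fold, wt_fold) <= 0)) {
    stop("fold changes must be positive", call. = FALSE)
  }
  stopifnot(threshold > 0, threshold < 1)
  ratio <- mut_fold / wt_fold
  list(ratio = ratio, pass = ratio <= (1 - threshold), threshold = threshold)
}

# 4PL response on log10 dose; hill > 0 gives a decreasing (inhibition) curve
fourpl <- function(dose, top, bottom, log_ic50, hill) {
  bottom + (top - bottom) / (1 + 10^(hill * (log10(dose) - log_ic50)))
}

#' Fit a four-parameter-logistic dose-response curve
#'
#' Least-squares 4PL on log10 dose, fitted with bounded
#' Levenberg-Marquardt. Replicate responses at the same dose are averaged
#' before fitting (set `summarize_replicates = FALSE` to fit every point).
#' IC50 is the inflection dose. Bounds: top in \[0.5, 1.5\], bottom in
#' \[-0.2, 0.5\], hill in \[0.2, 5\]. Initial values: plateaus from the
#' response extremes, hill 1, IC50 from the dose whose response is closest
#' to the half-range. A fit whose amplitude collapses (top - bottom
#' < 0.1) or that fails to converge is flagged, not silently dropped.
#'
#' @param doses Dose vector (nM, > 0).
#' @param responses Residual-expression fractions, same length.
#' @param summarize_replicates Average replicates per dose first.
#' @return Object of class `dose_response_fit`: `ic50` (nM), `hill`,
#'   `top`, `bottom`, `r_squared`, `n_points`, `degenerate`, `converged`.
#' @export
fit_dose_response <- function(doses, responses, summarize_replicates = TRUE) {
  stopifnot(length(doses) == length(responses), all(doses > 0),
            all(is.finite(responses)))
  if (length(unique(doses)) < 4L) {
    stop("at least 4 distinct doses are required", call. = FALSE)
  }
  if (summarize_replicates) {
    agg <- stats::aggregate(responses, list(dose = doses), mean)
    doses <- agg$dose
    responses <- agg$x
  }
  ld <- log10(doses)
  lower <- c(top = 0.5, bottom = -0.2, log_ic50 = min(ld) - 2, hill = 0.2)
  upper <- c(top = 1.5, bottom = 0.5, log_ic50 = max(ld) + 2, hill = 5)
  clamp <- function(x, lo, hi) min(max(x, lo), hi)
  half <- (max(responses) + min(responses)) / 2
  start <- c(top = clamp(max(responses), 0.5, 1.5),
             bottom = clamp(min(responses), -0.2, 0.5),
             log_ic50 = ld[which.min(abs(responses - half))],
             hill = 1)
  df <- data.frame(dose = doses, y = responses)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ fourpl(dose, top, bottom, log_ic50, hill),
                      data = df, start = as.list(start),
                      lower = lower, upper = upper,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(ic50 = NA_real_, hill = NA_real_, top = NA_real_,
                          bottom = NA_real_, r_squared = NA_real_,
                          n_points = length(doses), degenerate = TRUE,
                          converged = FALSE),
                     class = "dose_response_fit"))
  }
  cf <- stats::coef(fit)
  pred <- fourpl(doses, cf["top"], cf["bottom"], cf["log_ic50"], cf["hill"])
  ss_res <- sum((responses - pred)^2)
  ss_tot <- sum((responses - mean(responses))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  structure(list(ic50 = unname(10^cf["log_ic50"]),
                 hill = unname(cf["hill"]),
                 top = unname(cf["top"]), bottom = unname(cf["bottom"]),
                 r_squared = r2, n_points = length(doses),
                 degenerate = unname(cf["top"] - cf["bottom"] < 0.1),
                 converged = TRUE),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat(sprintf("4PL fit: IC50 %.3g nM, hill %.2f, top %.2f, bottom %.2f, R2 %.3f%s\n",
              x$ic50, x$hill, x$top, x$bottom, x$r_squared,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Allele-selectivity report from two dose-response fits
#'
#' @param fit_mut,fit_wt [fit_dose_response()] results for the mutant and
#'   wild-type allele.
#' @param mut_fold,wt_fold Optional single-dose residual expressions to
#'   include the [screen_selective()] verdict.
#' @param threshold Screen threshold (see [screen_selective()]).
#' @return Object of class `selectivity_report`: `ic50_mut`, `ic50_wt`,
#'   `selectivity_index` (`ic50_wt / ic50_mut`; > 1 means the mutant is
#'   preferentially silenced), `flagged` (TRUE when either fit is
#'   degenerate or unconverged), and `mut_to_wt_ratio` / `screen_pass`
#'   when the single-dose folds are given.
#' @export
selectivity_report <- function(fit_mut, fit_wt, mut_fold = NULL, wt_fold = NULL,
                               threshold = 0.75) {
  stopifnot(inherits(fit_mut, "dose_response_fit"),
            inherits(fit_wt, "dose_response_fit"))
  flagged <- isTRUE(fit_mut$degenerate) || isTRUE(fit_wt$degenerate) ||
    !isTRUE(fit_mut$converged) || !isTRUE(fit_wt$converged)
  out <- list(ic50_mut = fit_mut$ic50, ic50_wt = fit_wt$ic50,
              selectivity_index = fit_wt$ic50 / fit_mut$ic50,
              flagged = flagged,
              mut_to_wt_ratio = NA_real_, screen_pass = NA)
  if (!is.null(mut_fold) && !is.null(wt_fold)) {
    sc <- screen_selective(mut_fold, wt_fold, threshold)
    out$mut_to_wt_ratio <- sc$ratio
    out$screen_pass <- sc$pass
  }
  structure(out, class = "selectivity_report")
}

#' Read a dose-response table
#'
#' TSV with columns `design`, `allele`, `dose_nM`, `replicate`,
#' `fold_change`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_dose_response_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("design", "allele", "dose_nM", "replicate", "fold_change")
  if (!all(need %in% names(df))) {
    stop("dose-response table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Fit one design/allele stratum of a dose-response table
#'
#' @param df A [read_dose_response_tsv()]-shaped data.frame.
#' @param design,allele Stratum selectors.
#' @return A [fit_dose_response()] result.
#' @export
fit_dose_response_table <- function(df, design, allele) {
  sub <- df[df$design == design & df$allele == allele, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no rows for ", design, "/", allele, call. = FALSE)
  fit_dose_response(sub$dose_nM, sub$fold_change)
}
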