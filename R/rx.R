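#' Classifier configuration
#'
#' Holds the confidence-interval multiplier and the two decision
#' thresholds of the Rx sex classifier.  Defaults follow the established
#' cut-offs: a sample is called heterogametic (XY male / ZW female) when
#' the CI upper bound falls below 0.60, homogametic (XX female / ZZ male)
#' when the CI lower bound rises above 0.80, and left unassigned in
#' between.  Comparisons are strict; CI bounds exactly on a threshold give
#' an unassigned call.
#'
#' @param z positive CI multiplier; 1.96 gives a 95% normal interval.
#' @param lower_threshold the heterogametic cut-off (default 0.60).
#' @param upper_threshold the homogametic cut-off (default 0.80).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(z = 1.96, lower_threshold = 0.60,
                              upper_threshold = 0.80) {
  if (!is.numeric(z) || length(z) != 1L || z <= 0)
    stop("z must be a positive number", call. = FALSE)
  if (!(lower_threshold > 0 && lower_threshold < upper_threshold))
    stop("need 0 < lower_threshold < upper_threshold", call. = FALSE)
  structure(list(z = z, lower_threshold = lower_threshold,
                 upper_threshold = upper_threshold),
            class = "classifier_config")
}

#' Per-autosome depth ratios
#'
#' For each autosome i with mapped count m_i > 0 and length L_i, computes
#' the length-normalized depth ratio against the shared sex chromosome,
#' r_i = (m_X / L_X) / (m_i / L_i).  Autosomes with zero mapped reads are
#' dropped (ultra-low-coverage samples can leave small chromosomes empty)
#' and reported via the `"dropped"` attribute and a warning; a zero count
#' on the sex chromosome itself is a hard error.
#'
#' This direct form is algebraically identical to formulations that first
#' divide every chromosome's count by the library total and its length by
#' the genome total: both totals cancel in the ratio.
#'
#' @param counts an `rx_counts` join (see [join_counts()]).
#' @return Numeric vector of ratios (named by autosome), with attribute
#'   `dropped` listing zero-count autosomes.
#' @export
autosome_ratios <- function(counts) {
  stopifnot(inherits(counts, "rx_counts"))
  x <- counts[counts$role == "shared_sex", , drop = FALSE]
  if (nrow(x) != 1L)
    stop("counts must contain exactly one shared sex chromosome",
         call. = FALSE)
  if (x$mapped <= 0)
    stop("no reads on shared sex chromosome '", x$name, "'", call. = FALSE)
  auto <- counts[counts$role == "autosome", , drop = FALSE]
  dropped <- auto$name[auto$mapped == 0]
  if (length(dropped) > 0L)
    warning("dropping zero-count autosome(s): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  auto <- auto[auto$mapped > 0, , drop = FALSE]
  if (nrow(auto) < 2L)
    stop("fewer than 2 autosomes with mapped reads", call. = FALSE)
  r <- (x$mapped / x$length) / (auto$mapped / auto$length)
  names(r) <- auto$name
  attr(r, "dropped") <- dropped
  r
}

#' Compute the Rx statistic and sex call for one sample
#'
#' The Rx ratio is the mean over autosomes of the length-normalized depth
#' ratio between the shared sex chromosome and each autosome.  With two
#' copies of the X (or Z) it is expected near 1.0, with one copy near 0.5.
#' The standard error is the sample standard deviation of the
#' per-autosome ratios divided by the square root of the number of
#' autosomes used, and the confidence interval is `rx +/- z * se`.
#'
#' @param counts an `rx_counts` join (see [join_counts()]).
#' @param config a [classifier_config()].
#' @param sample_id overrides the sample id carried by `counts`.
#' @return An object of class `rx_result`: a list with elements
#'   `sample_id`, `ratios`, `rx`, `se`, `ci_low`, `ci_high`, `n_autosomes`,
#'   `call` (`"homogametic"`, `"heterogametic"` or `"unassigned"`),
#'   `call_label` (`"female"` / `"male"` / `"unassigned"` resolved by the
#'   sex-determination system) and `dropped_autosomes`.
#' @export
#' @examples
#' kt <- elephant_karyotype()
#' tab <- simulate_idxstats(sim_spec(kt, "heterogametic", 1e5, seed = 1))
#' compute_rx(join_counts(tab, kt))
compute_rx <- function(counts, config = classifier_config(),
                       sample_id = NULL) {
  stopifnot(inherits(config, "classifier_config"))
  r <- autosome_ratios(counts)
  n <- length(r)
  rx <- mean(r)
  se <- stats::sd(r) / sqrt(n)
  ci_low <- rx - config$z * se
  ci_high <- rx + config$z * se
  system <- attr(counts, "system")
  cl <- classify(ci_low, ci_high, system = system, config = config)
  structure(list(
    sample_id = if (is.null(sample_id)) sample_id_of(counts) else sample_id,
    ratios = r, rx = rx, se = se, ci_low = ci_low, ci_high = ci_high,
    n_autosomes = n, call = cl$call, call_label = cl$label,
    system = system, dropped_autosomes = attr(r, "dropped")),
    class = "rx_result")
}

#' @export
print.rx_result <- function(x, ...) {
  cat(sprintf("Rx result for '%s' (%s system)\n", x$sample_id, x$system))
  cat(sprintf("  Rx = %.7f  SE = %.3g  95%% CI [%.7f, %.7f]  (n = %d autosomes)\n",
              x$rx, x$se, x$ci_low, x$ci_high, x$n_autosomes))
  cat(sprintf("  call: %s (%s)\n", x$call_label, x$call))
  if (length(x$dropped_autosomes) > 0L)
    cat("  dropped zero-count autosomes: ",
        paste(x$dropped_autosomes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify a confidence interval into a sex call
#'
#' Heterogametic (one copy of the shared sex chromosome) when the CI upper
#' bound is strictly below the lower threshold; homogametic (two copies)
#' when the CI lower bound is strictly above the upper threshold;
#' unassigned otherwise.  Under XY the heterogametic sex is male; under ZW
#' it is female.  The unassigned zone is a first-class outcome, never
#' coerced to a sex.
#'
#' @param ci_low,ci_high CI bounds, `ci_low <= ci_high`.
#' @param system `"XY"` or `"ZW"`.
#' @param config a [classifier_config()].
#' @return A list with `call` (enum) and `label` (`"male"`, `"female"` or
#'   `"unassigned"`).
#' @export
#' @examples
#' classify(0.48, 0.52, "XY")$label  # "male"
#' classify(0.85, 0.95, "XY")$label  # "female"
#' classify(0.59, 0.61, "XY")$label  # "unassigned"
classify <- function(ci_low, ci_high, system = c("XY", "ZW"),
                     config = classifier_config()) {
  system <- match.arg(system)
  stopifnot(inherits(config, "classifier_config"))
  if (is.na(ci_low) || is.na(ci_high) || ci_low > ci_high)
    stop("need ci_low <= ci_high", call. = FALSE)
  call <- if (ci_high < config$lower_threshold) "heterogametic"
          else if (ci_low > config$upper_threshold) "homogametic"
          else "unassigned"
  label <- switch(call,
    heterogametic = if (system == "XY") "male" else "female",
    homogametic   = if (system == "XY") "female" else "male",
    unassigned    = "unassigned")
  list(call = call, label = label)
}

#' Coverage-sufficiency regression
#'
#' Ordinary least squares of per-autosome mapped read counts against
#' autosome length.  When coverage is adequate for the Rx statistic, reads
#' accumulate in proportion to chromosome size and the regression F-test
#' is highly significant; a non-significant fit flags a sample whose
#' counts carry no length signal (too few reads, or pathological mapping).
#' Only autosomes enter the fit: including the sex chromosome would
#' confound coverage adequacy with the very copy-number signal being
#' tested.
#'
#' @param counts an `rx_counts` join (see [join_counts()]).
#' @param alpha significance level for the sufficiency flag
#'   (default 0.001).
#' @return An object of class `coverage_check`: list with `slope`
#'   (reads per bp), `intercept`, `f_stat`, `p_value`, `sufficient`,
#'   `n_autosomes`, `alpha`.
#' @export
coverage_regression <- function(counts, alpha = 0.001) {
  stopifnot(inherits(counts, "rx_counts"))
  auto <- counts[counts$role == "autosome", , drop = FALSE]
  if (nrow(auto) < 3L)
    stop("insufficient chromosomes for regression (need >= 3 autosomes)",
         call. = FALSE)
  fit <- stats::lm(mapped ~ length, data = auto)
  mss <- sum((stats::fitted(fit) - mean(auto$mapped))^2)
  rss <- sum(stats::residuals(fit)^2)
  df2 <- nrow(auto) - 2L
  tol <- 1e-12 * sum(auto$mapped^2) + 1e-300
  if (mss <= tol) {            # no length signal (e.g. constant counts)
    f_stat <- 0
    p_value <- 1
  } else if (rss <= tol) {     # numerically perfect fit
    f_stat <- Inf
    p_value <- 0
  } else {
    f_stat <- (mss / 1) / (rss / df2)
    p_value <- stats::pf(f_stat, 1, df2, lower.tail = FALSE)
  }
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 f_stat = f_stat, p_value = unname(p_value),
                 sufficient = unname(p_value) < alpha,
                 n_autosomes = nrow(auto), alpha = alpha),
            class = "coverage_check")
}

#' @export
print.coverage_check <- function(x, ...) {
  cat(sprintf(
    "coverage check: slope %.3g reads/bp, F = %.3g, p = %.3g -> %s (alpha = %g)\n",
    x$slope, x$f_stat, x$p_value,
    if (x$sufficient) "sufficient" else "NOT sufficient", x$alpha))
  invisible(x)
}
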