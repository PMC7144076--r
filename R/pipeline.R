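#' Run sex identification over a set of idxstats files
#'
#' The batch driver: for each sample it reads the idxstats table, joins it
#' with the karyotype, runs the coverage-sufficiency regression and the Rx
#' computation, and classifies the sample.  A sample that fails (missing
#' chromosomes, unreadable file) is recorded in the failure log and does
#' not abort the remaining samples; warnings (dropped autosomes,
#' insufficient coverage) never abort.
#'
#' @param inputs character vector of idxstats file paths, or a single
#'   directory whose `*.idxstats` / `*.txt` / `*.tsv` files are processed.
#' @param kt a [karyotype], or a path to a karyotype configuration file.
#' @param config a [classifier_config()].
#' @param alpha significance level for the coverage check.
#' @param aliases optional name alias map passed to [join_counts()].
#' @param out optional path; when given, the result table is written there
#'   as TSV (deterministic: identical inputs give byte-identical files).
#' @return A data frame of class `rx_results` with one row per
#'   successfully processed sample and columns `sample_id`, `rx`, `se`,
#'   `ci_low`, `ci_high`, `n_autosomes`, `call`, `sufficient_coverage`,
#'   `p_value`.  Failures are in attribute `"failures"` (sample, reason);
#'   the full `rx_result` objects are in attribute `"details"`.
#' @export
run_sex_id <- function(inputs, kt, config = classifier_config(),
                       alpha = 0.001, aliases = NULL, out = NULL) {
  if (is.character(kt)) kt <- read_karyotype(kt)
  stopifnot(inherits(kt, "karyotype"))
  if (length(inputs) == 1L && dir.exists(inputs)) {
    inputs <- list.files(inputs, pattern = "\\.(idxstats|txt|tsv)$",
                         full.names = TRUE)
    inputs <- sort(inputs)
  }
  if (length(inputs) == 0L)
    stop("no input samples", call. = FALSE)

  rows <- list(); details <- list(); failures <- list()
  for (path in inputs) {
    sid <- sub("\\.[^.]*$", "", basename(path))
    res <- tryCatch({
      tab <- read_idxstats(path)
      joined <- join_counts(tab, kt, aliases = aliases)
      cov <- coverage_regression(joined, alpha = alpha)
      rx <- compute_rx(joined, config = config)
      list(rx = rx, cov = cov)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        data.frame(sample_id = sid, reason = conditionMessage(res),
                   stringsAsFactors = FALSE)
      message("sample '", sid, "' failed: ", conditionMessage(res))
      next
    }
    rx <- res$rx; cov <- res$cov
    details[[rx$sample_id]] <- res
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = rx$sample_id, rx = rx$rx, se = rx$se,
      ci_low = rx$ci_low, ci_high = rx$ci_high,
      n_autosomes = rx$n_autosomes, call = rx$call_label,
      sufficient_coverage = cov$sufficient, p_value = cov$p_value,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("all samples failed; first failure: ", failures[[1L]]$reason,
         call. = FALSE)
  res_df <- do.call(rbind, rows)
  rownames(res_df) <- NULL
  attr(res_df, "failures") <- if (length(failures) > 0L)
    do.call(rbind, failures) else NULL
  attr(res_df, "details") <- details
  attr(res_df, "system") <- karyo_system(kt)
  class(res_df) <- c("rx_results", "data.frame")
  if (!is.null(out)) write_rx_results(res_df, out)
  res_df
}

#' Write an Rx result table as TSV
#'
#' @param results an `rx_results` data frame from [run_sex_id()], or any
#'   data frame with the same columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rx_results <- function(results, path) {
  df <- as.data.frame(results)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) formatC(v, digits = 15,
                                                 format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Dot plot of Rx values with confidence intervals
#'
#' One point per sample with its CI as a vertical bar, plus horizontal
#' reference lines at the two decision thresholds.  Points are colored by
#' call (blue male, red female) or, when `known` is supplied, samples of
#' unknown status are shown gray; unassigned calls are drawn as open
#' triangles.  Layout is deterministic: samples appear in table order.
#'
#' @param results an `rx_results` data frame (or compatible data frame
#'   with columns `sample_id`, `rx`, `ci_low`, `ci_high`, `call`).
#' @param file optional output path; `.pdf` or `.png` decides the device.
#'   `NULL` draws on the current device.
#' @param config a [classifier_config()]; its thresholds position the
#'   reference lines.
#' @param known optional logical vector (recycled): is the sample of
#'   independently known sex?  Unknown samples are plotted gray.
#' @param main plot title.
#' @return `file` (or `NULL`), invisibly.
#' @export
plot_rx <- function(results, file = NULL, config = classifier_config(),
                    known = TRUE, main = "Rx ratio sex assignment") {
  df <- as.data.frame(results)
  if (nrow(df) < 1L) stop("no results to plot", call. = FALSE)
  known <- rep_len(known, nrow(df))
  col <- ifelse(!known, "gray50",
         ifelse(df$call == "male", "blue",
         ifelse(df$call == "female", "red", "black")))
  pch <- ifelse(df$call == "unassigned", 2L, 19L)
  if (!is.null(file)) {
    ext <- tolower(tools::file_ext(file))
    switch(ext,
           pdf = grDevices::pdf(file, width = max(6, 0.4 * nrow(df)),
                                height = 5),
           png = grDevices::png(file, width = max(600, 40 * nrow(df)),
                                height = 500),
           stop("unsupported figure format: ", ext, call. = FALSE))
    on.exit(grDevices::dev.off())
  }
  xi <- seq_len(nrow(df))
  ylim <- range(c(df$ci_low, df$ci_high,
                  config$lower_threshold, config$upper_threshold))
  ylim <- ylim + c(-0.05, 0.05) * diff(ylim)
  graphics::plot(xi, df$rx, ylim = ylim, xaxt = "n", xlab = "",
                 ylab = "Rx ratio (95% CI)", pch = pch, col = col,
                 main = main)
  graphics::segments(xi, df$ci_low, xi, df$ci_high, col = col)
  graphics::abline(h = c(config$lower_threshold, config$upper_threshold),
                   lty = 2, col = "gray30")
  graphics::axis(1, at = xi, labels = df$sample_id, las = 2,
                 cex.axis = 0.7)
  invisible(file)
}
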