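## Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(code)
}

## Deterministic per-replicate seed stream derived from one integer seed,
## kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 48271 + i * 16807) %% 2147483647)
}

#' Specification of a synthetic idxstats sample
#'
#' Describes one simulated individual: its karyotype, true chromosomal
#' sex, sequencing depth in mapped reads, and noise model.  The expected
#' read weight of chromosome c is `copy_number(c, sex) * length_c *
#' bias_c`, with copy number 2 for autosomes, 2 (homogametic) or 1
#' (heterogametic) for the shared sex chromosome, and 0 or 1 for the
#' sex-limited chromosome.
#'
#' @param karyotype a [karyotype].
#' @param true_sex `"homogametic"` (XX / ZZ) or `"heterogametic"`
#'   (XY / ZW).
#' @param total_reads positive integer, total mapped reads to distribute.
#' @param mode `"multinomial"` draws integer counts from a multinomial
#'   over the expected weights (the realistic generator); `"noise_free"`
#'   emits the exact expected counts, which may be non-integer, so the
#'   analytic fixtures Rx = 1.0 / 0.5 hold exactly.
#' @param bias optional named positive multipliers (mappability / GC
#'   effects); names must be karyotype chromosome names; default 1
#'   everywhere.
#' @param seed integer seed for the multinomial draw.
#' @param sample_id identifier for the simulated table.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(karyotype, true_sex = c("homogametic", "heterogametic"),
                     total_reads, mode = c("multinomial", "noise_free"),
                     bias = NULL, seed = NULL, sample_id = NULL) {
  stopifnot(inherits(karyotype, "karyotype"))
  true_sex <- match.arg(true_sex)
  mode <- match.arg(mode)
  if (!is.numeric(total_reads) || length(total_reads) != 1L ||
      total_reads < 1)
    stop("total_reads must be a positive integer", call. = FALSE)
  if (!is.null(bias)) {
    if (is.null(names(bias)) || !all(names(bias) %in% karyotype$name))
      stop("bias names must be karyotype chromosome names", call. = FALSE)
    if (any(bias <= 0))
      stop("bias factors must be positive", call. = FALSE)
  }
  if (is.null(sample_id))
    sample_id <- paste0("sim_", substr(true_sex, 1, 4), "_",
                        format(total_reads, scientific = FALSE))
  structure(list(karyotype = karyotype, true_sex = true_sex,
                 total_reads = total_reads, mode = mode, bias = bias,
                 seed = seed, sample_id = sample_id),
            class = "sim_spec")
}

copy_number <- function(role, true_sex) {
  ifelse(role == "autosome", 2,
  ifelse(role == "shared_sex", if (true_sex == "homogametic") 2 else 1,
  ifelse(role == "limited_sex", if (true_sex == "homogametic") 0 else 1,
         0)))
}

#' Simulate an idxstats table for a known-sex individual
#'
#' Distributes `total_reads` mapped reads over the karyotype's
#' chromosomes with expected weight copy number x length x bias.  In
#' `"multinomial"` mode counts are a single multinomial draw under the
#' spec's seed (reproducible bit for bit); in `"noise_free"` mode counts
#' equal their expectations exactly.
#'
#' @param spec a [sim_spec()].
#' @return An `idxstats` object covering every karyotype chromosome
#'   (excluded chromosomes receive zero reads).
#' @export
#' @examples
#' kt <- elephant_karyotype()
#' simulate_idxstats(sim_spec(kt, "homogametic", 1e5, seed = 7))
simulate_idxstats <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  kt <- spec$karyotype
  w <- copy_number(kt$role, spec$true_sex) * kt$length
  if (!is.null(spec$bias)) {
    idx <- match(names(spec$bias), kt$name)
    w[idx] <- w[idx] * spec$bias
  }
  if (all(w == 0))
    stop("all chromosome weights are zero", call. = FALSE)
  p <- w / sum(w)
  mapped <- if (spec$mode == "noise_free") {
    spec$total_reads * p
  } else {
    with_seed(spec$seed,
              as.numeric(stats::rmultinom(1L, size = spec$total_reads,
                                          prob = p)))
  }
  idxstats_table(kt$name, kt$length, mapped, unmapped = 0,
                 sample_id = spec$sample_id)
}

#' Subsample an idxstats table to an exact read total
#'
#' Draws `target_reads` reads without replacement from the table's mapped
#' reads (a multivariate hypergeometric draw across chromosomes), so the
#' output's total mapped count equals `target_reads` exactly.  This
#' differs from read-level Bernoulli thinning, whose realized total is
#' only approximate; exact totals make depth design points directly
#' testable.  Reproducible under `seed`.
#'
#' @param table an `idxstats` object with integer mapped counts.
#' @param target_reads positive integer, at most the table's total mapped
#'   count.
#' @param seed integer seed.
#' @return An `idxstats` object with the same rows and subsampled counts.
#' @export
subsample_idxstats <- function(table, target_reads, seed = NULL) {
  stopifnot(inherits(table, "idxstats"))
  m <- table$mapped
  if (any(m != trunc(m)))
    stop("subsampling requires integer mapped counts", call. = FALSE)
  total <- sum(m)
  if (!is.numeric(target_reads) || length(target_reads) != 1L ||
      target_reads < 1 || target_reads != trunc(target_reads))
    stop("target_reads must be a positive integer", call. = FALSE)
  if (target_reads > total)
    stop("target_reads (", target_reads, ") exceeds total mapped reads (",
         total, ")", call. = FALSE)
  if (target_reads == total) {
    out <- table
    attr(out, "sample_id") <- sample_id_of(table)
    return(out)
  }
  out_counts <- with_seed(seed, {
    k <- length(m)
    res <- numeric(k)
    remaining <- target_reads
    left <- sum(m)
    for (i in seq_len(k)) {       # sequential conditional hypergeometric
      left <- left - m[i]
      res[i] <- if (remaining == 0) 0
                else stats::rhyper(1L, m[i], left, remaining)
      remaining <- remaining - res[i]
    }
    res
  })
  idxstats_table(table$name, table$length, out_counts,
                 unmapped = table$unmapped,
                 sample_id = paste0(sample_id_of(table), "_sub",
                                    format(target_reads, scientific = FALSE)))
}

#' Depth sweep: classification behaviour versus sequencing depth
#'
#' For each target depth and replicate, obtains a count table (by
#' multinomial simulation when `x` is a [sim_spec()], or by hypergeometric
#' subsampling when `x` is an `idxstats` table), runs [compute_rx()] and
#' records the Rx value, CI and call.  Probes how far depth can fall
#' before confidence intervals broaden past the decision thresholds.
#'
#' @param x a `sim_spec` or an `idxstats` table.
#' @param depths vector of positive integer read totals.
#' @param replicates positive integer replicates per depth.
#' @param seed integer master seed; each depth x replicate uses a
#'   deterministically derived seed.
#' @param kt karyotype; required when `x` is an `idxstats` table, taken
#'   from the spec otherwise.
#' @param config a [classifier_config()].
#' @return A data frame of class `sweep_result` with one row per depth x
#'   replicate: `sample_id`, `target_depth`, `replicate`, `rx`, `ci_low`,
#'   `ci_high`, `call`, `call_label`, `ci_width`.  The attribute
#'   `"summary"` holds mean CI width and unassignment rate per depth.
#' @export
#' @examples
#' kt <- elephant_karyotype()
#' sw <- depth_sweep(sim_spec(kt, "heterogametic", 1e5),
#'                   depths = c(1e4, 1e3), replicates = 5, seed = 1)
#' attr(sw, "summary")
depth_sweep <- function(x, depths, replicates, seed = 1L, kt = NULL,
                        config = classifier_config()) {
  if (!is.numeric(replicates) || length(replicates) != 1L || replicates < 1)
    stop("replicates must be a positive integer", call. = FALSE)
  if (length(depths) < 1L || any(depths < 1))
    stop("depths must be positive integers", call. = FALSE)
  from_spec <- inherits(x, "sim_spec")
  if (from_spec) {
    kt <- x$karyotype
  } else if (inherits(x, "idxstats")) {
    if (is.null(kt))
      stop("kt (karyotype) is required when sweeping an idxstats table",
           call. = FALSE)
    if (any(depths > sum(x$mapped)))
      stop("depth exceeds available reads in table", call. = FALSE)
  } else {
    stop("x must be a sim_spec or an idxstats table", call. = FALSE)
  }
  rows <- vector("list", length(depths) * replicates)
  k <- 0L
  for (di in seq_along(depths)) {
    for (rep_i in seq_len(replicates)) {
      k <- k + 1L
      sub_seed <- derive_seed(seed, k)
      tab <- if (from_spec) {
        sp <- x
        sp$total_reads <- depths[di]
        sp$seed <- sub_seed
        simulate_idxstats(sp)
      } else {
        subsample_idxstats(x, depths[di], seed = sub_seed)
      }
      res <- compute_rx(join_counts(tab, kt), config = config)
      rows[[k]] <- data.frame(
        sample_id = res$sample_id, target_depth = depths[di],
        replicate = rep_i, rx = res$rx, ci_low = res$ci_low,
        ci_high = res$ci_high, call = res$call,
        call_label = res$call_label,
        ci_width = res$ci_high - res$ci_low,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(out, out$target_depth), function(d) {
    data.frame(target_depth = d$target_depth[1L],
               mean_ci_width = mean(d$ci_width),
               unassigned_rate = mean(d$call == "unassigned"))
  }))
  summ <- summ[order(-summ$target_depth), , drop = FALSE]
  rownames(summ) <- NULL
  attr(out, "summary") <- summ
  class(out) <- c("sweep_result", "data.frame")
  out
}
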