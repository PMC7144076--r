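test_that("autosome_ratios computes length-normalized depth ratios", {
  # hand arithmetic: (30/50) / (100/100) = 0.6 for each autosome
  kt <- toy_karyotype(3, auto_len = c(100, 100, 100), x_len = 50)
  r <- autosome_ratios(toy_counts(kt, c(100, 100, 100, 30)))
  expect_equal(unname(r), c(0.6, 0.6, 0.6), tolerance = 1e-9,
               ignore_attr = TRUE)

  # counts proportional to length with equal copy number -> all ratios 1
  kt2 <- toy_karyotype(4, auto_len = c(120, 90, 60, 30), x_len = 50)
  r2 <- autosome_ratios(toy_counts(kt2, c(12, 9, 6, 3, 5)))
  expect_equal(unname(r2), rep(1, 4), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("autosome_ratios handles zero counts per contract", {
  kt <- toy_karyotype(3)
  expect_error(autosome_ratios(toy_counts(kt, c(10, 10, 10, 0))),
               "no reads on shared sex chromosome")
  # zero-count autosome dropped with a warning, n shrinks
  expect_warning(r <- autosome_ratios(toy_counts(kt, c(10, 10, 0, 5))),
                 "chr3")
  expect_length(r, 2L)
  expect_identical(attr(r, "dropped"), "chr3")
  # < 2 usable autosomes is an error
  suppressWarnings(
    expect_error(autosome_ratios(toy_counts(kt, c(10, 0, 0, 5))),
                 "fewer than 2"))
})

test_that("compute_rx reproduces the analytic diploid fixtures", {
  kt <- elephant_karyotype()
  # female: every chromosome at copy number 2 -> rx 1.0, se 0
  f <- compute_rx(toy_counts(kt, 2 * kt$length / 1000))
  expect_equal(f$rx, 1.0, tolerance = 1e-9)
  expect_equal(f$se, 0, tolerance = 1e-9)
  expect_identical(f$call_label, "female")
  expect_equal(f$n_autosomes, 27L)
  # male: autosomes at 2x, X at 1x -> rx 0.5 exactly
  m_counts <- ifelse(kt$role == "shared_sex", kt$length, 2 * kt$length) / 1000
  m <- compute_rx(toy_counts(kt, m_counts))
  expect_equal(m$rx, 0.5, tolerance = 1e-9)
  expect_identical(m$call_label, "male")
})

test_that("CI construction follows rx +/- z * se", {
  kt <- elephant_karyotype()
  tab <- simulate_idxstats(sim_spec(kt, "homogametic", 1e5, seed = 11))
  res <- compute_rx(join_counts(tab, kt))
  expect_gt(res$se, 0)
  expect_equal((res$ci_high - res$rx) / res$se, 1.96, tolerance = 1e-9)
  expect_equal((res$rx - res$ci_low) / res$se, 1.96, tolerance = 1e-9)
  # se is the sample sd of the ratios over sqrt(n)
  expect_equal(res$se, sd(res$ratios) / sqrt(res$n_autosomes))
  expect_true(res$ci_low <= res$rx && res$rx <= res$ci_high)
})

test_that("classify applies strict thresholds and system labels", {
  cases <- list(
    list(0.48, 0.52, "XY", "male"),
    list(0.85, 0.95, "XY", "female"),
    list(0.59, 0.61, "XY", "unassigned"),   # straddles 0.60
    list(0.61, 0.79, "XY", "unassigned"),   # inside the gap
    list(0.40, 0.60, "XY", "unassigned"),   # boundary equality: not male
    list(0.80, 1.05, "XY", "unassigned"),   # boundary equality: not female
    list(0.48, 0.52, "ZW", "female"),       # ZW mirror of a one-Z female
    list(0.85, 0.95, "ZW", "male"))
  for (cs in cases) {
    got <- classify(cs[[1]], cs[[2]], system = cs[[3]])
    expect_identical(got$label, cs[[4]],
                     info = sprintf("CI [%g, %g] %s", cs[[1]], cs[[2]],
                                    cs[[3]]))
  }
  expect_error(classify(0.7, 0.6, "XY"), "ci_low <= ci_high")
})

test_that("classify is monotone in the CI bounds", {
  rank_of <- c(heterogametic = -1, unassigned = 0, homogametic = 1)
  lows <- seq(0.30, 1.00, by = 0.05)
  # raising ci_low (fixed ci_high) never moves the call away from homogametic
  for (hi in c(1.0, 1.1)) {
    calls <- vapply(lows[lows <= hi],
                    function(lo) classify(lo, hi, "XY")$call, "")
    expect_true(all(diff(rank_of[calls]) >= 0))
  }
  # lowering ci_high (fixed ci_low) never moves away from heterogametic
  his <- seq(1.0, 0.40, by = -0.05)
  for (lo in c(0.35, 0.4)) {
    calls <- vapply(his[his >= lo],
                    function(hi) classify(lo, hi, "XY")$call, "")
    expect_true(all(rank_of[calls] == cummin(rank_of[calls])))
  }
})

test_that("classifier_config validates its parameters", {
  expect_error(classifier_config(z = -1), "positive")
  expect_error(classifier_config(lower_threshold = 0.9,
                                 upper_threshold = 0.8), "lower_threshold")
  cfg <- classifier_config(z = 2.58, lower_threshold = 0.55,
                           upper_threshold = 0.85)
  expect_identical(classify(0.50, 0.54, "XY", cfg)$label, "male")
  expect_identical(classify(0.50, 0.56, "XY", cfg)$label, "unassigned")
})

test_that("rx is invariant to rescaling all mapped counts", {
  set.seed(42)
  kt <- random_karyotype()
  tab <- simulate_idxstats(sim_spec(kt, "heterogametic", 2e5, seed = 8))
  base <- compute_rx(join_counts(tab, kt))
  for (k in c(0.5, 3, 1000)) {
    tab2 <- idxstats_table(tab$name, tab$length, tab$mapped * k,
                           sample_id = "scaled")
    scaled <- compute_rx(join_counts(tab2, kt))
    expect_equal(scaled$ratios, base$ratios, tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(scaled$rx, base$rx, tolerance = 1e-12)
    expect_equal(scaled$se, base$se, tolerance = 1e-12)
    expect_identical(scaled$call, base$call)
  }
})

test_that("totals cancel: rate formulation equals the direct ratio", {
  # independent oracle: normalize counts and lengths by arbitrary totals
  # (with or without Y/excluded contributions) before taking the ratio
  oracle_ratios <- function(joined, M, L) {
    x <- joined[joined$role == "shared_sex", ]
    auto <- joined[joined$role == "autosome" & joined$mapped > 0, ]
    ((x$mapped / M) / (x$length / L)) /
      ((auto$mapped / M) / (auto$length / L))
  }
  set.seed(7)
  for (i in 1:20) {
    kt <- random_karyotype()
    sx <- sample(c("homogametic", "heterogametic"), 1)
    tab <- simulate_idxstats(sim_spec(kt, sx, 5e4,
                                      seed = sample.int(2^31 - 1, 1)))
    joined <- suppressWarnings(join_counts(tab, kt))
    direct <- suppressWarnings(autosome_ratios(joined))
    for (totals in list(c(sum(tab$mapped), sum(kt$length)),
                        c(sum(tab$mapped) + 12345, 3.2e9),
                        c(1, 1))) {
      expect_equal(unname(direct),
                   oracle_ratios(joined, totals[1], totals[2]),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("coverage_regression detects presence/absence of length signal", {
  kt <- elephant_karyotype()
  # counts exactly proportional to length: perfect fit, sufficient
  cov <- coverage_regression(toy_counts(kt, kt$length / 10))
  expect_true(cov$sufficient)
  expect_lt(cov$p_value, 1e-10)
  expect_equal(cov$n_autosomes, 27L)
  # constant counts: no length signal, not sufficient
  cov0 <- coverage_regression(toy_counts(kt, rep(1000, nrow(kt))))
  expect_false(cov0$sufficient)
  expect_equal(cov0$slope, 0, tolerance = 1e-9)
  # too few autosomes for the F test
  kt3 <- toy_karyotype(3)
  joined <- toy_counts(kt3, c(10, 10, 10, 5))
  joined2 <- joined[joined$name != "chr3", ]
  class(joined2) <- class(joined)
  attr(joined2, "system") <- "XY"
  expect_error(coverage_regression(joined2), "insufficient chromosomes")
})
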