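# Small karyotypes and count tables built in code; no stored fixtures.

toy_karyotype <- function(n_auto = 3, auto_len = NULL, x_len = 50,
                          system = "XY", with_y = FALSE, y_len = 20) {
  if (is.null(auto_len)) auto_len <- rep(100, n_auto)
  nm <- c(paste0("chr", seq_len(n_auto)), "chrX",
          if (with_y) "chrY")
  karyotype(
    name   = nm,
    length = c(auto_len, x_len, if (with_y) y_len),
    role   = c(rep("autosome", n_auto), "shared_sex",
               if (with_y) "limited_sex"),
    system = system)
}

# joined rx_counts built directly (bypasses file I/O)
toy_counts <- function(kt, mapped) {
  tab <- idxstats_table(kt$name, kt$length, mapped, sample_id = "toy")
  suppressMessages(join_counts(tab, kt))
}

# random karyotype for property tests: 5-30 autosomes, random lengths
random_karyotype <- function() {
  n_auto <- sample(5:30, 1)
  karyotype(
    name   = c(paste0("chr", seq_len(n_auto)), "chrX", "chrY", "chrM"),
    length = c(round(runif(n_auto, 2e7, 2.5e8)), round(runif(1, 5e7, 1.5e8)),
               round(runif(1, 1e7, 6e7)), 16000),
    role   = c(rep("autosome", n_auto), "shared_sex", "limited_sex",
               "excluded"),
    system = "XY")
}

write_tmp_idxstats <- function(lines, ext = ".idxstats") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
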