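Package: rxsex
Title: Chromosomal Sex Assignment from Low-Coverage Alignment Counts
Version: 1.0.0
Authors@R: person("rxsex", "maintainers", email = "rxsex@example.org",
    role = c("aut", "cre"))
Description: Identifies the chromosomal sex of individuals from shotgun
    sequencing data using only per-chromosome alignment counts (the
    'samtools idxstats' summary of a BAM file).  The X (or Z) to autosome
    normalized depth ratio and its 95% confidence interval classify a
    sample as male, female, or unassigned under either XY or ZW sex
    determination.  Includes a coverage-sufficiency regression, a
    multinomial read-count simulator and an exact hypergeometric count
    subsampler for validating calls at very low sequencing depth, plus a
    command-line interface and a dot-plot visualization of calls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
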