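---
title: "Sex identification from chromosome-level alignment counts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex identification from chromosome-level alignment counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxsex)
```

## The model

A shotgun library sequenced from a diploid individual spreads its reads
across chromosomes roughly in proportion to chromosome length times copy
number.  Autosomes are present in two copies in everyone; the shared sex
chromosome (X under XY determination, Z under ZW) is present in two
copies in the homogametic sex and one in the heterogametic sex.  The
per-autosome depth ratio

$$ r_i = \frac{m_X / L_X}{m_i / L_i} $$

therefore has expectation near 1 or 0.5 depending on X copy number, and
the Rx statistic is the mean of the $r_i$ over the $n$ autosomes, with

$$ \mathrm{SE} = \frac{\mathrm{sd}(r_i)}{\sqrt{n}},\qquad
   \mathrm{CI}_{95} = Rx \pm 1.96\,\mathrm{SE}. $$

The empirical spread of the $r_i$ absorbs, without modelling them
explicitly, the chromosome-specific deviations real data show
(mappability, repeat content, GC bias): any effect that perturbs
individual autosomes widens the interval rather than silently shifting
the call.  Effects that hit the X *specifically* (X-linked repeat
families, male-biased DNA degradation) are not captured — which is one
reason observed values sit near, not at, the ideals; published
elephant results, for instance, place females around 0.87–0.94 rather
than exactly 1.

### Assumptions

* Reads are assigned to chromosomes essentially uniquely (quality
  filtering upstream has removed multi-mappers).
* The reference is chromosome-level: X depth and autosome depth must be
  attributable to the right sequences.
* Counts are large enough that per-chromosome depth is informative; the
  coverage regression below tests exactly this.

## The classifier

The call is made from the CI, not the point estimate: heterogametic when
the CI upper bound is strictly below the lower threshold (default 0.60),
homogametic when the lower bound is strictly above the upper threshold
(default 0.80), otherwise **unassigned**.  Boundary equality is
unassigned — the thresholds are phrased as strict inequalities, and the
conservative direction is to refuse a call.  Under ZW the same geometry
applies with labels mirrored (ZZ male is homogametic, ZW female
heterogametic); the thresholds are the same configurable pair.

```{r}
classify(0.48, 0.52, "XY")$label
classify(0.48, 0.52, "ZW")$label
classify(0.59, 0.61, "XY")$label
```

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `z` | 1.96 | CI multiplier; 1.96 gives a 95% normal interval |
| `lower_threshold` | 0.60 | heterogametic cut-off on the CI upper bound |
| `upper_threshold` | 0.80 | homogametic cut-off on the CI lower bound |
| `alpha` | 0.001 | significance level of the coverage F-test |

The 0.60/0.80 pair deliberately leaves a gap: values between the two
diploid expectations of 0.5 and 1.0 should not be forced into a sex.
Widening the gap trades assignment rate for safety.

## The coverage check

Ordinary least squares of per-autosome mapped counts against autosome
length.  When coverage is adequate, counts scale with length and the
regression F-test is significant at `alpha`; a flat fit flags a sample
whose counts carry no depth signal.  Only autosomes enter the fit —
including the X would mix the copy-number signal being estimated into
the adequacy check.  The fit uses `stats::lm`, with the two degenerate
cases (exactly constant counts → p = 1; numerically perfect fit → p = 0)
resolved explicitly rather than left to floating-point noise in the
F statistic.

## The synthetic-data generator

`simulate_idxstats()` draws a sample's counts from a single multinomial
over expected weights *copy number × length × bias*.  This emulates the
leading-order behaviour of a real library: reads land on chromosomes in
proportion to how much template each contributes.  It does **not**
emulate mappability structure along chromosomes, GC amplification
curves, ancient-DNA fragment-length or damage patterns, or duplicate
structure — so a green simulation test establishes that the estimator
and classifier are correct *under the stated sampling model*, not that
any particular wet-lab pipeline is unbiased.  Optional per-chromosome
`bias` multipliers let one probe mappability-like distortions.

`mode = "noise_free"` emits the exact expected counts (non-integer
values permitted) so the two analytic fixtures hold to machine
precision: homogametic Rx = 1.0 with SE = 0, heterogametic Rx = 0.5.

```{r}
kt <- elephant_karyotype()
hom <- simulate_idxstats(sim_spec(kt, "homogametic", 1e5, mode = "noise_free"))
compute_rx(join_counts(hom, kt))$rx
```

The bundled `elephant_karyotype()` is a *synthetic* stand-in for a
savanna-elephant-like genome: 27 autosomes with lengths decaying
smoothly from 228 Mb to 45 Mb, a 126 Mb X, a female-derived assembly
(no Y), and an excluded mitochondrion.  Only relative lengths enter the
statistic, so results generalize to any karyotype of that shape.

## Subsampling semantics

`subsample_idxstats()` draws the target number of reads **without
replacement from the count vector** (a multivariate hypergeometric
draw), so the output total equals the target exactly.  BAM-level tools
typically thin per read with a fixed probability, realizing only an
approximate total; the count-level draw is distributionally the correct
conditional of that process given the realized total, and exact totals
make depth design points (e.g. "10 000 reads") directly testable.  All
stochastic operations are bitwise reproducible under their seed, and
`depth_sweep()` derives one deterministic seed per depth × replicate
from its master seed.

## Numerical choices

* SE uses the sample (n−1) standard deviation — the standard unbiased
  choice when nothing more specific is stated.
* The ratio is computed in the direct form $(m_X/L_X)/(m_i/L_i)$;
  formulations that first normalize counts by the library total and
  lengths by the genome total are algebraically identical because both
  totals cancel, and the test suite enforces this equivalence against an
  independently coded oracle on random karyotypes.
* Zero-count autosomes are dropped with a warning and $n$ shrinks
  (ultra-low-coverage samples can leave small chromosomes empty); a
  zero-count X is a hard error, as the statistic is undefined.
* Analytic tests use a relative tolerance of 1e−9; equality at the
  decision thresholds maps to unassigned.
* Chromosomes are matched by exact name (with an optional alias map),
  never by row position: row-order conventions differ between references
  and silently misassigning the X would invert calls.

## Behaviour at extreme low depth

```{r}
sw <- depth_sweep(sim_spec(kt, "heterogametic", 1e5),
                  depths = c(1e5, 1e4, 1e3), replicates = 10, seed = 11)
attr(sw, "summary")
```

The CI width grows approximately as depth$^{-1/2}$ (the test suite
checks the log–log slope is −0.5 ± 0.1 over a 100× range).  Around
10³ reads the interval starts crossing the thresholds and the
unassignment rate becomes substantial: the thresholds double as a
built-in confidence guard, refusing calls the data cannot support.

## Known limitations

* Per-chromosome bias beyond a scalar multiplier (positional
  mappability, GC curves, aDNA damage) is outside the generator's world;
  validate against samples of known sex when moving to a new taxon or
  pipeline.
* The method assumes the X/Z is correctly identified in the reference;
  a mislabelled sex chromosome produces confident wrong calls, which is
  why `karyotype_from_fai()` requires the shared sex chromosome by name.
* Sex-limited (Y/W) information is deliberately unused; taxa with
  degenerate or absent X homology in the assembly are out of scope.
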