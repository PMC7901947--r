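# adopanel

Allelic-dropout (ADO) risk screening and detection for PCR-based targeted
sequencing panels.

## The problem

Amplicon panels genotype by PCR-amplifying short inserts between designed
primer pairs. When an individual carries a single-nucleotide variant inside
a primer *binding site*, the mismatched haplotype can anneal poorly and
amplify weakly or not at all — **allelic dropout**. A true heterozygote
then appears homozygous (the wild-type allele vanishes: apparent
hemizygosity / pseudo-homozygosity), or a heterozygous "marker" variant
inside the insert is lost or underrepresented in the reads. Both NGS
amplicon panels and Sanger re-sequencing are PCR-based, so both are
susceptible, and a dropout on either platform silently converts real
findings into false negatives in diagnostic screening.

`adopanel` is for people who run or audit such panels: it screens a panel
design against a population variant catalogue for primer-site variants,
detects dropout signatures in per-sample allele observations, attributes
each event to candidate causal variants, and quantifies panel-wide risk.
A phased-haplotype simulator generates fully reproducible synthetic
panels and cohorts for validation.

## The model

**Screening.** Every incidence of a catalogued variant (allele frequency
*p*) inside a primer binding site becomes a risk finding with:

- a positional tier — `three_prime_critical` when the mismatch lies within
  7 nt of the primer 3′ terminus (the classical high-risk window),
  `five_prime` in the 5 bases nearest the 5′ end (also observed to cause
  dropout), `internal` otherwise;
- a frequency tier (`common` when the minor allele frequency ≥ 0.01);
- the Hardy–Weinberg heterozygous-carrier probability `2p(1 − p)` — the
  probability that a random individual has exactly one mismatched
  haplotype and is therefore at risk.

Per amplicon the dropout risk is `1 − Π(1 − 2pᵢ(1 − pᵢ))` over its
primer-site variants (independence assumed), and the panel summary
reports the flagged-amplicon percentage and the expected per-individual
burden.

**Detection.** Four evidence channels are combined, deduplicated by
strongest evidence, and annotated with causal candidates:

1. *allele balance* — two-sided exact binomial test of alt reads against
   the heterozygous 0.5 expectation, flagged on the low side only
   (`p < α = 0.001` and VAF < 0.25 at ≥ 20 reads);
2. *overlap discordance* — a variant in the shared insert of two tiled
   amplicons present on one but trace/absent on the other;
3. *platform discordance* — het on one platform or run vs `hom_alt`
   (pseudo-homozygous) or `hom_ref` (missing marker) on another;
4. *trio conflict* — a child apparently `hom_alt` while a parent is
   `hom_ref`, contradicting the obligate wild-type transmission.

**Simulation.** A haplotype mismatched under a primer amplifies with
efficiency `1 − ε` (tier-scaled; per-run escalation to complete dropout),
so the expected mismatched-allele read fraction is
`(1 − ε) / (2 − ε)`. Depths follow a calibrated mixture of a
failed-amplicon component (uniform 0–19 reads) and a negative binomial.

## Worked example

```r
library(adopanel)

# a 521-amplicon panel with four planted primer-site risk variants
p1 <- make_panel("PANEL1", seed = 1)
findings <- screen_panel(p1$manifest, p1$variants, min_af = 0)
s <- summarize_panel(p1$manifest, findings)
s$n_flagged;  s$percent_flagged
#> [1] 4
#> [1] 0.77

# six planted dropout cases plus 20 clean heterozygous controls
fx <- make_fixture("TABLE1", seed = 1)
events <- run_detection(fx$observations, NULL, fx$orthogonal_calls,
                        fx$trios, fx$manifest,
                        screen_panel(fx$manifest, fx$variants))
events[, c("sample_id", "event_type", "evidence", "vaf", "platform")]
#> # A tibble: 6 x 5
#>   sample_id  event_type        evidence              vaf platform
#>   <chr>      <chr>             <chr>               <dbl> <chr>
#> 1 CASE_DSP   missing_marker    platform_discordance NA   sanger
#> 2 CASE_LDB3A underrepresented  allele_balance       0.03 ngs
#> 3 CASE_LDB3B underrepresented  allele_balance       0.11 ngs
#> 4 CASE_PKP2  pseudo_homozygous platform_discordance NA   sanger
#> 5 CASE_SCN1B missing_marker    overlap_discordance  0    ngs
#> 6 CASE_SCN5A pseudo_homozygous trio_conflict        NA   sanger
```

Reading the output: the two `underrepresented` events are heterozygous
markers drowned to 3% and 11% of reads by partial dropout of their
haplotype; the `missing_marker` events are markers that vanished entirely
from one amplicon or one sequencing run; the `pseudo_homozygous` events
are heterozygotes whose wild-type allele failed to amplify, one of them
proven by a trio conflict (the mother is homozygous reference, so the
child's wild-type allele must exist). Each event carries ranked causal
primer-site candidates (`causal_pos`, `causal_af`, `causal_tier`) and a
`needs_confirmation` flag — re-sequencing with an independent,
non-overlapping primer pair is the confirmation standard.

A file-based workflow (`cli_simulate()`, `cli_screen()`, `cli_detect()`,
`cli_report()`, or the `inst/exec/adopanel` script) mirrors the same
stages with atomic outputs and a provenance JSON.

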