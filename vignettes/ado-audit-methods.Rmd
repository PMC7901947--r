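---
title: "Auditing allelic dropout in amplicon panels: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing allelic dropout in amplicon panels: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adopanel)
```

## The phenomenon and the package's model of it

PCR-based genotyping amplifies a target insert between two oligoprimers.
A single-nucleotide variant inside a primer *binding site* leaves one
haplotype mismatched under the primer; that haplotype anneals less
efficiently and can amplify weakly or not at all. This is allelic dropout
(ADO). Its two observable faces at a heterozygous site are:

* **pseudo-homozygosity** — the wild-type allele drops, and the carrier
  of a heterozygous variant is reported homozygous (or "hemizygous");
* **marker loss / underrepresentation** — the variant-bearing haplotype
  drops, so a real heterozygous variant vanishes from the reads or
  survives only as a small minority fraction.

Which face appears is a question of *phase*: a causal primer-site variant
in **cis** with an insert marker removes the marker; in **trans** it
removes the wild-type allele and the marker appears homozygous. The
package models amplification efficiency per (amplicon, haplotype, run): a
haplotype carrying a primer-site variant has efficiency $1-\varepsilon$
against 1 for the matched haplotype, giving an expected mismatched-allele
read fraction

$$f(\varepsilon) = \frac{1-\varepsilon}{2-\varepsilon},$$

which is 0.5 with no dropout and 0 at complete dropout. Efficiency loss
is applied once per run, not per read: run-to-run inconsistency (the same
sample positive in one run, negative in the next) is a documented feature
of dropout, so the model draws a per-run escalation to complete dropout
with probability `complete_prob` instead of averaging within a run.

## Screening: who is at risk, and how much

Screening intersects primer binding sites with a population catalogue
(VCF with an `AF` INFO key). Variants are matched by reference-span
overlap, so a deletion touching even one site base counts. Each incidence
is tiered two ways:

* **Position.** Distance is measured in bases from the primer
  3′-terminal base (0 = terminal). The forward primer's 3′ terminus is
  the last base of its site; the reverse primer anneals to the opposite
  strand, so its 3′ terminus is the *first* genomic base of its site.
  Mismatches at distance ≤ 6 (i.e. within 7 nt of the 3′ end) are
  `three_prime_critical` — the window classically reported to abolish
  extension; the 5 bases nearest the 5′ end are `five_prime`, a position
  also observed to cause dropout; everything else is `internal`. In
  sites short enough for the windows to overlap, the 3′ rule wins, since
  3′ mismatches act through polymerase extension and dominate.
* **Frequency.** `common` when the *minor* allele frequency is ≥ 0.01.
  Using the minor frequency (rather than the alt frequency) makes the
  tier symmetric: a site where the catalogue's alternate allele is at
  0.999 is really a rare *reference* mismatch, and is tiered `rare`.

The default frequency floor is `min_af = 0`: causal variants as rare as
allele frequency 6×10⁻⁴ are on record, so any floor loses real causes;
the frequency tier carries the common/rare distinction instead. A
non-zero floor additionally keeps any variant with `af ≥ 1 − min_af`, so
reference-rare sites never fall out.

Per carrier-risk arithmetic, a heterozygote is the at-risk genotype, with
Hardy–Weinberg probability $2p(1-p)$. Per amplicon the package reports
$1 - \prod_i (1 - 2p_i(1-p_i))$ over that amplicon's primer-site
variants. Independence between sites is assumed — linkage disequilibrium
is not modelled, because no haplotype information enters the screen; for
nearby sites in strong LD the compound risk is overstated. Flagged
percentages are rounded half away from zero to two decimals (4 of 521 is
printed 0.77).

## Detection: four evidence channels and one merge rule

1. **Allele balance** (NGS, per observation): a two-sided exact binomial
   test of alt reads against 0.5, flagged only when `p < alpha` *and*
   VAF < `vaf_max`. Flagging is one-sided low deliberately: dropout
   *hides* an allele; a high VAF at a het site is the trans signature and
   is caught as pseudo-homozygosity through calls, not balance.
   Observations with no alt reads at all are not tested — a zero could
   equally be a true homozygote, and only orthogonal evidence can tell.
2. **Overlap discordance**: tiled amplicons observe shared insert
   positions twice. Each side is classed `present`
   (VAF ≥ `presence_threshold`), `trace` (0 < VAF < threshold) or
   `absent` (0); any class disagreement between the two amplicons — with
   both at ≥ `min_depth` — is an event. The three-state rule is what
   lets a 5% trace on one amplicon against a clean zero on its partner
   fire (both sides are below the presence threshold, yet the pattern is
   exactly single-amplicon dropout), while concordant 50/50 or 0/0 pairs
   never do.
3. **Platform/run discordance**: genotype calls for the same (sample,
   variant) from different platforms *or runs of the same platform* are
   compared pairwise. Het vs `hom_alt` is `pseudo_homozygous`,
   attributed to the `hom_alt` side; het vs `hom_ref` is
   `missing_marker`, attributed to the `hom_ref` side. Hom-vs-hom
   discordance is not a dropout signature and is ignored; variants seen
   by a single source are coverage gaps, not events. Sanger
   presence/absence observations are converted to per-run calls
   internally, so run-to-run marker loss on one platform is caught by
   the same channel.
4. **Trio conflict**: a child called `hom_alt` while a genotyped parent
   is `hom_ref` contradicts the obligate wild-type transmission — the
   clinching observation for apparent hemizygosity. Only this direction
   is checked; general Mendelian QC is out of scope.

Events are deduplicated per (sample, marker variant) keeping the
strongest evidence, ordered `allele_balance < overlap_discordance <
platform_discordance < trio_conflict`. The ordering is a convention:
trio conflict is strongest because it is proof against an external
ground truth; balance is weakest because it is a single-channel
statistical signal. After deduplication, events sharing (sample,
amplicons, type, channel, platform) merge into one event carrying all
linked markers — one biological dropout commonly erases several
heterozygous markers travelling on the same haplotype, and counting it
once per marker would inflate event counts.

### Defaults and what they mean

| parameter | default | unit | why |
|---|---|---|---|
| `alpha` | 0.001 | — | balance-test significance; at panel depths (~192×) real events sit at 3–11% VAF where p-values are astronomically small, so a strict alpha costs no power while controlling multiplicity in cohort runs |
| `vaf_max` | 0.25 | fraction | separates dropout-grade imbalance from binomial noise around 0.5 |
| `presence_threshold` | 0.10 | fraction | an allele at ≥ 10% of reads is solidly "present" on an amplicon |
| `min_depth` | 20 | reads | per-amplicon coverage floor below which nothing is testable |
| `sanger_floor` | 0.15 | fraction | minor peaks below ~15–20% are invisible in a chromatogram; an allele under this expected fraction never appears in a simulated Sanger call |
| `fdr` | FALSE | — | per-case confirmation workflow by default; Benjamini–Hochberg across all balance tests available for cohort-scale runs |

No formal multiple-testing correction is applied by default because each
flagged event is expected to be individually confirmed (every event is
emitted with `needs_confirmation = TRUE`).

## The simulator: what it emulates, and what it does not

`make_panel()` / `make_fixture()` generate four named, seed-reproducible
presets emulating a multi-gene cardiomyopathy panel:

* `FULL` — 1,049 amplicons over 37 synthetic genes, exactly 153 kb of
  insert, two primer pools, tiling overlap on ~35% of adjacent pairs.
* `PANEL1` — 521 amplicons with primer-site SNVs planted on exactly four
  amplicons (allele frequencies 0.605, 0.044, 0.890 and 0.999, spread
  over 3′-critical, 5′ and internal positions), and none elsewhere; the
  planted sites sit on first/last amplicons of their genes so that
  tiling geometry cannot create accidental extra findings.
* `TABLE1` — six dropout case groups spanning the full phenotype space
  (trans/Sanger pseudo-homozygosity with and without trio proof,
  cis/Sanger run-to-run marker loss, two NGS underrepresentation cases
  at 3% and 11%, and an overlapping-amplicon case with a 5% trace on one
  amplicon and complete loss on its partner), plus 20 clean heterozygous
  controls.
* `COHORT232` — 232 samples over the same loci with *planted* carrier
  counts (1, 9, 1, 1, 1, 2); the rest of the cohort draws Hardy–Weinberg
  genotypes with clean observations. Carrier counts are planted, not
  drawn, because they represent observed confirmed cases, not population
  expectations; an HWE cohort is available through `sample_genotypes()`.

Two fixture-design decisions deserve a note. First, event-defining
observations are planted at counts that realize each case's
characteristic fraction (194 ref / 6 alt for the 3% case, and so on);
only controls and non-carriers are stochastic. The cases are what the fixture is defined to
contain, not a property to be rediscovered through binomial luck, and this keeps the fixture's event count invariant across
seeds. Second, in the efficiency model a variant cannot be inside both
an amplicon's insert and that same amplicon's primer site, so
"self-dropout" cases — where the dropout-causing SNV is its own marker
via a second primer design — are represented with a distinct planted
causal SNV (same frequency) in the reporting amplicon's own primer site,
in cis with the marker. The observable phenotype is identical; only the
identity of the causal variant differs from the self-caused original.

Read depths come from a two-component mixture: with probability
`fail_prob` an amplicon fails (uniform 0–19 reads), otherwise depth is
negative binomial. `calibrate_depth(192, 0.947, 0.7951)` solves the
three parameters against the panel run metrics (mean reads per amplicon;
fractions of amplicons at ≥ 20× and ≥ 100×) deterministically: the mean
constraint is absorbed analytically, a Nelder–Mead solve matches the two
tails to ≤ 10⁻⁶, and if the tails are achievable with `fail_prob = 0`
that edge solution is preferred (fewest mechanisms). The calibrated
solution for the default targets is `fail_prob ≈ 0.051`,
`nb_size ≈ 3.5`, `mean_depth ≈ 202`.

The simulator does **not** emulate: sequencing error (a non-carrier
never shows alt reads), index hopping or contamination, primer-dimer and
thermodynamic effects (tier multipliers 1.0 / 0.8 / 0.5 for 3′ / 5′ /
internal are stated model assumptions, not measured efficiencies — no
quantitative per-position data exist), linkage disequilibrium between
population variants, CNVs or consanguinity (both real-world alternative
explanations for apparent hemizygosity), or read-level artifacts
(no FASTQ/BAM is produced). Passing tests on these fixtures therefore
establish that the detector recognises the modelled signatures at
realistic depths and rates — not that real panels contain no other
failure modes.

## Numerical choices

* Coordinates are 0-based half-open internally; manifest files and VCF
  positions are 1-based on disk and converted exactly once at IO.
* The binomial test is `stats::binom.test`; the suite checks it against
  an independent density-summation oracle to 10⁻¹² relative for depths
  up to 500.
* Percentages round half away from zero (base R rounds half to even,
  which would print 0.765 as 0.76).
* All randomness flows through a single integer seed per operation
  (`withr::with_seed`), and repeated invocations are byte-identical —
  verified on written files by checksum.
* Degenerate inputs: empty VCF bodies, catalogues with no AF (treated as
  monomorphic, with a warning), variants on contigs absent from the
  manifest (skipped silently), observations below `min_depth` (distinct
  not-testable status), and zero-efficiency double dropout (depth thins
  to zero) are all defined behaviours with tests.

## Problem sizes used in the test suite

Property checks run at sizes chosen to make their statistical bounds
sharp but the suite quick: oracle comparisons on random instances of
10–50 amplicons and 30–80 variants; Hardy–Weinberg convergence at 10⁴
samples (3σ binomial bands); phase-law monotonicity at depth 10⁴ over an
ε-grid; the false-positive bound on ~150-sample null cohorts
(α·n_tests + 3σ); recovery of complete dropouts on 120-sample cohorts at
depth 150; Monte-Carlo validation of the depth calibration at 10⁶ draws
(tail agreement within 10⁻³).

## Known limitations

* The amplicon-level risk product ignores LD; panel-level expected
  burden is an upper-tier approximation.
* Attribution ranks candidate causal variants by positional tier and
  carrier probability; it does not prove causality — that requires
  re-sequencing with independent primers, which is why every event is
  flagged for orthogonal confirmation.
* Sanger evidence is reduced to presence/absence above a peak floor;
  chromatogram signal quality is not modelled.
* The trio check covers only the dropout-relevant direction (child
  `hom_alt` vs parent `hom_ref`); it is not a general Mendelian
  consistency screen.
* Population choice for allele frequencies is the caller's: the screen
  uses whatever single `AF` the input VCF supplies.
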