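#' Primer-site variant screening and panel risk
#'
#' The screening stage intersects every amplicon's forward and reverse
#' primer binding sites with a population variant catalogue.  A variant
#' under a primer mismatches one haplotype in heterozygous carriers and can
#' suppress or abolish its amplification, so each incidence becomes a
#' `RiskFinding` with a positional tier (mismatches near the primer 3'
#' terminus are the classic high-risk position; the 5' terminus is also
#' risky), a frequency tier, and the Hardy-Weinberg heterozygous-carrier
#' probability `2p(1-p)`.
#'
#' @name risk_screen
NULL

#' Positional risk tier of a primer-site mismatch
#'
#' Mismatches within 7 nt of the primer 3' terminus (`dist_3prime <= 6`)
#' are tiered `three_prime_critical`; the 5 bases nearest the 5' end are
#' `five_prime`; everything else `internal`.  When a short site makes both
#' windows overlap, the 3' rule wins.
#'
#' @param dist_3prime Integer distance in bases from the primer 3'-terminal
#'   base (0 = terminal base itself).
#' @param site_length Length of the primer binding site in bases.
#' @return One of `"three_prime_critical"`, `"five_prime"`, `"internal"`.
#' @export
classify_position <- function(dist_3prime, site_length) {
  if (any(dist_3prime < 0L | dist_3prime >= site_length)) {
    stop("dist_3prime must satisfy 0 <= dist_3prime < site_length", call. = FALSE)
  }
  ifelse(dist_3prime <= 6L, "three_prime_critical",
         ifelse(dist_3prime >= site_length - 5L, "five_prime", "internal"))
}

#' Hardy-Weinberg heterozygous-carrier probability
#'
#' For a biallelic site with alternate allele frequency `af`, the
#' probability that a random individual is heterozygous is `2 af (1 - af)`
#' under Hardy-Weinberg equilibrium.  Heterozygotes are the individuals a
#' primer-site variant puts at dropout risk: one haplotype anneals, the
#' other does not.  The form is symmetric in `af <-> 1 - af`, so a
#' reference-rare site (af near 1) carries the same risk.
#'
#' @param af Allele frequency in `[0, 1]`.
#' @return `2 * af * (1 - af)`, in `[0, 0.5]`.
#' @export
het_carrier_prob <- function(af) {
  if (any(is.na(af) | af < 0 | af > 1)) {
    stop("af must be in [0, 1]", call. = FALSE)
  }
  2 * af * (1 - af)
}

# Distance from a variant's reference span to a primer 3'-terminal base,
# both 0-based.  For spans (indels) the nearest overlapping base counts.
dist_to_3prime <- function(span_start, span_end, site_start, site_end, tp_pos) {
  lo <- pmax(span_start, site_start)
  hi <- pmin(span_end, site_end) - 1L
  # nearest base of [lo, hi] to tp_pos
  nearest <- pmin(pmax(tp_pos, lo), hi)
  abs(nearest - tp_pos)
}

#' Screen a panel's primer binding sites against population variants
#'
#' One finding is emitted per (variant, primer site) incidence.  A variant
#' is matched to a site by containment/overlap of its reference span
#' (`pos ... pos + nchar(ref) - 1`, 1-based): an indel touching any site
#' base counts, since a partial-overlap deletion can disturb annealing.
#'
#' The forward primer's 3'-terminal base is the last base of `fwd_site`;
#' the reverse primer anneals to the opposite strand, so its 3'-terminal
#' base is the *first* genomic base of `rev_site`.
#'
#' Findings require `af >= min_af` or `af >= 1 - min_af` (the latter keeps
#' reference-rare sites, where the *reference* allele is the mismatch, in
#' view whatever the floor).  The default `min_af = 0` reports every
#' catalogued primer-site variant: causal variants as rare as af 6e-4 are
#' on record, so no frequency floor is safe; the `freq_tier` column
#' (`common` when the minor allele frequency is >= 0.01, else `rare`)
#' carries the distinction instead.
#'
#' @param manifest A validated panel manifest.
#' @param variants Population variant tibble ([read_population_vcf()]).
#' @param min_af Frequency floor in `[0, 1)`; default 0.
#' @return A tibble of findings: `amplicon_id, gene, primer (F|R), contig,
#'   pos, ref, alt, af, dist_3prime, position_tier, freq_tier,
#'   het_carrier_prob`, ordered by (amplicon_id, primer, pos).  Variants on
#'   contigs absent from the manifest are skipped silently.
#' @export
screen_panel <- function(manifest, variants, min_af = 0) {
  validate_manifest(manifest)
  if (min_af < 0 || min_af >= 1) stop("min_af must be in [0, 1)", call. = FALSE)
  empty <- tibble(amplicon_id = character(), gene = character(),
                  primer = character(), contig = character(), pos = integer(),
                  ref = character(), alt = character(), af = double(),
                  dist_3prime = integer(), position_tier = character(),
                  freq_tier = character(), het_carrier_prob = double())
  if (nrow(variants) == 0 || nrow(manifest) == 0) return(empty)

  keep <- variants$af >= min_af | variants$af >= 1 - min_af
  variants <- variants[keep, , drop = FALSE]
  if (nrow(variants) == 0) return(empty)

  # variant reference spans, 0-based half-open
  vspan_start <- variants$pos - 1L
  vspan_end <- vspan_start + nchar(variants$ref)
  vgr <- granges0(variants$contig, vspan_start, vspan_end)

  sites <- bind_rows(
    tibble(idx = seq_len(nrow(manifest)), primer = "F",
           site_start = manifest$fwd_start, site_end = manifest$fwd_end,
           tp_pos = manifest$fwd_end - 1L),
    tibble(idx = seq_len(nrow(manifest)), primer = "R",
           site_start = manifest$rev_start, site_end = manifest$rev_end,
           tp_pos = manifest$rev_start))
  sgr <- granges0(manifest$contig[sites$idx], sites$site_start, sites$site_end)

  hits <- suppressWarnings(GenomicRanges::findOverlaps(vgr, sgr))
  if (length(hits) == 0) return(empty)
  vi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)

  out <- tibble(
    amplicon_id = manifest$amplicon_id[sites$idx[si]],
    gene = manifest$gene[sites$idx[si]],
    primer = sites$primer[si],
    contig = variants$contig[vi],
    pos = as.integer(variants$pos[vi]),
    ref = variants$ref[vi],
    alt = variants$alt[vi],
    af = variants$af[vi],
    dist_3prime = dist_to_3prime(vspan_start[vi], vspan_end[vi],
                                 sites$site_start[si], sites$site_end[si],
                                 sites$tp_pos[si]),
    site_length = sites$site_end[si] - sites$site_start[si])
  out$position_tier <- classify_position(out$dist_3prime, out$site_length)
  maf <- pmin(out$af, 1 - out$af)
  out$freq_tier <- ifelse(maf >= 0.01, "common", "rare")
  out$het_carrier_prob <- het_carrier_prob(out$af)
  out$site_length <- NULL
  arrange(out, .data$amplicon_id, .data$primer, .data$pos)
}

#' Aggregate per-amplicon dropout risk
#'
#' Probability that a random individual is heterozygous for at least one of
#' the amplicon's primer-site variants, assuming independence between
#' sites: `1 - prod(1 - 2 af_i (1 - af_i))`.  Linkage disequilibrium is not
#' modelled; treat the value as an upper-tier approximation.
#'
#' @param findings Findings for a single amplicon ([screen_panel()] rows).
#' @return A probability in `[0, 1]`; 0 for no findings.
#' @export
amplicon_ado_risk <- function(findings) {
  if (is.null(findings) || nrow(findings) == 0) return(0)
  if (length(unique(findings$amplicon_id)) > 1) {
    stop("findings must share one amplicon_id", call. = FALSE)
  }
  1 - prod(1 - het_carrier_prob(findings$af))
}

#' Panel-wide risk summary
#'
#' Counts amplicons with at least one primer-site finding and reports the
#' flagged percentage (rounded half-up to two decimals) plus the expected
#' per-individual burden: the sum over amplicons of [amplicon_ado_risk()],
#' i.e. the expected number of amplicons at dropout risk in a random
#' individual.
#'
#' @param manifest The manifest the findings were screened from.
#' @param findings Tibble from [screen_panel()].
#' @return A list with `panel_id, n_amplicons, n_flagged, percent_flagged,
#'   expected_burden, per_gene` (named flagged-amplicon counts by gene).
#' @export
summarize_panel <- function(manifest, findings) {
  validate_manifest(manifest)
  n_amp <- nrow(manifest)
  flagged_ids <- unique(findings$amplicon_id)
  if (length(flagged_ids) && !all(flagged_ids %in% manifest$amplicon_id)) {
    stop("findings reference amplicons absent from manifest", call. = FALSE)
  }
  n_flagged <- length(flagged_ids)
  burden <- 0
  per_gene <- integer(0)
  if (n_flagged) {
    by_amp <- split(findings, findings$amplicon_id)
    burden <- sum(vapply(by_amp, amplicon_ado_risk, numeric(1)))
    genes <- manifest$gene[match(flagged_ids, manifest$amplicon_id)]
    per_gene <- table(genes)
    per_gene <- setNames(as.integer(per_gene), names(per_gene))
  }
  list(panel_id = manifest$panel_id[1],
       n_amplicons = n_amp,
       n_flagged = n_flagged,
       percent_flagged = if (n_amp) round_half_up(100 * n_flagged / n_amp, 2) else 0,
       expected_burden = burden,
       per_gene = as.list(per_gene))
}

#' Write a findings report
#'
#' @param findings Tibble from [screen_panel()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_findings <- function(findings, path) {
  write.table(findings, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_findings
#' @export
read_findings <- function(path) {
  f <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  f$pos <- as.integer(f$pos)
  f
}
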