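#' Synthetic panel and cohort presets
#'
#' Named, fully reproducible fixtures emulating a multi-gene cardiomyopathy
#' amplicon panel:
#'
#' * `FULL` — a whole design: 1,049 amplicons over 37 synthetic genes,
#'   total insert length 153 kb, two primer pools, tiling overlap on a
#'   fraction of adjacent pairs, plus a background population catalogue.
#' * `PANEL1` — a 521-amplicon sub-panel with primer-site population SNVs
#'   planted on exactly four risk amplicons (a spread of common,
#'   low-frequency and reference-rare alleles across 3', internal and 5'
#'   positions) and none elsewhere.
#' * `TABLE1` — six dropout case groups (pseudo-homozygosity and
#'   marker-loss on Sanger; underrepresentation, overlap discordance and
#'   run-to-run loss on NGS) plus 20 clean heterozygous controls.
#' * `COHORT232` — 232 samples over the `TABLE1` loci with planted carrier
#'   counts per case (1, 9, 1, 1, 1 and 2 confirmed carriers); remaining
#'   samples draw clean Hardy-Weinberg genotypes.
#'
#' Event-defining observations are planted at counts realizing each case's
#' characteristic allele fraction (e.g. 6 alt / 194 ref for the 3% case),
#' so the cases themselves are deterministic; control and non-carrier
#' observations are stochastic draws under the given seed.
#'
#' @name presets
NULL

.presets <- c("FULL", "PANEL1", "TABLE1", "COHORT232")

# Draw insert lengths with an exact total, all within [min_len, max_len].
.lengths_with_total <- function(n, total, mean_len = 146, sd_len = 25,
                                min_len = 80, max_len = 260) {
  stopifnot(total >= n * min_len, total <= n * max_len)
  len <- pmin(pmax(round(rnorm(n, mean_len, sd_len)), min_len), max_len)
  diff <- total - sum(len)
  while (diff != 0) {
    step <- sign(diff)
    room <- if (step > 0) which(len < max_len) else which(len > min_len)
    take <- room[sample.int(length(room), min(length(room), abs(diff)))]
    len[take] <- len[take] + step
    diff <- total - sum(len)
  }
  len
}

#' Generate a random tiled amplicon panel
#'
#' Genes live on their own synthetic contigs (`chrS1`, `chrS2`, ...).
#' Within a gene, consecutive amplicons either tile (insert overlap of
#' 30-60 nt, probability `overlap_frac`) or leave a short gap; primer
#' binding sites (18-27 nt) flank each insert directly, and tiled
#' neighbours are assigned to alternating pools as multiplexed designs do.
#'
#' @param n_amplicons,n_genes Panel dimensions.
#' @param total_insert_len Exact total insert length in bases.
#' @param overlap_frac Fraction of adjacent pairs that tile.
#' @param panel_id Panel label.
#' @param seed Integer seed.
#' @return A validated manifest tibble.
#' @export
generate_panel <- function(n_amplicons, n_genes, total_insert_len,
                           overlap_frac = 0.35, panel_id = "panelS",
                           seed = 1) {
  withr::with_seed(seed, {
    per_gene <- rep(n_amplicons %/% n_genes, n_genes)
    extra <- n_amplicons %% n_genes
    if (extra) per_gene[seq_len(extra)] <- per_gene[seq_len(extra)] + 1L
    lens <- .lengths_with_total(n_amplicons, total_insert_len)
    rows <- vector("list", n_amplicons)
    k <- 0
    for (g in seq_len(n_genes)) {
      gene <- sprintf("GENE%02d", g)
      contig <- paste0("chrS", g)
      cursor <- 1000L
      for (a in seq_len(per_gene[g])) {
        k <- k + 1
        if (a > 1 && runif(1) < overlap_frac) {
          start <- cursor - sample(30:60, 1)
        } else {
          start <- cursor + sample(5:50, 1)
        }
        end <- start + lens[k]
        lf <- sample(18:27, 1); lr <- sample(18:27, 1)
        rows[[k]] <- tibble(
          amplicon_id = sprintf("%s_%s_%03d", panel_id, gene, a),
          gene = gene, contig = contig,
          insert_start = start, insert_end = end,
          fwd_start = start - lf, fwd_end = start,
          rev_start = end, rev_end = end + lr,
          pool = if (a %% 2 == 1) 1L else 2L,
          panel_id = panel_id)
        cursor <- end
      }
    }
    validate_manifest(bind_rows(rows))
  })
}

# Background insert ("marker") variants for a manifest: placed in insert
# interiors and filtered against every primer site so they never create
# screening findings.
.background_markers <- function(manifest, prob = 0.25, seed = 1) {
  withr::with_seed(seed, {
    pick <- which(runif(nrow(manifest)) < prob)
    if (!length(pick)) {
      return(tibble(contig = character(), pos = integer(), ref = character(),
                    alt = character(), af = double(), var_id = character()))
    }
    m <- manifest[pick, ]
    pos0 <- m$insert_start + (m$insert_end - m$insert_start) %/% 2L
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, length(pick), replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    v <- tibble(contig = m$contig, pos = pos0 + 1L, ref = ref, alt = alt,
                af = pmax(round(stats::rbeta(length(pick), 0.5, 3), 4), 1e-4),
                var_id = paste0("bg", seq_along(pick)))
    sites <- granges0(rep(manifest$contig, 2),
                      c(manifest$fwd_start, manifest$rev_start),
                      c(manifest$fwd_end, manifest$rev_end))
    vg <- granges0(v$contig, v$pos - 1L, v$pos)
    hit <- GenomicRanges::countOverlaps(vg, sites) > 0
    v[!hit, ]
  })
}

# A primer-site variant for one amplicon at a requested tier.
.plant_site_variant <- function(amp, primer, tier, af, var_id) {
  if (primer == "F") {
    s <- amp$fwd_start; e <- amp$fwd_end; tp <- amp$fwd_end - 1L
  } else {
    s <- amp$rev_start; e <- amp$rev_end; tp <- amp$rev_start
  }
  len <- e - s
  pos0 <- switch(tier,
    three_prime_critical = if (primer == "F") tp - 1L else tp + 1L,
    five_prime = if (primer == "F") s else e - 1L,
    internal = s + len %/% 2L)
  stopifnot(classify_position(abs(pos0 - tp), len) == tier)
  tibble(contig = amp$contig, pos = pos0 + 1L, ref = "C", alt = "T",
         af = af, var_id = var_id)
}

# TABLE1 case-group layout: the six dropout cases on their printed hg19
# amplicon spans, plus control amplicons.  Pure geometry, no RNG.
.table1_layout <- function() {
  amp <- function(id, gene, contig, p_start, p_end, lf = 25L, lr = 25L,
                  pool = 1L) {
    conv <- from_printed(p_start, p_end)
    tibble(amplicon_id = id, gene = gene, contig = contig,
           insert_start = conv$start, insert_end = conv$end,
           fwd_start = conv$start - lf, fwd_end = conv$start,
           rev_start = conv$end, rev_end = conv$end + lr,
           pool = pool, panel_id = "TABLE1")
  }
  manifest <- bind_rows(
    amp("AMP_SCN5A_1", "SCN5A", "chr3", 38597041L, 38597372L),
    amp("AMP_PKP2_1", "PKP2", "chr12", 32948847L, 32949434L),
    amp("AMP_DSP_1", "DSP", "chr6", 7572015L, 7572438L),
    amp("AMP_LDB3_1", "LDB3", "chr10", 88466446L, 88466568L),
    amp("AMP_LDB3_2", "LDB3", "chr10", 88451719L, 88451942L),
    # SCN1B case: printed span plus a tiling partner sharing 82 nt of insert
    amp("AMP_SCN1B_X", "SCN1B", "chr19", 35524839L, 35525003L),
    amp("AMP_SCN1B_Y", "SCN1B", "chr19", 35524751L, 35524920L, pool = 2L))

  v <- function(contig, pos1, ref, alt, af, var_id) {
    tibble(contig = contig, pos = as.integer(pos1), ref = ref, alt = alt,
           af = af, var_id = var_id)
  }
  a <- function(id) manifest[manifest$amplicon_id == id, ]
  # causal primer-site SNVs; MAFs are the case frequencies on record
  causal <- bind_rows(
    .plant_site_variant(a("AMP_SCN5A_1"), "R", "three_prime_critical",
                        0.087, "SCN5A_causal"),
    .plant_site_variant(a("AMP_PKP2_1"), "F", "five_prime",
                        0.139, "PKP2_causal"),
    .plant_site_variant(a("AMP_DSP_1"), "R", "three_prime_critical",
                        0.411, "DSP_causal"),
    .plant_site_variant(a("AMP_LDB3_1"), "F", "three_prime_critical",
                        0.0006, "LDB3a_causal"),
    .plant_site_variant(a("AMP_LDB3_2"), "R", "three_prime_critical",
                        0.0014, "LDB3b_causal"),
    .plant_site_variant(a("AMP_SCN1B_X"), "R", "three_prime_critical",
                        0.0042, "SCN1B_causal_X"),
    .plant_site_variant(a("AMP_SCN1B_Y"), "R", "three_prime_critical",
                        0.0042, "SCN1B_causal_Y"))
  markers <- bind_rows(
    v("chr3", 38597200, "C", "T", 0.0001, "SCN5A_marker"),     # c.4516C>T-like
    v("chr12", 32949000, "A", "G", 0.01, "PKP2_marker1"),
    v("chr12", 32949100, "G", "A", 0.012, "PKP2_marker2"),
    v("chr12", 32949200, "T", "C", 0.011, "PKP2_marker3"),
    v("chr6", 7572200, "A", "G", 0.02, "DSP_marker"),          # c.2091A>G-like
    v("chr10", 88466500, "A", "G", 0.0006, "LDB3a_marker"),    # c.1051A>G-like
    v("chr10", 88451800, "A", "G", 0.0014, "LDB3b_marker"),    # c.752A>G-like
    v("chr19", 35524900, "G", "A", 0.0042, "SCN1B_m641"),      # shared insert
    v("chr19", 35524950, "C", "A", 0.001, "SCN1B_m744"),       # X only
    v("chr19", 35524960, "G", "C", 0.001, "SCN1B_m749"))       # X only

  case_samples <- c(SCN5A = "CASE_SCN5A", PKP2 = "CASE_PKP2",
                    DSP = "CASE_DSP", LDB3a = "CASE_LDB3A",
                    LDB3b = "CASE_LDB3B", SCN1B = "CASE_SCN1B")
  list(manifest = manifest, causal = causal, markers = markers,
       case_samples = case_samples)
}

# Control amplicons (clean heterozygous markers) appended to a layout.
.control_amplicons <- function(n_controls, seed) {
  manifest <- generate_panel(n_controls, max(1L, n_controls %/% 5L),
                             n_controls * 150L, overlap_frac = 0,
                             panel_id = "CTRL", seed = seed)
  markers <- withr::with_seed(seed + 1L, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n_controls, replace = TRUE)
    tibble(contig = manifest$contig,
           pos = manifest$insert_start +
             (manifest$insert_end - manifest$insert_start) %/% 2L + 1L,
           ref = ref,
           alt = vapply(ref, function(r) sample(setdiff(bases, r), 1), ""),
           af = 0.2,
           var_id = paste0("ctrl_m", seq_len(n_controls)))
  })
  list(manifest = manifest, markers = markers)
}

#' Generate a preset panel and population catalogue
#'
#' @param preset One of `"FULL"`, `"PANEL1"`, `"TABLE1"`, `"COHORT232"`.
#' @param seed Integer seed; identical calls are byte-identical.
#' @return A list with `manifest` (validated tibble) and `variants`
#'   (population catalogue tibble, VCF-shaped).  For `PANEL1` the planted
#'   risk amplicon ids are attached as `risk_amplicons`.
#' @export
make_panel <- function(preset, seed = 1) {
  preset <- match.arg(preset, .presets)
  if (preset == "FULL") {
    manifest <- generate_panel(1049L, 37L, 153000L, overlap_frac = 0.35,
                               panel_id = "panelFULL", seed = seed)
    bg <- .background_markers(manifest, prob = 0.25, seed = seed + 1L)
    site <- withr::with_seed(seed + 2L, {
      pick <- which(runif(nrow(manifest)) < 0.05)
      if (length(pick)) {
        bind_rows(lapply(seq_along(pick), function(i) {
          ampl <- manifest[pick[i], ]
          .plant_site_variant(
            ampl,
            primer = sample(c("F", "R"), 1),
            tier = sample(.position_tiers, 1),
            af = pmax(round(stats::rbeta(1, 0.4, 2), 4), 1e-4),
            var_id = paste0("site", i))
        }))
      } else NULL
    })
    variants <- arrange(bind_rows(bg, site), .data$contig, .data$pos)
    return(list(preset = preset, manifest = manifest, variants = variants))
  }
  if (preset == "PANEL1") {
    manifest <- generate_panel(521L, 15L, 76000L, overlap_frac = 0.35,
                               panel_id = "panel1", seed = seed)
    # risk loci on unambiguous sites: the F site of a gene's first
    # amplicon and the R site of a gene's last amplicon cannot fall in any
    # neighbouring amplicon's territory
    first_of <- function(g) manifest[manifest$gene == g, ][1, ]
    last_of <- function(g) {
      mg <- manifest[manifest$gene == g, ]; mg[nrow(mg), ]
    }
    plan <- list(
      list(a = first_of("GENE03"), primer = "F",
           tier = "three_prime_critical", af = 0.605),
      list(a = first_of("GENE06"), primer = "F", tier = "five_prime",
           af = 0.044),
      list(a = last_of("GENE09"), primer = "R",
           tier = "three_prime_critical", af = 0.890),
      list(a = last_of("GENE12"), primer = "R", tier = "internal",
           af = 0.999))
    site <- bind_rows(lapply(seq_along(plan), function(i) {
      p <- plan[[i]]
      .plant_site_variant(p$a, p$primer, p$tier, p$af, paste0("risk", i))
    }))
    bg <- .background_markers(manifest, prob = 0.25, seed = seed + 1L)
    variants <- arrange(bind_rows(bg, site), .data$contig, .data$pos)
    out <- list(preset = preset, manifest = manifest, variants = variants,
                risk_amplicons = vapply(plan, function(p) p$a$amplicon_id, ""))
    return(out)
  }
  # TABLE1 / COHORT232 share one layout
  lay <- .table1_layout()
  ctrl <- .control_amplicons(20L, seed = seed + 10L)
  manifest <- bind_rows(lay$manifest, ctrl$manifest)
  manifest$panel_id <- preset
  variants <- arrange(bind_rows(lay$causal, lay$markers, ctrl$markers),
                      .data$contig, .data$pos)
  list(preset = preset, manifest = validate_manifest(manifest),
       variants = variants, layout = lay, control_markers = ctrl$markers)
}
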