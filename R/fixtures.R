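#' Build a complete named fixture
#'
#' [make_panel()] gives the panel and population catalogue; this adds the
#' per-sample evidence: allele observations, genotype calls from the
#' orthogonal platform, and a trio pedigree where the case calls for one.
#' `TABLE1` yields the six dropout cases with one sample each plus 20
#' clean heterozygous control samples; `COHORT232` spreads planted
#' carriers (1, 9, 1, 1, 1, 2 across the six case loci) over a 232-sample
#' cohort whose remaining members draw Hardy-Weinberg genotypes and clean
#' observations.  `FULL` and `PANEL1` are screening fixtures and carry no
#' observations.
#'
#' @param preset One of `"FULL"`, `"PANEL1"`, `"TABLE1"`, `"COHORT232"`.
#' @param seed Integer seed; identical calls are byte-identical.
#' @return A list: `preset, seed, manifest, variants, observations,
#'   ngs_calls, orthogonal_calls, trios, truth` (`truth` lists every
#'   planted dropout case with its expected event type, evidence channel
#'   and platform; `NULL` tables where the preset has none).
#' @export
make_fixture <- function(preset, seed = 1) {
  preset <- match.arg(preset, .presets)
  panel <- make_panel(preset, seed)
  if (preset %in% c("FULL", "PANEL1")) {
    return(c(panel, list(seed = seed, observations = NULL, ngs_calls = NULL,
                         orthogonal_calls = NULL, trios = NULL, truth = NULL)))
  }
  lay <- panel$layout
  mk <- function(id) lay$markers[lay$markers$var_id == id, ]
  obs_row <- function(s, amp, m, ref_reads, alt_reads, platform, run) {
    tibble(sample_id = s, amplicon_id = amp, contig = m$contig, pos = m$pos,
           ref = m$ref, alt = m$alt, ref_reads = as.integer(ref_reads),
           alt_reads = as.integer(alt_reads), platform = platform,
           run_id = run)
  }
  call_row <- function(s, m, zyg, platform, run = "ortho") {
    tibble(sample_id = s, contig = m$contig, pos = m$pos, ref = m$ref,
           alt = m$alt, zygosity = zyg, platform = platform, run_id = run)
  }
  truth_row <- function(s, gene, amps, m, type, evidence, platform) {
    tibble(sample_id = s, gene = gene, amplicon_ids = amps, pos = m$pos,
           event_type = type, evidence = evidence, platform = platform)
  }

  # planted case evidence; counts realize each case's characteristic
  # allele fraction, so the cases do not depend on the seed
  case_scn5a <- function(s, mother) {
    m <- mk("SCN5A_marker")
    list(obs = bind_rows(obs_row(s, "AMP_SCN5A_1", m, 0, 1, "sanger", "r1"),
                         obs_row(mother, "AMP_SCN5A_1", m, 1, 0, "sanger", "r1")),
         ortho = call_row(s, m, "het", "ngs"),
         trios = tibble(child = s, mother = mother, father = NA_character_),
         truth = truth_row(s, "SCN5A", "AMP_SCN5A_1", m, "pseudo_homozygous",
                           "trio_conflict", "sanger"))
  }
  case_pkp2 <- function(s) {
    ms <- lapply(paste0("PKP2_marker", 1:3), mk)
    list(obs = bind_rows(lapply(ms, function(m)
           obs_row(s, "AMP_PKP2_1", m, 0, 1, "sanger", "r1"))),
         ortho = bind_rows(lapply(ms, function(m) call_row(s, m, "het", "ngs"))),
         truth = truth_row(s, "PKP2", "AMP_PKP2_1", ms[[1]],
                           "pseudo_homozygous", "platform_discordance",
                           "sanger"))
  }
  case_dsp <- function(s) {
    m <- mk("DSP_marker")
    list(obs = bind_rows(obs_row(s, "AMP_DSP_1", m, 1, 1, "sanger", "r1"),
                         obs_row(s, "AMP_DSP_1", m, 1, 0, "sanger", "r2"),
                         obs_row(s, "AMP_DSP_1", m, 1, 0, "sanger", "r3")),
         ortho = call_row(s, m, "het", "ngs"),
         truth = truth_row(s, "DSP", "AMP_DSP_1", m, "missing_marker",
                           "platform_discordance", "sanger"))
  }
  case_ldb3 <- function(s, which, amp, ref_n, alt_n) {
    m <- mk(paste0("LDB3", which, "_marker"))
    list(obs = obs_row(s, amp, m, ref_n, alt_n, "ngs", "r1"),
         ortho = call_row(s, m, "het", "sanger"),
         truth = truth_row(s, "LDB3", amp, m, "underrepresented",
                           "allele_balance", "ngs"))
  }
  case_scn1b <- function(s) {
    m641 <- mk("SCN1B_m641"); m744 <- mk("SCN1B_m744"); m749 <- mk("SCN1B_m749")
    list(obs = bind_rows(
           obs_row(s, "AMP_SCN1B_X", m641, 180, 0, "ngs", "r1"),
           obs_row(s, "AMP_SCN1B_X", m744, 180, 0, "ngs", "r1"),
           obs_row(s, "AMP_SCN1B_X", m749, 180, 0, "ngs", "r1"),
           obs_row(s, "AMP_SCN1B_Y", m641, 171, 9, "ngs", "r1")),
         ortho = bind_rows(call_row(s, m641, "het", "sanger"),
                           call_row(s, m744, "het", "sanger"),
                           call_row(s, m749, "het", "sanger")),
         truth = truth_row(s, "SCN1B", "AMP_SCN1B_X;AMP_SCN1B_Y", m641,
                           "missing_marker", "overlap_discordance", "ngs"))
  }
  clean_het_obs <- function(samples, markers, marker_amp, depth) {
    # clean heterozygous observations, one (sample, marker) per row of input
    n_alt <- rbinom(length(samples), depth, 0.5)
    tibble(sample_id = samples, amplicon_id = marker_amp,
           contig = markers$contig, pos = markers$pos, ref = markers$ref,
           alt = markers$alt, ref_reads = as.integer(depth - n_alt),
           alt_reads = as.integer(n_alt), platform = "ngs", run_id = "r1")
  }

  # which amplicons contain each marker (for clean observations)
  marker_amps <- function(markers) {
    vg <- granges0(markers$contig, markers$pos - 1L, markers$pos)
    ig <- granges0(panel$manifest$contig, panel$manifest$insert_start,
                   panel$manifest$insert_end)
    h <- suppressWarnings(GenomicRanges::findOverlaps(vg, ig))
    tibble(mi = S4Vectors::queryHits(h),
           amplicon_id = panel$manifest$amplicon_id[S4Vectors::subjectHits(h)])
  }

  if (preset == "TABLE1") {
    cases <- list(case_scn5a("CASE_SCN5A", "CASE_SCN5A_MOTHER"),
                  case_pkp2("CASE_PKP2"), case_dsp("CASE_DSP"),
                  case_ldb3("CASE_LDB3A", "a", "AMP_LDB3_1", 194, 6),
                  case_ldb3("CASE_LDB3B", "b", "AMP_LDB3_2", 178, 22),
                  case_scn1b("CASE_SCN1B"))
    ctrl <- withr::with_seed(seed + 20L, {
      cm <- panel$control_markers
      ma <- marker_amps(cm)
      depths <- rnbinom(nrow(ma), mu = 192, size = 20) + 20L
      clean_het_obs(sprintf("CTRL%02d", ma$mi), cm[ma$mi, ], ma$amplicon_id,
                    depths)
    })
    observations <- bind_rows(c(lapply(cases, `[[`, "obs"), list(ctrl)))
    return(c(panel, list(
      seed = seed,
      observations = observations,
      ngs_calls = NULL,
      orthogonal_calls = bind_rows(lapply(cases, `[[`, "ortho")),
      trios = bind_rows(lapply(cases, `[[`, "trios")),
      truth = bind_rows(lapply(cases, `[[`, "truth")))))
  }

  # COHORT232
  ids <- sprintf("S%03d", seq_len(232L))
  cases <- c(list(case_scn5a(ids[1], "S001_MOTHER")),
             lapply(2:10, function(i) case_pkp2(ids[i])),
             list(case_dsp(ids[11]),
                  case_ldb3(ids[12], "a", "AMP_LDB3_1", 194, 6),
                  case_ldb3(ids[13], "b", "AMP_LDB3_2", 178, 22),
                  case_scn1b(ids[14]), case_scn1b_partner(ids[15], mk)))
  clean_ids <- ids[16:232]
  hwe_obs <- withr::with_seed(seed + 30L, {
    all_m <- bind_rows(lay$markers, panel$control_markers)
    ma <- marker_amps(all_m)
    rows <- list()
    for (k in seq_len(nrow(ma))) {
      m <- all_m[ma$mi[k], ]
      g <- runif(length(clean_ids))
      het <- g < 2 * m$af * (1 - m$af)
      hom <- g >= 2 * m$af * (1 - m$af) & g < 2 * m$af * (1 - m$af) + m$af^2
      carriers <- clean_ids[het | hom]
      if (!length(carriers)) next
      depth <- rnbinom(length(carriers), mu = 192, size = 20) + 20L
      n_alt <- rbinom(length(carriers), depth,
                      ifelse(het[het | hom], 0.5, 1))
      rows[[length(rows) + 1]] <- tibble(
        sample_id = carriers, amplicon_id = ma$amplicon_id[k],
        contig = m$contig, pos = m$pos, ref = m$ref, alt = m$alt,
        ref_reads = as.integer(depth - n_alt), alt_reads = as.integer(n_alt),
        platform = "ngs", run_id = "r1")
    }
    bind_rows(rows)
  })
  observations <- bind_rows(c(lapply(cases, `[[`, "obs"), list(hwe_obs)))
  c(panel, list(
    seed = seed,
    observations = observations,
    ngs_calls = NULL,
    orthogonal_calls = bind_rows(lapply(cases, `[[`, "ortho")),
    trios = bind_rows(lapply(cases, `[[`, "trios")),
    truth = bind_rows(lapply(cases, `[[`, "truth"))))
}

# second confirmed SCN1B-style carrier (same locus, its own sample)
case_scn1b_partner <- function(s, mk) {
  m641 <- mk("SCN1B_m641"); m744 <- mk("SCN1B_m744"); m749 <- mk("SCN1B_m749")
  list(obs = bind_rows(
         tibble(sample_id = s, amplicon_id = "AMP_SCN1B_X", contig = m641$contig,
                pos = m641$pos, ref = m641$ref, alt = m641$alt,
                ref_reads = 190L, alt_reads = 0L, platform = "ngs",
                run_id = "r1"),
         tibble(sample_id = s, amplicon_id = "AMP_SCN1B_X", contig = m744$contig,
                pos = m744$pos, ref = m744$ref, alt = m744$alt,
                ref_reads = 190L, alt_reads = 0L, platform = "ngs",
                run_id = "r1"),
         tibble(sample_id = s, amplicon_id = "AMP_SCN1B_Y", contig = m641$contig,
                pos = m641$pos, ref = m641$ref, alt = m641$alt,
                ref_reads = 182L, alt_reads = 10L, platform = "ngs",
                run_id = "r1")),
       ortho = tibble(sample_id = s, contig = m641$contig, pos = m641$pos,
                      ref = m641$ref, alt = m641$alt, zygosity = "het",
                      platform = "sanger", run_id = "ortho"),
       truth = tibble(sample_id = s, gene = "SCN1B",
                      amplicon_ids = "AMP_SCN1B_X;AMP_SCN1B_Y", pos = m641$pos,
                      event_type = "missing_marker",
                      evidence = "overlap_discordance", platform = "ngs"))
}
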