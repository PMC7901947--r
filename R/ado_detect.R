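#' Allelic-dropout detection
#'
#' Four evidence channels reveal dropout of one allele at a heterozygous
#' site:
#'
#' * **allele balance** — the marker variant is present but underrepresented
#'   in NGS reads (exact binomial test of alt reads against the 0.5
#'   heterozygous expectation, low side only);
#' * **overlap discordance** — a variant in the shared insert of two tiled
#'   amplicons is seen on one but absent/trace on the other;
#' * **platform discordance** — a heterozygote on one platform (or run)
#'   appears homozygous on another: `hom_alt` means the wild-type allele
#'   vanished (pseudo-homozygosity / apparent hemizygosity), `hom_ref`
#'   means the marker itself vanished;
#' * **trio conflict** — a child apparently homozygous for the alternate
#'   allele while a parent is `hom_ref`, contradicting the obligate
#'   wild-type transmission.
#'
#' Events are deduplicated keeping the strongest evidence and annotated
#' with candidate causal primer-site variants from the screening stage.
#'
#' @name ado_detect
NULL

#' Default detection configuration
#'
#' `alpha = 0.001` and `vaf_max = 0.25` separate genuine partial dropout
#' (marker fractions of a few percent at typical panel depths around 200x)
#' from binomial noise around 0.5; `presence_threshold = 0.10` is the
#' fraction above which an allele counts as solidly present on an
#' amplicon; `min_depth = 20` matches the usual per-amplicon coverage
#' floor; `sanger_floor = 0.15` is the minor-peak fraction below which a
#' chromatogram shows nothing.  `fdr = FALSE` leaves p-values uncorrected
#' (per-case confirmation workflow); set `TRUE` for Benjamini-Hochberg
#' control across a cohort's balance tests.
#'
#' @param alpha,vaf_max,presence_threshold,min_depth,sanger_floor,fdr
#'   Override any default.
#' @return A named list of detection parameters.
#' @export
detect_config <- function(alpha = 0.001, vaf_max = 0.25,
                          presence_threshold = 0.10, min_depth = 20,
                          sanger_floor = 0.15, fdr = FALSE) {
  stopifnot(alpha > 0, alpha < 1, vaf_max > 0, vaf_max <= 0.5,
            presence_threshold > 0, presence_threshold < 0.5,
            min_depth >= 1, sanger_floor >= 0, sanger_floor <= 0.5)
  list(alpha = alpha, vaf_max = vaf_max,
       presence_threshold = presence_threshold, min_depth = min_depth,
       sanger_floor = sanger_floor, fdr = fdr)
}

#' Exact binomial allele-balance test
#'
#' For an NGS observation with `alt` and `ref` read counts, tests the
#' two-sided exact binomial hypothesis that alt reads arise with
#' probability 0.5 (the heterozygous expectation).  An observation is
#' flagged only on the low side: `p_value < alpha` *and* `vaf < vaf_max`.
#' Observations below `min_depth` total reads are not testable and are
#' never flagged (`testable = FALSE`, `p_value = NA`).
#'
#' @param ref_reads,alt_reads Non-negative integer vectors (recycled to a
#'   common length).
#' @param alpha Significance level.
#' @param vaf_max Upper bound on the variant allele fraction for flagging.
#' @param min_depth Minimum total reads for a testable observation.
#' @return A tibble with columns `vaf, p_value, flagged, testable`.
#' @export
test_allele_balance <- function(ref_reads, alt_reads, alpha = 0.001,
                                vaf_max = 0.25, min_depth = 20) {
  n <- max(length(ref_reads), length(alt_reads))
  ref_reads <- rep_len(as.integer(ref_reads), n)
  alt_reads <- rep_len(as.integer(alt_reads), n)
  if (any(ref_reads < 0 | alt_reads < 0)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  depth <- ref_reads + alt_reads
  testable <- depth >= min_depth
  vaf <- ifelse(depth > 0, alt_reads / depth, NA_real_)
  p <- rep(NA_real_, n)
  for (i in which(testable)) {
    p[i] <- binom.test(alt_reads[i], depth[i], p = 0.5)$p.value
  }
  flagged <- testable & !is.na(p) & p < alpha & vaf < vaf_max
  tibble(vaf = vaf, p_value = p, flagged = flagged, testable = testable)
}

.empty_events <- function() {
  tibble(sample_id = character(), amplicon_ids = character(),
         contig = character(), pos = integer(), ref = character(),
         alt = character(), marker_variants = character(),
         event_type = character(), evidence = character(),
         vaf = double(), p_value = double(), platform = character(),
         note = character())
}

.site_key <- function(pos, ref, alt) paste0(pos, ":", ref, ">", alt)

# present / trace / absent status of an allele observation
.presence_status <- function(vaf, presence_threshold) {
  ifelse(vaf >= presence_threshold, "present",
         ifelse(vaf > 0, "trace", "absent"))
}

#' Detect dropout through overlapping-amplicon discordance
#'
#' For every variant whose position lies in the insert intersection of an
#' overlapping amplicon pair, compares the variant's representation on the
#' two amplicons within each (sample, run).  Each side is classed
#' `present` (vaf >= `presence_threshold`), `trace` (0 < vaf < threshold)
#' or `absent` (vaf = 0); an event fires when the classes disagree —
#' present/absent, present/trace or trace/absent.  Absence on one side is
#' a `missing_marker` event (the marker vanished from that amplicon);
#' present/trace is `underrepresented`.  Sides below `min_depth` are not
#' compared.
#'
#' @param observations NGS observation tibble ([read_observations()]).
#' @param manifest A validated manifest.
#' @param config Detection parameters ([detect_config()]).
#' @return An event tibble (see [run_detection()] for columns).
#' @export
detect_overlap_discordance <- function(observations, manifest,
                                       config = detect_config()) {
  pairs <- overlapping_amplicon_pairs(manifest)
  obs <- filter(observations, .data$platform == "ngs")
  if (nrow(pairs) == 0 || nrow(obs) == 0) return(.empty_events())
  idx <- match(c(pairs$amplicon_a, pairs$amplicon_b), manifest$amplicon_id)
  ia <- idx[seq_len(nrow(pairs))]
  ib <- idx[nrow(pairs) + seq_len(nrow(pairs))]
  shared_start <- pmax(manifest$insert_start[ia], manifest$insert_start[ib])
  shared_end <- pmin(manifest$insert_end[ia], manifest$insert_end[ib])

  obs$depth <- obs$ref_reads + obs$alt_reads
  obs$vaf <- ifelse(obs$depth > 0, obs$alt_reads / obs$depth, 0)
  events <- list()
  for (k in seq_len(nrow(pairs))) {
    oa <- filter(obs, .data$amplicon_id == pairs$amplicon_a[k],
                 .data$pos - 1L >= shared_start[k], .data$pos - 1L < shared_end[k])
    ob <- filter(obs, .data$amplicon_id == pairs$amplicon_b[k],
                 .data$pos - 1L >= shared_start[k], .data$pos - 1L < shared_end[k])
    if (nrow(oa) == 0 || nrow(ob) == 0) next
    j <- dplyr::inner_join(
      oa, ob,
      by = c("sample_id", "contig", "pos", "ref", "alt", "run_id"),
      suffix = c("_a", "_b"))
    if (nrow(j) == 0) next
    j <- filter(j, .data$depth_a >= config$min_depth,
                .data$depth_b >= config$min_depth)
    if (nrow(j) == 0) next
    sa <- .presence_status(j$vaf_a, config$presence_threshold)
    sb <- .presence_status(j$vaf_b, config$presence_threshold)
    hit <- sa != sb  # any class disagreement between the two amplicons
    if (!any(hit)) next
    jj <- j[hit, , drop = FALSE]
    type <- ifelse(sa[hit] == "absent" | sb[hit] == "absent",
                   "missing_marker", "underrepresented")
    events[[length(events) + 1]] <- tibble(
      sample_id = jj$sample_id,
      amplicon_ids = paste(pairs$amplicon_a[k], pairs$amplicon_b[k], sep = ";"),
      contig = jj$contig, pos = jj$pos, ref = jj$ref, alt = jj$alt,
      marker_variants = .site_key(jj$pos, jj$ref, jj$alt),
      event_type = type, evidence = "overlap_discordance",
      vaf = pmin(jj$vaf_a, jj$vaf_b), p_value = NA_real_,
      platform = "ngs",
      note = paste0("vaf ", signif(jj$vaf_a, 3), " on ", pairs$amplicon_a[k],
                    " vs ", signif(jj$vaf_b, 3), " on ", pairs$amplicon_b[k]))
  }
  if (!length(events)) return(.empty_events())
  arrange(bind_rows(events), .data$sample_id, .data$contig, .data$pos)
}

#' Compare genotype calls across platforms and runs
#'
#' Pairs calls for the same (sample, variant) made by different
#' (platform, run) sources.  A heterozygote on one side versus `hom_alt`
#' on the other is a `pseudo_homozygous` event attributed to the `hom_alt`
#' side (its wild-type allele dropped); het versus `hom_ref` is a
#' `missing_marker` event attributed to the `hom_ref` side.  Concordant
#' pairs, and hom/hom discordances (not a dropout signature), yield
#' nothing.  Variants present in only one call set are recorded in the
#' `coverage_gaps` attribute of the result, not as events.
#'
#' @param calls_a,calls_b Genotype-call tibbles ([read_genotypes()]).
#'   `calls_b` may be `NULL` if `calls_a` already mixes sources.
#' @return An event tibble; `attr(, "coverage_gaps")` lists unpaired
#'   (sample, variant) keys.
#' @export
compare_platforms <- function(calls_a, calls_b = NULL) {
  calls <- if (is.null(calls_b)) calls_a else bind_rows(calls_a, calls_b)
  if (is.null(calls$run_id)) calls$run_id <- "call"
  if (nrow(calls) == 0) {
    out <- .empty_events()
    attr(out, "coverage_gaps") <- tibble(sample_id = character(),
                                         contig = character(), pos = integer(),
                                         ref = character(), alt = character())
    return(out)
  }
  calls <- distinct(calls, .data$sample_id, .data$contig, .data$pos, .data$ref,
                    .data$alt, .data$platform, .data$run_id,
                    .keep_all = TRUE)
  key <- paste(calls$sample_id, calls$contig, calls$pos, calls$ref, calls$alt,
               sep = "\r")
  groups <- split(seq_len(nrow(calls)), key)
  events <- list()
  gaps <- list()
  for (g in groups) {
    if (length(g) < 2) {
      # seen by a single (platform, run) source: no comparison possible
      if (!is.null(calls_b)) {
        gaps[[length(gaps) + 1]] <- calls[g, c("sample_id", "contig", "pos",
                                               "ref", "alt")]
      }
      next
    }
    cg <- calls[g, , drop = FALSE]
    cb <- utils::combn(nrow(cg), 2)
    for (p in seq_len(ncol(cb))) {
      z1 <- cg$zygosity[cb[1, p]]; z2 <- cg$zygosity[cb[2, p]]
      if (z1 == z2) next
      zz <- c(z1, z2)
      if (!("het" %in% zz)) next  # hom_ref vs hom_alt: not a dropout signature
      hom_side <- cb[which(zz != "het"), p]
      type <- if (cg$zygosity[hom_side] == "hom_alt") "pseudo_homozygous"
              else "missing_marker"
      events[[length(events) + 1]] <- tibble(
        sample_id = cg$sample_id[1],
        amplicon_ids = NA_character_,
        contig = cg$contig[1], pos = cg$pos[1],
        ref = cg$ref[1], alt = cg$alt[1],
        marker_variants = .site_key(cg$pos[1], cg$ref[1], cg$alt[1]),
        event_type = type, evidence = "platform_discordance",
        vaf = NA_real_, p_value = NA_real_,
        platform = cg$platform[hom_side],
        note = paste0(cg$zygosity[hom_side], " on ", cg$platform[hom_side],
                      "/", cg$run_id[hom_side], " vs het on ",
                      cg$platform[cb[which(zz == "het"), p]], "/",
                      cg$run_id[cb[which(zz == "het"), p]]))
    }
  }
  out <- if (length(events)) {
    distinct(arrange(bind_rows(events), .data$sample_id, .data$contig,
                     .data$pos, .data$platform, .data$event_type),
             dplyr::across(-dplyr::all_of("note")), .keep_all = TRUE)
  } else .empty_events()
  attr(out, "coverage_gaps") <- if (length(gaps)) bind_rows(gaps) else
    tibble(sample_id = character(), contig = character(), pos = integer(),
           ref = character(), alt = character())
  out
}

#' Trio transmission check for apparent homozygosity
#'
#' A child genuinely homozygous for the alternate allele must have received
#' it from both parents, so each genotyped parent must carry at least one
#' alternate allele.  A `hom_ref` parent therefore contradicts a `hom_alt`
#' child: the child's wild-type allele exists but dropped out.  Only this
#' direction is checked — it is the dropout signature; general Mendelian
#' QC is out of scope.
#'
#' @param child_call Child zygosity (`hom_ref | het | hom_alt`).
#' @param mother_call,father_call Parent zygosities, `NA` when ungenotyped.
#' @return A list: `conflict` (logical) and `reason` (character, `NA` when
#'   no conflict) naming the contradicting parent(s).
#' @export
check_trio <- function(child_call, mother_call = NA, father_call = NA) {
  stopifnot(child_call %in% .zygosities,
            is.na(mother_call) || mother_call %in% .zygosities,
            is.na(father_call) || father_call %in% .zygosities)
  if (!identical(child_call, "hom_alt")) {
    return(list(conflict = FALSE, reason = NA_character_))
  }
  who <- c(if (isTRUE(mother_call == "hom_ref")) "mother",
           if (isTRUE(father_call == "hom_ref")) "father")
  if (length(who) == 0) return(list(conflict = FALSE, reason = NA_character_))
  list(conflict = TRUE,
       reason = paste0("child hom_alt but ", paste(who, collapse = " and "),
                       " hom_ref: obligate wild-type allele missing"))
}

# Trio-conflict events from a call table and a trio pedigree.
detect_trio_conflicts <- function(calls, trios) {
  if (is.null(trios) || nrow(trios) == 0 || nrow(calls) == 0) {
    return(.empty_events())
  }
  events <- list()
  vkey <- function(d) paste(d$contig, d$pos, d$ref, d$alt, sep = "\r")
  for (i in seq_len(nrow(trios))) {
    child <- filter(calls, .data$sample_id == trios$child[i],
                    .data$zygosity == "hom_alt")
    if (nrow(child) == 0) next
    for (j in seq_len(nrow(child))) {
      key <- vkey(child[j, ])
      parent_z <- function(id) {
        if (is.na(id)) return(NA_character_)
        pc <- calls[calls$sample_id == id & vkey(calls) == key, ]
        if (nrow(pc) == 0) return(NA_character_)
        # any hom_ref call from any platform/run contradicts
        if (any(pc$zygosity == "hom_ref")) "hom_ref" else pc$zygosity[1]
      }
      res <- check_trio("hom_alt", parent_z(trios$mother[i]),
                        parent_z(trios$father[i]))
      if (!res$conflict) next
      events[[length(events) + 1]] <- tibble(
        sample_id = child$sample_id[j],
        amplicon_ids = NA_character_,
        contig = child$contig[j], pos = child$pos[j],
        ref = child$ref[j], alt = child$alt[j],
        marker_variants = .site_key(child$pos[j], child$ref[j], child$alt[j]),
        event_type = "pseudo_homozygous", evidence = "trio_conflict",
        vaf = NA_real_, p_value = NA_real_,
        platform = child$platform[j],
        note = res$reason)
    }
  }
  if (!length(events)) return(.empty_events())
  distinct(arrange(bind_rows(events), .data$sample_id, .data$contig, .data$pos),
           dplyr::across(-dplyr::all_of("note")), .keep_all = TRUE)
}

#' Derive genotype calls from allele observations
#'
#' NGS observations call `hom_ref` below `presence_threshold`, `hom_alt`
#' above `1 - presence_threshold`, `het` between; observations below
#' `min_depth` yield no call.  Sanger observations (presence/absence
#' pseudo-counts) call het when both alleles are visible, the matching
#' homozygote when only one is.
#'
#' @param observations Observation tibble.
#' @param config Detection parameters.
#' @return A genotype-call tibble with `run_id` preserved.
#' @export
call_genotypes <- function(observations, config = detect_config()) {
  obs <- observations
  depth <- obs$ref_reads + obs$alt_reads
  ngs <- obs$platform == "ngs"
  keep <- (!ngs & depth > 0) | (ngs & depth >= config$min_depth)
  obs <- obs[keep, , drop = FALSE]
  depth <- depth[keep]
  vaf <- obs$alt_reads / depth
  zyg <- ifelse(vaf < config$presence_threshold, "hom_ref",
                ifelse(vaf > 1 - config$presence_threshold, "hom_alt", "het"))
  sg <- obs$platform == "sanger"
  zyg[sg] <- ifelse(obs$ref_reads[sg] > 0 & obs$alt_reads[sg] > 0, "het",
                    ifelse(obs$alt_reads[sg] > 0, "hom_alt", "hom_ref"))
  tibble(sample_id = obs$sample_id, contig = obs$contig, pos = obs$pos,
         ref = obs$ref, alt = obs$alt, zygosity = zyg,
         platform = obs$platform, run_id = obs$run_id)
}

#' Attach candidate causal primer-site variants to events
#'
#' Candidates are the screening findings on the event's amplicon(s),
#' ordered by positional tier (`three_prime_critical`, then `five_prime`,
#' then `internal`) and, within a tier, by descending heterozygous-carrier
#' probability.  The top candidate is flattened into `causal_pos,
#' causal_af, causal_tier`; the full ordered list is kept in the
#' `causal_candidates` list-column.
#'
#' @param events Event tibble.
#' @param findings Findings from [screen_panel()] on the same manifest.
#' @return The events, enriched (possibly with zero candidates).
#' @export
attribute_cause <- function(events, findings) {
  if (nrow(events) == 0) {
    events$causal_pos <- integer(0); events$causal_af <- double(0)
    events$causal_tier <- character(0); events$n_causal <- integer(0)
    events$causal_candidates <- list()
    return(events)
  }
  tier_rank <- match(findings$position_tier, .position_tiers)
  events$causal_candidates <- lapply(seq_len(nrow(events)), function(i) {
    amps <- strsplit(events$amplicon_ids[i], ";", fixed = TRUE)[[1]]
    f <- findings[findings$amplicon_id %in% amps, , drop = FALSE]
    if (nrow(f) == 0) return(f)
    r <- tier_rank[findings$amplicon_id %in% amps]
    f[order(r, -f$het_carrier_prob, f$pos), , drop = FALSE]
  })
  top <- function(col, default) {
    vapply(events$causal_candidates,
           function(f) if (nrow(f)) f[[col]][1] else default,
           default)
  }
  events$causal_pos <- top("pos", NA_integer_)
  events$causal_af <- top("af", NA_real_)
  events$causal_tier <- top("position_tier", NA_character_)
  events$n_causal <- vapply(events$causal_candidates, nrow, integer(1))
  events
}

# Map call-based events (no amplicon attached) to the manifest amplicons
# whose insert contains the variant position.
.fill_amplicons <- function(events, manifest) {
  need <- which(is.na(events$amplicon_ids))
  for (i in need) {
    p0 <- events$pos[i] - 1L
    hit <- manifest$contig == events$contig[i] &
      manifest$insert_start <= p0 & p0 < manifest$insert_end
    events$amplicon_ids[i] <- if (any(hit)) {
      paste(sort(manifest$amplicon_id[hit]), collapse = ";")
    } else ""
  }
  events
}

#' Run the full detection workflow
#'
#' Unions the four evidence channels, deduplicates by (sample, marker
#' variant) keeping the strongest evidence (`allele_balance <
#' overlap_discordance < platform_discordance < trio_conflict`), merges
#' events that share (sample, amplicons, type, evidence, platform) into
#' one event carrying all linked marker variants, and annotates causal
#' candidates.  Sanger observations are converted to per-run genotype
#' calls and folded into the platform-discordance channel, so run-to-run
#' loss of a heterozygous marker on one platform is also caught (dropout
#' is not reproducible between runs).
#'
#' With `config$fdr = TRUE` the allele-balance p-values are
#' Benjamini-Hochberg adjusted across all testable observations before
#' flagging.
#'
#' @param observations Observation tibble (NGS depths and/or Sanger
#'   pseudo-counts).
#' @param ngs_calls,orthogonal_calls Optional genotype-call tibbles.
#' @param trios Optional trio pedigree tibble.
#' @param manifest A validated manifest.
#' @param findings Optional findings from [screen_panel()] for cause
#'   attribution.
#' @param config Detection parameters ([detect_config()]).
#' @return An event tibble: `sample_id, amplicon_ids, contig, pos, ref,
#'   alt, marker_variants, event_type, evidence, vaf, p_value, platform,
#'   note, causal_*`, `needs_confirmation` (always `TRUE`: every event
#'   should be re-sequenced with an independent primer pair), in
#'   deterministic order.
#' @export
run_detection <- function(observations, ngs_calls = NULL,
                          orthogonal_calls = NULL, trios = NULL,
                          manifest, findings = NULL,
                          config = detect_config()) {
  validate_manifest(manifest)
  channels <- list()

  ngs_obs <- filter(observations, .data$platform == "ngs")
  if (nrow(ngs_obs)) {
    depth <- ngs_obs$ref_reads + ngs_obs$alt_reads
    testable <- ngs_obs$alt_reads >= 1L & depth >= config$min_depth
    tb <- ngs_obs[testable, , drop = FALSE]
    if (nrow(tb)) {
      res <- test_allele_balance(tb$ref_reads, tb$alt_reads,
                                 alpha = config$alpha,
                                 vaf_max = config$vaf_max,
                                 min_depth = config$min_depth)
      p_use <- if (config$fdr) stats::p.adjust(res$p_value, "BH") else res$p_value
      flag <- !is.na(p_use) & p_use < config$alpha & res$vaf < config$vaf_max
      if (any(flag)) {
        fb <- tb[flag, , drop = FALSE]
        channels$balance <- tibble(
          sample_id = fb$sample_id, amplicon_ids = fb$amplicon_id,
          contig = fb$contig, pos = fb$pos, ref = fb$ref, alt = fb$alt,
          marker_variants = .site_key(fb$pos, fb$ref, fb$alt),
          event_type = "underrepresented", evidence = "allele_balance",
          vaf = res$vaf[flag], p_value = res$p_value[flag],
          platform = "ngs",
          note = paste0(fb$alt_reads, "/", (fb$ref_reads + fb$alt_reads),
                        " alt reads on ", fb$amplicon_id, " run ", fb$run_id))
      }
    }
  }

  channels$overlap <- detect_overlap_discordance(observations, manifest, config)

  sanger_obs <- filter(observations, .data$platform == "sanger")
  derived <- if (nrow(sanger_obs)) call_genotypes(sanger_obs, config) else NULL
  all_calls <- bind_rows(ngs_calls, orthogonal_calls, derived)
  if (!is.null(all_calls) && nrow(all_calls)) {
    if (is.null(all_calls$run_id)) all_calls$run_id <- "call"
    all_calls$run_id[is.na(all_calls$run_id)] <- "call"
    channels$platform <- compare_platforms(all_calls)
    channels$trio <- detect_trio_conflicts(all_calls, trios)
  }

  events <- bind_rows(channels)
  if (nrow(events) == 0) {
    out <- attribute_cause(.empty_events(),
                           if (is.null(findings)) .empty_findings() else findings)
    out$needs_confirmation <- logical(0)
    return(out)
  }

  # strongest evidence per (sample, marker variant)
  events$strength <- match(events$evidence, .evidence_order)
  events <- events %>%
    group_by(.data$sample_id, .data$contig, .data$pos, .data$ref, .data$alt) %>%
    filter(.data$strength == max(.data$strength)) %>%
    dplyr::slice(1) %>%
    ungroup()
  events <- .fill_amplicons(events, manifest)

  # merge linked markers: one biological event can expose several markers
  # on the same amplicon(s) through the same channel
  events <- events %>%
    arrange(.data$sample_id, .data$contig, .data$pos) %>%
    group_by(.data$sample_id, .data$amplicon_ids, .data$contig,
             .data$event_type, .data$evidence, .data$platform) %>%
    summarise(marker_variants = paste(.data$marker_variants, collapse = ","),
              pos = .data$pos[1], ref = .data$ref[1], alt = .data$alt[1],
              vaf = .data$vaf[1], p_value = .data$p_value[1],
              note = .data$note[1], .groups = "drop") %>%
    select(dplyr::all_of(names(.empty_events()))) %>%
    arrange(.data$sample_id, .data$contig, .data$pos, .data$evidence)

  if (is.null(findings)) findings <- .empty_findings()
  events <- attribute_cause(events, findings)
  events$needs_confirmation <- TRUE
  events
}

.empty_findings <- function() {
  tibble(amplicon_id = character(), gene = character(), primer = character(),
         contig = character(), pos = integer(), ref = character(),
         alt = character(), af = double(), dist_3prime = integer(),
         position_tier = character(), freq_tier = character(),
         het_carrier_prob = double())
}

#' Write or read an events report
#'
#' The TSV drops the `causal_candidates` list-column (the flattened top
#' candidate remains); [events_to_json()] keeps full candidate lists.
#'
#' @param events Event tibble from [run_detection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  flat <- events[, setdiff(names(events), "causal_candidates")]
  write.table(flat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
events_to_json <- function(events, path) {
  lst <- lapply(seq_len(nrow(events)), function(i) {
    e <- as.list(events[i, setdiff(names(events), "causal_candidates")])
    e$causal_candidates <- events$causal_candidates[[i]]
    e
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
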