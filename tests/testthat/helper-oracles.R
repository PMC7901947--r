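# Independent oracles and small fixture builders used across test files.
# Oracles are deliberately naive (enumeration, double loops, direct tail
# sums) and never share code with the implementation they check.

# Two-sided exact binomial p-value against p = 0.5 by direct density
# summation: sum the probabilities of all outcomes no more likely than the
# observed one.
oracle_binom_p <- function(k, n) {
  d <- dbinom(0:n, n, 0.5)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# All overlapping insert pairs by an O(n^2) scan.
oracle_overlap_pairs <- function(manifest) {
  out <- list()
  n <- nrow(manifest)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (manifest$contig[i] == manifest$contig[j] &&
            manifest$insert_start[i] < manifest$insert_end[j] &&
            manifest$insert_start[j] < manifest$insert_end[i]) {
        out[[length(out) + 1]] <- c(manifest$amplicon_id[i],
                                    manifest$amplicon_id[j])
      }
    }
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, function(p) paste(sort(p), collapse = "|"), ""))
}

# Exhaustive (variant x primer site) containment scan; returns a sorted
# key per finding.
oracle_screen_keys <- function(manifest, variants, min_af = 0) {
  keys <- character(0)
  for (v in seq_len(nrow(variants))) {
    if (!(variants$af[v] >= min_af || variants$af[v] >= 1 - min_af)) next
    vs <- variants$pos[v] - 1
    ve <- vs + nchar(variants$ref[v])
    for (a in seq_len(nrow(manifest))) {
      if (manifest$contig[a] != variants$contig[v]) next
      if (vs < manifest$fwd_end[a] && ve > manifest$fwd_start[a]) {
        keys <- c(keys, paste(manifest$amplicon_id[a], "F",
                              variants$pos[v], variants$alt[v]))
      }
      if (vs < manifest$rev_end[a] && ve > manifest$rev_start[a]) {
        keys <- c(keys, paste(manifest$amplicon_id[a], "R",
                              variants$pos[v], variants$alt[v]))
      }
    }
  }
  sort(keys)
}

# Mendelian-transmission oracle for the dropout trio check: a child who
# appears hom_alt needs an alt allele from every genotyped parent, and a
# hom_ref parent has none to give.
oracle_trio_conflict <- function(child, mother, father) {
  if (child != "hom_alt") return(FALSE)
  can_give_alt <- function(z) is.na(z) || z %in% c("het", "hom_alt")
  !can_give_alt(mother) || !can_give_alt(father)
}

# One-amplicon manifest with symmetric primer sites.
mk_amplicon <- function(id = "amp1", contig = "chrT", insert_start = 1000L,
                        insert_len = 200L, site_len = 22L, gene = "GENE",
                        pool = 1L, panel_id = "toy") {
  tibble::tibble(
    amplicon_id = id, gene = gene, contig = contig,
    insert_start = insert_start, insert_end = insert_start + insert_len,
    fwd_start = insert_start - site_len, fwd_end = insert_start,
    rev_start = insert_start + insert_len,
    rev_end = insert_start + insert_len + site_len,
    pool = pool, panel_id = panel_id)
}

# Random valid manifest for property tests.
mk_random_manifest <- function(n, seed, n_contigs = 3) {
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      mk_amplicon(id = sprintf("ra%03d", i),
                  contig = paste0("chrT", sample.int(n_contigs, 1)),
                  insert_start = sample(100:5000, 1),
                  insert_len = sample(80:260, 1),
                  site_len = sample(15:40, 1))
    })
    dplyr::bind_rows(rows)
  })
}

# Random variant catalogue (SNVs plus some short indels) over a manifest's
# genomic territory.
mk_random_variants <- function(manifest, n, seed) {
  withr::with_seed(seed, {
    contigs <- sample(unique(manifest$contig), n, replace = TRUE)
    pos <- sample(50:5500, n, replace = TRUE)
    bases <- c("A", "C", "G", "T")
    ref <- vapply(seq_len(n), function(i) {
      paste(sample(bases, sample(c(1, 1, 1, 3), 1), replace = TRUE),
            collapse = "")
    }, "")
    alt <- vapply(ref, function(r) {
      a <- sample(bases, 1)
      while (a == r) a <- sample(bases, 1)
      a
    }, "")
    tibble::tibble(contig = contigs, pos = as.integer(pos), ref = ref,
                   alt = alt, af = round(runif(n), 3),
                   var_id = paste0("rv", seq_len(n)))
  })
}

mk_obs <- function(sample_id, amplicon_id, pos, ref_reads, alt_reads,
                   contig = "chrT", ref = "A", alt = "G",
                   platform = "ngs", run_id = "r1") {
  tibble::tibble(sample_id = sample_id, amplicon_id = amplicon_id,
                 contig = contig, pos = as.integer(pos),
                 ref_reads = as.integer(ref_reads),
                 alt_reads = as.integer(alt_reads),
                 ref = ref, alt = alt, platform = platform, run_id = run_id)
}

mk_call <- function(sample_id, zygosity, platform, pos = 1100L,
                    contig = "chrT", ref = "A", alt = "G", run_id = "call") {
  tibble::tibble(sample_id = sample_id, contig = contig, pos = as.integer(pos),
                 ref = ref, alt = alt, zygosity = zygosity,
                 platform = platform, run_id = run_id)
}
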