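#' Panel manifests, population variants and observation tables
#'
#' The panel manifest is the central object: one row per amplicon with the
#' insert interval (the sequenced target) and the forward/reverse primer
#' binding-site intervals that flank it.  A variant falling inside a primer
#' site can abolish annealing of one haplotype and cause allelic dropout;
#' a variant inside the insert is an observable "marker".
#'
#' On disk all coordinates are printed 1-based inclusive; in memory they are
#' 0-based half-open (see [from_printed()]).
#'
#' @name panel_model
NULL

.manifest_cols <- c("amplicon_id", "gene", "contig",
                    "insert_start", "insert_end",
                    "fwd_start", "fwd_end", "rev_start", "rev_end",
                    "pool", "panel_id")

#' Validate a panel manifest
#'
#' Checks the structural invariants every downstream stage relies on:
#' unique amplicon ids, well-formed intervals on a shared contig, primer
#' sites flanking the insert (`fwd_end <= insert_start`,
#' `insert_end <= rev_start`) and primer site lengths in 15-40 nt.
#'
#' @param manifest A tibble with internal (0-based half-open) coordinates.
#' @return The manifest, invisibly, if valid; otherwise an error naming the
#'   first offending row.
#' @export
validate_manifest <- function(manifest) {
  missing_cols <- setdiff(.manifest_cols, names(manifest))
  if (length(missing_cols)) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(manifest$amplicon_id)) {
    dup <- manifest$amplicon_id[duplicated(manifest$amplicon_id)][1]
    stop("duplicate amplicon_id: ", dup, call. = FALSE)
  }
  check_intervals(manifest$contig, manifest$insert_start, manifest$insert_end, "insert")
  check_intervals(manifest$contig, manifest$fwd_start, manifest$fwd_end, "fwd primer site")
  check_intervals(manifest$contig, manifest$rev_start, manifest$rev_end, "rev primer site")
  bad <- which(manifest$fwd_end > manifest$insert_start |
                 manifest$insert_end > manifest$rev_start)
  if (length(bad)) {
    stop(sprintf("primer sites do not flank insert at row %d (amplicon %s)",
                 bad[1], manifest$amplicon_id[bad[1]]), call. = FALSE)
  }
  flen <- manifest$fwd_end - manifest$fwd_start
  rlen <- manifest$rev_end - manifest$rev_start
  bad <- which(flen < 15L | flen > 40L | rlen < 15L | rlen > 40L)
  if (length(bad)) {
    stop(sprintf("primer site length outside [15, 40] at row %d (amplicon %s)",
                 bad[1], manifest$amplicon_id[bad[1]]), call. = FALSE)
  }
  invisible(manifest)
}

#' Read a panel manifest from TSV
#'
#' Expects a header row with columns `amplicon_id, gene, contig,
#' insert_start, insert_end, fwd_start, fwd_end, rev_start, rev_end, pool,
#' panel_id`, coordinates printed 1-based inclusive.  Row order is
#' preserved; coordinates are converted to the internal convention.
#'
#' @param path Path to a tab-separated manifest file.
#' @return A validated manifest tibble.
#' @export
read_panel_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path, call. = FALSE)
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(.manifest_cols, names(raw))
  if (length(missing_cols)) {
    stop("manifest is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  num_cols <- c("insert_start", "insert_end", "fwd_start", "fwd_end",
                "rev_start", "rev_end", "pool")
  for (cc in num_cols) {
    v <- suppressWarnings(as.integer(raw[[cc]]))
    if (anyNA(v)) {
      stop(sprintf("malformed manifest line %d: column '%s' is not an integer",
                   which(is.na(v))[1] + 1L, cc), call. = FALSE)
    }
    raw[[cc]] <- v
  }
  m <- as_tibble(raw)
  for (pair in list(c("insert_start", "insert_end"),
                    c("fwd_start", "fwd_end"),
                    c("rev_start", "rev_end"))) {
    conv <- from_printed(m[[pair[1]]], m[[pair[2]]])
    m[[pair[1]]] <- conv$start
    m[[pair[2]]] <- conv$end
  }
  validate_manifest(m)
  m
}

#' Write a panel manifest to TSV
#'
#' Inverse of [read_panel_manifest()]: coordinates are printed 1-based
#' inclusive.  Reading the written file yields a field-identical manifest.
#'
#' @param manifest A validated manifest tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  out <- manifest[, .manifest_cols]
  for (pair in list(c("insert_start", "insert_end"),
                    c("fwd_start", "fwd_end"),
                    c("rev_start", "rev_end"))) {
    conv <- to_printed(out[[pair[1]]], out[[pair[2]]])
    out[[pair[1]]] <- conv$start
    out[[pair[2]]] <- conv$end
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read population variants from a VCF
#'
#' Reads a VCF v4.x with an `AF` INFO key (gnomAD-style).  Multi-allelic
#' records are split into one row per alternate allele with its own AF.
#' Records lacking AF are kept with `af = 0` (treated as monomorphic) and a
#' warning, so screening still runs on sparse annotation.
#'
#' @param path Path to a VCF file.
#' @return A tibble with columns `contig, pos (1-based), ref, alt, af,
#'   var_id`, one row per (site, alt allele).
#' @export
read_population_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  empty <- tibble(contig = character(), pos = integer(), ref = character(),
                  alt = character(), af = double(), var_id = character())
  if (is.null(fix) || nrow(fix) == 0) return(empty)
  af_raw <- vcfR::extract.info(v, "AF")
  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    afs <- if (is.na(af_raw[i]) || !nzchar(af_raw[i])) {
      rep(NA_real_, length(alts))
    } else {
      suppressWarnings(as.numeric(strsplit(af_raw[i], ",", fixed = TRUE)[[1]]))
    }
    length(afs) <- length(alts)  # pad with NA if AF list is short
    tibble(contig = fix[i, "CHROM"],
           pos = as.integer(fix[i, "POS"]),
           ref = fix[i, "REF"],
           alt = alts,
           af = afs,
           var_id = if (is.na(fix[i, "ID"])) "." else fix[i, "ID"])
  })
  out <- bind_rows(rows)
  if (anyNA(out$af)) {
    warning(sum(is.na(out$af)), " variant record(s) lack AF; set to 0",
            call. = FALSE)
    out$af[is.na(out$af)] <- 0
  }
  if (any(out$af > 1 | out$af < 0)) {
    stop("AF outside [0, 1] at ", out$contig[which(out$af > 1 | out$af < 0)[1]],
         ":", out$pos[which(out$af > 1 | out$af < 0)[1]], call. = FALSE)
  }
  bad <- which(out$ref == out$alt | !grepl("^[ACGT]+$", out$ref) |
                 !grepl("^[ACGT]+$", out$alt))
  if (length(bad)) {
    stop("malformed REF/ALT at record ", bad[1], call. = FALSE)
  }
  out$var_id <- ifelse(out$var_id == ".",
                       paste0(out$contig, ":", out$pos, ":", out$ref, ">", out$alt),
                       out$var_id)
  out
}

#' Write population variants as a minimal VCF
#'
#' Emits a VCFv4.2 file with the single INFO key `AF`, one record per row
#' (no multi-allelic collapsing).  Used by the simulator to hand synthetic
#' population catalogues to the screening stage through the standard
#' format.
#'
#' @param variants Tibble as returned by [read_population_vcf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_population_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=adopanel",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t"))
  body <- if (nrow(variants)) {
    paste(variants$contig, variants$pos, variants$var_id, variants$ref,
          variants$alt, ".", "PASS",
          paste0("AF=", format(variants$af, trim = TRUE, scientific = FALSE)),
          sep = "\t")
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read or write per-amplicon allele observations
#'
#' Observations are one row per (sample, amplicon, variant, run):
#' `sample_id, amplicon_id, contig, pos, ref, alt, ref_reads, alt_reads,
#' platform, run_id`.  For `platform = "sanger"` the read counts are
#' presence/absence pseudo-counts in \{0, 1\} per allele, since a
#' chromatogram carries no depths.
#'
#' @param path Path to a tab-separated observations file.
#' @return A tibble of observations.
#' @export
read_observations <- function(path) {
  obs <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  req <- c("sample_id", "amplicon_id", "contig", "pos", "ref", "alt",
           "ref_reads", "alt_reads", "platform", "run_id")
  missing_cols <- setdiff(req, names(obs))
  if (length(missing_cols)) {
    stop("observations missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  obs$pos <- as.integer(obs$pos)
  obs$ref_reads <- as.integer(obs$ref_reads)
  obs$alt_reads <- as.integer(obs$alt_reads)
  obs$run_id <- as.character(obs$run_id)
  if (any(obs$ref_reads < 0 | obs$alt_reads < 0)) {
    stop("negative read counts in observations", call. = FALSE)
  }
  if (!all(obs$platform %in% .platforms)) {
    stop("platform must be one of: ", paste(.platforms, collapse = ", "),
         call. = FALSE)
  }
  sg <- obs$platform == "sanger"
  if (any(sg & (obs$ref_reads > 1L | obs$alt_reads > 1L))) {
    stop("sanger observations carry presence/absence pseudo-counts in {0, 1}",
         call. = FALSE)
  }
  obs
}

#' @rdname read_observations
#' @param obs Tibble of observations.
#' @export
write_observations <- function(obs, path) {
  write.table(obs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read or write genotype call tables
#'
#' Calls are one row per (sample, variant, platform[, run]):
#' `sample_id, contig, pos, ref, alt, zygosity, platform` with zygosity in
#' `hom_ref | het | hom_alt`.  Apparent hemizygosity is represented as
#' `hom_alt` from the platform that shows it, never as a fourth state.
#' An optional `run_id` column distinguishes repeated runs on the same
#' platform (dropout is not reproducible run to run).
#'
#' @param path Path to a tab-separated genotype file.
#' @return A tibble of genotype calls.
#' @export
read_genotypes <- function(path) {
  g <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
  req <- c("sample_id", "contig", "pos", "ref", "alt", "zygosity", "platform")
  missing_cols <- setdiff(req, names(g))
  if (length(missing_cols)) {
    stop("genotypes missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  g$pos <- as.integer(g$pos)
  if (!all(g$zygosity %in% .zygosities)) {
    stop("zygosity must be one of: ", paste(.zygosities, collapse = ", "),
         call. = FALSE)
  }
  if (!all(g$platform %in% .platforms)) {
    stop("platform must be one of: ", paste(.platforms, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(g$run_id)) g$run_id <- "call"
  g$run_id <- as.character(g$run_id)
  g
}

#' @rdname read_genotypes
#' @param calls Tibble of genotype calls.
#' @export
write_genotypes <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trio pedigree table
#'
#' Columns `child, mother, father`; empty strings or NA mark an absent
#' parent.  Ids within a row must be distinct.
#'
#' @param path Path to a tab-separated trio file.
#' @return A tibble with columns `child, mother, father` (NA for absent).
#' @export
read_trios <- function(path) {
  t <- as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                            colClasses = "character"))
  req <- c("child", "mother", "father")
  missing_cols <- setdiff(req, names(t))
  if (length(missing_cols)) {
    stop("trios missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  t$mother[!nzchar(t$mother) | is.na(t$mother)] <- NA_character_
  t$father[!nzchar(t$father) | is.na(t$father)] <- NA_character_
  for (i in seq_len(nrow(t))) {
    ids <- stats::na.omit(unlist(t[i, req]))
    if (anyDuplicated(ids)) stop("trio ids not distinct at row ", i, call. = FALSE)
  }
  t
}

#' Overlapping amplicon pairs
#'
#' All unordered pairs of amplicons whose *inserts* share at least one base
#' on the same contig.  Overlapping (tiled) amplicons observe a shared
#' variant twice, which is what makes single-amplicon dropout detectable.
#'
#' @param manifest A validated manifest.
#' @return A tibble with columns `amplicon_a, amplicon_b` (each unordered
#'   pair once, `amplicon_a` earlier in manifest order).
#' @export
overlapping_amplicon_pairs <- function(manifest) {
  validate_manifest(manifest)
  if (nrow(manifest) < 2) {
    return(tibble(amplicon_a = character(), amplicon_b = character()))
  }
  gr <- granges0(manifest$contig, manifest$insert_start, manifest$insert_end)
  hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  i <- S4Vectors::queryHits(hits)
  j <- S4Vectors::subjectHits(hits)
  a <- pmin(i, j)
  b <- pmax(i, j)
  ord <- order(a, b)
  tibble(amplicon_a = manifest$amplicon_id[a[ord]],
         amplicon_b = manifest$amplicon_id[b[ord]])
}
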