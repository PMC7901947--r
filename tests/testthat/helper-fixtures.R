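# one amplicon with a marker mid-insert and a causal SNV at the reverse
# primer 3' end; phase chosen by placing the two on the same or opposite
# haplotypes
phase_fixture <- function(phase = c("cis", "trans"), n = 1) {
  phase <- match.arg(phase)
  m <- mk_amplicon("ampP", insert_start = 1000L, insert_len = 200L)
  marker <- tibble::tibble(contig = "chrT", pos = 1101L, ref = "A", alt = "G")
  causal <- tibble::tibble(contig = "chrT", pos = m$rev_start + 2L,
                           ref = "C", alt = "T")
  ids <- sprintf("P%03d", seq_len(n))
  phased <- dplyr::bind_rows(
    tibble::tibble(sample_id = ids, contig = marker$contig, pos = marker$pos,
                   ref = marker$ref, alt = marker$alt, hap = "A"),
    tibble::tibble(sample_id = ids, contig = causal$contig, pos = causal$pos,
                   ref = causal$ref, alt = causal$alt,
                   hap = if (phase == "cis") "A" else "B"))
  list(manifest = m, phased = phased, marker = marker, causal = causal)
}
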