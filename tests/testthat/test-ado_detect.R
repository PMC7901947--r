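test_that("allele-balance test flags underrepresented markers, low side only", {
  r <- test_allele_balance(100, 100)
  expect_equal(r$vaf, 0.5)
  expect_false(r$flagged)

  r <- test_allele_balance(194, 6)   # the 3% marker
  expect_equal(r$vaf, 0.03)
  expect_true(r$flagged)

  r <- test_allele_balance(97, 3)
  expect_equal(r$p_value, oracle_binom_p(3, 100), tolerance = 1e-12)
  expect_equal(r$p_value, 2.63e-25, tolerance = 0.01)
  expect_true(r$flagged)

  # high side never flags: dropout hides the marker, it does not inflate it
  r <- test_allele_balance(3, 97)
  expect_true(r$p_value < 1e-3)
  expect_false(r$flagged)

  r <- test_allele_balance(5, 4)     # depth 9 < min_depth 20
  expect_false(r$testable)
  expect_false(r$flagged)
  expect_true(is.na(r$p_value))
})

test_that("balance p-values match the direct density-summation oracle", {
  for (n in c(10, 21, 50, 137, 256, 500)) {
    ks <- unique(c(0, 1, 2, n %/% 5, n %/% 3, n %/% 2, n - 1, n))
    r <- test_allele_balance(n - ks, ks, min_depth = 1)
    expected <- vapply(ks, oracle_binom_p, numeric(1), n = n)
    expect_equal(r$p_value, pmin(expected, 1), tolerance = 1e-12)
  }
})

test_that("decreasing the alt count never unflags at fixed depth", {
  n <- 200
  r <- test_allele_balance(n - (0:n), 0:n)
  flagged_k <- which(r$flagged) - 1
  expect_true(length(flagged_k) > 0)
  expect_equal(flagged_k, 0:max(flagged_k))  # contiguous from zero
})

test_that("overlap discordance fires on present/trace/absent disagreement only", {
  m <- dplyr::bind_rows(
    mk_amplicon("ampA", insert_start = 100L, insert_len = 200L),
    mk_amplicon("ampB", insert_start = 250L, insert_len = 200L))
  shared_pos <- 281L  # 1-based, inside both inserts

  both <- function(ra, aa, rb, ab) {
    dplyr::bind_rows(mk_obs("s1", "ampA", shared_pos, ra, aa),
                     mk_obs("s1", "ampB", shared_pos, rb, ab))
  }
  # the archetype: trace on one amplicon, absent on the other
  ev <- detect_overlap_discordance(both(171, 9, 180, 0), m)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_type, "missing_marker")
  expect_equal(ev$evidence, "overlap_discordance")
  expect_equal(ev$amplicon_ids, "ampA;ampB")

  expect_equal(nrow(detect_overlap_discordance(both(100, 100, 90, 110), m)), 0)
  expect_equal(nrow(detect_overlap_discordance(both(200, 0, 180, 0), m)), 0)

  ev <- detect_overlap_discordance(both(100, 100, 180, 0), m)  # present/absent
  expect_equal(ev$event_type, "missing_marker")
  ev <- detect_overlap_discordance(both(100, 100, 190, 10), m)  # present/trace
  expect_equal(ev$event_type, "underrepresented")
  expect_equal(ev$vaf, 0.05)

  # a side below min_depth is never compared
  expect_equal(nrow(detect_overlap_discordance(both(10, 0, 100, 100), m)), 0)
  # variant outside the shared interval is ignored
  off <- dplyr::bind_rows(mk_obs("s1", "ampA", 150L, 100, 100),
                          mk_obs("s1", "ampB", 150L, 180, 0))
  expect_equal(nrow(detect_overlap_discordance(off, m)), 0)
})

test_that("concordant tiled observations never produce events", {
  m <- dplyr::bind_rows(
    mk_amplicon("ampA", insert_start = 100L, insert_len = 200L),
    mk_amplicon("ampB", insert_start = 250L, insert_len = 200L))
  withr::with_seed(7, {
    obs <- dplyr::bind_rows(lapply(1:20, function(i) {
      v <- sample(c(0, 0.5, 1), 1)
      da <- 150 + sample(0:50, 1); db <- 150 + sample(0:50, 1)
      aa <- rbinom(1, da, v); ab <- rbinom(1, db, v)
      # redraw until both sides land in the same presence class
      cls <- function(x, d) if (x / d >= 0.1) "p" else if (x > 0) "t" else "a"
      while (cls(aa, da) != cls(ab, db)) ab <- rbinom(1, db, v)
      dplyr::bind_rows(
        mk_obs(paste0("s", i), "ampA", 281L, da - aa, aa),
        mk_obs(paste0("s", i), "ampB", 281L, db - ab, ab))
    }))
    expect_equal(nrow(detect_overlap_discordance(obs, m)), 0)
  })
})

test_that("platform comparison classifies het-vs-hom discordances", {
  ev <- compare_platforms(mk_call("s1", "het", "ngs"),
                          mk_call("s1", "hom_alt", "sanger"))
  expect_equal(ev$event_type, "pseudo_homozygous")
  expect_equal(ev$platform, "sanger")  # attributed to the hom_alt side

  ev <- compare_platforms(mk_call("s1", "het", "ngs"),
                          mk_call("s1", "hom_ref", "sanger"))
  expect_equal(ev$event_type, "missing_marker")
  expect_equal(ev$platform, "sanger")

  expect_equal(nrow(compare_platforms(mk_call("s1", "het", "ngs"),
                                      mk_call("s1", "het", "sanger"))), 0)
  expect_equal(nrow(compare_platforms(mk_call("s1", "hom_ref", "ngs"),
                                      mk_call("s1", "hom_alt", "sanger"))), 0)

  # symmetric in input order up to attribution labels
  a <- compare_platforms(mk_call("s1", "het", "ngs"),
                         mk_call("s1", "hom_alt", "sanger"))
  b <- compare_platforms(mk_call("s1", "hom_alt", "sanger"),
                         mk_call("s1", "het", "ngs"))
  expect_equal(as.data.frame(a), as.data.frame(b))

  # single-source variants are coverage gaps, not events
  ev <- compare_platforms(mk_call("s1", "het", "ngs"),
                          mk_call("s1", "het", "sanger", pos = 9999L))
  expect_equal(nrow(ev), 0)
  expect_equal(nrow(attr(ev, "coverage_gaps")), 2)
})

test_that("run-to-run loss on one platform raises missing_marker", {
  runs <- dplyr::bind_rows(mk_call("s1", "het", "sanger", run_id = "r1"),
                           mk_call("s1", "hom_ref", "sanger", run_id = "r2"),
                           mk_call("s1", "hom_ref", "sanger", run_id = "r3"))
  ev <- compare_platforms(runs)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_type, "missing_marker")
  expect_equal(ev$platform, "sanger")
})

test_that("trio check equals the transmission enumeration over all 27 states", {
  states <- c("hom_ref", "het", "hom_alt")
  for (ch in states) for (mo in c(states, NA)) for (fa in c(states, NA)) {
    got <- check_trio(ch, mo, fa)
    expect_identical(got$conflict, oracle_trio_conflict(ch, mo, fa),
                     info = paste(ch, mo, fa))
    if (got$conflict) expect_match(got$reason, "mother|father")
  }
  expect_false(check_trio("het", "hom_ref", "hom_ref")$conflict)
  expect_true(check_trio("hom_alt", "hom_ref", NA)$conflict)
})

test_that("causal candidates are ordered by positional tier then carrier probability", {
  ev <- tibble::tibble(sample_id = "s1", amplicon_ids = "amp1",
                       contig = "chrT", pos = 1100L, ref = "A", alt = "G",
                       marker_variants = "1100:A>G",
                       event_type = "underrepresented",
                       evidence = "allele_balance", vaf = 0.05,
                       p_value = 1e-10, platform = "ngs", note = "")
  f <- tibble::tibble(
    amplicon_id = "amp1", gene = "G", primer = c("F", "F", "R"),
    contig = "chrT", pos = c(990L, 995L, 1210L), ref = "C", alt = "T",
    af = c(0.3, 0.05, 0.2),
    dist_3prime = c(10L, 2L, 3L),
    position_tier = c("internal", "three_prime_critical",
                      "three_prime_critical"),
    freq_tier = "common",
    het_carrier_prob = het_carrier_prob(c(0.3, 0.05, 0.2)))
  out <- attribute_cause(ev, f)
  cand <- out$causal_candidates[[1]]
  # both 3'-critical first, higher carrier probability leading
  expect_equal(cand$pos, c(1210L, 995L, 990L))
  expect_equal(out$causal_tier, "three_prime_critical")
  expect_equal(out$causal_pos, 1210L)
  expect_equal(out$n_causal, 3L)

  none <- attribute_cause(ev, f[f$amplicon_id == "other", ])
  expect_equal(none$n_causal, 0L)
})

test_that("detection merges duplicate evidence keeping the strongest channel", {
  m <- dplyr::bind_rows(
    mk_amplicon("ampA", insert_start = 100L, insert_len = 200L),
    mk_amplicon("ampB", insert_start = 250L, insert_len = 200L))
  # same marker visible to allele balance (trace on ampA) and to overlap
  # discordance (absent on ampB)
  obs <- dplyr::bind_rows(mk_obs("s1", "ampA", 281L, 171, 9),
                          mk_obs("s1", "ampB", 281L, 180, 0))
  ev <- run_detection(obs, manifest = m)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$evidence, "overlap_discordance")
  expect_true(all(ev$needs_confirmation))

  empty <- run_detection(obs[0, ], manifest = m)
  expect_equal(nrow(empty), 0)
})

test_that("linked markers lost through one mechanism merge into one event", {
  m <- mk_amplicon("amp1")
  obs <- dplyr::bind_rows(
    mk_obs("s1", "amp1", 1100L, 0, 1, platform = "sanger"),
    mk_obs("s1", "amp1", 1120L, 0, 1, platform = "sanger", alt = "T"))
  ortho <- dplyr::bind_rows(
    mk_call("s1", "het", "ngs", pos = 1100L),
    mk_call("s1", "het", "ngs", pos = 1120L, alt = "T"))
  ev <- run_detection(obs, orthogonal_calls = ortho, manifest = m)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$event_type, "pseudo_homozygous")
  expect_match(ev$marker_variants, "1100:A>G,1120:A>T")
})

test_that("Benjamini-Hochberg option tempers borderline balance flags", {
  m <- mk_amplicon("amp1")
  # one strong signal among many borderline ones
  obs <- dplyr::bind_rows(
    mk_obs(paste0("s", 1:20), "amp1", 1100L, 78, 22),   # p ~ 2e-8 each
    mk_obs("s21", "amp1", 1100L, 194, 6))
  plain <- run_detection(obs, manifest = m)
  bh <- run_detection(obs, manifest = m, config = detect_config(fdr = TRUE))
  expect_true(nrow(bh) <= nrow(plain))
  expect_true("s21" %in% bh$sample_id)
})
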