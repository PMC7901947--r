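test_that("expected mismatched-allele fraction follows (1-e)/(2-e)", {
  expect_equal(expected_mismatch_fraction(0), 0.5)
  expect_equal(expected_mismatch_fraction(1), 0)
  expect_equal(expected_mismatch_fraction(0.9), 0.1 / 1.1)
  e <- seq(0, 1, by = 0.1)
  expect_true(all(diff(expected_mismatch_fraction(e)) < 0))
})

test_that("depth calibration hits the panel run metrics analytically and by Monte Carlo", {
  m <- calibrate_depth(192, 0.947, 0.7951)
  expect_equal(depth_model_mean(m), 192, tolerance = 1e-9)
  expect_equal(depth_model_tail(m, 20), 0.947, tolerance = 1e-6)
  expect_equal(depth_model_tail(m, 100), 0.7951, tolerance = 1e-6)
  expect_true(m$fail_prob > 0 && m$fail_prob < 0.053)

  withr::with_seed(99, {
    d <- draw_depths(2e5, m)
    expect_equal(mean(d), 192, tolerance = 0.005)        # 0.5% of target
    expect_equal(mean(d >= 20), 0.947, tolerance = 3e-3)
    expect_equal(mean(d >= 100), 0.7951, tolerance = 3e-3)
  })
})

test_that("calibration prefers the no-failure edge when the tails allow it", {
  # targets generated from a pure negative binomial are reachable at
  # fail_prob = 0, the preferred (fewest-mechanisms) solution
  pure <- depth_model(192, 1.3688, 0)
  m <- calibrate_depth(192, depth_model_tail(pure, 20),
                       depth_model_tail(pure, 100))
  expect_equal(m$fail_prob, 0)
  expect_equal(m$mean_depth, 192)

  expect_error(calibrate_depth(100, 1.0, 0.999), "p_ge")
  expect_error(calibrate_depth(100, 0.5, 0.6), "p_ge")
  expect_error(calibrate_depth(5, 0.9, 0.5), "infeasible")
})

test_that("phased genotypes converge to Hardy-Weinberg proportions", {
  v <- tibble::tibble(contig = "chrT", pos = 500L, ref = "A", alt = "G",
                      af = 0.5, var_id = "v1")
  expect_equal(nrow(sample_genotypes(dplyr::mutate(v, af = 0), 500, 1)), 0)

  for (af in c(0.5, 0.139)) {
    n <- 10000
    g <- sample_genotypes(dplyr::mutate(v, af = .env$af), n, 7)
    z <- phased_zygosity(g)
    het <- sum(z$zygosity == "het") / n
    p_het <- 2 * af * (1 - af)
    expect_equal(het, p_het, tolerance = 3 * sqrt(p_het * (1 - p_het) / n) / p_het)
  }
  expect_identical(sample_genotypes(v, 100, 3), sample_genotypes(v, 100, 3))
})

test_that("a cis complete dropout erases the marker in every run", {
  fx <- phase_fixture("cis", n = 5)
  sim <- simulate_observations(fx$manifest, fx$phased,
                               dropout_model(epsilon = 1),
                               depth_model(200, 1e6), n_runs = 4, seed = 11)
  expect_true(all(sim$observations$alt_reads == 0))
  expect_true(all(sim$truth$mechanism == "complete_dropout"))
  expect_equal(nrow(sim$truth), 5 * 4)  # one dropped haplotype per run
})

test_that("a trans complete dropout makes the marker look homozygous", {
  fx <- phase_fixture("trans")
  sim <- simulate_observations(fx$manifest, fx$phased,
                               dropout_model(epsilon = 1),
                               depth_model(200, 1e6), n_runs = 1, seed = 12)
  expect_true(all(sim$observations$ref_reads == 0))
  sg <- simulate_observations(fx$manifest, fx$phased,
                              dropout_model(epsilon = 1),
                              depth_model(200, 1e6), platform = "sanger",
                              n_runs = 1, seed = 12)
  z <- call_genotypes(sg$observations)
  expect_equal(z$zygosity, "hom_alt")  # apparent hemizygosity
})

test_that("marker fraction moves monotonically with epsilon, by phase", {
  eps_grid <- c(0, 0.3, 0.6, 0.9)
  mean_vaf <- function(phase) {
    vapply(eps_grid, function(e) {
      fx <- phase_fixture(phase, n = 20)
      sim <- simulate_observations(
        fx$manifest, fx$phased,
        dropout_model(epsilon = e, complete_prob = 0),
        depth_model(1e4, 1e6), n_runs = 1, seed = 21)
      obs <- dplyr::filter(sim$observations, pos == fx$marker$pos)
      mean(obs$alt_reads / (obs$ref_reads + obs$alt_reads))
    }, numeric(1))
  }
  cis <- mean_vaf("cis")
  expect_true(all(diff(cis) < 0))          # marker rides the dropped allele
  expect_equal(cis[4], expected_mismatch_fraction(0.9), tolerance = 0.02)
  trans <- mean_vaf("trans")
  expect_true(all(diff(trans) > 0))        # wild-type allele drops instead
  expect_true(trans[4] > 0.85)
})

test_that("epsilon zero is a clean null: balanced hets, empty truth table", {
  fx <- phase_fixture("cis", n = 30)
  sim <- simulate_observations(fx$manifest, fx$phased,
                               dropout_model(epsilon = 0),
                               depth_model(192, 5), n_runs = 1, seed = 31)
  expect_equal(nrow(sim$truth), 0)
  obs <- dplyr::filter(sim$observations, pos == fx$marker$pos,
                       ref_reads + alt_reads >= 50)
  expect_equal(mean(obs$alt_reads / (obs$ref_reads + obs$alt_reads)), 0.5,
               tolerance = 0.05)
})

test_that("sanger chromatograms hide alleles below the detection floor", {
  fx <- phase_fixture("cis")
  # epsilon 0.8 -> mismatch fraction 1/6 = 0.167: visible at floor 0.15,
  # hidden at floor 0.20
  sim1 <- simulate_observations(fx$manifest, fx$phased,
                                dropout_model(epsilon = 0.8, complete_prob = 0),
                                depth_model(200, 1e6), platform = "sanger",
                                n_runs = 1, seed = 41, sanger_floor = 0.15)
  expect_equal(sim1$observations$alt_reads, 1L)
  sim2 <- simulate_observations(fx$manifest, fx$phased,
                                dropout_model(epsilon = 0.8, complete_prob = 0),
                                depth_model(200, 1e6), platform = "sanger",
                                n_runs = 1, seed = 41, sanger_floor = 0.20)
  expect_equal(sim2$observations$alt_reads, 0L)
  expect_true(all(sim2$observations$ref_reads == 1L))
})

test_that("simulation and fixtures are byte-identical under a repeated seed", {
  fx <- phase_fixture("cis", n = 10)
  s1 <- simulate_observations(fx$manifest, fx$phased, dropout_model(0.7),
                              depth_model(192, 3, 0.05), n_runs = 2, seed = 5)
  s2 <- simulate_observations(fx$manifest, fx$phased, dropout_model(0.7),
                              depth_model(192, 3, 0.05), n_runs = 2, seed = 5)
  expect_identical(s1, s2)
  f1 <- make_fixture("TABLE1", 9)
  f2 <- make_fixture("TABLE1", 9)
  expect_identical(f1, f2)
  expect_false(identical(f1$observations,
                         make_fixture("TABLE1", 10)$observations))
})

test_that("presets reproduce the panel geometry they advertise", {
  full <- make_panel("FULL", 2)
  expect_equal(nrow(full$manifest), 1049)
  expect_equal(length(unique(full$manifest$gene)), 37)
  total <- sum(full$manifest$insert_end - full$manifest$insert_start)
  expect_true(abs(total - 153000) <= 1530)  # within 1%
  expect_equal(sort(unique(full$manifest$pool)), c(1, 2))

  p1 <- make_panel("PANEL1", 2)
  expect_equal(nrow(p1$manifest), 521)
  f <- screen_panel(p1$manifest, p1$variants)
  expect_setequal(unique(f$amplicon_id), p1$risk_amplicons)

  t1 <- make_panel("TABLE1", 2)
  printed <- to_printed(t1$manifest$insert_start[1], t1$manifest$insert_end[1])
  expect_equal(c(printed$start, printed$end), c(38597041L, 38597372L))
  expect_error(make_panel("NOPE", 1), "arg")
})

test_that("null simulation keeps the detector's false-positive rate below alpha", {
  # 200 heterozygous samples, no dropout anywhere
  v <- tibble::tibble(contig = "chrT", pos = 1101L, ref = "A", alt = "G",
                      af = 0.5, var_id = "m")
  m <- mk_amplicon("ampN")
  g <- sample_genotypes(v, 200, 55)
  sim <- simulate_observations(m, g, dropout_model(epsilon = 0),
                               depth_model(192, 5), n_runs = 1, seed = 56)
  ev <- run_detection(sim$observations, manifest = m)
  n_tests <- sum(sim$observations$alt_reads >= 1 &
                   sim$observations$ref_reads + sim$observations$alt_reads >= 20)
  alpha <- 0.001
  bound <- alpha * n_tests + 3 * sqrt(alpha * n_tests)
  expect_true(nrow(ev) <= bound)
})

test_that("complete dropouts at depth >= 100 are recovered through orthogonal calls", {
  v <- tibble::tibble(contig = "chrT",
                      pos = c(1101L, 1202L),  # marker; causal at rev 3' end
                      ref = c("A", "C"), alt = c("G", "T"),
                      af = 0.5, var_id = c("m", "c"))
  m <- mk_amplicon("ampR", insert_start = 1000L, insert_len = 200L)
  g <- sample_genotypes(v, 120, 61)
  sim <- simulate_observations(m, g, dropout_model(epsilon = 1),
                               depth_model(150, 1e6), n_runs = 1, seed = 62)
  # orthogonal truth: per-sample zygosity from the phased genotypes
  z <- phased_zygosity(g)
  ortho <- dplyr::mutate(dplyr::filter(z, pos == 1101L),
                         platform = "sanger", run_id = "truth")
  ngs_calls <- call_genotypes(sim$observations)
  ev <- run_detection(sim$observations, ngs_calls = ngs_calls,
                      orthogonal_calls = ortho, manifest = m)
  # recoverable cases: heterozygous marker with exactly one haplotype dropped
  zw <- tidyr::pivot_wider(g, id_cols = "sample_id", names_from = "pos",
                           values_from = "hap",
                           values_fn = function(x) paste(sort(x), collapse = ""))
  zw <- zw[!is.na(zw$`1101`) & zw$`1101` %in% c("A", "B") &
             !is.na(zw$`1202`) & zw$`1202` %in% c("A", "B"), ]
  expect_gte(nrow(zw), 20)
  recovered <- mean(zw$sample_id %in% ev$sample_id)
  expect_gte(recovered, 0.95)
})
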