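#' Phased-haplotype dropout simulator
#'
#' Generates synthetic amplicon panels, population variant catalogues,
#' Hardy-Weinberg phased cohorts and per-amplicon allele observations
#' under an explicit allele-specific amplification-efficiency model: a
#' haplotype carrying a variant under one of an amplicon's primers
#' amplifies with efficiency `1 - epsilon_eff`, where `epsilon_eff` scales
#' with the mismatch position tier and may escalate to complete dropout
#' per run (dropout is a stochastic, run-level process).
#'
#' @name ado_sim
NULL

#' Dropout model parameters
#'
#' `epsilon` is the amplification-efficiency loss of a haplotype mismatched
#' under a primer (1 = complete dropout).  `tier_multiplier` scales
#' `epsilon` by the mismatch position: the 3'-terminal window is fully
#' penalised, the 5' window and internal positions less so (no
#' quantitative per-position efficiencies are established in the
#' literature; these are model assumptions, exposed here).
#' `complete_prob` is the per-run probability that a partial-dropout locus
#' drops completely, reproducing run-to-run inconsistency.
#'
#' @param epsilon Efficiency loss in `[0, 1]`.
#' @param complete_prob Per-run complete-dropout escalation probability.
#' @param tier_multiplier Named multipliers for the three position tiers.
#' @return A `dropout_model` list.
#' @export
dropout_model <- function(epsilon = 1, complete_prob = 0.5,
                          tier_multiplier = c(three_prime_critical = 1,
                                              five_prime = 0.8,
                                              internal = 0.5)) {
  stopifnot(epsilon >= 0, epsilon <= 1,
            complete_prob >= 0, complete_prob <= 1,
            all(.position_tiers %in% names(tier_multiplier)),
            all(tier_multiplier >= 0 & tier_multiplier <= 1))
  structure(list(epsilon = epsilon, complete_prob = complete_prob,
                 tier_multiplier = tier_multiplier),
            class = "dropout_model")
}

#' Read-depth model: failed-amplicon / negative-binomial mixture
#'
#' With probability `fail_prob` an amplicon yields near-zero depth
#' (uniform on 0-19 reads); otherwise depth is negative binomial with mean
#' `mean_depth` and dispersion `nb_size`.
#'
#' @param mean_depth Mean of the non-failed (negative binomial) component.
#' @param nb_size Negative binomial size (dispersion) parameter.
#' @param fail_prob Probability of amplicon failure.
#' @return A `depth_model` list.
#' @export
depth_model <- function(mean_depth, nb_size, fail_prob = 0) {
  stopifnot(mean_depth > 0, nb_size > 0, fail_prob >= 0, fail_prob <= 1)
  structure(list(mean_depth = mean_depth, nb_size = nb_size,
                 fail_prob = fail_prob),
            class = "depth_model")
}

#' Analytic moments of a depth model
#'
#' `depth_model_mean()` is the mixture mean
#' `fail_prob * 9.5 + (1 - fail_prob) * mean_depth`;
#' `depth_model_tail(model, k)` is `P(depth >= k)`.
#'
#' @param model A [depth_model()].
#' @param k Non-negative integer threshold(s).
#' @return Numeric.
#' @export
depth_model_mean <- function(model) {
  model$fail_prob * 9.5 + (1 - model$fail_prob) * model$mean_depth
}

#' @rdname depth_model_mean
#' @export
depth_model_tail <- function(model, k) {
  p_unif <- pmax(0, pmin(1, (20 - k) / 20))  # P(U{0..19} >= k)
  p_nb <- pnbinom(k - 1, mu = model$mean_depth, size = model$nb_size,
                  lower.tail = FALSE)
  model$fail_prob * p_unif + (1 - model$fail_prob) * p_nb
}

#' Draw per-amplicon depths
#'
#' @param n Number of draws.
#' @param model A [depth_model()].
#' @return Integer vector of depths.
#' @export
draw_depths <- function(n, model) {
  fail <- runif(n) < model$fail_prob
  d <- rnbinom(n, mu = model$mean_depth, size = model$nb_size)
  d[fail] <- sample(0:19, sum(fail), replace = TRUE)
  d
}

#' Calibrate the depth model to run metrics
#'
#' Solves for `(mean_depth, nb_size, fail_prob)` so that the mixture's
#' analytic mean equals `mean_target` (exactly, by construction) and the
#' two tail probabilities `P(depth >= 20)` and `P(depth >= 100)` hit their
#' targets within `1e-6` absolute.  If the tails are achievable with
#' `fail_prob = 0` (tail mismatch within 1e-3), that edge solution is
#' preferred — fewest mechanisms.  The solve is deterministic (no
#' sampling).
#'
#' @param mean_target Target mean reads per amplicon.
#' @param p_ge20_target Target `P(depth >= 20)`, in `(0, 1)`.
#' @param p_ge100_target Target `P(depth >= 100)`, must be `< p_ge20_target`.
#' @return A calibrated [depth_model()].
#' @export
calibrate_depth <- function(mean_target, p_ge20_target, p_ge100_target) {
  if (!(p_ge100_target > 0 && p_ge100_target < p_ge20_target &&
          p_ge20_target < 1)) {
    stop("need 0 < p_ge100_target < p_ge20_target < 1", call. = FALSE)
  }
  if (mean_target <= 9.5) {
    stop("mean_target infeasible: mixture mean cannot fall below the failed ",
         "component alone", call. = FALSE)
  }
  targets <- c(p_ge20_target, p_ge100_target)
  tails_at <- function(f, size) {
    mu <- (mean_target - 9.5 * f) / (1 - f)
    m <- depth_model(mu, size, f)
    c(depth_model_tail(m, 20), depth_model_tail(m, 100))
  }
  # edge: no failed component
  g <- function(s) tails_at(0, s)[1] - p_ge20_target
  lo <- 1e-3; hi <- 1e5
  if (g(lo) * g(hi) < 0) {
    r <- uniroot(g, c(lo, hi), tol = 1e-12)
    t0 <- tails_at(0, r$root)
    if (abs(t0[2] - p_ge100_target) <= 1e-3) {
      return(depth_model(mean_target, r$root, 0))
    }
  }
  obj <- function(par) {
    f <- plogis(par[1])
    if (f >= 1 || mean_target - 9.5 * f <= 0) return(1e6)
    sum((tails_at(f, exp(par[2])) - targets)^2)
  }
  fit <- optim(c(qlogis(0.05), log(3)), obj, method = "Nelder-Mead",
               control = list(maxit = 10000, reltol = 1e-16))
  fit <- optim(fit$par, obj, method = "Nelder-Mead",
               control = list(maxit = 10000, reltol = 1e-16))
  f <- plogis(fit$par[1]); size <- exp(fit$par[2])
  mu <- (mean_target - 9.5 * f) / (1 - f)
  got <- tails_at(f, size)
  resid <- abs(got - targets)
  if (any(resid > 1e-6)) {
    which_bad <- c("P(depth >= 20)", "P(depth >= 100)")[which.max(resid)]
    stop("calibration infeasible: ", which_bad, " off target by ",
         signif(max(resid), 3), call. = FALSE)
  }
  depth_model(mu, size, f)
}

#' Expected mismatched-allele read fraction under partial dropout
#'
#' With the matched haplotype at efficiency 1 and the mismatched one at
#' `1 - epsilon`, the mismatched allele's expected share of reads is
#' `(1 - epsilon) / (2 - epsilon)`: 0.5 at no dropout, 0 at complete
#' dropout.
#'
#' @param epsilon Efficiency loss in `[0, 1]`.
#' @return Expected fraction in `[0, 0.5]`.
#' @export
expected_mismatch_fraction <- function(epsilon) {
  stopifnot(all(epsilon >= 0 & epsilon <= 1))
  (1 - epsilon) / (2 - epsilon)
}

#' Sample phased genotypes under Hardy-Weinberg equilibrium
#'
#' Each of a sample's two haplotypes carries each variant independently
#' with probability `af`, so genotype frequencies follow Hardy-Weinberg
#' proportions.
#'
#' @param variants Population variant tibble (`contig, pos, ref, alt, af`).
#' @param n_samples Number of samples.
#' @param seed Integer seed; same seed, same cohort.
#' @param prefix Sample-id prefix.
#' @return A phased-genotype tibble: one row per carried (sample, variant,
#'   haplotype), columns `sample_id, contig, pos, ref, alt, hap` (`"A"` or
#'   `"B"`); homozygotes appear on both haplotypes.
#' @export
sample_genotypes <- function(variants, n_samples, seed, prefix = "S") {
  stopifnot(all(variants$af >= 0 & variants$af <= 1))
  withr::with_seed(seed, {
    ids <- sprintf("%s%04d", prefix, seq_len(n_samples))
    rows <- lapply(seq_len(nrow(variants)), function(i) {
      carA <- runif(n_samples) < variants$af[i]
      carB <- runif(n_samples) < variants$af[i]
      bind_rows(
        tibble(sample_id = ids[carA], contig = variants$contig[i],
               pos = variants$pos[i], ref = variants$ref[i],
               alt = variants$alt[i], hap = "A"),
        tibble(sample_id = ids[carB], contig = variants$contig[i],
               pos = variants$pos[i], ref = variants$ref[i],
               alt = variants$alt[i], hap = "B"))
    })
    out <- bind_rows(rows)
    if (nrow(out)) out <- arrange(out, .data$sample_id, .data$contig,
                                  .data$pos, .data$hap)
    out
  })
}

#' Zygosity table from phased genotypes
#'
#' @param phased Phased-genotype tibble ([sample_genotypes()]).
#' @return One row per (sample, variant) with `zygosity` (`het` or
#'   `hom_alt`; non-carriers are not listed).
#' @export
phased_zygosity <- function(phased) {
  if (nrow(phased) == 0) {
    return(tibble(sample_id = character(), contig = character(),
                  pos = integer(), ref = character(), alt = character(),
                  zygosity = character()))
  }
  phased %>%
    group_by(.data$sample_id, .data$contig, .data$pos, .data$ref, .data$alt) %>%
    summarise(zygosity = ifelse(dplyr::n_distinct(.data$hap) == 2,
                                "hom_alt", "het"),
              .groups = "drop")
}

# Effective epsilon of each (amplicon, haplotype) given carried primer-site
# variants: the worst (max) tier-scaled epsilon over the haplotype's
# variants under that amplicon's primers.
.primer_site_epsilons <- function(manifest, phased, dropout) {
  if (nrow(phased) == 0) {
    return(tibble(sample_id = character(), amplicon_id = character(),
                  hap = character(), eps = double(), causal_pos = integer()))
  }
  sites <- bind_rows(
    tibble(amplicon_id = manifest$amplicon_id, contig = manifest$contig,
           start = manifest$fwd_start, end = manifest$fwd_end,
           tp = manifest$fwd_end - 1L),
    tibble(amplicon_id = manifest$amplicon_id, contig = manifest$contig,
           start = manifest$rev_start, end = manifest$rev_end,
           tp = manifest$rev_start))
  vgr <- granges0(phased$contig, phased$pos - 1L,
                  phased$pos - 1L + nchar(phased$ref))
  sgr <- granges0(sites$contig, sites$start, sites$end)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(vgr, sgr))
  if (length(hits) == 0) {
    return(tibble(sample_id = character(), amplicon_id = character(),
                  hap = character(), eps = double(), causal_pos = integer()))
  }
  vi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  d3 <- dist_to_3prime(phased$pos[vi] - 1L,
                       phased$pos[vi] - 1L + nchar(phased$ref[vi]),
                       sites$start[si], sites$end[si], sites$tp[si])
  tier <- classify_position(d3, sites$end[si] - sites$start[si])
  tibble(sample_id = phased$sample_id[vi],
         amplicon_id = sites$amplicon_id[si],
         hap = phased$hap[vi],
         eps = dropout$epsilon * unname(dropout$tier_multiplier[tier]),
         causal_pos = phased$pos[vi]) %>%
    group_by(.data$sample_id, .data$amplicon_id, .data$hap) %>%
    dplyr::slice_max(.data$eps, n = 1, with_ties = FALSE) %>%
    ungroup()
}

#' Simulate per-amplicon allele observations
#'
#' Per (sample, amplicon, run): a depth is drawn from the depth model;
#' each haplotype carrying a variant under that amplicon's primers gets
#' efficiency `1 - epsilon_eff` (tier-scaled, escalated to complete
#' dropout with probability `complete_prob` per run); total depth is
#' thinned by the mean haplotype efficiency; alt reads for every insert
#' variant the sample carries are binomial with success probability equal
#' to the carrying haplotypes' efficiency share.  For
#' `platform = "sanger"` counts become presence/absence pseudo-counts: an
#' allele is visible only if its expected fraction reaches `sanger_floor`
#' (a chromatogram hides small minor peaks).
#'
#' @param manifest A validated manifest.
#' @param phased Phased-genotype tibble ([sample_genotypes()]).
#' @param dropout A [dropout_model()].
#' @param depth A [depth_model()].
#' @param platform `"ngs"` or `"sanger"`.
#' @param n_runs Runs per (sample, amplicon); run ids `r1, r2, ...`.
#' @param seed Integer seed.
#' @param sanger_floor Chromatogram detection floor (expected fraction).
#' @return A list: `observations` (the standard observation tibble) and
#'   `truth` — one row per (sample, amplicon, run, haplotype) with a
#'   planted efficiency loss: `sample_id, amplicon_id, run_id, hap,
#'   mechanism (partial_dropout | complete_dropout), epsilon_effective,
#'   causal_pos, platform`.
#' @export
simulate_observations <- function(manifest, phased, dropout, depth,
                                  platform = "ngs", n_runs = 1, seed = 1,
                                  sanger_floor = 0.15) {
  validate_manifest(manifest)
  stopifnot(platform %in% .platforms, n_runs >= 1)
  eps_tbl <- .primer_site_epsilons(manifest, phased, dropout)

  # insert (marker) content per sample and amplicon
  empty_obs <- tibble(sample_id = character(), amplicon_id = character(),
                      contig = character(), pos = integer(), ref = character(),
                      alt = character(), ref_reads = integer(),
                      alt_reads = integer(), platform = character(),
                      run_id = character())
  empty_truth <- tibble(sample_id = character(), amplicon_id = character(),
                        run_id = character(), hap = character(),
                        mechanism = character(), epsilon_effective = double(),
                        causal_pos = integer(), platform = character())
  if (nrow(phased) == 0) {
    return(list(observations = empty_obs, truth = empty_truth))
  }
  zyg <- phased %>%
    group_by(.data$sample_id, .data$contig, .data$pos, .data$ref, .data$alt) %>%
    summarise(on_A = any(.data$hap == "A"), on_B = any(.data$hap == "B"),
              .groups = "drop")
  vgr <- granges0(zyg$contig, zyg$pos - 1L, zyg$pos - 1L + nchar(zyg$ref))
  igr <- granges0(manifest$contig, manifest$insert_start, manifest$insert_end)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(vgr, igr, type = "within"))
  if (length(hits) == 0) {
    return(list(observations = empty_obs, truth = empty_truth))
  }
  vi <- S4Vectors::queryHits(hits); ai <- S4Vectors::subjectHits(hits)
  content <- tibble(zyg[vi, ], amplicon_id = manifest$amplicon_id[ai])

  withr::with_seed(seed, {
    obs <- list(); truth <- list()
    # unit of simulation: (sample, amplicon) cells that have any marker
    cells <- distinct(content, .data$sample_id, .data$amplicon_id)
    cells <- left_join(cells,
                       tidyr::pivot_wider(eps_tbl,
                                          id_cols = c("sample_id", "amplicon_id"),
                                          names_from = "hap",
                                          values_from = c("eps", "causal_pos")),
                       by = c("sample_id", "amplicon_id"))
    for (col in c("eps_A", "eps_B")) {
      if (is.null(cells[[col]])) cells[[col]] <- 0
      cells[[col]][is.na(cells[[col]])] <- 0
    }
    for (col in c("causal_pos_A", "causal_pos_B")) {
      if (is.null(cells[[col]])) cells[[col]] <- NA_integer_
    }
    cells <- arrange(cells, .data$sample_id, .data$amplicon_id)
    for (r in seq_len(n_runs)) {
      run <- paste0("r", r)
      eps_A <- cells$eps_A
      eps_B <- cells$eps_B
      esc_A <- eps_A > 0 & eps_A < 1 & runif(nrow(cells)) < dropout$complete_prob
      esc_B <- eps_B > 0 & eps_B < 1 & runif(nrow(cells)) < dropout$complete_prob
      eps_A[esc_A] <- 1; eps_B[esc_B] <- 1
      w_A <- 1 - eps_A; w_B <- 1 - eps_B
      d <- draw_depths(nrow(cells), depth)
      d_eff <- rbinom(nrow(cells), d, (w_A + w_B) / 2)
      ci <- match(paste(content$sample_id, content$amplicon_id),
                  paste(cells$sample_id, cells$amplicon_id))
      wsum <- w_A[ci] + w_B[ci]
      f <- ifelse(wsum > 0,
                  (w_A[ci] * content$on_A + w_B[ci] * content$on_B) / wsum, 0)
      if (platform == "ngs") {
        n_alt <- rbinom(nrow(content), d_eff[ci], f)
        o <- tibble(sample_id = content$sample_id,
                    amplicon_id = content$amplicon_id,
                    contig = content$contig, pos = content$pos,
                    ref = content$ref, alt = content$alt,
                    ref_reads = d_eff[ci] - n_alt, alt_reads = n_alt,
                    platform = "ngs", run_id = run)
      } else {
        o <- tibble(sample_id = content$sample_id,
                    amplicon_id = content$amplicon_id,
                    contig = content$contig, pos = content$pos,
                    ref = content$ref, alt = content$alt,
                    ref_reads = as.integer(1 - f >= sanger_floor),
                    alt_reads = as.integer(f >= sanger_floor),
                    platform = "sanger", run_id = run)
      }
      obs[[r]] <- o
      planted <- which(eps_A > 0 | eps_B > 0)
      if (length(planted)) {
        tr <- lapply(c("A", "B"), function(h) {
          e <- if (h == "A") eps_A else eps_B
          cp <- if (h == "A") cells$causal_pos_A else cells$causal_pos_B
          k <- which(e > 0)
          if (!length(k)) return(NULL)
          tibble(sample_id = cells$sample_id[k],
                 amplicon_id = cells$amplicon_id[k],
                 run_id = run, hap = h,
                 mechanism = ifelse(e[k] >= 1, "complete_dropout",
                                    "partial_dropout"),
                 epsilon_effective = e[k],
                 causal_pos = cp[k], platform = platform)
        })
        truth[[length(truth) + 1]] <- bind_rows(tr)
      }
    }
    observations <- arrange(bind_rows(obs), .data$sample_id,
                            .data$amplicon_id, .data$run_id, .data$pos)
    truth <- if (length(truth)) {
      arrange(bind_rows(truth), .data$sample_id, .data$amplicon_id,
              .data$run_id, .data$hap)
    } else empty_truth
    list(observations = observations, truth = truth)
  })
}
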