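test_that("poly-C runs are maximal, folded, with mirrored flanks", {
  g <- c(chr1 = "AACCCTAGGGT")
  runs <- find_polyc_runs(g)
  cr <- runs[runs$strand == "+", ]
  expect_equal(cr$start, 3L)
  expect_equal(cr$n, 3L)
  expect_equal(cr$flank5, "A")
  expect_equal(cr$flank3, "T")
  # AGGGT: folded flank5 = complement of the base 3' of the G run
  gr <- runs[runs$strand == "-", ]
  expect_equal(gr$n, 3L)
  expect_equal(gr$flank5, "A")
  expect_equal(gr$flank3, "T")
})

test_that("boundary runs carry NA flanks", {
  g <- c(chr1 = "CCCCA")
  runs <- find_polyc_runs(g)
  expect_true(is.na(runs$flank5[runs$strand == "+"]))
  expect_equal(runs$flank3[runs$strand == "+"], "A")
})

test_that("run and A-tract detectors match the regex oracles", {
  set.seed(23)
  for (i in 1:200) {
    g <- random_genome(200, gc = runif(1, 0.3, 0.7))
    expect_identical(find_polyc_runs(g), oracle_polyc_runs(g))
    mine <- find_atracts(g)
    orc <- oracle_atracts(g)
    if (is.null(orc)) {
      expect_equal(nrow(mine), 0L)
    } else {
      rownames(mine) <- NULL
      expect_identical(mine, orc)
    }
  }
})

test_that("A-tract definition splits at TA steps", {
  expect_equal(nrow(find_atracts(c(x = "GGAAAAGG"))), 1L)
  expect_equal(nrow(find_atracts(c(x = "GGAATTGG"))), 1L)  # no TA step
  expect_equal(nrow(find_atracts(c(x = "GGATATGG"))), 0L)  # TA inside
  tr <- find_atracts(c(x = "CCTTTTTAAAAACC"))
  expect_equal(tr$length, c(5L, 5L))                       # split at TA
})

test_that("gradient arithmetic and tie handling are exact", {
  g <- c(chr1 = "AACCCCTAA")
  runs <- find_polyc_runs(g)
  runs$site_reactivities <- I(list(c(0.06, 0.04, 0.03, 0.02)))
  runs$complete <- TRUE
  gp <- gradient_profile(runs, cpg_mode = "include")
  expect_equal(gp$ratios$ratio53[gp$ratios$n == 4], 3.0)
  prev <- gradient_prevalence(runs)
  expect_equal(prev$fraction, 1.0)
  # equal terminals count as gradient-absent
  runs$site_reactivities <- I(list(rep(0.02, 4)))
  expect_equal(gradient_prevalence(runs)$fraction, 0)
  expect_equal(gradient_profile(runs, "include")$ratios$ratio53[1], 1.0)
})

test_that("positional means reconcile with the overall class mean", {
  cfg <- sim_config(genome_length = 30000L, depth = 500L,
                    polyc_spec = c(`3` = 150L), atract_spec = integer(0),
                    seed = 41L)
  gen <- generate_genome(cfg)
  sim <- simulate_pileups(gen$genome, cfg)
  sites <- fold_pileup(sim$pileup, gen$genome)
  runs <- attach_run_reactivities(find_polyc_runs(gen$genome), sites)
  gp <- gradient_profile(runs, cpg_mode = "include")
  p3 <- gp$profile[gp$profile$n == 3, ]
  pooled <- sum(p3$mean * p3$count) / sum(p3$count)
  r3 <- runs[runs$complete & runs$n == 3 & !is.na(runs$flank5) &
               !is.na(runs$flank3) & runs$flank5 != "N" &
               runs$flank3 != "N", ]
  direct <- mean(unlist(r3$site_reactivities))
  expect_equal(pooled, direct, tolerance = 1e-12)
})

test_that("gradient profile is invariant under reverse complement", {
  cfg <- sim_config(genome_length = 20000L, depth = 500L,
                    polyc_spec = c(`2` = 50L, `4` = 50L),
                    atract_spec = integer(0), seed = 43L)
  gen <- generate_genome(cfg)
  sim <- simulate_pileups(gen$genome, cfg)
  sites <- fold_pileup(sim$pileup, gen$genome)
  gp <- gradient_profile(attach_run_reactivities(
    find_polyc_runs(gen$genome), sites))

  L <- nchar(unname(gen$genome))
  g_rc <- revcomp_genome(gen$genome)
  sites_rc <- fold_pileup(mirror_pileup(sim$pileup, L), g_rc)
  gp_rc <- gradient_profile(attach_run_reactivities(
    find_polyc_runs(g_rc), sites_rc))
  expect_equal(gp$profile, gp_rc$profile, tolerance = 1e-12)
  expect_equal(gp$pooled_step_ratio, gp_rc$pooled_step_ratio,
               tolerance = 1e-12)
})

test_that("flanking effects recover planted 5' modifiers", {
  cfg <- sim_config(genome_length = 60000L, depth = 2000L,
                    gc_content = 0.45,
                    polyc_spec = integer(0), atract_spec = integer(0),
                    flank_modifiers = list(`-1` = c(G = 1.5, T = 0.5)),
                    cpg_methylated_fraction = 0, seed = 47L)
  gen <- generate_genome(cfg)
  sim <- simulate_pileups(gen$genome, cfg)
  sites <- apply_site_filters(fold_pileup(sim$pileup, gen$genome),
                              min_depth = 500L)$kept
  fe <- flanking_effects(sites)
  m1 <- fe[fe$offset == -1, ]
  mG <- m1$mean[m1$base == "G"]
  mT <- m1$mean[m1$base == "T"]
  mA <- m1$mean[m1$base == "A"]
  expect_gt(mG, mA)
  expect_gt(mA, mT)
  expect_lt(m1$p_signed_rank[m1$base == "G"], 0.01)
  expect_lt(m1$p_signed_rank[m1$base == "T"], 0.01)
})

test_that("CpG classification follows the folded 3' neighbour", {
  sites <- data.frame(
    context = c("AAACGAA", "AAACGAA", "AAACAAA"),
    reactivity = c(0.002, 0.05, 0.002))
  expect_equal(classify_cpg(sites),
               c("CpG-low", "CpG-reactive", "non-CpG"))
})

test_that("motif table aggregates and flags GnCn contexts", {
  sites <- data.frame(context = c("GGGCCCC", "GGGCCCC", "CTCCATC"),
                      reactivity = c(0.3, 0.35, 0.01))
  mt <- motif_reactivity_table(sites, k = 7L)
  expect_equal(mt$mean[mt$motif == "GGGCCCC"], 0.325)
  expect_true(mt$is_gnc[mt$motif == "GGGCCCC"])
  expect_false(mt$is_gnc[mt$motif == "CTCCATC"])
})

test_that("step-parameter regression handles exact and degenerate cases", {
  sites <- data.frame(
    context = c("AAACAAA", "AATCTAA", "AAGCGAA", "ACGCAGA"),
    reactivity = c(0.01, 0.02, 0.03, 0.04))
  # perfect linear relation across dinucleotides
  kmers <- unique(unlist(lapply(sites$context, function(s)
    c(substr(s, 3, 4), substr(s, 4, 5)))))
  tab <- data.frame(kmer = kmers, lin = seq_along(kmers),
                    flat = 1)
  res <- suppressWarnings(step_parameter_regression(sites, tab, k = 2L))
  expect_true(res$degenerate[res$parameter == "flat"])
  expect_false(res$degenerate[res$parameter == "lin"])

  tab2 <- data.frame(kmer = kmers, x = rnorm(length(kmers)))
  mu <- tapply(c(sites$reactivity, sites$reactivity),
               c(substr(sites$context, 3, 4), substr(sites$context, 4, 5)),
               mean)
  tab2$x <- as.numeric(mu[tab2$kmer]) * 2 + 1   # exact linear in the means
  res2 <- step_parameter_regression(sites, tab2, k = 2L)
  expect_equal(res2$r, 1, tolerance = 1e-12)
})

test_that("A-tract GLM recovers planted suppression and flags dispersion", {
  cfg <- sim_config(genome_length = 80000L, depth = 500L,
                    polyc_spec = c(`1` = 700L), atract_spec = integer(0),
                    atract_adjacent_frac = 0.3, p0 = 0.05,
                    gradient_factor = 1, flank_modifiers = list(),
                    cpg_methylated_fraction = 0, atract_suppression = 0.6,
                    seed = 53L)
  gen <- generate_genome(cfg)
  sim <- simulate_pileups(gen$genome, cfg)
  sites <- apply_site_filters(fold_pileup(sim$pileup, gen$genome))$kept
  fit <- atract_glm(sites, gen$genome)
  co <- fit$coefficients
  b <- co$estimate[co$term == "atract5"]
  expect_lt(b, 0)
  expect_lt(co$p[co$term == "atract5"], 0.05)
  # odds-scale effect within +/-30% of the planted factor
  expect_lt(abs(exp(b) - 0.6), 0.18)
})
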