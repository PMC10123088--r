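test_that("genome generation plants the configured elements and is pure", {
  cfg <- sim_config(genome_length = 20000L, polyc_spec = c(`4` = 10L),
                    atract_spec = c(`5` = 5L), atract_adjacent_frac = 0,
                    seed = 3L)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1$genome, g2$genome)
  pc <- g1$manifest[g1$manifest$type == "polyC", ]
  expect_equal(nrow(pc), 10L)
  # planted runs are maximal runs of the stated length in the realised genome
  runs <- find_polyc_runs(g1$genome)
  key <- paste(runs$start, runs$end, runs$strand)
  expect_true(all(paste(pc$start, pc$end, pc$strand) %in% key))
  expect_true(all(runs$n[match(paste(pc$start, pc$end, pc$strand),
                               key)] == 4L))
  # planted A-tracts are recovered by the detector
  at <- g1$manifest[g1$manifest$type == "atract", ]
  tr <- find_atracts(g1$genome)
  expect_true(all(paste(at$start, at$end) %in% paste(tr$start, tr$end)))
})

test_that("background composition matches the configured GC content", {
  cfg <- sim_config(genome_length = 1e5L, gc_content = 0.5,
                    polyc_spec = integer(0), atract_spec = integer(0),
                    seed = 9L)
  g <- generate_genome(cfg)
  chars <- strsplit(unname(g$genome), "")[[1]]
  gc <- mean(chars %in% c("C", "G"))
  expect_gt(gc, 0.49)
  expect_lt(gc, 0.51)
})

test_that("conversion probabilities follow the geometric gradient model", {
  g <- c(sim1 = "ATTACCCCTAGGA")
  cfg <- sim_config(p0 = 0.02, gradient_factor = 1.5,
                    flank_modifiers = list(), atract_adjacent_frac = 0,
                    cpg_methylated_fraction = 0, seed = 1L)
  tt <- site_conversion_probability(g, cfg)
  run <- tt[tt$run_n == 4L, ]
  run <- run[order(run$pos), ]
  # '+' C-run ACCCCT: positions 5'->3' carry p0*g^3 .. p0*g^0
  expect_equal(run$p_true, c(0.0675, 0.045, 0.03, 0.02), tolerance = 1e-12)
  # g = 1 flattens the gradient everywhere
  cfg1 <- sim_config(p0 = 0.02, gradient_factor = 1,
                     flank_modifiers = list(), cpg_methylated_fraction = 0,
                     seed = 1L)
  tt1 <- site_conversion_probability(g, cfg1)
  expect_true(all(tt1$p_true == 0.02))
})

test_that("flank modifiers and A-tract suppression scale the probability", {
  # isolated C with 5' G; and an A-tract touching a run's 5' end
  g <- c(sim1 = "TTGCATTTAAAACCTGG")
  cfg <- sim_config(p0 = 0.02, gradient_factor = 1,
                    flank_modifiers = list(`-1` = c(G = 1.5)),
                    atract_suppression = 0.6, cpg_methylated_fraction = 0,
                    seed = 1L)
  tt <- site_conversion_probability(g, cfg)
  # folded '-' site at the G (pos 3): folded 5' neighbour is G -> x1.5
  isoG <- tt[tt$pos == 3L & tt$strand == "-", ]
  expect_equal(isoG$p_true, 0.02 * 1.5)
  # '+' isolated C at pos 4: 5' G (x1.5) and a touching 3' A-tract
  # (ATTT at 5-8), which carries the default 3' suppression of 0.75
  iso <- tt[tt$pos == 4L & tt$strand == "+", ]
  expect_equal(iso$p_true, 0.02 * 1.5 * 0.75)
  # CC run at 13-14 with the AAAA tract (9-12) touching its 5' end
  run5 <- tt[tt$pos %in% c(13L, 14L) & tt$strand == "+", ]
  expect_equal(run5$p_true, c(0.6 * 0.02, 0.6 * 0.02))
})

test_that("pileup simulation is exact at the degenerate settings", {
  g <- c(sim1 = "ACGTCCGGAT")
  cfg <- sim_config(p0 = 1e-9, gradient_factor = 1, error_rate = 0,
                    flank_modifiers = list(), cpg_methylated_fraction = 0,
                    depth = 100L, seed = 2L)
  sim <- simulate_pileups(g, cfg)
  p <- sim$pileup
  ref_count <- ifelse(p$ref == "A", p$nA, ifelse(p$ref == "C", p$nC,
                      ifelse(p$ref == "G", p$nG, p$nT)))
  expect_true(all(ref_count == p$depth))
  expect_true(all(p$nA + p$nC + p$nG + p$nT == p$depth))
})

test_that("converted counts are binomial with the configured mean", {
  set.seed(1)
  g <- stats::setNames(paste(rep("ACT", 1200), collapse = ""), "sim1")
  cfg <- sim_config(p0 = 0.1, gradient_factor = 1, error_rate = 0,
                    flank_modifiers = list(), cpg_methylated_fraction = 0,
                    depth = 500L, seed = 4L)
  sim <- simulate_pileups(g, cfg)
  conv <- sim$pileup$nT[sim$pileup$ref == "C"]
  n <- length(conv)
  expect_gte(n, 1000)
  se <- sqrt(500 * 0.1 * 0.9 / n)
  expect_lt(abs(mean(conv) - 50), 3 * se)
  # same seed -> byte-identical output
  sim2 <- simulate_pileups(g, cfg)
  expect_identical(sim$pileup, sim2$pileup)
})

test_that("dyad placement is uniform at odds 1 and empty at count 0", {
  cfg <- sim_config(genome_length = 60000L,
                    polyc_spec = c(`4` = 100L), atract_spec = integer(0),
                    dyad_count = 10000L, dyad_enrichment_odds = 1,
                    seed = 8L)
  gen <- generate_genome(cfg)
  roll <- synthetic_roll_profile()
  dy <- simulate_dyads(gen$genome, gen$manifest, roll, cfg)
  pl <- attr(dy, "placements")
  enr <- offset_enrichment(pl$offset, roll)
  expect_gt(enr$chisq_p, 0.01)
  expect_lt(abs(enr$frac_positive - enr$expected_frac), 0.02)

  cfg0 <- sim_config(dyad_count = 0L, seed = 8L)
  dy0 <- simulate_dyads(gen$genome, gen$manifest, roll, cfg0)
  expect_equal(nrow(dy0), 0L)
})

test_that("mutation counts follow the configured per-motif rates", {
  set.seed(2)
  g <- random_genome(2e5, gc = 0.5, name = "sim1")
  names(g) <- "sim1"
  tab <- data.frame(pattern = "NCN", class = "C>T", rate = 1e-3)
  cfg <- sim_config(mutation_rate_table = tab, chrom_name = "sim1",
                    seed = 21L)
  m <- simulate_mutations(g, cfg)
  opp <- attr(m, "opportunities")$eligible
  expect_gt(opp, 1e4)
  lam <- opp * 1e-3
  expect_gte(nrow(m), qpois(0.005, lam))
  expect_lte(nrow(m), qpois(0.995, lam))
  # all-zero rates give an empty list; same seed reproduces exactly
  cfg0 <- sim_config(mutation_rate_table =
                       data.frame(pattern = "NCN", class = "C>T", rate = 0),
                     chrom_name = "sim1", seed = 21L)
  expect_equal(nrow(simulate_mutations(g, cfg0)), 0L)
  m2 <- simulate_mutations(g, cfg)
  expect_identical(as.data.frame(m), as.data.frame(m2))
})

test_that("pipeline reactivity estimates converge to the planted truth", {
  cfg <- sim_config(genome_length = 15000L, depth = 5000L,
                    polyc_spec = c(`2` = 50L, `3` = 50L, `4` = 50L),
                    atract_spec = integer(0), seed = 31L)
  gen <- generate_genome(cfg)
  sim <- simulate_pileups(gen$genome, cfg)
  sites <- fold_pileup(sim$pileup, gen$genome)
  key <- paste(sites$chrom, sites$pos, sites$strand)
  tt <- sim$truth
  m <- match(paste(tt$chrom, tt$pos, tt$strand), key)
  err <- abs(sites$reactivity[m] - tt$p_true)
  expect_gte(length(err), 500)
  expect_lt(mean(err, na.rm = TRUE), 0.01)
})
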