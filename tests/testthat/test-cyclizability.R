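make_records <- function(seqs, scores, rep_sd = 0) {
  data.frame(seq = seqs,
             c26 = scores + rnorm(length(seqs), sd = rep_sd),
             c29 = scores + rnorm(length(seqs), sd = rep_sd),
             c31 = scores + rnorm(length(seqs), sd = rep_sd)) |>
    (\(d) { d$mean_score <- (d$c26 + d$c29 + d$c31) / 3; d })()
}

test_that("windowed reactivity averages the model over folded cytosines", {
  sites <- data.frame(context = c("AAACAAA", "TTTCTTT"),
                      reactivity = c(0.02, 0.02))
  model <- fit_reactivity_model(sites, k = 4L)
  seq_c <- paste0(strrep("A", 20), "C", strrep("A", 29))
  expect_equal(windowed_reactivity(seq_c, model), 0.02)
  # a sequence without any C or G has no folded cytosine
  expect_true(is.na(windowed_reactivity(strrep("AT", 25), model)))
  expect_error(windowed_reactivity("ACG", model), "window larger")
})

test_that("a k-mer model scores poly-C-rich sequences above C-poor ones", {
  cfg <- sim_config(genome_length = 40000L, depth = 500L,
                    polyc_spec = c(`4` = 150L), atract_spec = integer(0),
                    seed = 73L)
  gen <- generate_genome(cfg)
  sim <- simulate_pileups(gen$genome, cfg)
  sites <- apply_site_filters(fold_pileup(sim$pileup, gen$genome))$kept
  model <- fit_reactivity_model(sites, k = 4L)
  rich <- paste0(strrep("A", 10), "TCCCCT", strrep("ACCCCT", 5),
                 strrep("A", 4))
  poor <- paste0(strrep("AT", 22), "ACTGAT")
  expect_gt(windowed_reactivity(rich, model),
            windowed_reactivity(poor, model))
})

test_that("regressing the score on itself gives r = 1", {
  set.seed(79)
  seqs <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 50, TRUE), collapse = ""),
    character(1))
  rec <- make_records(seqs, rnorm(50))
  reg <- pearson_regression(rec$mean_score, rec$mean_score)
  expect_equal(reg$r, 1, tolerance = 1e-12)
})

test_that("a planted TA-count effect is the strongest dinucleotide signal", {
  set.seed(83)
  g <- random_genome(60000, gc = 0.45, name = "sim1")
  cfg <- sim_config(chrom_name = "sim1", cyc_n = 4000L,
                    cyc_beta_ta = 0.25, cyc_beta_polyc = 0,
                    cyc_replicate_sd = 0.5, seed = 89L)
  rec <- simulate_cyclizability(g, cfg)
  reg <- cyclizability_regressions(rec)
  din <- reg[startsWith(reg$predictor, "dinuc_"), ]
  best <- din$predictor[which.max(abs(din$r))]
  expect_equal(best, "dinuc_TA")
  r_ta <- din$r[din$predictor == "dinuc_TA"]
  # attenuated by replicate noise: compare to the construction's value
  lat <- attr(rec, "latent")
  r_constr <- cor(count_dinucleotide(rec$seq, "TA"), rec$mean_score)
  expect_equal(r_ta, r_constr, tolerance = 1e-9)
  expect_gt(r_ta, 0.15)
})

test_that("null scores give near-zero correlations", {
  set.seed(97)
  g <- random_genome(60000, gc = 0.45, name = "sim1")
  cfg <- sim_config(chrom_name = "sim1", cyc_n = 10000L,
                    cyc_beta_ta = 0, cyc_beta_polyc = 0, seed = 101L)
  rec <- simulate_cyclizability(g, cfg)
  reg <- cyclizability_regressions(rec)
  expect_true(all(abs(reg$r[!reg$skipped]) < 0.05))
})

test_that("poly-C enrichment splits halves and extremes correctly", {
  set.seed(103)
  rich <- paste0("CCCCA", "GGGGA", "CCCCA", strrep("AT", 17), "C")  # 3 runs
  poor <- paste0("CCCCA", strrep("AT", 22), "C")                    # 1 run
  seqs <- c(rep(rich, 1000), rep(poor, 1000))
  # scores planted to rank run-rich sequences on top
  rec <- make_records(seqs, c(rep(1, 1000), rep(-1, 1000)) + rnorm(2000,
                                                                   sd = 0.1))
  enr <- polyc_enrichment_by_score(rec)
  expect_gt(enr$halves$enrichment, 2)
  expect_lt(enr$halves$chisq_p, 1e-3)
  # with exactly 2000 records the extreme sets are the halves
  expect_equal(enr$extremes$count_top, enr$halves$count_top)
  expect_warning(polyc_enrichment_by_score(rec[1:100, ]), "fewer than 2000")
})

test_that("replicate-noise report follows the sample-SD definition", {
  rec <- data.frame(seq = c(strrep("A", 50), strrep("C", 50)),
                    c26 = c(1, -1), c29 = c(1, 0), c31 = c(1, 1))
  rec$mean_score <- (rec$c26 + rec$c29 + rec$c31) / 3
  out <- replicate_noise_report(rec)
  expect_equal(out$fraction, 0.5)  # (1,1,1) no; (-1,0,1) yes
  # Monte-Carlo oracle: i.i.d. standard-normal replicates
  set.seed(107)
  n <- 10000
  reps <- matrix(rnorm(3 * n), ncol = 3)
  frac_oracle <- mean(apply(reps, 1, sd) > abs(rowMeans(reps)))
  rec2 <- data.frame(seq = strrep("A", 50), c26 = reps[, 1],
                     c29 = reps[, 2], c31 = reps[, 3])
  rec2$mean_score <- rowMeans(reps)
  expect_equal(replicate_noise_report(rec2)$fraction, frac_oracle)
})
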