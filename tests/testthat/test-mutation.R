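test_that("mutation folding maps strands onto C classes", {
  g <- c(chr1 = "TTAGGGTCATT")
  muts <- data.frame(chrom = "chr1", pos = c(5L, 8L, 2L),
                     ref = c("G", "C", "T"), alt = c("A", "A", "C"))
  f <- fold_mutation(muts, g)
  expect_equal(nrow(f), 2L)           # T>C dropped
  expect_equal(f$class[f$pos == 5], "C>T")   # G>A folds to C>T
  expect_equal(f$strand[f$pos == 5], "-")
  expect_equal(f$class[f$pos == 8], "C>A")   # C>A unchanged
})

test_that("run-end rates exclude CpG and reconcile with brute-force counts", {
  set.seed(109)
  g <- random_genome(50000, gc = 0.5)
  rates <- polyc_end_rates(data.frame(chrom = character(), pos = integer(),
                                      ref = character(), alt = character()),
                           g)
  for (i in seq_len(nrow(rates$rates))) {
    row <- rates$rates[i, ]
    if (row$class != "C>T") next    # opportunities identical across classes
    rng <- as.integer(strsplit(row$bin, "-")[[1]])
    brute <- oracle_end_count(g, rng[1], rng[2], row$flank5, row$end)
    expect_equal(row$opportunities, brute,
                 info = paste(row$bin, row$flank5, row$end))
  }
})

test_that("hits conservation: strata sum to folded mutations at end motifs", {
  set.seed(113)
  g <- random_genome(100000, gc = 0.5, name = "sim1")
  tab <- data.frame(pattern = c("DCC", "CCD"), class = "C>T",
                    rate = c(0.02, 0.02))
  cfg <- sim_config(chrom_name = "sim1", mutation_rate_table = tab,
                    seed = 127L)
  muts <- simulate_mutations(g, cfg)
  out <- polyc_end_rates(muts, g, n_bins = list(c(2L, 100L)))
  # every simulated mutation sits at a run end; those at CpG-excluded or
  # boundary/N-flank positions drop out of the strata
  folded <- fold_mutation(muts, g)
  ends <- bisreact:::polyc_end_sites(g, list(c(2L, 100L)),
                                     c("A", "G", "T"))
  covered <- paste(folded$chrom, folded$pos, folded$strand) %in%
    paste(ends$chrom, ends$pos, ends$strand)
  expect_equal(sum(out$rates$hits), sum(covered))
})

test_that("rates are invariant under reverse complement", {
  set.seed(131)
  g <- random_genome(30000, gc = 0.5, name = "sim1")
  tab <- data.frame(pattern = c("DCC", "CCD"), class = "C>T",
                    rate = c(0.03, 0.02))
  cfg <- sim_config(chrom_name = "sim1", mutation_rate_table = tab,
                    seed = 137L)
  muts <- simulate_mutations(g, cfg)
  out <- polyc_end_rates(muts, g)

  L <- nchar(unname(g))
  g_rc <- revcomp_genome(g)
  muts_rc <- data.frame(chrom = muts$chrom, pos = L + 1L - muts$pos,
                        ref = chartr("ACGT", "TGCA", muts$ref),
                        alt = chartr("ACGT", "TGCA", muts$alt))
  out_rc <- polyc_end_rates(muts_rc, g_rc)
  key <- function(x) x$rates[order(x$rates$bin, x$rates$flank5,
                                   x$rates$end, x$rates$class), ]
  a <- key(out); b <- key(out_rc)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("an empty genome stratum yields an empty table", {
  g <- c(chr1 = strrep("AT", 100))
  out <- polyc_end_rates(data.frame(chrom = character(), pos = integer(),
                                    ref = character(), alt = character()),
                         g)
  expect_equal(nrow(out$rates), 0L)
})

test_that("roll stratification detects planted region-dependent rates", {
  set.seed(139)
  cfg <- sim_config(genome_length = 200000L,
                    polyc_spec = c(`2` = 400L, `3` = 400L),
                    atract_spec = integer(0), dyad_count = 800L,
                    dyad_enrichment_odds = 1, seed = 149L)
  gen <- generate_genome(cfg)
  roll <- synthetic_roll_profile(147L)
  dyads <- simulate_dyads(gen$genome, gen$manifest, roll, cfg)
  # assign mutations by the majority roll sign over all covering dyads:
  # 3x rate in negative-roll territory
  ends <- bisreact:::polyc_end_sites(gen$genome,
                                     list(c(2L, 3L)), c("A", "G", "T"))
  dp <- sort(dyads$dyad_pos)
  sign_of <- vapply(seq_len(nrow(ends)), function(i) {
    p <- ends$pos[i]
    lo <- findInterval(p - 74L, dp) + 1L
    hi <- findInterval(p + 73L, dp)
    if (hi < lo) return(NA)
    off <- dyad_offset(rep(p, hi - lo + 1L), dp[lo:hi], ends$strand[i],
                       roll)
    off <- off[!is.na(off)]
    if (length(off) == 0L) return(NA)
    mean(roll$positive[match(off, roll$offsets)]) >= 0.5
  }, logical(1))
  rate <- ifelse(is.na(sign_of), 0, ifelse(sign_of, 0.01, 0.03))
  hit <- runif(nrow(ends)) < rate
  muts <- data.frame(chrom = ends$chrom[hit], pos = ends$pos[hit],
                     ref = ifelse(ends$strand[hit] == "+", "C", "G"),
                     alt = ifelse(ends$strand[hit] == "+", "T", "A"))
  out <- stratify_by_roll(muts, gen$genome, dyads, roll,
                          n_bins = list(c(2L, 3L)))
  p <- out$tests$p[out$tests$class == "C>T"]
  expect_true(any(p < 0.01, na.rm = TRUE))
  neg <- out$rates[out$rates$class == "C>T" & out$rates$region == "negative", ]
  pos <- out$rates[out$rates$class == "C>T" & out$rates$region == "positive", ]
  expect_gt(sum(neg$hits) / sum(neg$opportunities),
            sum(pos$hits) / sum(pos$opportunities))

  # no dyads -> empty with warning
  expect_warning(
    out0 <- stratify_by_roll(muts, gen$genome,
                             data.frame(chrom = character(),
                                        dyad_pos = integer(),
                                        strength = numeric()), roll),
    "footprint")
  expect_equal(nrow(out0$rates), 0L)
})
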