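# Per-motif de novo mutation rates with strand folding and CpG exclusion.
# Rates are per-site probabilities: each genomic instance of a motif counts
# once in the denominator; folded mutations at that instance count in the
# numerator.

#' Fold mutations onto the C strand
#'
#' G>N mutations are mapped to the complementary C>N' class with
#' reverse-complemented context; C>N records are kept unchanged; A/T
#' reference sites are dropped.
#'
#' @param mutations Mutation table ([read_mutations_tsv()]).
#' @param genome Genome.
#' @return data.frame: \code{chrom, pos, strand, class, context} (folded
#'   heptamer).
#' @export
fold_mutation <- function(mutations, genome) {
  keep <- mutations$ref %in% c("C", "G")
  m <- mutations[keep, , drop = FALSE]
  if (nrow(m) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), class = character(),
                      context = character(), stringsAsFactors = FALSE))
  strand <- ifelse(m$ref == "C", "+", "-")
  alt_fold <- ifelse(m$ref == "C", m$alt, comp_base(m$alt))
  ctx <- if (nrow(m)) folded_contexts(genome, m$chrom, m$pos, strand, 3L)
    else character(0)
  data.frame(chrom = m$chrom, pos = m$pos, strand = strand,
             class = paste0("C>", alt_fold), context = ctx,
             stringsAsFactors = FALSE)
}

MUT_CLASSES <- c("C>T", "C>A", "C>G")

# Qualifying run-end sites: one row per (run, end) with folded position,
# n-bin and 5'-flank class; CpG-excluded (no site whose folded 3'
# neighbour is G).
polyc_end_sites <- function(genome, n_bins, flank5_classes, runs = NULL) {
  if (is.null(runs)) runs <- find_polyc_runs(genome)
  runs <- runs[!is.na(runs$flank5) & !is.na(runs$flank3) &
                 runs$flank5 %in% flank5_classes, , drop = FALSE]
  bin_label <- rep(NA_character_, nrow(runs))
  for (b in n_bins) {
    lab <- paste0(b[1], "-", b[2])
    bin_label[runs$n >= b[1] & runs$n <= b[2]] <- lab
  }
  runs <- runs[!is.na(bin_label), , drop = FALSE]
  bin_label <- bin_label[!is.na(bin_label)]
  if (nrow(runs) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), bin = character(),
                      flank5 = character(), end = character(),
                      stringsAsFactors = FALSE))
  e5 <- ifelse(runs$strand == "+", runs$start, runs$end)
  e3 <- ifelse(runs$strand == "+", runs$end, runs$start)
  out <- rbind(
    data.frame(chrom = runs$chrom, pos = e5, strand = runs$strand,
               bin = bin_label, flank5 = runs$flank5, end = "5p",
               cpg = FALSE, stringsAsFactors = FALSE),
    data.frame(chrom = runs$chrom, pos = e3, strand = runs$strand,
               bin = bin_label, flank5 = runs$flank5, end = "3p",
               cpg = runs$flank3 == "G", stringsAsFactors = FALSE))
  out <- out[!out$cpg, , drop = FALSE]   # CpG exclusion
  out$cpg <- NULL
  out
}

#' Mutation rates at poly-C run ends
#'
#' For each (run-length bin, 5'-flank base, end, mutation class): hits are
#' folded de novo mutations at that end position; opportunities are
#' genomic instances of the motif. Every C whose folded 3' neighbour is G
#' (all CpG dinucleotides) is excluded from numerator and denominator,
#' which removes 3'-end sites of runs with a 3' G flank (5'-end sites of
#' runs of length >= 2 are never CpG). Rates carry a binomial SEM; the
#' 5':3' ratio is reported per stratum, pooled per class, and pooled
#' overall.
#'
#' @param mutations Mutation table ([read_mutations_tsv()]).
#' @param genome Genome.
#' @param n_bins list of length-2 vectors of run-length bounds
#'   (default \code{list(c(2,3), c(4,6))}).
#' @param flank5_classes 5'-flank bases stratified over (default A, G, T).
#' @return list: \code{rates} (bin, flank5, end, class, hits,
#'   opportunities, rate, sem), \code{ratios} (per-stratum 5':3' rate
#'   ratios), \code{pooled} (per class and overall: pooled ratio and mean
#'   of per-stratum ratios). Strata with zero opportunities are omitted.
#' @export
polyc_end_rates <- function(mutations, genome,
                            n_bins = list(c(2L, 3L), c(4L, 6L)),
                            flank5_classes = c("A", "G", "T")) {
  ends <- polyc_end_sites(genome, n_bins, flank5_classes)
  folded <- fold_mutation(mutations, genome)
  if (nrow(ends) == 0L)
    return(list(rates = data.frame(), ratios = data.frame(),
                pooled = data.frame()))
  endkey <- paste(ends$chrom, ends$pos, ends$strand)
  strata <- expand.grid(bin = unique(ends$bin), flank5 = flank5_classes,
                        end = c("5p", "3p"), class = MUT_CLASSES,
                        stringsAsFactors = FALSE)
  rates <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    st <- strata[i, ]
    sel <- ends$bin == st$bin & ends$flank5 == st$flank5 &
      ends$end == st$end
    opp <- sum(sel)
    if (opp == 0L) return(NULL)
    mk <- paste(folded$chrom, folded$pos, folded$strand)
    hits <- sum(folded$class == st$class & mk %in% endkey[sel])
    rate <- hits / opp
    data.frame(st, hits = hits, opportunities = opp, rate = rate,
               sem = sqrt(rate * (1 - rate) / opp),
               stringsAsFactors = FALSE)
  }))
  ratios <- NULL
  for (b in unique(rates$bin)) for (f in unique(rates$flank5))
    for (cl in MUT_CLASSES) {
      r5 <- rates[rates$bin == b & rates$flank5 == f & rates$end == "5p" &
                    rates$class == cl, , drop = FALSE]
      r3 <- rates[rates$bin == b & rates$flank5 == f & rates$end == "3p" &
                    rates$class == cl, , drop = FALSE]
      if (nrow(r5) == 1L && nrow(r3) == 1L && r3$rate > 0)
        ratios <- rbind(ratios, data.frame(
          bin = b, flank5 = f, class = cl, ratio = r5$rate / r3$rate,
          stringsAsFactors = FALSE))
    }
  pooled_for <- function(sel_class) {
    r <- rates[rates$class %in% sel_class, , drop = FALSE]
    h5 <- sum(r$hits[r$end == "5p"]); o5 <- sum(r$opportunities[r$end == "5p"])
    h3 <- sum(r$hits[r$end == "3p"]); o3 <- sum(r$opportunities[r$end == "3p"])
    pr <- if (o5 > 0 && o3 > 0 && h3 > 0) (h5 / o5) / (h3 / o3) else NA_real_
    rr <- ratios[ratios$class %in% sel_class, "ratio"]
    c(pooled_ratio = pr,
      mean_stratum_ratio = if (length(rr)) mean(rr) else NA_real_)
  }
  pooled <- rbind(
    data.frame(class = "all", t(pooled_for(MUT_CLASSES))),
    do.call(rbind, lapply(MUT_CLASSES, function(cl)
      data.frame(class = cl, t(pooled_for(cl))))))
  list(rates = rates, ratios = ratios %||% data.frame(), pooled = pooled)
}

#' Stratify run-end mutation rates by nucleosome roll sign
#'
#' Assigns each run-end opportunity (and each hit at it) to positive- or
#' negative-roll territory per overlapping dyad (one incidence per dyad;
#' out-of-footprint sites are excluded) and reports rates per (end, class,
#' roll region) with a chi-square homogeneity test per (end, class).
#' Raw and Bonferroni-adjusted p-values are reported.
#'
#' @param mutations Mutation table.
#' @param genome Genome.
#' @param dyads Dyad table.
#' @param roll A \code{roll_profile}.
#' @param n_bins,flank5_classes As in [polyc_end_rates()].
#' @return list: \code{rates} (end, class, region, hits, opportunities,
#'   rate), \code{tests} (end, class, chisq_stat, p, p_bonferroni). When
#'   no dyads overlap any site both elements are empty (with a warning).
#' @export
stratify_by_roll <- function(mutations, genome, dyads, roll,
                             n_bins = list(c(2L, 3L), c(4L, 6L)),
                             flank5_classes = c("A", "G", "T")) {
  ends <- polyc_end_sites(genome, n_bins, flank5_classes)
  folded <- fold_mutation(mutations, genome)
  mk <- paste(folded$chrom, folded$pos, folded$strand)
  regions <- character(0); ends_i <- integer(0)
  half <- max(abs(roll$offsets))
  for (ch in unique(ends$chrom)) {
    dp <- sort(dyads$dyad_pos[dyads$chrom == ch])
    if (length(dp) == 0L) next
    idx <- which(ends$chrom == ch)
    for (i in idx) {
      p <- ends$pos[i]
      lo <- findInterval(p - half - 1L, dp) + 1L
      hi <- findInterval(p + half, dp)
      if (hi < lo) next
      off <- dyad_offset(rep(p, hi - lo + 1L), dp[lo:hi], ends$strand[i],
                         roll)
      off <- off[!is.na(off)]
      if (length(off) == 0L) next
      sign_pos <- roll$positive[match(off, roll$offsets)]
      regions <- c(regions, ifelse(sign_pos, "positive", "negative"))
      ends_i <- c(ends_i, rep(i, length(off)))
    }
  }
  if (length(ends_i) == 0L) {
    warning("no run-end sites within any dyad footprint")
    return(list(rates = data.frame(), tests = data.frame()))
  }
  inc <- data.frame(end = ends$end[ends_i],
                    key = paste(ends$chrom, ends$pos, ends$strand)[ends_i],
                    region = regions, stringsAsFactors = FALSE)
  grid <- expand.grid(end = c("5p", "3p"), class = MUT_CLASSES,
                      region = c("positive", "negative"),
                      stringsAsFactors = FALSE)
  rates <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    sel <- inc$end == g$end & inc$region == g$region
    opp <- sum(sel)
    # a hit counts once per incidence of its site in this cell
    keys <- inc$key[sel]
    per_site_hits <- table(mk[folded$class == g$class])
    hv <- as.integer(per_site_hits[keys])
    hits <- sum(hv, na.rm = TRUE)
    data.frame(g, hits = as.integer(hits), opportunities = opp,
               rate = if (opp > 0) hits / opp else NA_real_,
               stringsAsFactors = FALSE)
  }))
  tests <- do.call(rbind, lapply(unique(grid$end), function(e) {
    do.call(rbind, lapply(MUT_CLASSES, function(cl) {
      r <- rates[rates$end == e & rates$class == cl, , drop = FALSE]
      rp <- r[r$region == "positive", ]; rn <- r[r$region == "negative", ]
      if (nrow(rp) == 0L || nrow(rn) == 0L || rp$opportunities == 0L ||
          rn$opportunities == 0L || (rp$hits + rn$hits) == 0L)
        return(data.frame(end = e, class = cl, chisq_stat = NA_real_,
                          p = NA_real_, stringsAsFactors = FALSE))
      tot_h <- rp$hits + rn$hits
      exp_p <- rp$opportunities / (rp$opportunities + rn$opportunities)
      tst <- chi_square(c(rp$hits, rn$hits),
                        c(exp_p, 1 - exp_p) * tot_h)
      data.frame(end = e, class = cl, chisq_stat = tst$statistic,
                 p = tst$p_value, stringsAsFactors = FALSE)
    }))
  }))
  tests$p_bonferroni <- pmin(1, tests$p * sum(!is.na(tests$p)))
  list(rates = rates, tests = tests)
}
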