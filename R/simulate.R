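# Synthetic-data generation with planted, recoverable structure: a
# geometric 3'->5' conversion gradient within poly-C runs, multiplicative
# flanking-base modifiers, A-tract suppression, CpG methylation, nucleosome
# dyads enriched at poly-C 5' ends in positive-roll windows, and per-motif
# mutation rates. Every generator is a pure function of (config, seed);
# each stage uses its own RNG stream (seed + a fixed per-stage offset) so
# stages can be regenerated independently.

#' Simulation configuration
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' ~2\% conversion at isolated C, a multiplicative per-step gradient of 1.5
#' toward the 5' end of runs, 5'-G enhancement and 5'-T suppression of
#' flanking effects, 42\% suppression by touching 5' A-tracts (25\% for 3'),
#' mostly-methylated CpG, <0.5\% off-target error, read depths around the
#' observed sequencing mean, and run-end mutation rates 28\% higher at the
#' 5' end (scaled up from genome-scale rates so that desk-scale genomes
#' yield countable events).
#'
#' @param genome_length Background genome length in bp.
#' @param gc_content Background GC fraction in (0,1).
#' @param chrom_name Name of the single simulated contig.
#' @param polyc_spec Named integer vector: run length -> number of maximal
#'   poly-C runs to plant.
#' @param atract_spec Named integer vector: tract length -> number of
#'   standalone A-tracts to plant.
#' @param atract_adjacent_frac Fraction of planted poly-C runs given a
#'   touching 5' A-tract.
#' @param p0 Conversion probability of an isolated, unmodified C.
#' @param gradient_factor Multiplicative reactivity increase per base
#'   toward the 5' end within a run (>= 1; 1 disables the gradient).
#' @param flank_modifiers Nested list: offset (as character, "-3".."3") ->
#'   named numeric vector of per-base multiplicative factors. Modifiers act
#'   only at offsets falling outside the run.
#' @param atract_suppression Multiplicative factor applied to a run with a
#'   touching 5' A-tract.
#' @param atract_suppression3 Factor for a touching 3' A-tract.
#' @param cpg_methylated_fraction Fraction of CpG cytosines drawn
#'   methylated.
#' @param cpg_meth_reactivity Residual conversion probability at methylated
#'   CpG.
#' @param error_rate Off-target mismatch probability per read-base.
#' @param depth Read depth (fixed, or Poisson mean with
#'   \code{depth_model = "poisson"}).
#' @param depth_model "fixed" or "poisson".
#' @param mapq Mean mapping quality written to pileups.
#' @param dyad_count Number of dyads to place.
#' @param dyad_enrichment_odds Odds multiplier for anchoring a planted
#'   poly-C 5' end at a positive-roll offset (1 = uniform placement).
#' @param mutation_rate_table data.frame(pattern, class, rate): centered
#'   IUPAC context patterns (odd width, central base C after folding),
#'   mutation class in \{C>T, C>A, C>G\}, per-site probability. Within a
#'   class, the first matching pattern wins.
#' @param cyc_n Number of 50-mers to draw for the cyclizability table.
#' @param cyc_beta_ta,cyc_beta_polyc Standardised effect of TA-dinucleotide
#'   count and of poly-C(>=4) run count on the simulated cyclizability
#'   score.
#' @param cyc_replicate_sd SD of replicate noise around each score.
#' @param seed Integer master seed.
#' @return Object of class \code{sim_config}.
#' @export
sim_config <- function(genome_length = 1e5L,
                       gc_content = 0.41,
                       chrom_name = "sim1",
                       polyc_spec = c(`2` = 300L, `3` = 300L, `4` = 300L,
                                      `5` = 300L),
                       atract_spec = c(`4` = 50L, `5` = 50L, `6` = 50L),
                       atract_adjacent_frac = 0.15,
                       p0 = 0.02,
                       gradient_factor = 1.5,
                       flank_modifiers = list(`-1` = c(G = 1.5, T = 0.5),
                                              `1` = c(G = 0.7)),
                       atract_suppression = 0.58,
                       atract_suppression3 = 0.75,
                       cpg_methylated_fraction = 0.75,
                       cpg_meth_reactivity = 0.001,
                       error_rate = 0.003,
                       depth = 6900L,
                       depth_model = c("fixed", "poisson"),
                       mapq = 60,
                       dyad_count = 2000L,
                       dyad_enrichment_odds = 3,
                       mutation_rate_table = default_mutation_rates(),
                       cyc_n = 2000L,
                       cyc_beta_ta = 0.25,
                       cyc_beta_polyc = 0.15,
                       cyc_replicate_sd = 1,
                       seed = 1L) {
  depth_model <- match.arg(depth_model)
  stopifnot(genome_length >= 100, gc_content > 0, gc_content < 1,
            p0 > 0, p0 < 1, gradient_factor >= 1,
            atract_suppression > 0, atract_suppression <= 1,
            cpg_methylated_fraction >= 0, cpg_methylated_fraction <= 1,
            error_rate >= 0, error_rate < 1, depth >= 1,
            dyad_enrichment_odds > 0)
  structure(as.list(environment()), class = "sim_config")
}

#' Default planted per-motif mutation rates
#'
#' Run-end patterns (DCC = a 5'-terminal run C, CCD = a 3'-terminal run C)
#' carry a 5' > 3' polarity for C>T and C>A and the reverse for C>G; CpG
#' carries the familiar deamination excess. Rates are per-site
#' probabilities scaled for desk-scale genomes.
#'
#' @return data.frame(pattern, class, rate).
#' @export
default_mutation_rates <- function() {
  data.frame(
    pattern = c("NCG", "DCC", "CCD", "DCC", "CCD", "DCC", "CCD",
                "NCN", "NCN", "NCN"),
    class = c("C>T", "C>T", "C>T", "C>A", "C>A", "C>G", "C>G",
              "C>T", "C>A", "C>G"),
    rate = c(0.010, 0.00128, 0.0010, 0.00060, 0.00030, 0.00010, 0.00015,
             0.00080, 0.00020, 0.00010),
    stringsAsFactors = FALSE)
}

rand_tract <- function(len) {
  # A^i T^(len-i) never contains a TA step
  i <- sample.int(len + 1L, 1L) - 1L
  paste0(strrep("A", i), strrep("T", len - i))
}

#' Generate a synthetic genome with planted elements
#'
#' Background bases are i.i.d. at the configured GC content; planted
#' poly-C runs are maximal (guarded by non-C on both sides, strand chosen
#' at random, 3' flank drawn from \{A,T\} and 5' flank from \{A,G,T\}) and
#' planted A-tracts contain no TA step. A configurable fraction of poly-C
#' runs receives a touching 5' A-tract. Elements never overlap.
#'
#' @param config A \code{sim_config}.
#' @return list(genome = named character vector, manifest = data.frame of
#'   planted elements with reference coordinates, folded strand/flanks and
#'   an \code{atract5} flag).
#' @export
generate_genome <- function(config) {
  set.seed(config$seed + 1L)
  L <- as.integer(config$genome_length)
  gc <- config$gc_content
  chars <- sample(DNA_BASES, L, replace = TRUE,
                  prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  occupied <- logical(L)
  manifest <- list()
  place <- function(width) {
    for (try in 1:200) {
      s <- sample.int(L - width + 1L, 1L)
      if (!any(occupied[s:(s + width - 1L)])) return(s)
    }
    stop("infeasible packing: cannot place element of width ", width,
         call. = FALSE)
  }
  mk <- 0L
  # poly-C runs
  for (nn_chr in names(config$polyc_spec)) {
    nn <- as.integer(nn_chr)
    for (rep_i in seq_len(config$polyc_spec[[nn_chr]])) {
      strand <- sample(c("+", "-"), 1L)
      f5 <- sample(c("A", "G", "T"), 1L)
      f3 <- sample(c("A", "T"), 1L)
      with_tract <- stats::runif(1) < config$atract_adjacent_frac
      tract <- if (with_tract) {
        tl <- sample(4:6, 1L)
        paste0(strrep("A", tl))     # ends in A: the 5' flank becomes A
      } else ""
      if (with_tract) f5 <- NULL
      core5 <- paste0(tract, if (is.null(f5)) "" else f5)
      elem_fold <- paste0(if (nzchar(core5)) core5 else "",
                          strrep("C", nn), f3)
      guard5 <- if (with_tract) sample(c("C", "G"), 1L) else ""
      elem_fold <- paste0(guard5, elem_fold)
      elem_ref <- if (strand == "+") elem_fold else revcomp(elem_fold)
      wid <- nchar(elem_ref)
      s <- place(wid)
      substr_chars <- strsplit(elem_ref, "", fixed = TRUE)[[1]]
      chars[s:(s + wid - 1L)] <- substr_chars
      occupied[s:(s + wid - 1L)] <- TRUE
      # reference coordinates of the run core
      pre <- nchar(guard5) + nchar(core5)
      if (strand == "+") {
        run_s <- s + pre; run_e <- run_s + nn - 1L
      } else {
        run_e <- s + wid - 1L - pre; run_s <- run_e - nn + 1L
      }
      mk <- mk + 1L
      manifest[[mk]] <- data.frame(
        type = "polyC", chrom = config$chrom_name, start = run_s,
        end = run_e, strand = strand, n = nn,
        flank5 = if (with_tract) "A" else f5, flank3 = f3,
        atract5 = with_tract, stringsAsFactors = FALSE)
    }
  }
  # standalone A-tracts (guarded by S bases so length is as configured)
  for (tl_chr in names(config$atract_spec)) {
    tl <- as.integer(tl_chr)
    for (rep_i in seq_len(config$atract_spec[[tl_chr]])) {
      tract <- rand_tract(tl)
      elem <- paste0(sample(c("C", "G"), 1L), tract,
                     sample(c("C", "G"), 1L))
      wid <- nchar(elem)
      s <- place(wid)
      chars[s:(s + wid - 1L)] <- strsplit(elem, "", fixed = TRUE)[[1]]
      occupied[s:(s + wid - 1L)] <- TRUE
      mk <- mk + 1L
      manifest[[mk]] <- data.frame(
        type = "atract", chrom = config$chrom_name, start = s + 1L,
        end = s + tl, strand = "+", n = tl, flank5 = NA_character_,
        flank3 = NA_character_, atract5 = FALSE, stringsAsFactors = FALSE)
    }
  }
  genome <- stats::setNames(paste(chars, collapse = ""), config$chrom_name)
  list(genome = genome,
       manifest = do.call(rbind, manifest) %||%
         data.frame(type = character(), chrom = character(),
                    start = integer(), end = integer(), strand = character(),
                    n = integer(), flank5 = character(),
                    flank3 = character(), atract5 = logical()))
}

#' True conversion probability of every folded cytosine site
#'
#' Implements the generative reactivity model on the realised genome:
#' \code{p = p0 * g^d * flank factors * A-tract factor}, where \code{d} is
#' the distance in bases from the run's folded 3' end (d = 0 at the 3' C;
#' an isolated C has d = 0). Flank modifiers apply only at offsets outside
#' the run. CpG sites drawn methylated are set to the configured residual
#' reactivity. Probabilities are clamped to [0, 1].
#'
#' @param genome Genome (typically from [generate_genome()]).
#' @param config A \code{sim_config}.
#' @return Truth table data.frame: \code{chrom, pos, strand, run_n, d3,
#'   p_true, cpg, methylated}.
#' @export
site_conversion_probability <- function(genome, config) {
  runs <- find_polyc_runs(genome)
  atracts <- find_atracts(genome)
  fl <- run_atract_flags(runs, atracts, max_gap = 0L)
  ex <- expand_run_positions(runs)
  chrom <- runs$chrom[ex$row]
  strand <- runs$strand[ex$row]
  ctx <- folded_contexts(genome, chrom, ex$pos, strand, w = 3L)
  p <- config$p0 * config$gradient_factor^ex$d3
  for (off_chr in names(config$flank_modifiers)) {
    off <- as.integer(off_chr)
    mods <- config$flank_modifiers[[off_chr]]
    outside <- if (off < 0L) -off > ex$off5 else off > ex$d3
    b <- ctx_char(ctx, off)
    for (base in names(mods)) {
      hit <- outside & b == base
      p[hit] <- p[hit] * mods[[base]]
    }
  }
  p <- p * ifelse(fl$atract5[ex$row], config$atract_suppression, 1)
  p <- p * ifelse(fl$atract3[ex$row], config$atract_suppression3, 1)
  cpg <- ex$d3 == 0L & !is.na(runs$flank3[ex$row]) &
    runs$flank3[ex$row] == "G"
  set.seed(config$seed + 6L)
  meth <- cpg & stats::runif(length(p)) < config$cpg_methylated_fraction
  p[meth] <- config$cpg_meth_reactivity
  p <- pmin(pmax(p, 0), 1)
  out <- data.frame(chrom = chrom, pos = ex$pos, strand = strand,
                    run_n = runs$n[ex$row], d3 = ex$d3, p_true = p,
                    cpg = cpg, methylated = meth, stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Simulate pileup counts
#'
#' Converted-read counts at each folded C site are Binomial(depth, p_true);
#' off-target mismatches are Binomial(depth, error_rate) split uniformly
#' over the non-reference, non-conversion bases (two at C/G sites, three at
#' A/T sites). Deterministic under the config seed.
#'
#' @param genome Genome.
#' @param config A \code{sim_config}.
#' @param truth Optional precomputed truth table
#'   ([site_conversion_probability()]).
#' @return list(pileup = data.frame, truth = truth table).
#' @export
simulate_pileups <- function(genome, config, truth = NULL) {
  if (is.null(truth)) truth <- site_conversion_probability(genome, config)
  set.seed(config$seed + 2L)
  pieces <- lapply(names(genome), function(ch) {
    chars <- seq_chars(genome, ch)
    pos <- which(chars != "N")
    ref <- chars[pos]
    n <- length(pos)
    depth <- if (config$depth_model == "poisson")
      stats::rpois(n, config$depth) else rep(as.integer(config$depth), n)
    tt <- truth[truth$chrom == ch, , drop = FALSE]
    p_true <- numeric(n)
    m <- match(pos, tt$pos)
    p_true[!is.na(m)] <- tt$p_true[m[!is.na(m)]]
    conv <- stats::rbinom(n, depth, p_true)
    err <- pmin(stats::rbinom(n, depth, config$error_rate), depth - conv)
    isCG <- ref %in% c("C", "G")
    # split errors uniformly over the available non-ref, non-conversion
    # bases: two at C/G sites, three at A/T sites
    e1 <- stats::rbinom(n, err, ifelse(isCG, 0.5, 1 / 3))
    e2 <- ifelse(isCG, err - e1,
                 stats::rbinom(n, err - e1, 0.5))
    e3 <- err - e1 - e2
    refn <- depth - conv - err
    nA <- ifelse(ref == "A", refn,
          ifelse(ref == "G", conv,
          ifelse(ref == "C", e1, e1)))
    nC <- ifelse(ref == "C", refn,
          ifelse(ref == "A", e1,
          ifelse(ref == "G", e1, e2)))
    nG <- ifelse(ref == "G", refn,
          ifelse(ref == "A", e2,
          ifelse(ref == "C", e2, e3)))
    nT <- ifelse(ref == "T", refn,
          ifelse(ref == "C", conv,
          ifelse(ref == "A", e3, e2)))
    data.frame(chrom = ch, pos = pos, ref = ref, depth = depth,
               nA = nA, nC = nC, nG = nG, nT = nT, mapq = config$mapq,
               stringsAsFactors = FALSE)
  })
  list(pileup = do.call(rbind, pieces), truth = truth)
}

#' Simulate nucleosome dyads anchored to poly-C 5' ends
#'
#' Each dyad is anchored to a random planted poly-C run: an offset is drawn
#' from the footprint with the odds of positive-roll offsets multiplied by
#' \code{dyad_enrichment_odds}, and the dyad is placed so that the run's
#' folded 5' end lands at that offset. Odds of 1 give uniform placement.
#' Strengths are drawn from a Gamma(2, 2) distribution.
#'
#' @param genome Genome.
#' @param manifest Planting manifest from [generate_genome()].
#' @param roll A \code{roll_profile}.
#' @param config A \code{sim_config}.
#' @return Dyad data.frame (\code{chrom, dyad_pos, strength}) with
#'   attribute \code{"placements"}: the anchored run index and offset per
#'   dyad.
#' @export
simulate_dyads <- function(genome, manifest, roll, config) {
  set.seed(config$seed + 3L)
  runs <- manifest[manifest$type == "polyC", , drop = FALSE]
  nd <- as.integer(config$dyad_count)
  if (nd == 0L || nrow(runs) == 0L) {
    out <- data.frame(chrom = character(), dyad_pos = integer(),
                      strength = numeric(), stringsAsFactors = FALSE)
    attr(out, "placements") <- data.frame(run = integer(),
                                          offset = integer())
    return(out)
  }
  wts <- ifelse(roll$positive, config$dyad_enrichment_odds, 1)
  L <- genome_length(genome, config$chrom_name)
  ri <- integer(nd); oi <- integer(nd); dp <- integer(nd)
  for (i in seq_len(nd)) {
    repeat {
      r <- sample.int(nrow(runs), 1L)
      o <- sample(roll$offsets, 1L, prob = wts)
      e5 <- if (runs$strand[r] == "+") runs$start[r] else runs$end[r]
      d <- if (runs$strand[r] == "+") e5 - o else e5 + o
      if (d >= 1L && d <= L) break
    }
    ri[i] <- r; oi[i] <- o; dp[i] <- d
  }
  out <- data.frame(chrom = runs$chrom[ri], dyad_pos = dp,
                    strength = stats::rgamma(nd, shape = 2, rate = 2),
                    stringsAsFactors = FALSE)
  attr(out, "placements") <- data.frame(run = ri, offset = oi)
  out
}

#' Simulate de novo mutations per motif
#'
#' Every folded cytosine site is matched against the configured centered
#' context patterns (first match wins within a mutation class) and mutates
#' independently with the class rate. '-' strand hits are written as the
#' complementary reference G mutation. Deterministic under the config seed.
#'
#' @param genome Genome.
#' @param config A \code{sim_config}.
#' @return Mutation data.frame (\code{chrom, pos, ref, alt}) with attribute
#'   \code{"opportunities"}: eligible site counts per (pattern, class).
#' @export
simulate_mutations <- function(genome, config) {
  set.seed(config$seed + 4L)
  tab <- config$mutation_rate_table
  sites <- list()
  for (ch in names(genome)) {
    chars <- seq_chars(genome, ch)
    posC <- which(chars == "C"); posG <- which(chars == "G")
    sites[[ch]] <- data.frame(
      chrom = ch, pos = c(posC, posG),
      strand = c(rep("+", length(posC)), rep("-", length(posG))),
      stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, sites)
  ctx <- folded_contexts(genome, sites$chrom, sites$pos, sites$strand,
                         w = 3L)
  muts <- list(); mi <- 0L
  opp <- tab; opp$eligible <- 0L
  for (cl in unique(tab$class)) {
    rows <- which(tab$class == cl)
    assigned <- rep(FALSE, nrow(sites))
    alt_fold <- sub("^C>", "", cl)
    for (r in rows) {
      el <- !assigned & context_matches(ctx, tab$pattern[r])
      assigned <- assigned | el
      opp$eligible[r] <- sum(el)
      if (!any(el) || tab$rate[r] <= 0) next
      hit <- which(el)[stats::runif(sum(el)) < tab$rate[r]]
      if (length(hit) == 0L) next
      mi <- mi + 1L
      muts[[mi]] <- data.frame(
        chrom = sites$chrom[hit], pos = sites$pos[hit],
        ref = ifelse(sites$strand[hit] == "+", "C", "G"),
        alt = ifelse(sites$strand[hit] == "+", alt_fold,
                     comp_base(alt_fold)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, muts) %||%
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "opportunities") <- opp
  out
}

#' Simulate a loop-seq-style cyclizability table
#'
#' 50-mers are sampled from the genome; the latent bendability score is a
#' linear function of standardised TA-dinucleotide count and poly-C(>=4)
#' run count plus Gaussian noise, and each of the three replicates adds
#' independent replicate noise.
#'
#' @param genome Genome.
#' @param config A \code{sim_config}.
#' @return data.frame \code{seq, c26, c29, c31, mean_score} with attribute
#'   \code{"latent"} (the noise-free scores).
#' @export
simulate_cyclizability <- function(genome, config) {
  set.seed(config$seed + 5L)
  ch <- config$chrom_name
  L <- genome_length(genome, ch)
  n <- as.integer(config$cyc_n)
  starts <- sample.int(L - 49L, n, replace = TRUE)
  seqs <- substring(unname(genome[[ch]]), starts, starts + 49L)
  ok <- !grepl("N", seqs, fixed = TRUE)
  seqs <- seqs[ok]
  zs <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
    else x * 0
  ta <- count_dinucleotide(seqs, "TA")
  pc <- count_polyc_runs(seqs, 4L)
  resid_sd <- sqrt(max(0.1, 1 - config$cyc_beta_ta^2 -
                         config$cyc_beta_polyc^2))
  latent <- config$cyc_beta_ta * zs(ta) + config$cyc_beta_polyc * zs(pc) +
    stats::rnorm(length(seqs), sd = resid_sd)
  reps <- vapply(1:3, function(k)
    latent + stats::rnorm(length(seqs), sd = config$cyc_replicate_sd),
    numeric(length(seqs)))
  out <- data.frame(seq = seqs, c26 = reps[, 1], c29 = reps[, 2],
                    c31 = reps[, 3], stringsAsFactors = FALSE)
  out$mean_score <- (out$c26 + out$c29 + out$c31) / 3
  attr(out, "latent") <- latent
  out
}
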