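# Sequence-context machinery: maximal poly-C run detection (strand-folded),
# the polar 3'->5' reactivity gradient, flanking-base effects at isolated C,
# CpG handling, A-tract detection and the quasibinomial reactivity model.

#' Find all maximal poly-C runs, strand-folded
#'
#' Returns every maximal run of C on the reference ('+' strand) and every
#' maximal run of G folded onto '-' (a G-run read 3'->5' is a C-run on the
#' complementary strand, so its folded 5' end is the reference 3' end and
#' flanks are complemented and mirrored). \code{n = 1} runs are isolated
#' cytosines (DCD). Flanks at contig boundaries are \code{NA}.
#'
#' @param genome Genome as from [read_fasta()].
#' @return data.frame: \code{chrom, start, end} (reference coordinates,
#'   1-based inclusive), \code{strand, n, flank5, flank3} (folded flanking
#'   bases).
#' @export
find_polyc_runs <- function(genome) {
  out <- vector("list", length(genome) * 2L)
  k <- 0L
  for (ch in names(genome)) {
    chars <- seq_chars(genome, ch)
    r <- rle(chars)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    flank_lo <- ifelse(starts > 1L, chars[pmax(starts - 1L, 1L)], NA)
    flank_hi <- ifelse(ends < length(chars), chars[pmin(ends + 1L,
                                                        length(chars))], NA)
    iC <- which(r$values == "C")
    if (length(iC)) {
      k <- k + 1L
      out[[k]] <- data.frame(chrom = ch, start = starts[iC], end = ends[iC],
                             strand = "+", n = r$lengths[iC],
                             flank5 = flank_lo[iC], flank3 = flank_hi[iC],
                             stringsAsFactors = FALSE)
    }
    iG <- which(r$values == "G")
    if (length(iG)) {
      k <- k + 1L
      out[[k]] <- data.frame(chrom = ch, start = starts[iG], end = ends[iG],
                             strand = "-", n = r$lengths[iG],
                             flank5 = comp_base(flank_hi[iG]),
                             flank3 = comp_base(flank_lo[iG]),
                             stringsAsFactors = FALSE)
    }
  }
  runs <- do.call(rbind, out[seq_len(k)])
  if (is.null(runs)) {
    runs <- data.frame(chrom = character(), start = integer(),
                       end = integer(), strand = character(), n = integer(),
                       flank5 = character(), flank3 = character(),
                       stringsAsFactors = FALSE)
  }
  runs <- runs[order(runs$chrom, runs$start, runs$strand), , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

# Reference positions of a run's folded 5'->3' residues, expanded across all
# runs at once. Returns list(row = run index, pos, d3 = distance from the
# folded 3' end).
expand_run_positions <- function(runs) {
  lens <- runs$n
  row <- rep(seq_len(nrow(runs)), lens)
  off5 <- sequence(lens) - 1L            # 0 at the 5' end
  pos <- ifelse(runs$strand[row] == "+", runs$start[row] + off5,
                runs$end[row] - off5)
  list(row = row, pos = pos, off5 = off5, d3 = runs$n[row] - 1L - off5)
}

#' Attach per-position reactivities to runs
#'
#' Looks each run position up in a (filtered) site table and stores its
#' reactivity, ordered 5'->3' along the folded strand. Runs with any
#' unmeasured position are marked incomplete.
#'
#' @param runs Run table from [find_polyc_runs()].
#' @param sites Site table from [fold_pileup()] (typically after
#'   [apply_site_filters()]).
#' @return \code{runs} with list-column \code{site_reactivities} and logical
#'   \code{complete}.
#' @export
attach_run_reactivities <- function(runs, sites) {
  ex <- expand_run_positions(runs)
  sitekey <- paste(sites$chrom, sites$pos, sites$strand)
  key <- paste(runs$chrom[ex$row], ex$pos, runs$strand[ex$row])
  react <- sites$reactivity[match(key, sitekey)]
  per_run <- split(react, factor(ex$row, levels = seq_len(nrow(runs))))
  runs$site_reactivities <- I(unname(per_run))
  runs$complete <- !vapply(per_run, anyNA, logical(1))
  runs
}

run_terminal5 <- function(runs) {
  vapply(runs$site_reactivities, function(r) r[1], numeric(1))
}

run_terminal3 <- function(runs) {
  vapply(runs$site_reactivities, function(r) r[length(r)], numeric(1))
}

# Runs usable for flank-stratified statistics: measured everywhere, flanks
# defined and unambiguous.
complete_interior_runs <- function(runs) {
  ok <- runs$complete & !is.na(runs$flank5) & !is.na(runs$flank3) &
    runs$flank5 != "N" & runs$flank3 != "N"
  runs[ok, , drop = FALSE]
}

#' Polar gradient profile across poly-C runs
#'
#' For each run-length class, the mean reactivity (with SEM) at each
#' position ordered 5'->3', the terminal 5':3' ratio, and a per-step ratio
#' estimated by weighted log-linear regression of positional means on
#' distance from the 3' end. CpG handling: \code{"exclude-runs-with-3pG"}
#' restricts to D(C)nW runs (3' flank A or T), \code{"exclude-CpG-sites"}
#' keeps all runs but drops the 3'-terminal value of runs whose 3' flank is
#' G, \code{"include"} uses everything.
#'
#' @param runs Runs with reactivities ([attach_run_reactivities()]).
#' @param cpg_mode CpG handling mode (above).
#' @return list: \code{profile} (n, pos, mean, sem, count), \code{ratios}
#'   (n, ratio53, step_ratio, n_runs), \code{pooled_step_ratio} (classes
#'   n >= 2 combined), \code{pooled_ratio53}.
#' @export
gradient_profile <- function(runs,
                             cpg_mode = c("exclude-runs-with-3pG",
                                          "exclude-CpG-sites", "include")) {
  cpg_mode <- match.arg(cpg_mode)
  runs <- complete_interior_runs(runs)
  if (cpg_mode == "exclude-runs-with-3pG")
    runs <- runs[runs$flank3 %in% c("A", "T"), , drop = FALSE]
  if (nrow(runs) == 0L) stop("no usable runs", call. = FALSE)
  ex <- expand_run_positions(runs)
  react <- unlist(runs$site_reactivities, use.names = FALSE)
  keep <- rep(TRUE, length(react))
  if (cpg_mode == "exclude-CpG-sites")
    keep <- !(ex$d3 == 0L & runs$flank3[ex$row] == "G")
  n_of <- runs$n[ex$row]
  posi <- ex$off5 + 1L
  cls <- sort(unique(runs$n))
  prof <- do.call(rbind, lapply(cls, function(nn) {
    sel <- keep & n_of == nn
    if (!any(sel)) return(NULL)
    agg_m <- tapply(react[sel], posi[sel], mean)
    agg_s <- tapply(react[sel], posi[sel],
                    function(v) stats::sd(v) / sqrt(length(v)))
    agg_c <- tapply(react[sel], posi[sel], length)
    data.frame(n = nn, pos = as.integer(names(agg_m)),
               mean = as.numeric(agg_m), sem = as.numeric(agg_s),
               count = as.integer(agg_c))
  }))
  ratios <- do.call(rbind, lapply(cls, function(nn) {
    p <- prof[prof$n == nn, , drop = FALSE]
    r53 <- if (any(p$pos == 1L) && any(p$pos == nn))
      p$mean[p$pos == 1L] / p$mean[p$pos == nn] else NA_real_
    sr <- NA_real_
    if (nn >= 2L && nrow(p) >= 2L && all(p$mean > 0)) {
      d <- nn - p$pos
      fit <- stats::lm(log(p$mean) ~ d, weights = p$count)
      sr <- exp(unname(stats::coef(fit)[2]))
    }
    data.frame(n = nn, ratio53 = r53, step_ratio = sr,
               n_runs = sum(runs$n == nn))
  }))
  multi <- prof[prof$n >= 2L & prof$mean > 0, , drop = FALSE]
  pooled_step <- NA_real_
  if (nrow(multi) >= 2L) {
    d <- multi$n - multi$pos
    fit <- if (length(unique(multi$n)) >= 2L)
      stats::lm(log(multi$mean) ~ d + factor(multi$n),
                weights = multi$count)
    else stats::lm(log(multi$mean) ~ d, weights = multi$count)
    pooled_step <- exp(unname(stats::coef(fit)["d"]))
  }
  r2 <- runs[runs$n >= 2L, , drop = FALSE]
  pooled_r53 <- NA_real_
  if (nrow(r2) > 0L) {
    t5 <- run_terminal5(r2)
    t3 <- run_terminal3(r2)
    if (cpg_mode == "exclude-CpG-sites") {
      ok <- r2$flank3 != "G"
      t5 <- t5[ok]; t3 <- t3[ok]
    }
    if (length(t3) && mean(t3) > 0) pooled_r53 <- mean(t5) / mean(t3)
  }
  list(profile = prof, ratios = ratios, pooled_step_ratio = pooled_step,
       pooled_ratio53 = pooled_r53)
}

#' Gradient prevalence per run-length class
#'
#' Fraction of runs whose 5'-terminal reactivity strictly exceeds the
#' 3'-terminal reactivity (ties count as gradient-absent), with an exact
#' binomial 95\% CI.
#'
#' @param runs Runs with reactivities; classes with n >= 2 are reported.
#' @return data.frame: \code{n, n_runs, n_gradient, fraction, ci_lo, ci_hi}.
#' @export
gradient_prevalence <- function(runs) {
  runs <- runs[runs$complete & runs$n >= 2L, , drop = FALSE]
  cls <- sort(unique(runs$n))
  do.call(rbind, lapply(cls, function(nn) {
    r <- runs[runs$n == nn, , drop = FALSE]
    g <- sum(run_terminal5(r) > run_terminal3(r))
    bt <- stats::binom.test(g, nrow(r))
    data.frame(n = nn, n_runs = nrow(r), n_gradient = g,
               fraction = g / nrow(r), ci_lo = bt$conf.int[1],
               ci_hi = bt$conf.int[2])
  }))
}

ctx_char <- function(contexts, offset) {
  w <- (nchar(contexts[1]) - 1L) %/% 2L
  substr(contexts, w + 1L + offset, w + 1L + offset)
}

#' Flanking-base effects at isolated cytosines
#'
#' Restricted to isolated C sites (no C at folded positions -1/+1). For
#' each offset in -max_offset..+max_offset (excluding 0) and each base, the
#' mean reactivity with SEM, plus a Wilcoxon signed-rank test of that base
#' against all other bases at the offset. The test pairs sites by the full
#' remaining context: strata that contain both target-flank and
#' other-flank sites contribute one paired difference of stratum means.
#'
#' @param sites Site table (filtered); contexts must cover max_offset.
#' @param max_offset Largest flank distance examined (default 3).
#' @return data.frame: \code{offset, base, mean, sem, count,
#'   p_signed_rank, n_strata}. Bases absent at an offset get NA mean.
#' @export
flanking_effects <- function(sites, max_offset = 3L) {
  w <- (nchar(sites$context[1]) - 1L) %/% 2L
  if (max_offset > w)
    stop("context half-width ", w, " smaller than max_offset", call. = FALSE)
  iso <- ctx_char(sites$context, -1L) != "C" &
    ctx_char(sites$context, 1L) != "C" &
    !grepl("N", sites$context, fixed = TRUE)
  s <- sites[iso, , drop = FALSE]
  if (nrow(s) == 0L) stop("no isolated-C sites", call. = FALSE)
  offs <- setdiff(seq.int(-max_offset, max_offset), 0L)
  res <- expand.grid(offset = offs, base = DNA_BASES,
                     stringsAsFactors = FALSE)
  res$mean <- NA_real_; res$sem <- NA_real_; res$count <- 0L
  res$p_signed_rank <- NA_real_; res$n_strata <- 0L
  half <- (nchar(s$context[1]) - 1L) %/% 2L
  for (i in seq_len(nrow(res))) {
    o <- res$offset[i]; b <- res$base[i]
    at <- ctx_char(s$context, o)
    hit <- at == b
    if (!any(hit)) next
    res$mean[i] <- mean(s$reactivity[hit])
    res$sem[i] <- stats::sd(s$reactivity[hit]) / sqrt(sum(hit))
    res$count[i] <- sum(hit)
    # stratify by remaining context (mask the tested offset)
    strat <- s$context
    substr(strat, half + 1L + o, half + 1L + o) <- "."
    mt <- tapply(s$reactivity[hit], strat[hit], mean)
    mo <- tapply(s$reactivity[!hit], strat[!hit], mean)
    common <- intersect(names(mt), names(mo))
    diffs <- as.numeric(mt[common]) - as.numeric(mo[common])
    res$n_strata[i] <- length(diffs)
    if (length(diffs) >= 2L)
      res$p_signed_rank[i] <- wilcoxon_signed_rank(diffs)$p_value
  }
  res[order(res$offset, res$base), , drop = FALSE]
}

#' Classify sites by CpG status and reactivity
#'
#' A site is CpG iff its folded 3' neighbour is G. CpG sites below the
#' low-modification threshold (default 0.4\%) are labelled
#' \code{"CpG-low"} (consistent with near-complete methylation), others
#' \code{"CpG-reactive"}.
#'
#' @param sites Site table with folded contexts.
#' @param low_mod_threshold Reactivity threshold (default 0.004).
#' @return Character vector of labels
#'   \code{\{non-CpG, CpG-low, CpG-reactive\}}.
#' @export
classify_cpg <- function(sites, low_mod_threshold = 0.004) {
  nxt <- ctx_char(sites$context, 1L)
  ifelse(nxt != "G", "non-CpG",
         ifelse(sites$reactivity < low_mod_threshold, "CpG-low",
                "CpG-reactive"))
}

#' Find A-tracts
#'
#' An A-tract is four or more consecutive A:T base pairs containing no TA
#' dinucleotide step on the reference strand. Maximal A/T runs are split at
#' every TA step and fragments of length >= \code{min_len} are kept. The
#' definition is strand-symmetric (TA is its own reverse complement).
#'
#' @param genome Genome as from [read_fasta()].
#' @param min_len Minimum tract length (default 4).
#' @return data.frame: \code{chrom, start, end, length}.
#' @export
find_atracts <- function(genome, min_len = 4L) {
  out <- list()
  for (ch in names(genome)) {
    chars <- seq_chars(genome, ch)
    isW <- chars %in% c("A", "T")
    r <- rle(isW)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    wi <- which(r$values & r$lengths >= min_len)
    if (length(wi) == 0L) next
    # TA step start positions, sorted
    ta <- which(chars == "T" & c(chars[-1], "") == "A")
    frags_s <- integer(0); frags_e <- integer(0)
    for (j in wi) {
      s <- starts[j]; e <- ends[j]
      lo <- findInterval(s - 1L, ta) + 1L
      hi <- findInterval(e - 1L, ta)
      cuts <- if (hi >= lo) ta[lo:hi] else integer(0)
      fs <- c(s, cuts + 1L)
      fe <- c(cuts, e)
      ok <- fe - fs + 1L >= min_len
      frags_s <- c(frags_s, fs[ok]); frags_e <- c(frags_e, fe[ok])
    }
    if (length(frags_s))
      out[[ch]] <- data.frame(chrom = ch, start = frags_s, end = frags_e,
                              length = frags_e - frags_s + 1L,
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# Map each folded site to its containing run (every reference C/G belongs
# to exactly one strand-matched run). Returns run row indices.
site_run_index <- function(sites, runs) {
  ex <- expand_run_positions(runs)
  key <- paste(runs$chrom[ex$row], ex$pos, runs$strand[ex$row])
  m <- match(paste(sites$chrom, sites$pos, sites$strand), key)
  ex$row[m]
}

# A-tract adjacency for runs: does a tract end within max_gap bases of the
# run's folded 5' (or 3') terminus?
run_atract_flags <- function(runs, atracts, max_gap = 0L) {
  a5 <- logical(nrow(runs)); a3 <- logical(nrow(runs))
  for (ch in unique(runs$chrom)) {
    tr <- atracts[atracts$chrom == ch, , drop = FALSE]
    ri <- which(runs$chrom == ch)
    if (nrow(tr) == 0L || length(ri) == 0L) next
    # reference-coordinate gap on the low side: run start - tract end - 1
    low_adj <- vapply(ri, function(i) {
      any(runs$start[i] - tr$end - 1L >= 0L &
            runs$start[i] - tr$end - 1L <= max_gap)
    }, logical(1))
    high_adj <- vapply(ri, function(i) {
      any(tr$start - runs$end[i] - 1L >= 0L &
            tr$start - runs$end[i] - 1L <= max_gap)
    }, logical(1))
    plus <- runs$strand[ri] == "+"
    a5[ri] <- ifelse(plus, low_adj, high_adj)
    a3[ri] <- ifelse(plus, high_adj, low_adj)
  }
  data.frame(atract5 = a5, atract3 = a3)
}

local_at_content <- function(genome, chrom, pos, window) {
  out <- numeric(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    chars <- seq_chars(genome, ch)
    L <- length(chars)
    isW <- chars %in% c("A", "T")
    isN <- chars == "N"
    cw <- c(0, cumsum(isW))
    cn <- c(0, cumsum(isN))
    lo <- pmax(1L, pos[idx] - window)
    hi <- pmin(L, pos[idx] + window)
    nW <- cw[hi + 1L] - cw[lo] - isW[pos[idx]]
    nTot <- (hi - lo + 1L) - (cn[hi + 1L] - cn[lo]) - 1L
    out[idx] <- ifelse(nTot > 0, nW / nTot, NA_real_)
  }
  out
}

#' Quasibinomial model of A-tract and AT-content effects on reactivity
#'
#' Fits converted counts out of depth on: adjacent 5' and 3' A-tract
#' indicators (tract within \code{max_gap} bases of the run terminus),
#' local AT-content (fraction of A/T in \code{at_window} bases each side of
#' the site), a 5'-T flank indicator and a 5'-TA dinucleotide indicator,
#' with a logit link and free dispersion. Predictors that never vary in
#' the data are dropped with a warning before fitting.
#'
#' @param sites Filtered site table.
#' @param genome Genome.
#' @param at_window AT-content window half-width in bp (default 20).
#' @param max_gap Maximum tract-to-run gap counted as adjacent (default 0,
#'   i.e. touching).
#' @param runs Optional precomputed run table.
#' @param atracts Optional precomputed A-tract table.
#' @return A \code{bisreact_glm} (see [quasibinomial_irls()]).
#' @export
atract_glm <- function(sites, genome, at_window = 20L, max_gap = 0L,
                       runs = NULL, atracts = NULL) {
  if (is.null(runs)) runs <- find_polyc_runs(genome)
  if (is.null(atracts)) atracts <- find_atracts(genome)
  ri <- site_run_index(sites, runs)
  if (anyNA(ri)) stop("some sites not assignable to runs", call. = FALSE)
  fl <- run_atract_flags(runs, atracts, max_gap = max_gap)
  f5 <- runs$flank5[ri]
  ctx <- sites$context
  ta5 <- ctx_char(ctx, -2L) == "T" & ctx_char(ctx, -1L) == "A" &
    !is.na(f5)
  # the TA must sit immediately 5' of the run, so only 5'-terminal sites
  ex5 <- expand_run_positions(runs)
  is5 <- paste(sites$chrom, sites$pos, sites$strand) %in%
    paste(runs$chrom[ex5$row], ex5$pos, runs$strand[ex5$row])[ex5$off5 == 0L]
  ta5 <- ta5 & is5
  X <- cbind(intercept = 1,
             atract5 = as.numeric(fl$atract5[ri]),
             atract3 = as.numeric(fl$atract3[ri]),
             at_content = local_at_content(genome, sites$chrom, sites$pos,
                                           at_window),
             t5 = as.numeric(!is.na(f5) & f5 == "T"),
             ta5 = as.numeric(ta5))
  ok <- stats::complete.cases(X)
  X <- X[ok, , drop = FALSE]
  constant <- vapply(seq_len(ncol(X)), function(j)
    j > 1L && stats::sd(X[, j]) == 0, logical(1))
  if (any(constant)) {
    warning("dropping constant predictor(s): ",
            paste(colnames(X)[constant], collapse = ", "))
    X <- X[, !constant, drop = FALSE]
  }
  quasibinomial_irls(sites$converted[ok], sites$depth[ok], X)
}

#' Mean reactivity per folded k-mer context
#'
#' @param sites Filtered site table (apply the heterozygosity filter
#'   upstream).
#' @param k Odd motif width, at most the stored context width.
#' @return data.frame ranked by decreasing mean: \code{motif, mean, sem,
#'   count, is_gnc} (whether the motif is a G-block directly followed by a
#'   C-block, the poly-C 5'-end/GGGCCC-style context).
#' @export
motif_reactivity_table <- function(sites, k = 7L) {
  if (k %% 2L != 1L) stop("k must be odd", call. = FALSE)
  w <- (nchar(sites$context[1]) - 1L) %/% 2L
  if (k > 2L * w + 1L) stop("k exceeds stored context width", call. = FALSE)
  off <- w - (k - 1L) %/% 2L
  motif <- substr(sites$context, off + 1L, off + k)
  ok <- !grepl("N", motif, fixed = TRUE)
  motif <- motif[ok]
  react <- sites$reactivity[ok]
  mu <- tapply(react, motif, mean)
  sd_ <- tapply(react, motif, stats::sd)
  n_ <- tapply(react, motif, length)
  out <- data.frame(motif = names(mu), mean = as.numeric(mu),
                    sem = as.numeric(sd_) / sqrt(as.numeric(n_)),
                    count = as.integer(n_), stringsAsFactors = FALSE)
  out$is_gnc <- is_gnc_motif(out$motif)
  out <- out[order(-out$mean), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Is a motif a G-block followed by a C-block?
#'
#' True for motifs like GGGCCCC (centered on a C): all Gs, then all Cs,
#' with the central base a C.
#'
#' @param motif Character vector of odd-width motifs.
#' @return Logical vector.
#' @export
is_gnc_motif <- function(motif) {
  ctr <- (nchar(motif) + 1L) %/% 2L
  grepl("^G+C+$", motif) & substr(motif, ctr, ctr) == "C"
}

#' Regress per-k-mer reactivity on helical step parameters
#'
#' Computes the mean reactivity of each k-mer (each site contributes once
#' for every k-mer window of its folded context that covers the central C)
#' and regresses it on each supplied step-parameter column separately by
#' ordinary least squares.
#'
#' @param sites Filtered site table.
#' @param step_table data.frame with column \code{kmer} plus one numeric
#'   column per parameter (e.g. twist, roll, tilt, slide, shift, rise).
#' @param k k-mer width (2 or 4 in typical use).
#' @return data.frame: \code{parameter, slope, r, p, n_kmers, degenerate}.
#'   k-mers absent from the table are excluded with a warning.
#' @export
step_parameter_regression <- function(sites, step_table, k = 2L) {
  w <- (nchar(sites$context[1]) - 1L) %/% 2L
  if (k - 1L > w) stop("k too large for stored context", call. = FALSE)
  acc_m <- character(0); acc_r <- numeric(0)
  for (shift in 0:(k - 1L)) {
    s0 <- w + 1L - shift
    km <- substr(sites$context, s0, s0 + k - 1L)
    ok <- !grepl("N", km, fixed = TRUE) & nchar(km) == k
    acc_m <- c(acc_m, km[ok])
    acc_r <- c(acc_r, sites$reactivity[ok])
  }
  mu <- tapply(acc_r, acc_m, mean)
  km_tab <- data.frame(kmer = names(mu), mean = as.numeric(mu),
                       stringsAsFactors = FALSE)
  miss <- setdiff(km_tab$kmer, step_table$kmer)
  if (length(miss) > 0L)
    warning("k-mers missing from step table, excluded: ",
            paste(utils::head(miss, 5), collapse = ", "),
            if (length(miss) > 5) " ...")
  merged <- merge(km_tab, step_table, by = "kmer")
  params <- setdiff(names(step_table), "kmer")
  do.call(rbind, lapply(params, function(pn) {
    reg <- pearson_regression(merged[[pn]], merged$mean)
    data.frame(parameter = pn, slope = reg$slope, r = reg$r, p = reg$p,
               n_kmers = reg$n, degenerate = reg$degenerate,
               stringsAsFactors = FALSE)
  }))
}
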