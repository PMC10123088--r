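# Loop-seq-style cyclizability of 50-mers vs sequence-context reactivity
# and motif content. The reactivity of a 50-mer is summarised by a k-mer
# lookup model fitted from site data (4 bp windows by default); strands are
# folded, so reference G bases contribute as cytosines of the complementary
# strand.

# count occurrences of a dinucleotide per sequence (overlapping)
count_dinucleotide <- function(seqs, dinuc) {
  vapply(gregexpr(paste0("(?=", dinuc, ")"), seqs, perl = TRUE),
         function(m) sum(m > 0), numeric(1))
}

# count maximal C-or-G runs of at least min_len per sequence
count_polyc_runs <- function(seqs, min_len = 4L) {
  pat <- paste0("C{", min_len, ",}|G{", min_len, ",}")
  vapply(gregexpr(pat, seqs), function(m) sum(m > 0), numeric(1))
}

count_atracts_in_seqs <- function(seqs, min_len = 4L) {
  g <- stats::setNames(seqs, paste0("s", seq_along(seqs)))
  tr <- find_atracts(g, min_len = min_len)
  counts <- table(factor(tr$chrom, levels = names(g)))
  as.numeric(counts)
}

#' Fit a k-mer reactivity lookup model from site data
#'
#' Each site contributes its reactivity to the k-mer window containing its
#' central C (for even k the C sits at position \code{k/2}, i.e. the window
#' covers folded offsets \code{-(k/2 - 1) .. k/2}). Unseen k-mers are
#' imputed by the global mean reactivity.
#'
#' @param sites Filtered site table.
#' @param k Window width (default 4).
#' @return Object of class \code{reactivity_model}: named vector of k-mer
#'   means with the global mean and k as attributes.
#' @export
fit_reactivity_model <- function(sites, k = 4L) {
  w <- (nchar(sites$context[1]) - 1L) %/% 2L
  lead <- k %/% 2L - 1L      # bases 5' of the C inside the window
  if (lead + 1L > w || (k - lead - 1L) > w + 1L)
    stop("stored context too narrow for k = ", k, call. = FALSE)
  s0 <- w + 1L - lead
  km <- substr(sites$context, s0, s0 + k - 1L)
  ok <- !grepl("N", km, fixed = TRUE)
  mu <- tapply(sites$reactivity[ok], km[ok], mean)
  structure(as.numeric(mu), names = names(mu),
            global_mean = mean(sites$reactivity[ok]), k = k,
            class = "reactivity_model")
}

model_lookup <- function(model, kmers) {
  v <- unclass(model)[kmers]
  v[is.na(v)] <- attr(model, "global_mean")
  unname(v)
}

#' Mean model reactivity per cytosine of a 50-mer
#'
#' Averages, over every folded cytosine of each sequence (C bases, plus G
#' bases folded to the complementary strand), the model value of the k-mer
#' window containing it. Windows are shifted inward at sequence edges.
#' Sequences without any C or G are NA.
#'
#' @param seqs Character vector of sequences (50-mers in typical use).
#' @param model A \code{reactivity_model} from [fit_reactivity_model()].
#' @return Numeric vector, one mean per sequence.
#' @export
windowed_reactivity <- function(seqs, model) {
  k <- attr(model, "k")
  if (any(nchar(seqs) < k)) stop("window larger than sequence",
                                 call. = FALSE)
  lead <- k %/% 2L - 1L
  vapply(seqs, function(s) {
    L <- nchar(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    vals <- c()
    posC <- which(chars == "C")
    if (length(posC)) {
      st <- pmin(pmax(posC - lead, 1L), L - k + 1L)
      vals <- c(vals, model_lookup(model, substring(s, st, st + k - 1L)))
    }
    posG <- which(chars == "G")
    if (length(posG)) {
      # folded window: the C of the '-' strand at a reference G
      en <- pmax(pmin(posG + lead, L), k)
      wins <- substring(s, en - k + 1L, en)
      vals <- c(vals, model_lookup(model, revcomp(wins)))
    }
    if (length(vals) == 0L) NA_real_ else mean(vals)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Per-predictor regressions against mean cyclizability
#'
#' Ordinary least squares of the replicate-mean cyclizability score on each
#' predictor separately: windowed model reactivity (when a model is
#' supplied), G/C content, A-tract count, and the count of every
#' dinucleotide. Pearson r and two-sided p are reported; zero-variance
#' predictors are flagged and skipped.
#'
#' @param records Cyclizability table ([read_cyclizability_tsv()]).
#' @param reactivity_model Optional \code{reactivity_model}.
#' @return data.frame: \code{predictor, slope, r, p, n, skipped}.
#' @export
cyclizability_regressions <- function(records, reactivity_model = NULL) {
  preds <- list()
  if (!is.null(reactivity_model))
    preds$windowed_reactivity <- windowed_reactivity(records$seq,
                                                     reactivity_model)
  preds$gc_content <- (nchar(gsub("[AT]", "", records$seq))) /
    nchar(records$seq)
  preds$atract_count <- count_atracts_in_seqs(records$seq)
  for (d in as.vector(outer(DNA_BASES, DNA_BASES, paste0)))
    preds[[paste0("dinuc_", d)]] <- count_dinucleotide(records$seq, d)
  do.call(rbind, lapply(names(preds), function(pn) {
    x <- preds[[pn]]
    reg <- pearson_regression(x, records$mean_score)
    data.frame(predictor = pn, slope = reg$slope, r = reg$r, p = reg$p,
               n = reg$n, skipped = reg$degenerate,
               stringsAsFactors = FALSE)
  }))
}

#' Poly-C enrichment by cyclizability score
#'
#' Counts poly-C (or poly-G) runs of at least \code{run_min_len} per
#' 50-mer and compares the most-bendable half of the records against the
#' least-bendable half (and the top 1000 vs bottom 1000 when at least 2000
#' records are present). Ties in score are broken by sequence lexical
#' order; with an odd record count the middle record is dropped.
#'
#' @param records Cyclizability table.
#' @param run_min_len Minimum qualifying run length (default 4).
#' @return list: \code{halves} (count_top, count_bottom, enrichment,
#'   chisq_p), \code{extremes} (same for top/bottom 1000, NULL when
#'   skipped).
#' @export
polyc_enrichment_by_score <- function(records, run_min_len = 4L) {
  ord <- order(-records$mean_score, records$seq, method = "radix")
  runs <- count_polyc_runs(records$seq, run_min_len)[ord]
  n <- length(runs)
  nh <- n %/% 2L
  half <- function(top, bottom) {
    ct <- sum(top); cb <- sum(bottom)
    tst <- chi_square(c(ct, cb), c(0.5, 0.5) * (ct + cb))
    list(count_top = ct, count_bottom = cb,
         enrichment = if (cb > 0) ct / cb else NA_real_,
         chisq_stat = tst$statistic, chisq_p = tst$p_value)
  }
  out <- list(halves = half(runs[seq_len(nh)],
                            runs[seq.int(n - nh + 1L, n)]))
  if (n >= 2000L) {
    out$extremes <- half(runs[1:1000], runs[seq.int(n - 999L, n)])
  } else {
    warning("fewer than 2000 records: extreme-set comparison skipped")
    out$extremes <- NULL
  }
  out
}

#' Replicate-noise report
#'
#' Fraction of records whose replicate standard deviation (sample SD over
#' c26/c29/c31) exceeds the magnitude of their mean score.
#'
#' @param records Cyclizability table.
#' @return list: \code{fraction}, \code{n}.
#' @export
replicate_noise_report <- function(records) {
  sds <- apply(cbind(records$c26, records$c29, records$c31), 1, stats::sd)
  list(fraction = mean(sds > abs(records$mean_score)), n = nrow(records))
}
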