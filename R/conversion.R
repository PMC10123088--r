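# Strand-folded per-cytosine conversion scoring. Both strands contribute to
# one statistic: a G -> A transition on the reference is read as C -> T on
# the complementary strand, and contexts at '-' sites are
# reverse-complemented so a G-run context (e.g. HGGGH) is recorded as its
# folded poly-C equivalent (DCCCD).

#' Fold pileup records into cytosine sites
#'
#' Reference-C positions become '+' strand sites with \code{converted} =
#' T count; reference-G positions become '-' strand sites with
#' \code{converted} = A count. All remaining non-reference reads count as
#' \code{other_mismatch} (on '-' this includes C reads: only the
#' Watson-Crick complement transition is bisulfite-attributable).
#' Reference A/T positions yield no site.
#'
#' @param pileup Pileup data.frame (see [read_pileup_tsv()]).
#' @param genome Genome as from [read_fasta()].
#' @param context_halfwidth Half-width of the folded context written for
#'   each site (default 3: a heptamer centered on the C).
#' @return data.frame of sites: \code{chrom, pos, strand, depth, converted,
#'   other_mismatch, reactivity, error_rate, mapq, context}. Sites with
#'   zero depth are given reactivity/error 0.
#' @export
fold_pileup <- function(pileup, genome, context_halfwidth = 3L) {
  isC <- pileup$ref == "C"
  isG <- pileup$ref == "G"
  sub <- pileup[isC | isG, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), depth = integer(),
                      converted = integer(), other_mismatch = integer(),
                      reactivity = numeric(), error_rate = numeric(),
                      mapq = numeric(), context = character(),
                      stringsAsFactors = FALSE))
  }
  strand <- ifelse(sub$ref == "C", "+", "-")
  converted <- ifelse(sub$ref == "C", sub$nT, sub$nA)
  ref_count <- ifelse(sub$ref == "C", sub$nC, sub$nG)
  other <- sub$depth - ref_count - converted
  reactivity <- ifelse(sub$depth > 0, converted / sub$depth, 0)
  error_rate <- ifelse(sub$depth > 0, other / sub$depth, 0)
  ctx <- folded_contexts(genome, sub$chrom, sub$pos, strand,
                         w = context_halfwidth)
  data.frame(chrom = sub$chrom, pos = sub$pos, strand = strand,
             depth = sub$depth, converted = converted,
             other_mismatch = other, reactivity = reactivity,
             error_rate = error_rate, mapq = sub$mapq, context = ctx,
             stringsAsFactors = FALSE)
}

#' Site-level filters
#'
#' Keeps sites with depth >= \code{min_depth}, mean mapping quality >=
#' \code{min_mapq} and reactivity <= \code{het_max_reactivity} (sites
#' converted in more than 40\% of reads are excluded as possible
#' heterozygous SNVs). All bounds inclusive on the kept side.
#'
#' @param sites Site data.frame from [fold_pileup()].
#' @param min_depth Minimum read depth (default 500).
#' @param min_mapq Minimum mean mapping quality (default 20).
#' @param het_max_reactivity Heterozygosity ceiling on reactivity
#'   (default 0.40); set to \code{Inf} to disable.
#' @return list(kept = sites, excluded = sites with a \code{reason} column).
#'   \code{nrow(kept) + nrow(excluded) == nrow(sites)} always.
#' @export
apply_site_filters <- function(sites, min_depth = 500L, min_mapq = 20,
                               het_max_reactivity = 0.40) {
  low_depth <- sites$depth < min_depth
  low_mapq <- !low_depth & sites$mapq < min_mapq
  het <- !low_depth & !low_mapq & sites$reactivity > het_max_reactivity
  keep <- !(low_depth | low_mapq | het)
  excluded <- sites[!keep, , drop = FALSE]
  excluded$reason <- ifelse(low_depth[!keep], "depth",
                            ifelse(low_mapq[!keep], "mapq", "heterozygosity"))
  list(kept = sites[keep, , drop = FALSE], excluded = excluded)
}

#' Summarise off-target (non-conversion) error rates
#'
#' Reports the mean per-site error rate (fraction of reads that are neither
#' the reference base nor the bisulfite transition) overall and, when a
#' grouping is supplied, per group with pairwise two-tailed Welch t-tests.
#'
#' @param sites Site data.frame.
#' @param groups Optional factor/character vector, one label per site.
#' @return list(overall_mean, by_group = data.frame(group, mean, n),
#'   comparisons = data.frame(group1, group2, statistic, p, degenerate)).
#'   Empty or single-site groups are reported with NA comparisons rather
#'   than raising.
#' @export
summarize_error <- function(sites, groups = NULL) {
  if (nrow(sites) == 0L) stop("no sites supplied", call. = FALSE)
  out <- list(overall_mean = mean(sites$error_rate))
  if (!is.null(groups)) {
    groups <- as.character(groups)
    gl <- sort(unique(groups))
    out$by_group <- data.frame(
      group = gl,
      mean = vapply(gl, function(g) mean(sites$error_rate[groups == g]),
                    numeric(1)),
      n = vapply(gl, function(g) sum(groups == g), integer(1)),
      row.names = NULL, stringsAsFactors = FALSE)
    cmp <- NULL
    if (length(gl) >= 2L) {
      pairs <- utils::combn(gl, 2L)
      cmp <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                        statistic = NA_real_, p = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE)
      for (k in seq_len(ncol(pairs))) {
        tr <- t_test_two_tailed(sites$error_rate[groups == pairs[1, k]],
                                sites$error_rate[groups == pairs[2, k]])
        cmp$statistic[k] <- tr$statistic
        cmp$p[k] <- tr$p_value
        cmp$degenerate[k] <- tr$degenerate
      }
    }
    out$comparisons <- cmp
  }
  out
}
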