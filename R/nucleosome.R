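# Dyad-relative positioning of poly-C run ends against a nucleosome roll
# profile. Offsets are relative to the dyad (point of internal symmetry);
# positive roll bends DNA toward the major groove.

#' Construct a dyad-relative roll profile
#'
#' Accepts either 147 values (offsets -73..73) or 146 values (offset 0
#' absent: the dyad sits between -1 and +1). Positive-roll windows are
#' derived from the sign of the roll after smoothing single-offset sign
#' flips with a 3-offset majority filter.
#'
#' @param values Roll angles (degrees), ordered by offset.
#' @param offsets Optional explicit integer offsets (derived from the
#'   footprint length when omitted).
#' @return Object of class \code{roll_profile}: \code{values, offsets,
#'   footprint_length, positive} (smoothed positive-roll indicator) and
#'   \code{positive_windows} (data.frame of maximal positive intervals).
#' @export
roll_profile <- function(values, offsets = NULL) {
  n <- length(values)
  if (is.null(offsets)) {
    if (n == 147L) offsets <- -73:73
    else if (n == 146L) offsets <- setdiff(-73:73, 0L)
    else stop("roll profile must have 146 or 147 values (got ", n, ")",
              call. = FALSE)
  }
  if (length(offsets) != n)
    stop("offsets and values lengths differ", call. = FALSE)
  if (!n %in% c(146L, 147L))
    stop("roll profile must have 146 or 147 values (got ", n, ")",
         call. = FALSE)
  pos_raw <- values > 0
  pos <- pos_raw
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      pos[i] <- sum(pos_raw[(i - 1L):(i + 1L)]) >= 2L
    }
  }
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  iw <- which(r$values)
  windows <- data.frame(start_offset = offsets[starts[iw]],
                        end_offset = offsets[ends[iw]])
  structure(list(values = as.numeric(values), offsets = as.integer(offsets),
                 footprint_length = n, positive = pos,
                 positive_windows = windows),
            class = "roll_profile")
}

#' Synthetic nucleosome roll profile
#'
#' A sinusoidal stand-in for the crystal-structure roll profile: roll
#' oscillates with the ~10 bp helical period, positive (major-groove
#' directed) at the dyad and at multiples of the period from it. Intended
#' for simulation and testing when no measured profile is supplied; it
#' reproduces the alternation of positive and negative roll, not the
#' measured amplitudes.
#'
#' @param footprint 146 or 147 (default 147).
#' @param period Oscillation period in bp (default 10.2).
#' @param amplitude Peak roll in degrees (default 4).
#' @return A \code{roll_profile}.
#' @export
synthetic_roll_profile <- function(footprint = 147L, period = 10.2,
                                   amplitude = 4) {
  offsets <- if (footprint == 147L) -73:73 else setdiff(-73:73, 0L)
  roll_profile(amplitude * cos(2 * pi * offsets / period), offsets)
}

#' Offset of a position from a dyad, strand-reflected
#'
#' For '+' runs the offset is \code{position - dyad_pos}; for '-' runs it
#' is \code{dyad_pos - position}, so 5' ends are comparable across
#' strands. Returns NA when the offset is outside the footprint.
#'
#' @param position Reference position(s).
#' @param dyad_pos Dyad position(s).
#' @param strand '+' or '-' (folded C-run strand), recycled.
#' @param roll Roll profile defining the admissible offsets.
#' @return Integer offsets, NA outside the footprint.
#' @export
dyad_offset <- function(position, dyad_pos, strand, roll) {
  n <- max(length(position), length(dyad_pos), length(strand))
  position <- rep_len(position, n)
  dyad_pos <- rep_len(dyad_pos, n)
  strand <- rep_len(strand, n)
  off <- ifelse(strand == "+", position - dyad_pos, dyad_pos - position)
  off[!off %in% roll$offsets] <- NA_integer_
  as.integer(off)
}

# All (end position, dyad) incidences within the footprint, per chrom.
# Returns offsets (one per incidence).
end_dyad_offsets <- function(ends_pos, ends_strand, chrom, dyads, roll) {
  half <- max(abs(roll$offsets))
  acc <- vector("list", length(ends_pos))
  for (ch in unique(chrom)) {
    dp <- sort(dyads$dyad_pos[dyads$chrom == ch])
    if (length(dp) == 0L) next
    idx <- which(chrom == ch)
    for (i in idx) {
      p <- ends_pos[i]
      lo <- findInterval(p - half - 1L, dp) + 1L
      hi <- findInterval(p + half, dp)
      if (hi < lo) next
      off <- dyad_offset(rep(p, hi - lo + 1L), dp[lo:hi],
                         ends_strand[i], roll)
      acc[[i]] <- off[!is.na(off)]
    }
  }
  as.integer(unlist(acc, use.names = FALSE))
}

#' Positive-roll enrichment of a set of dyad-relative offsets
#'
#' Tests the fraction of offsets falling in positive-roll windows against
#' the expectation proportional to window width (chi-square), and the
#' observed odds ratio relative to uniform placement.
#'
#' @param offsets Integer dyad-relative offsets (within the footprint).
#' @param roll A \code{roll_profile}.
#' @return list: \code{n, frac_positive, expected_frac, odds_ratio,
#'   chisq_stat, chisq_p}.
#' @export
offset_enrichment <- function(offsets, roll) {
  offsets <- offsets[offsets %in% roll$offsets]
  n <- length(offsets)
  exp_frac <- mean(roll$positive)
  if (n == 0L)
    return(list(n = 0L, frac_positive = NA_real_,
                expected_frac = exp_frac, odds_ratio = NA_real_,
                chisq_stat = NA_real_, chisq_p = NA_real_))
  in_pos <- sum(roll$positive[match(offsets, roll$offsets)])
  ct <- chi_square(c(in_pos, n - in_pos), c(exp_frac, 1 - exp_frac) * n)
  odds <- (in_pos / max(n - in_pos, 1)) / (exp_frac / (1 - exp_frac))
  list(n = n, frac_positive = in_pos / n, expected_frac = exp_frac,
       odds_ratio = odds, chisq_stat = ct$statistic, chisq_p = ct$p_value)
}

#' Enrichment of poly-C run ends around nucleosome dyads
#'
#' Counts 5' and 3' run ends at each dyad-relative offset (one incidence
#' per overlapping dyad) and tests, per end type: (a) the fraction of
#' incidences falling in positive-roll windows against the expectation
#' proportional to window width (chi-square), and (b) the regression of
#' per-offset end density on the roll value.
#'
#' @param runs Run table ([find_polyc_runs()]); filter to the classes of
#'   interest first.
#' @param dyads Dyad table ([read_dyads_bed()]).
#' @param roll A \code{roll_profile}.
#' @return list: \code{table} (offset, roll, positive, count_end5,
#'   count_end3), \code{stats} (end, n, frac_positive, expected_frac,
#'   chisq_stat, chisq_p, roll_slope, roll_r, roll_p). Ends with no
#'   incidences are reported with NA statistics.
#' @export
end_enrichment <- function(runs, dyads, roll) {
  end5 <- ifelse(runs$strand == "+", runs$start, runs$end)
  end3 <- ifelse(runs$strand == "+", runs$end, runs$start)
  off5 <- end_dyad_offsets(end5, runs$strand, runs$chrom, dyads, roll)
  off3 <- end_dyad_offsets(end3, runs$strand, runs$chrom, dyads, roll)
  tab <- data.frame(offset = roll$offsets, roll = roll$values,
                    positive = roll$positive)
  tab$count_end5 <- as.integer(table(factor(off5, levels = roll$offsets)))
  tab$count_end3 <- as.integer(table(factor(off3, levels = roll$offsets)))
  exp_frac <- mean(roll$positive)
  one_end <- function(offv, counts, label) {
    n <- length(offv)
    if (n == 0L)
      return(data.frame(end = label, n = 0L, frac_positive = NA_real_,
                        expected_frac = exp_frac, chisq_stat = NA_real_,
                        chisq_p = NA_real_, roll_slope = NA_real_,
                        roll_r = NA_real_, roll_p = NA_real_,
                        stringsAsFactors = FALSE))
    in_pos <- sum(counts[roll$positive])
    ct <- chi_square(c(in_pos, n - in_pos),
                     c(exp_frac, 1 - exp_frac) * n)
    reg <- pearson_regression(roll$values, counts / n)
    data.frame(end = label, n = n, frac_positive = in_pos / n,
               expected_frac = exp_frac, chisq_stat = ct$statistic,
               chisq_p = ct$p_value, roll_slope = reg$slope,
               roll_r = reg$r, roll_p = reg$p, stringsAsFactors = FALSE)
  }
  stats <- rbind(one_end(off5, tab$count_end5, "5p"),
                 one_end(off3, tab$count_end3, "3p"))
  list(table = tab, stats = stats)
}

#' Sliding-window reactivity around dyads
#'
#' For each dyad-relative offset, the mean over dyad incidences of the
#' window-averaged reactivity centered at that offset (default 7 bp
#' windows: the mean of site reactivities within +/-3 of the position).
#' The curve's Pearson correlation with the roll profile is reported,
#' optionally per dyad-strength quantile bin.
#'
#' @param sites Filtered site table.
#' @param dyads Dyad table.
#' @param roll A \code{roll_profile}.
#' @param window Odd window width (default 7).
#' @param strength_bins Number of dyad-strength quantile bins (default 1 =
#'   no stratification).
#' @return list of per-bin results: \code{profile} (offset, mean_reactivity,
#'   n), \code{roll_correlation} (r, p, degenerate).
#' @export
sliding_reactivity_profile <- function(sites, dyads, roll, window = 7L,
                                       strength_bins = 1L) {
  if (window %% 2L != 1L) stop("window must be odd", call. = FALSE)
  hw <- (window - 1L) %/% 2L
  # per-position window-averaged reactivity, per chrom
  wavg <- list()
  for (ch in unique(sites$chrom)) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    L <- max(c(s$pos, dyads$dyad_pos[dyads$chrom == ch])) + 80L
    sum_r <- numeric(L); cnt <- numeric(L)
    for (d in -hw:hw) {
      at <- s$pos + d
      ok <- at >= 1L & at <= L
      sum_r[at[ok]] <- sum_r[at[ok]] + s$reactivity[ok]
      cnt[at[ok]] <- cnt[at[ok]] + 1
    }
    wavg[[ch]] <- ifelse(cnt > 0, sum_r / pmax(cnt, 1), NA_real_)
  }
  if (strength_bins > 1L) {
    qs <- stats::quantile(dyads$strength,
                          probs = seq(0, 1, length.out = strength_bins + 1L))
    bin <- cut(dyads$strength, unique(qs), include.lowest = TRUE,
               labels = FALSE)
  } else bin <- rep(1L, nrow(dyads))
  lapply(seq_len(max(bin)), function(b) {
    dd <- dyads[bin == b, , drop = FALSE]
    acc <- matrix(0, nrow = length(roll$offsets), ncol = 2)
    for (i in seq_len(nrow(dd))) {
      wa <- wavg[[dd$chrom[i]]]
      if (is.null(wa)) next
      at <- dd$dyad_pos[i] + roll$offsets
      ok <- at >= 1L & at <= length(wa) & !is.na(wa[at])
      acc[ok, 1] <- acc[ok, 1] + wa[at[ok]]
      acc[ok, 2] <- acc[ok, 2] + 1
    }
    prof <- data.frame(offset = roll$offsets,
                       mean_reactivity = ifelse(acc[, 2] > 0,
                                                acc[, 1] / pmax(acc[, 2], 1),
                                                NA_real_),
                       n = acc[, 2])
    ok <- !is.na(prof$mean_reactivity)
    reg <- pearson_regression(roll$values[ok], prof$mean_reactivity[ok])
    list(profile = prof,
         roll_correlation = list(r = reg$r, p = reg$p,
                                 degenerate = reg$degenerate))
  })
}
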