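# Independent oracles and fixture builders used across the suite.

# Regex-based poly-C run scan (independent of the rle-based implementation):
# matches C{1,} on '+' and G{1,} folded to '-', with flanks by substring.
oracle_polyc_runs <- function(genome) {
  out <- list(); k <- 0L
  for (ch in names(genome)) {
    s <- unname(genome[[ch]])
    L <- nchar(s)
    for (spec in list(list(pat = "C+", strand = "+"),
                      list(pat = "G+", strand = "-"))) {
      m <- gregexpr(spec$pat, s)[[1]]
      if (m[1] == -1L) next
      st <- as.integer(m)
      en <- st + attr(m, "match.length") - 1L
      lo <- ifelse(st > 1L, substring(s, st - 1L, st - 1L), NA)
      hi <- ifelse(en < L, substring(s, en + 1L, en + 1L), NA)
      k <- k + 1L
      if (spec$strand == "+") {
        out[[k]] <- data.frame(chrom = ch, start = st, end = en,
                               strand = "+", n = en - st + 1L,
                               flank5 = lo, flank3 = hi,
                               stringsAsFactors = FALSE)
      } else {
        out[[k]] <- data.frame(chrom = ch, start = st, end = en,
                               strand = "-", n = en - st + 1L,
                               flank5 = chartr("ACGTN", "TGCAN", hi),
                               flank3 = chartr("ACGTN", "TGCAN", lo),
                               stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Regex-based A-tract scan: maximal [AT]{4,} matches, fragments delimited
# by TA step positions found with a lookahead.
oracle_atracts <- function(genome, min_len = 4L) {
  out <- list(); k <- 0L
  for (ch in names(genome)) {
    s <- unname(genome[[ch]])
    m <- gregexpr(sprintf("[AT]{%d,}", min_len), s)[[1]]
    if (m[1] == -1L) next
    st <- as.integer(m)
    en <- st + attr(m, "match.length") - 1L
    for (j in seq_along(st)) {
      seg <- substring(s, st[j], en[j])
      ta <- gregexpr("(?=TA)", seg, perl = TRUE)[[1]]
      cuts <- if (ta[1] == -1L) integer(0) else as.integer(ta)
      fs <- c(1L, cuts + 1L)
      fe <- c(cuts, nchar(seg))
      for (q in seq_along(fs)) {
        if (fe[q] - fs[q] + 1L >= min_len) {
          k <- k + 1L
          out[[k]] <- data.frame(chrom = ch, start = st[j] + fs[q] - 1L,
                                 end = st[j] + fe[q] - 1L,
                                 length = fe[q] - fs[q] + 1L,
                                 stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(res)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Brute-force count of CpG-excluded run-end motif instances by regex, for
# one (n-range, 5'-flank, end) stratum, both strands.
oracle_end_count <- function(genome, nmin, nmax, flank5, end) {
  total <- 0L
  for (ch in names(genome)) {
    s <- unname(genome[[ch]])
    # '+' strand: flank5 C-run flank3, run length in [nmin, nmax]
    if (end == "5p") {
      pat_p <- sprintf("(?=%s(C{%d,%d})[^C])", flank5, nmin, nmax)
      pat_m <- sprintf("(?=[^G](G{%d,%d})%s)", nmin, nmax,
                       chartr("ACGT", "TGCA", flank5))
    } else {
      # 3' end, CpG excluded: folded 3' flank must not be G (and not C)
      pat_p <- sprintf("(?=%s(C{%d,%d})[^CG])", flank5, nmin, nmax)
      pat_m <- sprintf("(?=[^GC](G{%d,%d})%s)", nmin, nmax,
                       chartr("ACGT", "TGCA", flank5))
    }
    for (pat in c(pat_p, pat_m)) {
      m <- gregexpr(pat, s, perl = TRUE)[[1]]
      if (m[1] != -1L) total <- total + length(m)
    }
  }
  total
}

# Mirror a pileup table onto the reverse-complemented genome: positions are
# reflected and base counts complement-swapped.
mirror_pileup <- function(pileup, L) {
  data.frame(chrom = pileup$chrom, pos = L + 1L - pileup$pos,
             ref = chartr("ACGT", "TGCA", pileup$ref),
             depth = pileup$depth, nA = pileup$nT, nC = pileup$nG,
             nG = pileup$nC, nT = pileup$nA, mapq = pileup$mapq,
             stringsAsFactors = FALSE)
}

revcomp_genome <- function(genome) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(genome)))
  names(rc) <- names(genome)
  rc
}

random_genome <- function(L, gc = 0.5, name = "chr1") {
  stats::setNames(paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                               prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                        (1 - gc) / 2)),
                        collapse = ""), name)
}

# minimal pileup row builder
pileup_row <- function(pos, ref, counts, mapq = 60, chrom = "chr1") {
  cc <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  cc[names(counts)] <- as.integer(counts)
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
             depth = sum(cc), nA = cc[["A"]], nC = cc[["C"]],
             nG = cc[["G"]], nT = cc[["T"]], mapq = mapq,
             stringsAsFactors = FALSE)
}
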