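# Shared sequence helpers. A genome is a named character vector of
# uppercase sequences over {A,C,G,T,N}; coordinates are 1-based inclusive.

DNA_BASES <- c("A", "C", "G", "T")

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    comp_base(paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

seq_chars <- function(genome, chrom) {
  strsplit(unname(genome[[chrom]]), "", fixed = TRUE)[[1]]
}

genome_length <- function(genome, chrom) nchar(unname(genome[[chrom]]))

#' @keywords internal
validate_genome <- function(genome) {
  if (is.null(names(genome)) || any(!nzchar(names(genome))))
    stop("genome sequences must be named", call. = FALSE)
  bad <- grepl("[^ACGTN]", genome)
  if (any(bad))
    stop("genome contains characters outside {A,C,G,T,N}: ",
         paste(names(genome)[bad], collapse = ", "), call. = FALSE)
  invisible(genome)
}

# Substring of a chromosome, clipped to bounds; returns NA if fully outside.
genome_sub <- function(genome, chrom, start, end) {
  L <- genome_length(genome, chrom)
  s <- max(1L, start); e <- min(L, end)
  if (s > e) return(NA_character_)
  substr(unname(genome[[chrom]]), s, e)
}

# Folded context of half-width w around a 1-based position: written 5'->3'
# on the strand carrying the C ('-' contexts are reverse-complemented).
# Positions outside the contig are padded with 'N'.
folded_context <- function(genome, chrom, pos, strand, w = 3L) {
  L <- genome_length(genome, chrom)
  lo <- pos - w; hi <- pos + w
  core <- genome_sub(genome, chrom, lo, hi)
  pad5 <- strrep("N", max(0L, 1L - lo))
  pad3 <- strrep("N", max(0L, hi - L))
  ctx <- paste0(pad5, core, pad3)
  if (strand == "-") ctx <- revcomp(ctx) else ctx
}

# Vectorised folded contexts for many positions at once. N-padded at
# contig edges; '-' contexts reverse-complemented.
folded_contexts <- function(genome, chrom, pos, strand, w = 3L) {
  ctx <- character(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- unname(genome[[ch]])
    L <- nchar(s)
    lo <- pos[idx] - w; hi <- pos[idx] + w
    core <- substring(s, pmax(1L, lo), pmin(L, hi))
    pad5 <- strrep("N", pmax(0L, 1L - lo))
    pad3 <- strrep("N", pmax(0L, hi - L))
    ctx[idx] <- paste0(pad5, core, pad3)
  }
  neg <- strand == "-"
  if (any(neg)) {
    rc <- Biostrings::reverseComplement(Biostrings::DNAStringSet(ctx[neg]))
    ctx[neg] <- as.character(rc)
  }
  ctx
}

# IUPAC-ish pattern matching on folded contexts (single characters).
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), S = c("C", "G"), R = c("A", "G"), Y = c("C", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

base_matches <- function(base, code) {
  set <- IUPAC_SETS[[code]]
  if (is.null(set)) stop("unknown IUPAC code: ", code, call. = FALSE)
  base %in% set
}

# Vectorised: does each context string match a centered IUPAC pattern?
# Pattern length must be odd and <= context length; both are centered.
context_matches <- function(contexts, pattern) {
  pl <- nchar(pattern)
  cl <- nchar(contexts[1])
  if (pl %% 2L != 1L) stop("pattern length must be odd", call. = FALSE)
  if (pl > cl) stop("pattern longer than context", call. = FALSE)
  off <- (cl - pl) %/% 2L
  ok <- rep(TRUE, length(contexts))
  pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
  for (i in seq_len(pl)) {
    b <- substr(contexts, off + i, off + i)
    ok <- ok & base_matches(b, pat[i])
  }
  ok
}

`%||%` <- function(a, b) if (is.null(a)) b else a
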