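#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and validated against the alphabet
#' \{A,C,G,T,N\}. Multi-record files are preserved in order.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names are record ids up to
#'   the first whitespace).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(trimws(lines[nonempty[1]]), ">"))
    stop("malformed FASTA header at line ", nonempty[1], " of ", path,
         call. = FALSE)
  is_seq <- !startsWith(trimws(lines), ">") & nzchar(trimws(lines))
  bad <- which(is_seq & grepl("[^ACGTNacgtn]", lines))
  if (length(bad) > 0L)
    stop("illegal sequence character at line ", bad[1], " of ", path,
         call. = FALSE)
  set <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("\\s.*$", "", names(set))
  validate_genome(out)
}

#' Write a genome to FASTA
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(genome, path) {
  validate_genome(genome)
  set <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

read_tsv_commented <- function(path, required_cols, colClasses = NA) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = colClasses)
  miss <- setdiff(required_cols, names(df))
  if (length(miss) > 0L)
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

write_tsv_commented <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments) > 0L) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-base pileup counts
#'
#' Expects a tab-delimited file with header columns
#' \code{chrom pos ref depth nA nC nG nT mapq}. Each record is validated
#' against the reference genome and the invariant
#' \code{nA + nC + nG + nT == depth}.
#'
#' @param path Path to the pileup TSV.
#' @param genome Genome as returned by [read_fasta()].
#' @return data.frame with one row per position.
#' @export
read_pileup_tsv <- function(path, genome) {
  df <- read_tsv_commented(path, c("chrom", "pos", "ref", "depth",
                                   "nA", "nC", "nG", "nT", "mapq"),
                           colClasses = c(chrom = "character",
                                          ref = "character"))
  validate_pileup(df, genome)
}

validate_pileup <- function(df, genome) {
  for (ch in unique(df$chrom)) {
    if (!ch %in% names(genome))
      stop("pileup chrom not in genome: ", ch, call. = FALSE)
    idx <- df$chrom == ch
    L <- genome_length(genome, ch)
    if (any(df$pos[idx] < 1L | df$pos[idx] > L))
      stop("pileup position out of bounds on ", ch, call. = FALSE)
    ref <- substring(unname(genome[[ch]]), df$pos[idx], df$pos[idx])
    mism <- which(ref != df$ref[idx])
    if (length(mism) > 0L)
      stop("pileup ref mismatch vs genome at ", ch, ":",
           df$pos[idx][mism[1]], call. = FALSE)
  }
  tot <- df$nA + df$nC + df$nG + df$nT
  bad <- which(tot != df$depth)
  if (length(bad) > 0L)
    stop("base counts do not sum to depth at ", df$chrom[bad[1]], ":",
         df$pos[bad[1]], call. = FALSE)
  if (any(df$depth < 0L)) stop("negative depth", call. = FALSE)
  df
}

#' Write a pileup table
#' @param df Pileup data.frame.
#' @param path Output path.
#' @param comments Optional '#' comment lines.
#' @export
write_pileup_tsv <- function(df, path, comments = character()) {
  write_tsv_commented(df, path, comments)
}

#' Read nucleosome dyad positions from BED
#'
#' BED is 0-based half-open; each dyad is a single-base interval. Column 5
#' (score), when present, is read as the positioning strength. Coordinates
#' are converted to the internal 1-based convention.
#'
#' @param path BED file path.
#' @param genome Genome for bounds checking.
#' @return data.frame with columns \code{chrom, dyad_pos, strength}.
#' @export
read_dyads_bed <- function(path, genome) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED needs at least 3 columns", call. = FALSE)
  out <- data.frame(chrom = as.character(df[[1]]),
                    dyad_pos = as.integer(df[[3]]),
                    strength = if (ncol(df) >= 5L) as.numeric(df[[5]]) else 1,
                    stringsAsFactors = FALSE)
  if (any(df[[3]] - df[[2]] != 1L))
    stop("dyad BED intervals must be single-base", call. = FALSE)
  for (ch in unique(out$chrom)) {
    if (!ch %in% names(genome))
      stop("dyad chrom not in genome: ", ch, call. = FALSE)
    idx <- out$chrom == ch
    if (any(out$dyad_pos[idx] < 1L |
            out$dyad_pos[idx] > genome_length(genome, ch)))
      stop("dyad position out of bounds on ", ch, call. = FALSE)
  }
  out
}

#' Write dyads to BED (0-based half-open)
#' @param dyads data.frame with \code{chrom, dyad_pos, strength}.
#' @param path Output path.
#' @export
write_dyads_bed <- function(dyads, path) {
  bed <- data.frame(dyads$chrom, dyads$dyad_pos - 1L, dyads$dyad_pos,
                    ".", dyads$strength)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a de novo mutation list
#'
#' Tab-delimited with header \code{chrom pos ref alt} (a minimal VCF-like
#' table; 1-based positions). \code{ref} must match the genome.
#'
#' @param path TSV path.
#' @param genome Genome for validation.
#' @return data.frame with columns \code{chrom, pos, ref, alt}.
#' @export
read_mutations_tsv <- function(path, genome) {
  df <- read_tsv_commented(path, c("chrom", "pos", "ref", "alt"),
                           colClasses = c(chrom = "character",
                                          pos = "integer",
                                          ref = "character",
                                          alt = "character"))
  if (any(!df$ref %in% DNA_BASES) || any(!df$alt %in% DNA_BASES))
    stop("ref/alt must be single bases in {A,C,G,T}", call. = FALSE)
  if (any(df$ref == df$alt)) stop("alt must differ from ref", call. = FALSE)
  for (ch in unique(df$chrom)) {
    if (!ch %in% names(genome))
      stop("mutation chrom not in genome: ", ch, call. = FALSE)
    idx <- df$chrom == ch
    gref <- substring(unname(genome[[ch]]), df$pos[idx], df$pos[idx])
    bad <- which(gref != df$ref[idx])
    if (length(bad) > 0L)
      stop("mutation ref mismatch vs genome at ", ch, ":",
           df$pos[idx][bad[1]], call. = FALSE)
  }
  df
}

#' Write a mutation list
#' @param df Mutation data.frame.
#' @param path Output path.
#' @param comments Optional comment lines.
#' @export
write_mutations_tsv <- function(df, path, comments = character()) {
  write_tsv_commented(df[, c("chrom", "pos", "ref", "alt")], path, comments)
}

#' Read a dyad-relative roll profile
#'
#' Tab-delimited with header \code{offset roll}; 146 or 147 rows covering
#' the nucleosome-bound footprint (for 146, offset 0 is absent and the dyad
#' sits between -1 and +1).
#'
#' @param path TSV path.
#' @return A \code{roll_profile} object (see [roll_profile()]).
#' @export
read_roll_tsv <- function(path) {
  df <- read_tsv_commented(path, c("offset", "roll"))
  roll_profile(values = as.numeric(df$roll), offsets = as.integer(df$offset))
}

#' Write a roll profile
#' @param roll A \code{roll_profile}.
#' @param path Output path.
#' @export
write_roll_tsv <- function(roll, path) {
  write_tsv_commented(data.frame(offset = roll$offsets, roll = roll$values),
                      path)
}

#' Read a cyclizability table
#'
#' Tab-delimited with header \code{seq c26 c29 c31}: a 50-mer and the three
#' replicate loop-seq bendability scores. The replicate mean is computed on
#' read.
#'
#' @param path TSV path.
#' @return data.frame with columns \code{seq, c26, c29, c31, mean_score}.
#' @export
read_cyclizability_tsv <- function(path) {
  df <- read_tsv_commented(path, c("seq", "c26", "c29", "c31"))
  df$seq <- toupper(as.character(df$seq))
  if (any(nchar(df$seq) != 50L))
    stop("cyclizability sequences must be 50-mers", call. = FALSE)
  if (any(grepl("[^ACGT]", df$seq)))
    stop("cyclizability sequences restricted to {A,C,G,T}", call. = FALSE)
  df$mean_score <- (df$c26 + df$c29 + df$c31) / 3
  df
}

#' Write a cyclizability table
#' @param df Cyclizability data.frame.
#' @param path Output path.
#' @export
write_cyclizability_tsv <- function(df, path) {
  write_tsv_commented(df[, c("seq", "c26", "c29", "c31")], path)
}
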