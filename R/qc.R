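# Read-level quality control. Reads are held as a plain list-of-columns:
# id (character), bases (character), quals (list of integer Phred scores,
# one vector per read, same length as bases).

#' Phred score to error probability
#'
#' @param q Phred quality score(s), non-negative.
#' @return \code{10^(-q/10)}.
#' @examples
#' phred_to_error_prob(32)  # 0.00063
#' phred_to_error_prob(20)  # 0.01
#' @export
phred_to_error_prob <- function(q) {
  if (any(q < 0)) stop("Phred score must be non-negative", call. = FALSE)
  10^(-q / 10)
}

#' Construct a read set
#' @param id Character ids.
#' @param bases Character sequences over \{A,C,G,T,N\}.
#' @param quals List of integer Phred vectors, lengths matching bases.
#' @return Object of class \code{qc_reads}.
#' @export
qc_reads <- function(id, bases, quals) {
  if (length(id) != length(bases) || length(bases) != length(quals))
    stop("id, bases, quals must have equal length", call. = FALSE)
  lens_ok <- nchar(bases) == lengths(quals)
  if (!all(lens_ok))
    stop("quality length mismatch for read ", id[which(!lens_ok)[1]],
         call. = FALSE)
  if (any(unlist(quals, use.names = FALSE) < 0) ||
      any(unlist(quals, use.names = FALSE) > 60))
    stop("Phred scores must lie in [0, 60]", call. = FALSE)
  structure(list(id = as.character(id), bases = toupper(bases),
                 quals = quals), class = "qc_reads")
}

n_reads <- function(reads) length(reads$id)

subset_reads <- function(reads, idx) {
  qc_reads(reads$id[idx], reads$bases[idx], reads$quals[idx])
}

#' Read FASTQ (Sanger Phred+33)
#' @param path FASTQ path.
#' @return A \code{qc_reads} object.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
  quals_chr <- as.character(S4Vectors::mcols(set)$qualities)
  quals <- lapply(quals_chr, function(s) utf8ToInt(s) - 33L)
  qc_reads(names(set), unname(as.character(set)), quals)
}

#' Write FASTQ (Sanger Phred+33)
#' @param reads A \code{qc_reads} object.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(n_reads(reads))) {
    writeLines(c(paste0("@", reads$id[i]), reads$bases[i], "+",
                 intToUtf8(reads$quals[[i]] + 33L)), con)
  }
  invisible(path)
}

#' Trim read ends by quality
#'
#' Removes bases from each end up to (but not including) the first base
#' from that end with quality at or above \code{q_threshold}. A read with
#' no such base becomes empty. Idempotent.
#'
#' @param reads A \code{qc_reads} object.
#' @param q_threshold Phred threshold (default 32).
#' @return Trimmed \code{qc_reads}.
#' @export
trim_reads <- function(reads, q_threshold = 32L) {
  bases <- character(n_reads(reads))
  quals <- vector("list", n_reads(reads))
  for (i in seq_len(n_reads(reads))) {
    q <- reads$quals[[i]]
    ok <- which(q >= q_threshold)
    if (length(ok) == 0L) {
      bases[i] <- ""
      quals[[i]] <- integer(0)
    } else {
      s <- ok[1]; e <- ok[length(ok)]
      bases[i] <- substr(reads$bases[i], s, e)
      quals[[i]] <- q[s:e]
    }
  }
  qc_reads(reads$id, bases, quals)
}

#' Filter reads by length and minimum base quality
#'
#' Keeps reads with length >= \code{min_len} and minimum base quality
#' >= \code{min_base_q}; both bounds are inclusive (a 500 bp read with
#' minimum quality exactly 22 passes). Intended to run on trimmed reads.
#'
#' @param reads A \code{qc_reads} object.
#' @param min_len Minimum retained length (default 500).
#' @param min_base_q Minimum per-base Phred score (default 22).
#' @return list(kept = qc_reads, dropped = data.frame(id, reason)).
#' @export
filter_reads <- function(reads, min_len = 500L, min_base_q = 22L) {
  lens <- nchar(reads$bases)
  minq <- vapply(reads$quals,
                 function(q) if (length(q)) min(q) else -1L, numeric(1))
  short <- lens < min_len
  lowq <- !short & minq < min_base_q
  keep <- !short & !lowq
  dropped <- data.frame(
    id = reads$id[!keep],
    reason = ifelse(short[!keep], "length", "quality"),
    stringsAsFactors = FALSE)
  list(kept = subset_reads(reads, keep), dropped = dropped)
}
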