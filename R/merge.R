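#' Merge one read pair by overlap (FLASH-style)
#'
#' Reverse-complements mate 2, then scans all overlap lengths from
#' `min_overlap` up to the shorter read length. The overlap minimizing
#' mismatch density is chosen (ties broken toward the longer overlap); the
#' pair is rejected when no overlap has mismatch density below
#' `max_mismatch_density`. In the overlap, the consensus base is the one with
#' the higher quality score, ties going to mate 1.
#'
#' @param seq1,seq2 Nucleotide strings of mates 1 and 2 (mate 2 in sequencing
#'   orientation, i.e. reverse strand).
#' @param qual1,qual2 Phred+33 quality strings (same lengths as the mates).
#' @param min_overlap Minimum acceptable overlap in bases (default 10).
#' @param max_mismatch_density Maximum fraction of mismatching positions in
#'   the accepted overlap (default 0.25).
#' @return A list with `seq`, `qual`, `overlap_len`, `mismatch_count`, or
#'   `NULL` when the pair cannot be merged.
#' @examples
#' amp <- paste(rep("ACGT", 10), collapse = "")   # 40 b amplicon
#' r1 <- substr(amp, 1, 25)
#' r2 <- as.character(Biostrings::reverseComplement(
#'   Biostrings::DNAString(substr(amp, 16, 40))))
#' q <- strrep("F", 25)
#' merge_pair(r1, r2, q, q)$overlap_len   # 10
#' @export
merge_pair <- function(seq1, seq2, qual1, qual2, min_overlap = 10L,
                       max_mismatch_density = 0.25) {
  if (!nzchar(seq1) || !nzchar(seq2)) stop("empty read sequence")
  if (nchar(seq1) != nchar(qual1) || nchar(seq2) != nchar(qual2))
    stop("sequence/quality length mismatch")
  s2 <- .revcomp(seq2)
  q2 <- paste(rev(strsplit(qual2, "")[[1]]), collapse = "")

  x1 <- charToRaw(seq1); x2 <- charToRaw(s2)
  n1 <- length(x1); n2 <- length(x2)
  omax <- min(n1, n2)
  if (omax < min_overlap) return(NULL)

  ovls <- min_overlap:omax
  dens <- vapply(ovls, function(o) {
    sum(x1[(n1 - o + 1L):n1] != x2[seq_len(o)]) / o
  }, 0)
  ok <- dens <= max_mismatch_density
  if (!any(ok)) return(NULL)
  best <- which(ok & dens <= min(dens[ok]) + 1e-12)
  o <- ovls[best[length(best)]]          # ties -> longer overlap
  mm <- as.integer(round(dens[best[length(best)]] * o))

  qr1 <- as.integer(charToRaw(qual1)); qr2 <- as.integer(charToRaw(q2))
  i1 <- (n1 - o + 1L):n1; i2 <- seq_len(o)
  take2 <- qr2[i2] > qr1[i1]             # quality ties -> mate 1 base
  cons <- x1[i1]; cons[take2] <- x2[i2][take2]
  consq <- as.raw(pmax(qr1[i1], qr2[i2]))

  list(seq = paste0(rawToChar(x1[seq_len(n1 - o)]), rawToChar(cons),
                    rawToChar(x2[(o + 1L):n2])),
       qual = paste0(substr(qual1, 1L, n1 - o), rawToChar(consq),
                     substr(q2, o + 1L, n2)),
       overlap_len = o, mismatch_count = mm)
}

#' Merge a batch of read pairs
#'
#' Vectorized wrapper around [merge_pair()]: identical (sequence, quality)
#' pairs are merged once and the result reused, which is fast on amplicon
#' data where most pairs are exact duplicates.
#'
#' @param pairs A data.frame with columns `id`, `seq1`, `seq2`, `qual1`,
#'   `qual2` (e.g. from [read_fastq_pairs()]).
#' @inheritParams merge_pair
#' @return A data.frame of merged reads (`id`, `seq`, `qual`, `overlap_len`,
#'   `mismatch_count`); rejected pairs are dropped. The number of rejected
#'   pairs is attached as attribute `n_rejected`.
#' @export
merge_pairs <- function(pairs, min_overlap = 10L, max_mismatch_density = 0.25) {
  if (nrow(pairs) == 0L) {
    out <- data.frame(id = character(0), seq = character(0),
                      qual = character(0), overlap_len = integer(0),
                      mismatch_count = integer(0), stringsAsFactors = FALSE)
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  key <- paste(pairs$seq1, pairs$seq2, pairs$qual1, pairs$qual2, sep = "\r")
  uk <- !duplicated(key)
  res <- lapply(which(uk), function(i) {
    merge_pair(pairs$seq1[i], pairs$seq2[i], pairs$qual1[i], pairs$qual2[i],
               min_overlap, max_mismatch_density)
  })
  names(res) <- key[uk]
  res <- res[key]
  keep <- !vapply(res, is.null, TRUE)
  out <- data.frame(
    id = pairs$id[keep],
    seq = vapply(res[keep], `[[`, "", "seq"),
    qual = vapply(res[keep], `[[`, "", "qual"),
    overlap_len = vapply(res[keep], `[[`, 0L, "overlap_len"),
    mismatch_count = vapply(res[keep], `[[`, 0L, "mismatch_count"),
    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Length-filter merged reads
#'
#' Retains merged reads of length >= `min_length` (combined reads shorter
#' than 300 b are excluded by default). Optionally also drops reads whose
#' mean Phred quality falls below `min_mean_quality` (off by default; the
#' mandatory filter is length only).
#'
#' @param merged Data.frame of merged reads (from [merge_pairs()]).
#' @param min_length Minimum combined length in bases (default 300).
#' @param min_mean_quality Optional minimum mean Phred score; `NULL` (the
#'   default) disables the quality filter.
#' @return The retained rows, with a `qc` attribute: a one-row data.frame
#'   with counts `n_input`, `n_kept`, `n_short`, `n_low_quality`.
#' @export
filter_reads <- function(merged, min_length = 300L, min_mean_quality = NULL) {
  len_ok <- nchar(merged$seq) >= min_length
  qual_ok <- rep(TRUE, nrow(merged))
  if (!is.null(min_mean_quality) && nrow(merged) > 0L) {
    meanq <- vapply(merged$qual,
                    function(q) mean(as.integer(charToRaw(q)) - 33L), 0,
                    USE.NAMES = FALSE)
    qual_ok <- meanq >= min_mean_quality
  }
  out <- merged[len_ok & qual_ok, , drop = FALSE]
  row.names(out) <- NULL
  attr(out, "qc") <- data.frame(
    n_input = nrow(merged), n_kept = nrow(out),
    n_short = sum(!len_ok), n_low_quality = sum(len_ok & !qual_ok))
  out
}

#' Read a FASTQ mate pair into a pairs table
#'
#' @param r1,r2 FASTQ paths for mates 1 and 2 (records in the same order;
#'   `/1`, `/2` id suffixes are stripped).
#' @return Data.frame with columns `id`, `seq1`, `seq2`, `qual1`, `qual2`.
#' @export
read_fastq_pairs <- function(r1, r2) {
  rd <- function(path) {
    lines <- readLines(path)
    if (length(lines) %% 4L != 0L) stop("truncated FASTQ: ", path)
    i <- seq(1L, length(lines), by = 4L)
    list(id = sub("/[12]$", "", sub("^@", "", sub("\\s.*$", "", lines[i]))),
         seq = toupper(lines[i + 1L]), qual = lines[i + 3L])
  }
  a <- rd(r1); b <- rd(r2)
  if (length(a$id) != length(b$id) || !all(a$id == b$id))
    stop("R1/R2 record ids do not match")
  data.frame(id = a$id, seq1 = a$seq, seq2 = b$seq,
             qual1 = a$qual, qual2 = b$qual, stringsAsFactors = FALSE)
}

#' Write merged reads to FASTQ
#'
#' @param merged Data.frame from [merge_pairs()].
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_merged_fastq <- function(merged, path) {
  lines <- if (nrow(merged)) {
    as.vector(rbind(paste0("@", merged$id), merged$seq, "+", merged$qual))
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}
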