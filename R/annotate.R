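# standard genetic code, built here rather than taken from an alignment
# library so tests can check it against an independent oracle
.codon_table <- local({
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aa, codons)
})

#' Translate an in-frame nucleotide string
#'
#' Standard genetic code; stop codons yield `*`. Codons containing characters
#' other than ACGT translate to `X`.
#'
#' @param nt Nucleotide string whose length is a multiple of 3.
#' @return Amino-acid string.
#' @export
translate_nt <- function(nt) {
  nt <- toupper(nt)
  n <- nchar(nt)
  if (n %% 3L != 0L) stop("sequence length not a multiple of 3")
  if (n == 0L) return("")
  codons <- substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- .codon_table[codons]
  aa[is.na(aa)] <- "X"
  paste0(aa, collapse = "")
}

#' Classify a codon substitution as silent or replacement
#'
#' @param germ_codon,obs_codon In-frame germline and observed codons.
#' @return `"silent"`, `"replacement"`, or `"unknown"` when either codon
#'   carries an ambiguity/gap character.
#' @examples
#' classify_mutation("CTG", "CTA")  # silent (Leu -> Leu)
#' classify_mutation("GAT", "GCT")  # replacement (Asp -> Ala)
#' @export
classify_mutation <- function(germ_codon, obs_codon) {
  g <- toupper(germ_codon); o <- toupper(obs_codon)
  if (nchar(g) != 3L || nchar(o) != 3L ||
      grepl("[^ACGT]", g) || grepl("[^ACGT]", o)) return("unknown")
  if (.codon_table[[g]] == .codon_table[[o]]) "silent" else "replacement"
}

.aln_scoring <- function(match = 2, mismatch = -1) {
  Biostrings::nucleotideSubstitutionMatrix(match, mismatch, baseOnly = TRUE)
}

# Parse one Biostrings overlap alignment into germline-coordinate features.
# Returns a `v_alignment`: aligned column vectors plus the germline-projected
# read (read bases at each covered germline position; "-" at deletions).
.parse_alignment <- function(pat_aligned, subj_aligned, subj_start) {
  pv <- strsplit(pat_aligned, "")[[1]]
  sv <- strsplit(subj_aligned, "")[[1]]
  spos0 <- subj_start - 1L + cumsum(sv != "-") - 1L   # 0-based germline pos
  is_ins <- sv == "-"
  is_del <- pv == "-"
  is_mm <- !is_ins & !is_del & pv != sv
  is_match <- !is_ins & !is_del & pv == sv
  cover <- !is_ins
  proj <- pv[cover]                       # one entry per germline position
  start0 <- subj_start - 1L
  end0 <- start0 + sum(cover)             # half-open
  structure(list(
    pattern = pv, subject = sv, start_germ = start0, end_germ = end0,
    n_match = sum(is_match), n_mismatch = sum(is_mm),
    n_insertion = sum(is_ins), n_deletion = sum(is_del),
    mut_pos0 = spos0[is_mm], mut_germ = sv[is_mm], mut_read = pv[is_mm],
    v_proj = paste0(proj, collapse = "")), class = "v_alignment")
}

#' Percent homology to germline
#'
#' 100 x identical aligned positions / aligned germline positions, reported
#' to one decimal. Indel columns count as non-identity: deletions consume
#' germline positions without matching, and insertion columns are added to
#' the denominator.
#'
#' @param alignment A `v_alignment` (from [assign_germline()]).
#' @return Percentage, rounded half-up to 1 decimal.
#' @export
percent_homology <- function(alignment) {
  denom <- (alignment$end_germ - alignment$start_germ) + alignment$n_insertion
  if (denom == 0L) stop("zero aligned length: homology undefined")
  round_half_up(100 * alignment$n_match / denom, 1L)
}

#' Round half away from zero
#'
#' Decimal rounding with halves up (`round_half_up(0.25, 1) == 0.3`),
#' matching how the reported percentages are printed, unlike base R's
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0L) {
  m <- 10^digits
  # signif() guards against binary representation error pushing an exact
  # decimal half (e.g. 0.15 -> 1.4999999999999946) below the threshold
  sign(x) * floor(signif(abs(x) * m, 12) + 0.5) / m
}

#' Assign the best germline IGHV allele to a merged read
#'
#' Aligns the read against every allele with a semi-global (free end-gap)
#' alignment (match +2, mismatch -1, gap open -6, gap extend -1); the best
#' score wins, ties broken by lexicographic allele name. Reads whose best
#' alignment has identity < `min_identity` or fewer than `min_aligned`
#' aligned germline bases are flagged unassignable.
#'
#' @param seq Merged read nucleotide string.
#' @param ref A `germline_set`.
#' @param min_identity Identity floor on the aligned region (default 0.5).
#' @param min_aligned Minimum aligned germline bases (default 100).
#' @return List with `v_call` (allele name or `NA`), `alignment`
#'   (`v_alignment` or `NULL`), `unassignable` flag.
#' @export
assign_germline <- function(seq, ref, min_identity = 0.5, min_aligned = 100L) {
  res <- .assign_germline_batch(seq, ref, min_identity, min_aligned)
  list(v_call = res$v_call[1L], alignment = res$alignment[[1L]],
       unassignable = res$unassignable[1L])
}

# Vectorized core: aligns all (unique) sequences against every allele.
.assign_germline_batch <- function(seqs, ref, min_identity = 0.5,
                                   min_aligned = 100L) {
  stopifnot(nrow(ref) >= 1L)
  pats <- Biostrings::DNAStringSet(seqs)
  ord <- order(ref$name)                  # lexicographic tie-break
  ref <- ref[ord, , drop = FALSE]
  mat <- .aln_scoring()
  alns <- lapply(seq_len(nrow(ref)), function(k) {
    Biostrings::pairwiseAlignment(
      pats, Biostrings::DNAString(ref$seq[k]), type = "overlap",
      substitutionMatrix = mat, gapOpening = 6, gapExtension = 1)
  })
  scores <- vapply(alns, Biostrings::score, numeric(length(seqs)))
  scores <- matrix(scores, nrow = length(seqs))
  best <- max.col(scores, ties.method = "first")      # first = lexicographic

  out <- list(v_call = character(length(seqs)),
              alignment = vector("list", length(seqs)),
              unassignable = logical(length(seqs)))
  for (i in seq_along(seqs)) {
    a <- alns[[best[i]]]
    pa <- as.character(Biostrings::pattern(a[i]))
    sa <- as.character(Biostrings::subject(a[i]))
    va <- .parse_alignment(pa, sa, Biostrings::start(
      Biostrings::subject(a[i])))
    aligned <- va$end_germ - va$start_germ
    ident <- if (aligned > 0L) va$n_match / aligned else 0
    if (aligned < min_aligned || ident < min_identity) {
      out$v_call[i] <- NA_character_
      out$unassignable[i] <- TRUE
    } else {
      out$v_call[i] <- ref$name[best[i]]
      out$alignment[[i]] <- va
      # read offset (0-based) of the first aligned germline base, used to
      # map germline coordinates into the read
      out$alignment[[i]]$read_offset <-
        Biostrings::start(Biostrings::pattern(a[i])) - 1L
    }
  }
  out
}

#' Extract the CDR3 nucleotide sequence
#'
#' The CDR3 runs from the codon aligned to the allele's conserved cysteine
#' (inclusive) through the first downstream in-frame J-anchor tryptophan
#' codon of motif TGG-GG (W-G, inclusive of the W codon). Returns `NA` when
#' the alignment does not cover the cysteine codon or no anchor lies within
#' `max_scan` bases downstream.
#'
#' @param seq Merged read nucleotide string.
#' @param alignment The read's `v_alignment` (with `read_offset`).
#' @param cys104_pos 0-based germline offset of the conserved Cys codon.
#' @param max_scan Anchor search window in bases (default 120).
#' @return CDR3 nucleotide string, or `NA_character_`.
#' @export
extract_cdr3 <- function(seq, alignment, cys104_pos, max_scan = 120L) {
  if (is.null(alignment)) return(NA_character_)
  if (cys104_pos < alignment$start_germ || cys104_pos >= alignment$end_germ)
    return(NA_character_)
  # read position (0-based) aligned to cys104_pos: walk aligned columns
  sv <- alignment$subject; pv <- alignment$pattern
  spos0 <- alignment$start_germ + cumsum(sv != "-") - 1L
  col <- which(sv != "-" & spos0 == cys104_pos)[1L]
  if (is.na(col) || pv[col] == "-") return(NA_character_)
  p0 <- alignment$read_offset + sum(pv[seq_len(col)] != "-") - 1L  # 0-based
  n <- nchar(seq)
  for (j in seq(p0 + 3L, min(p0 + max_scan, n - 5L), by = 3L)) {
    if (substr(seq, j + 1L, j + 3L) == "TGG" &&
        substr(seq, j + 4L, j + 5L) == "GG") {
      return(substr(seq, p0 + 1L, j + 3L))
    }
  }
  NA_character_
}

#' Annotate merged reads against a germline reference
#'
#' Batch driver for the annotation stage: assigns each merged read its best
#' germline allele, calls mutations (with silent/replacement classification),
#' computes percent homology, and extracts the CDR3 nucleotide and amino-acid
#' sequences. Identical read sequences are annotated once and the result
#' reused.
#'
#' @param merged Data.frame of merged reads (`id`, `seq`, ...).
#' @param ref A `germline_set`.
#' @param max_gaps Reads whose best alignment holds more than this many gap
#'   columns are flagged (`gap_flag`), as likely artifacts (default 3).
#' @inheritParams assign_germline
#' @return An AIRR-style rearrangement data.frame: `read_id`, `v_call`,
#'   `aln_start_germ`, `aln_end_germ` (0-based half-open), `homology_pct`,
#'   `cdr3`, `cdr3_aa`, `n_mutations`, `mutations` (JSON), `v_proj`
#'   (germline-projected read over the aligned interval), `unassignable`,
#'   `gap_flag`.
#' @export
annotate_reads <- function(merged, ref, min_identity = 0.5,
                           min_aligned = 100L, max_gaps = 3L) {
  n <- nrow(merged)
  empty <- data.frame(read_id = character(0), v_call = character(0),
                      aln_start_germ = integer(0), aln_end_germ = integer(0),
                      homology_pct = numeric(0), cdr3 = character(0),
                      cdr3_aa = character(0), n_mutations = integer(0),
                      mutations = character(0), v_proj = character(0),
                      unassignable = logical(0), gap_flag = logical(0),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  useq <- unique(merged$seq)
  ab <- .assign_germline_batch(useq, ref, min_identity, min_aligned)
  cys <- stats::setNames(ref$cys104_pos, ref$name)
  germ <- stats::setNames(ref$seq, ref$name)

  rows <- lapply(seq_along(useq), function(i) {
    va <- ab$alignment[[i]]
    if (ab$unassignable[i] || is.null(va)) {
      return(data.frame(v_call = NA_character_, aln_start_germ = NA_integer_,
                        aln_end_germ = NA_integer_, homology_pct = NA_real_,
                        cdr3 = NA_character_, cdr3_aa = NA_character_,
                        n_mutations = NA_integer_, mutations = NA_character_,
                        v_proj = NA_character_, unassignable = TRUE,
                        gap_flag = FALSE, stringsAsFactors = FALSE))
    }
    vc <- ab$v_call[i]
    muts <- .call_mutations(va, germ[[vc]])
    cdr3 <- extract_cdr3(useq[i], va, cys[[vc]])
    cdr3_aa <- if (!is.na(cdr3) && nchar(cdr3) %% 3L == 0L)
      translate_nt(cdr3) else NA_character_
    data.frame(v_call = vc, aln_start_germ = va$start_germ,
               aln_end_germ = va$end_germ,
               homology_pct = percent_homology(va),
               cdr3 = cdr3, cdr3_aa = cdr3_aa, n_mutations = nrow(muts),
               mutations = as.character(jsonlite::toJSON(muts)),
               v_proj = va$v_proj, unassignable = FALSE,
               gap_flag = (va$n_insertion + va$n_deletion) > max_gaps,
               stringsAsFactors = FALSE)
  })
  urows <- do.call(rbind, rows)
  out <- urows[match(merged$seq, useq), , drop = FALSE]
  out <- cbind(read_id = merged$id, out)
  row.names(out) <- NULL
  out
}

# Mutation table for one alignment: position (0-based germline), bases,
# codon index, silent/replacement call against the germline reading frame.
.call_mutations <- function(va, germ_seq) {
  if (length(va$mut_pos0) == 0L) {
    return(data.frame(pos = integer(0), germ_base = character(0),
                      read_base = character(0), codon_index = integer(0),
                      aa_effect = character(0), stringsAsFactors = FALSE))
  }
  ci <- va$mut_pos0 %/% 3L
  proj <- strsplit(va$v_proj, "")[[1]]
  aa <- vapply(seq_along(va$mut_pos0), function(k) {
    c0 <- ci[k] * 3L
    gcodon <- substr(germ_seq, c0 + 1L, c0 + 3L)
    # observed codon from the germline-projected read, if fully covered
    rel <- c0 - va$start_germ
    if (rel < 0L || rel + 3L > length(proj)) return("unknown")
    classify_mutation(gcodon, paste0(proj[(rel + 1L):(rel + 3L)],
                                     collapse = ""))
  }, "")
  data.frame(pos = va$mut_pos0, germ_base = va$mut_germ,
             read_base = va$mut_read, codon_index = ci, aa_effect = aa,
             stringsAsFactors = FALSE)
}

#' Write an AIRR-style rearrangement TSV
#'
#' @param annotated Data.frame from [annotate_reads()] (plus any extra
#'   columns such as `replicate`).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_airr_tsv <- function(annotated, path) {
  utils::write.table(annotated, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read an AIRR-style rearrangement TSV written by [write_airr_tsv()]
#'
#' @param path TSV path.
#' @return Data.frame.
#' @export
read_airr_tsv <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in c("unassignable", "gap_flag"))
    if (col %in% names(out)) out[[col]] <- as.logical(out[[col]])
  out
}
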