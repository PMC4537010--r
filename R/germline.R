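#' Read a germline IGHV allele reference
#'
#' Parses a FASTA file of germline IGHV alleles. Each header must carry a
#' `cys104=<int>` tag giving the 0-based offset of the first base of the
#' conserved CDR3-anchoring cysteine codon (TGT/TGC), e.g.
#' `>IGHV3-S30*18 cys104=294`. Alternatively a sidecar TSV with columns
#' `name` and `cys104` may be supplied.
#'
#' @param path Path to the allele FASTA file.
#' @param cys_tsv Optional path to a two-column TSV (`name`, `cys104`) used
#'   when headers carry no `cys104=` tag.
#' @return A `germline_set`: a data.frame with columns `name`, `seq`,
#'   `cys104_pos` (0-based codon-start offset), one row per allele.
#' @examples
#' ref <- read_germline_fasta(ighv_reference())
#' ref$name
#' @export
read_germline_fasta <- function(path, cys_tsv = NULL) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("germline reference '", path, "' contains no sequences")
  }
  headers <- names(seqs)
  name <- sub("\\s.*$", "", headers)
  tag <- regmatches(headers, regexpr("cys104=\\d+", headers))
  if (length(tag) == length(headers)) {
    cys <- as.integer(sub("cys104=", "", tag))
  } else if (!is.null(cys_tsv)) {
    side <- utils::read.delim(cys_tsv, stringsAsFactors = FALSE)
    idx <- match(name, side$name)
    if (anyNA(idx)) stop("sidecar TSV missing cys104 for: ",
                         paste(name[is.na(idx)], collapse = ", "))
    cys <- as.integer(side$cys104[idx])
  } else {
    stop("no cys104= header tags and no sidecar TSV given")
  }
  germline_set(name, as.character(seqs), cys)
}

#' Construct a germline allele set
#'
#' @param name Character vector of allele names (IMGT-like, gene*allele).
#' @param seq Nucleotide sequences (uppercase ACGT).
#' @param cys104_pos Integer vector, 0-based offset of the conserved Cys codon.
#' @return A `germline_set` data.frame.
#' @export
germline_set <- function(name, seq, cys104_pos) {
  seq <- toupper(seq)
  stopifnot(length(name) == length(seq), length(seq) == length(cys104_pos))
  cys_codon <- substr(seq, cys104_pos + 1L, cys104_pos + 3L)
  bad <- !(cys_codon %in% c("TGT", "TGC"))
  if (any(bad)) {
    stop("codon at cys104_pos is not TGT/TGC for allele(s): ",
         paste(name[bad], collapse = ", "))
  }
  out <- data.frame(name = name, seq = seq,
                    cys104_pos = as.integer(cys104_pos),
                    stringsAsFactors = FALSE)
  class(out) <- c("germline_set", "data.frame")
  out
}

#' Write a germline allele set to FASTA
#'
#' Headers carry the `cys104=` tag understood by [read_germline_fasta()].
#'
#' @param ref A `germline_set`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$seq)
  names(x) <- sprintf("%s cys104=%d", ref$name, ref$cys104_pos)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Bundled synthetic IGHV allele reference
#'
#' Path to the package's synthetic-but-realistic germline IGHV allele FASTA
#' (four ~300 b alleles, pairwise >= 10 substitutions apart, each with an
#' annotated conserved cysteine codon). These alleles are synthetic stand-ins,
#' not database sequences, so the test-suite runs without any download.
#'
#' @return File path of the bundled FASTA.
#' @export
ighv_reference <- function() {
  system.file("extdata", "ighv_synthetic_alleles.fasta", package = "icvseq",
              mustWork = TRUE)
}

#' Collapse an allele name to its gene
#'
#' Drops the `*NN` allele designation (`IGHV3-S30*18` -> `IGHV3-S30`).
#'
#' @param v_call Character vector of allele names.
#' @return Character vector of gene names.
#' @export
allele_to_gene <- function(v_call) sub("\\*.*$", "", v_call)
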