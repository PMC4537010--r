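#' Group annotated reads into clonotypes by identical CDR3
#'
#' Clonotypes are defined by exact CDR3 nucleotide identity; CDR3s differing
#' by even one base form distinct clonotypes. Reads lacking a CDR3 are
#' excluded and counted.
#'
#' @param annotated AIRR-style data.frame (see [annotate_reads()]) with an
#'   additional `replicate` column (`"A"`/`"B"`).
#' @return A clonotype data.frame sorted by descending total count: `cdr3`,
#'   `v_call` (plurality allele), `count_repA`, `count_repB`, `count_total`,
#'   `freq_pct` (percent of all CDR3-bearing reads). Attribute `n_no_cdr3`
#'   counts the excluded reads.
#' @export
group_by_cdr3 <- function(annotated) {
  stopifnot("replicate" %in% names(annotated))
  keep <- !is.na(annotated$cdr3)
  x <- data.table::as.data.table(annotated[keep, c("cdr3", "v_call",
                                                   "replicate")])
  if (nrow(x) == 0L) {
    out <- data.frame(cdr3 = character(0), v_call = character(0),
                      count_repA = integer(0), count_repB = integer(0),
                      count_total = integer(0), freq_pct = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_no_cdr3") <- sum(!keep)
    return(out)
  }
  replicate <- v_call <- cdr3 <- count_total <- NULL  # NSE binding note
  tab <- x[, list(
    v_call = names(sort(table(v_call), decreasing = TRUE))[1L],
    count_repA = sum(replicate == "A"),
    count_repB = sum(replicate == "B")), by = cdr3]
  tab[, count_total := count_repA + count_repB]
  data.table::setorder(tab, -count_total, cdr3)
  out <- as.data.frame(tab)
  out$freq_pct <- 100 * out$count_total / sum(out$count_total)
  attr(out, "n_no_cdr3") <- sum(!keep)
  out
}

#' Technical-replicate concordance filter
#'
#' Sequence variants (or clonotypes) are only analyzed where they are present
#' at sufficient frequency in *both* technical replicates, excluding PCR and
#' sequencing artifacts, which are expected to be replicate-exclusive or
#' near-exclusive. A row is retained when its within-replicate frequency is
#' at least `min_freq_each_replicate` percent *and* its count is at least
#' `min_count_each` in each replicate.
#'
#' @param tab Data.frame with `count_repA` and `count_repB` columns
#'   (clonotype or variant table).
#' @param min_freq_each_replicate Per-replicate frequency threshold in
#'   percent (default 0.01).
#' @param min_count_each Per-replicate minimum count (default 2).
#' @return The retained rows; if the table has a `freq_pct` column it is
#'   recomputed over the retained totals.
#' @export
concordance_filter <- function(tab, min_freq_each_replicate = 0.01,
                               min_count_each = 2L) {
  totA <- sum(tab$count_repA); totB <- sum(tab$count_repB)
  if (totA == 0L || totB == 0L)
    stop("a technical replicate is empty: the pipeline requires two ",
         "populated replicates")
  fA <- 100 * tab$count_repA / totA
  fB <- 100 * tab$count_repB / totB
  keep <- fA >= min_freq_each_replicate & fB >= min_freq_each_replicate &
    tab$count_repA >= min_count_each & tab$count_repB >= min_count_each
  out <- tab[keep, , drop = FALSE]
  row.names(out) <- NULL
  if ("freq_pct" %in% names(out) && nrow(out) > 0L)
    out$freq_pct <- 100 * out$count_total / sum(out$count_total)
  out
}

#' Call the dominant clonotype
#'
#' Returns the top clonotype iff its frequency strictly exceeds
#' `threshold_pct`; otherwise `NULL` (an oligoclonal/normal profile). The
#' 5\% default is the published cut-off for clonal IGHV gene use by deep
#' sequencing; for IgG myeloma calling a stricter 7.8\% cut-off is
#' recommended, since oligoclonal expansions in normal plasma cells reach
#' that size.
#'
#' @param clonotypes Clonotype table (sorted or not) with `freq_pct`.
#' @param threshold_pct Strict lower bound in percent (default 5.0;
#'   recommended 7.8 for myeloma calling).
#' @return The dominant clonotype row, or `NULL`.
#' @export
detect_dominant <- function(clonotypes, threshold_pct = 5.0) {
  if (nrow(clonotypes) == 0L) return(NULL)
  top <- clonotypes[which.max(clonotypes$freq_pct), , drop = FALSE]
  if (top$freq_pct > threshold_pct) top else NULL
}

#' Enumerate full-length sequence variants within a clonotype
#'
#' Variants are exact-identity groups over the germline-aligned V-region
#' string, truncated to the interval covered by every member so that
#' differing read offsets do not inflate the variant count. Ranked by
#' descending total read count, ties broken lexicographically.
#'
#' @param members Annotated reads of one clonotype (must share `cdr3`), with
#'   `v_proj`, `aln_start_germ`, `aln_end_germ`, `replicate` columns.
#' @return A variant table: `variant_seq`, `count_repA`, `count_repB`,
#'   `count_total`, `rank`. Attributes `interval` (0-based half-open shared
#'   germline interval) and `v_call`.
#' @export
enumerate_variants <- function(members) {
  stopifnot(nrow(members) > 0L)
  if (length(unique(members$cdr3)) != 1L)
    stop("members do not share a single CDR3")
  s0 <- max(members$aln_start_germ)
  e0 <- min(members$aln_end_germ)
  if (e0 <= s0) stop("no germline interval shared by all members")
  vseq <- substr(members$v_proj, s0 - members$aln_start_germ + 1L,
                 e0 - members$aln_start_germ)
  x <- data.table::data.table(variant_seq = vseq,
                              replicate = members$replicate)
  replicate <- variant_seq <- count_total <- NULL
  tab <- x[, list(count_repA = sum(replicate == "A"),
                  count_repB = sum(replicate == "B")), by = variant_seq]
  tab[, count_total := count_repA + count_repB]
  data.table::setorder(tab, -count_total, variant_seq)
  out <- as.data.frame(tab)
  out$rank <- seq_len(nrow(out))
  attr(out, "interval") <- c(s0, e0)
  attr(out, "v_call") <- members$v_call[1L]
  out
}

#' Top-n rows of a variant table
#'
#' @param variant_table From [enumerate_variants()].
#' @param n Number of top-ranked variants (default 10).
#' @return The first `min(n, nrow)` rows, attributes preserved.
#' @export
top_n_variants <- function(variant_table, n = 10L) {
  out <- variant_table[seq_len(min(n, nrow(variant_table))), , drop = FALSE]
  attr(out, "interval") <- attr(variant_table, "interval")
  attr(out, "v_call") <- attr(variant_table, "v_call")
  out
}

#' Germline gene usage summary
#'
#' Percent of assigned reads per germline IGHV gene (alleles collapsed to
#' genes), suitable for a linear-scale usage bar chart.
#'
#' @param annotated AIRR-style data.frame with `v_call`.
#' @return Data.frame `gene`, `n_reads`, `freq_pct`, sorted by descending
#'   frequency.
#' @export
germline_usage_summary <- function(annotated) {
  v <- annotated$v_call[!is.na(annotated$v_call)]
  if (length(v) == 0L) {
    return(data.frame(gene = character(0), n_reads = integer(0),
                      freq_pct = numeric(0), stringsAsFactors = FALSE))
  }
  tab <- sort(table(allele_to_gene(v)), decreasing = TRUE)
  data.frame(gene = names(tab), n_reads = as.integer(tab),
             freq_pct = 100 * as.integer(tab) / length(v),
             stringsAsFactors = FALSE, row.names = NULL)
}
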