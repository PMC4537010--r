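#' Intraclonal variation (ICV) fraction
#'
#' The proportion of variant subclonal sequence reads over and above the
#' dominant sequence, as a percentage of the entire tumor clone:
#' `100 * (1 - dominant / total)`, rounded half-up to one decimal.
#'
#' @param dominant_count Read count of the rank-1 (dominant) variant, or a
#'   variant table from [enumerate_variants()] (its rank-1 count is used and
#'   `total_count` defaults to the table's total).
#' @param total_count Total read count of the clonotype.
#' @return Percentage in \[0, 100\], one decimal.
#' @examples
#' icv_fraction(2862, 1660375)     # 99.8
#' icv_fraction(1393460, 2009338)  # 30.7
#' @export
icv_fraction <- function(dominant_count, total_count = NULL) {
  if (is.data.frame(dominant_count)) {
    vt <- dominant_count
    if (nrow(vt) == 0L) stop("empty variant table")
    if (is.null(total_count)) total_count <- sum(vt$count_total)
    dominant_count <- vt$count_total[which.max(vt$count_total)]
  }
  if (is.null(total_count) || total_count <= 0)
    stop("total_count must be positive")
  if (dominant_count < 0 || dominant_count > total_count)
    stop("dominant_count must lie in [0, total_count]")
  round_half_up(100 * (1 - dominant_count / total_count), 1L)
}

#' Extrapolate the subclonal variant tumor burden
#'
#' Converts an ICV fraction into an absolute number of transformed cells
#' carrying variant sequences, given a total tumor cell mass (in IgG myeloma,
#' 0.5-3.1e12 cells per patient).
#'
#' @param icv_fraction_pct ICV fraction in percent.
#' @param total_tumor_cells Total tumor cells (e.g. `0.5e12`).
#' @return Number of variant-bearing cells.
#' @examples
#' variant_burden(50.7, 0.5e12)  # 2.535e11 ~= 0.25e12 cells
#' @export
variant_burden <- function(icv_fraction_pct, total_tumor_cells) {
  stopifnot(icv_fraction_pct >= 0, total_tumor_cells >= 0)
  icv_fraction_pct / 100 * total_tumor_cells
}

#' Partition mutations into trunk and ICV sets
#'
#' A mutation (germline position + substituted base) present in every top-N
#' variant is a trunk mutation, acquired before the clone's last common
#' ancestor; all other observed mutations constitute the intraclonal
#' variation. The two sets partition the union of observed mutations.
#'
#' @param variant_table Top-N variant table (see [top_n_variants()]); its
#'   `interval` attribute fixes the germline coordinates of `variant_seq`.
#' @param germline_seq Full germline allele nucleotide sequence.
#' @return List with data.frames `trunk` and `icv` (`pos` 0-based germline
#'   position, `germ_base`, `read_base`, plus for `icv` the per-variant
#'   presence matrix as attribute `presence`), and `per_variant`: list of
#'   each variant's mutation data.frame.
#' @export
mutation_partition <- function(variant_table, germline_seq) {
  iv <- attr(variant_table, "interval")
  stopifnot(!is.null(iv))
  germ <- substr(germline_seq, iv[1L] + 1L, iv[2L])
  gv <- strsplit(germ, "")[[1]]
  per_variant <- lapply(variant_table$variant_seq, function(s) {
    sv <- strsplit(s, "")[[1]]
    d <- which(sv != gv)
    data.frame(pos = iv[1L] + d - 1L, germ_base = gv[d], read_base = sv[d],
               stringsAsFactors = FALSE)
  })
  keys <- lapply(per_variant, function(m) paste(m$pos, m$read_base))
  all_keys <- unique(unlist(keys))
  if (length(all_keys) == 0L) {
    empty <- data.frame(pos = integer(0), germ_base = character(0),
                        read_base = character(0), stringsAsFactors = FALSE)
    return(list(trunk = empty, icv = empty, per_variant = per_variant))
  }
  presence <- vapply(keys, function(k) all_keys %in% k,
                     logical(length(all_keys)))
  presence <- matrix(presence, nrow = length(all_keys))
  shared <- rowSums(presence) == ncol(presence)
  union_tab <- unique(do.call(rbind, per_variant))
  union_tab <- union_tab[match(all_keys, paste(union_tab$pos,
                                               union_tab$read_base)), ]
  ti <- which(shared); vi <- which(!shared)
  to <- order(union_tab$pos[ti]); vo <- order(union_tab$pos[vi])
  trunk <- union_tab[ti, , drop = FALSE][to, , drop = FALSE]
  icv <- union_tab[vi, , drop = FALSE][vo, , drop = FALSE]
  row.names(trunk) <- row.names(icv) <- NULL
  attr(icv, "presence") <- presence[vi, , drop = FALSE][vo, , drop = FALSE]
  list(trunk = trunk, icv = icv, per_variant = per_variant)
}

#' Build the ICV report for a clonotype
#'
#' @param variant_table Full variant table of the clonotype.
#' @param germline_seq Germline allele sequence (for the mutation partition).
#' @param top_n How many top variants enter the mutation partition
#'   (default 10).
#' @return An `icv_report` list: `dominant_variant_count`, `clonotype_total`,
#'   `icv_fraction_pct`, `n_variants`, `shared_mutations`,
#'   `variant_mutations`.
#' @export
icv_report <- function(variant_table, germline_seq, top_n = 10L) {
  stopifnot(nrow(variant_table) > 0L)
  total <- sum(variant_table$count_total)
  dom <- variant_table$count_total[1L]
  part <- mutation_partition(top_n_variants(variant_table, top_n),
                             germline_seq)
  structure(list(dominant_variant_count = dom, clonotype_total = total,
                 icv_fraction_pct = icv_fraction(dom, total),
                 n_variants = nrow(variant_table),
                 shared_mutations = part$trunk, icv_mutations = part$icv,
                 variant_mutations = part$per_variant),
            class = "icv_report")
}

#' Render a Fig-style informative-codon alignment
#'
#' Text table of the top variants against the dominant sequence: the
#' dominant (rank-1) variant is shown against germline, every other variant
#' against the dominant, with `.` marking identity. By default only
#' informative columns (where any variant differs from the dominant) are
#' shown.
#'
#' @param variant_table Top-N variant table.
#' @param germline_seq Germline allele sequence.
#' @param informative_only Show only differing columns (default TRUE).
#' @return Character vector of report lines.
#' @export
format_icv_alignment <- function(variant_table, germline_seq,
                                 informative_only = TRUE) {
  iv <- attr(variant_table, "interval")
  gv <- strsplit(substr(germline_seq, iv[1L] + 1L, iv[2L]), "")[[1]]
  mat <- do.call(rbind, strsplit(variant_table$variant_seq, ""))
  dom <- mat[1L, ]
  cols <- if (informative_only && nrow(mat) > 1L) {
    which(apply(mat, 2L, function(col) any(col != col[1L])) | dom != gv)
  } else seq_along(gv)
  if (length(cols) == 0L) cols <- integer(0)
  hdr <- sprintf("%-12s %s", "pos0", paste(iv[1L] + cols - 1L,
                                           collapse = " "))
  wd <- nchar(iv[1L] + cols - 1L)
  pad <- function(x) paste(mapply(formatC, x, width = wd), collapse = " ")
  lines <- c(hdr,
             sprintf("%-12s %s", "germline", pad(gv[cols])),
             sprintf("%-12s %s", sprintf("rank1 n=%d",
                                         variant_table$count_total[1L]),
                     pad(ifelse(dom[cols] == gv[cols], ".", dom[cols]))))
  if (nrow(mat) > 1L) {
    for (r in 2:nrow(mat)) {
      lines <- c(lines, sprintf(
        "%-12s %s", sprintf("rank%d n=%d", r, variant_table$count_total[r]),
        pad(ifelse(mat[r, cols] == dom[cols], ".", mat[r, cols]))))
    }
  }
  lines
}
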