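#' Project clonal variants onto a common germline interval
#'
#' Because the variant model is substitution-only and all variants of a
#' clonotype share a germline frame, a multiple alignment reduces to
#' projecting each variant onto germline coordinates and truncating to the
#' interval covered by every variant; the projection is gap-free and exact.
#' (For indel-bearing data a true multiple aligner would be required; see the
#' package vignette.)
#'
#' @param variants Either a variant table from [enumerate_variants()] /
#'   [top_n_variants()] (rows already share an interval), or a data.frame of
#'   annotated reads with `v_proj`, `aln_start_germ`, `aln_end_germ` and
#'   `v_call` columns.
#' @param labels Optional row labels; defaults to `rank<r>_<count>` for
#'   variant tables (read counts embedded per the lineage-tree convention).
#' @return Named character vector of equal-length aligned sequences.
#' @export
align_variants <- function(variants, labels = NULL) {
  if ("variant_seq" %in% names(variants)) {
    seqs <- variants$variant_seq
    if (length(unique(nchar(seqs))) > 1L)
      stop("variant table rows have unequal lengths")
    if (is.null(labels))
      labels <- sprintf("rank%d_%d", variants$rank, variants$count_total)
  } else {
    stopifnot(all(c("v_proj", "aln_start_germ", "aln_end_germ") %in%
                    names(variants)))
    if ("v_call" %in% names(variants) &&
        length(unique(variants$v_call)) > 1L)
      stop("variants annotated against different alleles cannot be ",
           "projected onto one germline frame")
    s0 <- max(variants$aln_start_germ)
    e0 <- min(variants$aln_end_germ)
    if (e0 <= s0) stop("no shared germline interval")
    seqs <- substr(variants$v_proj, s0 - variants$aln_start_germ + 1L,
                   e0 - variants$aln_start_germ)
    if (is.null(labels)) labels <- paste0("v", seq_along(seqs))
  }
  stats::setNames(seqs, labels)
}

#' Pairwise Hamming distances over an alignment
#'
#' @param alignment Named character vector of equal-length sequences.
#' @param p_distance Normalize by alignment length (default FALSE:
#'   substitution counts).
#' @return Symmetric numeric matrix with zero diagonal, dimnames from the
#'   alignment names.
#' @export
pairwise_distances <- function(alignment, p_distance = FALSE) {
  n <- length(alignment)
  if (length(unique(nchar(alignment))) > 1L)
    stop("alignment rows have unequal lengths")
  raws <- lapply(alignment, charToRaw)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        d[i, j] <- d[j, i] <- sum(raws[[i]] != raws[[j]])
      }
    }
  }
  if (p_distance) d <- d / nchar(alignment[[1L]])
  d
}

#' Neighbor-joining lineage tree (Saitou-Nei)
#'
#' Classic neighbor joining: iteratively joins the pair minimizing
#' `Q(i,j) = (m-2) d(i,j) - R_i - R_j` (R = row sums over the `m` active
#' clusters), with branch lengths
#' `l_i = d(i,j)/2 + (R_i - R_j) / (2(m-2))`. Ties in Q are broken by the
#' smallest (row, column) index pair for determinism. Negative branch lengths
#' are clamped to zero with the remainder transferred to the sibling edge, so
#' path lengths through the joined pair are preserved.
#'
#' @param dm Symmetric non-negative distance matrix with zero diagonal and
#'   dimnames (e.g. from [pairwise_distances()]).
#' @return An [ape::read.tree()] `phylo` object (unrooted, binary for
#'   n >= 3). For n < 3 a trivial tree is returned with a warning.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (is.null(rownames(dm))) rownames(dm) <- colnames(dm) <-
      paste0("t", seq_len(n))
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-12)))
    stop("distance matrix is not symmetric")
  if (any(dm < 0) || any(abs(diag(dm)) > 1e-12))
    stop("distance matrix must be non-negative with zero diagonal")
  labs <- rownames(dm)
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  if (n < 3L) {
    warning("fewer than 3 taxa: returning trivial tree")
    txt <- if (n == 1L) paste0("(", labs, ":0);")
    else paste0("(", labs[1L], ":", fmt(dm[1, 2] / 2), ",",
                labs[2L], ":", fmt(dm[1, 2] / 2), ");")
    return(ape::read.tree(text = txt))
  }
  sub <- labs          # Newick fragment per active cluster
  d <- dm
  while (length(sub) > 3L) {
    m <- nrow(d)
    R <- rowSums(d)
    best <- c(NA_integer_, NA_integer_); bq <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        q <- (m - 2) * d[i, j] - R[i] - R[j]
        if (q < bq - 1e-12) { bq <- q; best <- c(i, j) }
      }
    }
    i <- best[1L]; j <- best[2L]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newsub <- paste0("(", sub[i], ":", fmt(li), ",", sub[j], ":", fmt(lj),
                     ")")
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    sub <- c(sub[keep], newsub)
    d <- d2
  }
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- paste0("(", sub[1L], ":", fmt(l1), ",", sub[2L], ":", fmt(l2), ",",
                sub[3L], ":", fmt(l3), ");")
  ape::read.tree(text = txt)
}

#' Build the lineage tree of a clonotype's top variants
#'
#' Aligns the top-N variants by germline projection, computes Hamming
#' distances, and runs neighbor joining. Leaf labels carry read counts as
#' `rank<r>_<count>`.
#'
#' @param variant_table Variant table (see [enumerate_variants()]).
#' @param n Number of top variants (default 10).
#' @return A `phylo` object.
#' @export
variant_tree <- function(variant_table, n = 10L) {
  top <- top_n_variants(variant_table, n)
  nj_tree(pairwise_distances(align_variants(top)))
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lineage_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
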