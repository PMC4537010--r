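test_that("align_variants projects onto the shared germline interval", {
  vt <- data.frame(variant_seq = c("ACGT", "ACGA"), count_total = c(5L, 2L),
                   rank = 1:2, stringsAsFactors = FALSE)
  aln <- align_variants(vt)
  expect_identical(unname(aln), vt$variant_seq)
  expect_identical(names(aln), c("rank1_5", "rank2_2"))

  members <- fake_annotated(cdr3 = rep("TGTX", 2), replicate = c("A", "B"),
                            v_proj = c("AAAATTTT", "AATTTTGG"),
                            start = c(0L, 2L), end = c(8L, 10L))
  expect_identical(unname(align_variants(members)), c("AATTTT", "AATTTT"))

  members$v_call <- c("X*01", "Y*01")
  expect_error(align_variants(members), "different alleles")

  single <- align_variants(data.frame(variant_seq = "ACGT",
                                      count_total = 1L, rank = 1L))
  expect_length(single, 1L)
})

test_that("pairwise distances equal brute-force per-site comparison", {
  expect_identical(pairwise_distances(c(a = "ACGT", b = "ACGT"))[1, 2], 0)
  expect_identical(pairwise_distances(c(a = "ACGTAA", b = "AGGTAT"))[1, 2], 2)
  set.seed(401)
  aln <- stats::setNames(vapply(1:10, function(i) rand_dna(200), ""),
                         paste0("s", 1:10))
  d <- pairwise_distances(aln)
  expect_true(isSymmetric(d))
  expect_true(all(diag(d) == 0))
  chars <- lapply(aln, function(s) strsplit(s, "")[[1]])
  for (k in 1:15) {
    ij <- sample(10, 2)
    expect_identical(d[ij[1], ij[2]],
                     as.numeric(sum(chars[[ij[1]]] != chars[[ij[2]]])))
  }
  dp <- pairwise_distances(aln, p_distance = TRUE)
  expect_equal(dp, d / 200)
  expect_error(pairwise_distances(c(a = "ACG", b = "AC")), "unequal")
})

# path-length (cophenetic) matrix of a phylo tree, for additivity checks
path_lengths <- function(tree) ape::cophenetic.phylo(tree)

test_that("NJ exactly recovers an additive 4-taxon tree", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> additive distances
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(dm)
  expect_identical(ape::Ntip(tr), 4L)
  expect_identical(nrow(tr$edge), 2L * 4L - 3L)    # unrooted binary
  pl <- path_lengths(tr)[LETTERS[1:4], LETTERS[1:4]]
  expect_equal(pl, dm, tolerance = 1e-9)
  # recovered split is AB|CD
  oracle <- ls_topology_oracle(dm)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), oracle$tree)), 0)
  expect_lt(oracle$ss, 1e-18)
})

test_that("NJ matches the exhaustive least-squares oracle on additive
           5-taxon trees", {
  set.seed(402)
  for (i in 1:5) {
    # random additive 5-taxon tree with positive branch lengths
    topo <- sample(all_unrooted_topologies(LETTERS[1:5]), 1)
    tr0 <- ape::read.tree(text = topo)
    tr0$edge.length <- stats::runif(nrow(tr0$edge), 0.5, 3)
    dm <- path_lengths(tr0)[LETTERS[1:5], LETTERS[1:5]]
    tr <- nj_tree(dm)
    expect_identical(nrow(tr$edge), 7L)
    expect_equal(path_lengths(tr)[LETTERS[1:5], LETTERS[1:5]], dm,
                 tolerance = 1e-9)
    oracle <- ls_topology_oracle(dm)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), oracle$tree)), 0)
  }
})

test_that("NJ agrees with the reference implementation on random matrices", {
  set.seed(403)
  for (i in 1:5) {
    n <- sample(4:8, 1)
    x <- matrix(stats::runif(n * 20), n)
    dm <- as.matrix(stats::dist(x))
    dimnames(dm) <- list(paste0("t", 1:n), paste0("t", 1:n))
    tr <- nj_tree(dm)
    ref <- ape::nj(stats::as.dist(dm))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(ref))), 0)
  }
})

test_that("3-taxon closed form and degenerate inputs", {
  dm <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(dm)
  el <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(el[["A"]], 1); expect_equal(el[["B"]], 1)
  expect_equal(el[["C"]], 3)

  expect_warning(t2 <- nj_tree(matrix(c(0, 4, 4, 0), 2, 2,
    dimnames = list(c("A", "B"), c("A", "B")))), "trivial")
  expect_identical(sort(t2$tip.label), c("A", "B"))

  bad <- matrix(c(0, 1, 2, 0), 2, 2, dimnames = list(c("A", "B"),
                                                     c("A", "B")))
  expect_error(nj_tree(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2, dimnames = list(c("A", "B"),
                                                       c("A", "B")))
  expect_error(nj_tree(neg), "non-negative")
})

test_that("negative NJ branch lengths are clamped, preserving path lengths", {
  # a non-additive matrix known to produce a negative internal estimate
  dm <- matrix(c(0, 1, 6, 6,
                 1, 0, 6, 6,
                 6, 6, 0, 1,
                 6, 6, 1, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(dm)
  expect_true(all(tr$edge.length >= 0))
})

test_that("Newick serialization round-trips", {
  dm <- matrix(c(0, 3, 5, 6, 3, 0, 6, 7, 5, 6, 0, 7, 6, 7, 7, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(dm)
  f1 <- tempfile(fileext = ".nwk")
  write_lineage_newick(tr, f1)
  back <- ape::read.tree(f1)
  f2 <- tempfile(fileext = ".nwk")
  write_lineage_newick(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(sort(back$tip.label), sort(tr$tip.label))
})

test_that("variant_tree labels leaves with rank and read count", {
  set.seed(404)
  base <- rand_dna(40)
  mut <- function(s, k) { v <- strsplit(s, "")[[1]]
    for (p in sample(40, k)) v[p] <- setdiff(c("A","C","G","T"), v[p])[1]
    paste0(v, collapse = "") }
  vt <- data.frame(
    variant_seq = c(base, mut(base, 2), mut(base, 4), mut(base, 6)),
    count_total = c(900L, 50L, 30L, 20L), rank = 1:4,
    stringsAsFactors = FALSE)
  tr <- variant_tree(vt)
  expect_setequal(tr$tip.label,
                  c("rank1_900", "rank2_50", "rank3_30", "rank4_20"))
})
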