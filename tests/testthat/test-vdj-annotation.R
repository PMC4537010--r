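test_that("exact allele substrings are assigned with zero mutations", {
  ref <- tiny_ref()
  res <- assign_germline(ref$seq[1], ref)
  expect_identical(res$v_call, "TINYV1*01")
  expect_false(res$unassignable)
  expect_identical(length(res$alignment$mut_pos0), 0L)
  expect_identical(percent_homology(res$alignment), 100)
})

test_that("a mutated copy of one allele is not mis-assigned to the other", {
  ref <- tiny_ref()
  set.seed(201)
  for (rep_i in 1:5) {
    src <- sample(1:2, 1)
    v <- strsplit(ref$seq[src], "")[[1]]
    # interior positions only: a terminal mismatch is legitimately clipped
    # by the free-end-gap alignment
    pos <- sample(2:(length(v) - 1L), 5)
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    res <- assign_germline(paste0(v, collapse = ""), ref)
    expect_identical(res$v_call, ref$name[src])
    expect_identical(sort(res$alignment$mut_pos0), sort(pos - 1L))
  }
})

test_that("random reads are flagged unassignable", {
  set.seed(202)
  res <- assign_germline(rand_dna(350), tiny_ref())
  expect_true(res$unassignable)
  expect_true(is.na(res$v_call))
})

test_that("percent homology reproduces hand-computed values", {
  # 280 aligned germline bases with 15 and 30 mismatches: 94.6 and 89.3
  set.seed(203)
  germ <- rand_dna(280)
  ref <- germline_set("H*01", paste0(substr(germ, 1, 277), "TGT"), 277L)
  for (case in list(c(15L, 94.6), c(30L, 89.3), c(0L, 100))) {
    v <- strsplit(ref$seq[1], "")[[1]]
    if (case[1] > 0) {
      pos <- sample(2:270, case[1])
      for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
    }
    res <- assign_germline(paste0(v, collapse = ""), ref)
    expect_identical(percent_homology(res$alignment), case[2])
  }
  expect_error(percent_homology(structure(
    list(start_germ = 5L, end_germ = 5L, n_insertion = 0L, n_match = 0L),
    class = "v_alignment")), "zero aligned length")
})

test_that("CDR3 extraction recovers planted junctions and anchors", {
  ref <- tiny_ref()
  allele <- ref[1, ]
  junction <- "GATTACAGGCGA"                     # 12 b, no TGGGG
  jseg <- "TGGGGCCAAGGGACC"
  read <- paste0(allele$seq, junction, jseg, strrep("A", 30))
  res <- assign_germline(read, ref)
  cdr3 <- extract_cdr3(read, res$alignment, allele$cys104_pos)
  expect_identical(
    cdr3, paste0(substr(allele$seq, 121, 150), junction, "TGG"))
  expect_identical(nchar(cdr3) %% 3L, 0L)
  expect_identical(substr(translate_nt(cdr3), 1, 1), "C")

  # truncated before the J anchor -> absent
  trunc <- substr(read, 1, nchar(allele$seq) + 6)
  rest <- assign_germline(trunc, ref)
  expect_true(is.na(extract_cdr3(trunc, rest$alignment, allele$cys104_pos)))

  # an out-of-frame TGGGG inside the junction is skipped; the first
  # in-frame anchor is chosen
  junc2 <- "CTGGGGATCAGA"                        # TGGGG at frame offset 1
  read2 <- paste0(allele$seq, junc2, jseg, strrep("A", 30))
  res2 <- assign_germline(read2, ref)
  cdr32 <- extract_cdr3(read2, res2$alignment, allele$cys104_pos)
  expect_identical(
    cdr32, paste0(substr(allele$seq, 121, 150), junc2, "TGG"))
})

test_that("codon classification matches the translation oracle on all 64
           codons", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste0, collapse = "")
  # independent oracle: Biostrings' genetic code
  oracle <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(codons), no.init.codon = TRUE))
  expect_identical(vapply(codons, function(cd)
    translate_nt(cd), "", USE.NAMES = FALSE), oracle)

  # silent/replacement agrees with oracle equality for every codon pair
  set.seed(204)
  for (k in 1:200) {
    a <- sample(codons, 1); b <- sample(codons, 1)
    if (a == b) next
    expect_identical(classify_mutation(a, b) == "silent",
                     oracle[match(a, codons)] == oracle[match(b, codons)])
  }
  expect_identical(classify_mutation("CTG", "CTA"), "silent")
  expect_identical(classify_mutation("GAT", "GCT"), "replacement")
  expect_identical(classify_mutation("GAN", "GCT"), "unknown")
})

test_that("annotation of error-free simulated reads recovers the truth", {
  cfg <- fast_sim_config(seed = 23L, total_read_pairs = 500L,
                         seq_error_rate = 0, pcr_error_rate = 0,
                         n_background_clones = 4L)
  sim <- simulate_repertoire(cfg, file.path(tempdir(), "annrt"))
  ref <- read_germline_fasta(cfg$germline_ref)
  pairs <- read_fastq_pairs(sim$paths$r1_repA, sim$paths$r2_repA)
  merged <- merge_pairs(pairs)
  ann <- annotate_reads(filter_reads(merged), ref)

  # alleles in the bundled reference differ pairwise by >= 10 substitutions,
  # so every error-free read must map back to its generating allele
  expect_false(any(ann$unassignable))
  clone_reads <- ann$cdr3 %in% sim$truth$clone_cdr3
  expect_true(any(clone_reads))
  expect_true(all(ann$v_call[clone_reads] == sim$truth$allele))

  # founder homology is exactly 100 * (1 - trunk/aligned) on the clean
  # founder sequence
  founder_proj <- ann$v_proj[ann$v_proj == sim$truth$variants$v_seq[1]]
  expect_gt(length(founder_proj), 0)
  germ_len <- nchar(sim$truth$germline_seq)
  founder_rows <- which(ann$v_proj == sim$truth$variants$v_seq[1])
  expect_true(all(ann$homology_pct[founder_rows] ==
    round_half_up(100 * (germ_len - cfg$trunk_mutations) / germ_len, 1)))

  # every lineage read reports the identical CDR3 string
  lineage_ids <- sim$truth$realized$template_id[
    sim$truth$realized$origin == "clone"]
  expect_identical(unique(ann$cdr3[clone_reads]), sim$truth$clone_cdr3)
})

test_that("AIRR TSV round-trips", {
  ref <- tiny_ref()
  merged <- data.frame(id = c("a", "b"), seq = c(ref$seq[1], ref$seq[2]),
                       qual = strrep("F", 150), overlap_len = 50L,
                       mismatch_count = 0L, stringsAsFactors = FALSE)
  ann <- annotate_reads(merged, ref)
  path <- tempfile(fileext = ".tsv")
  write_airr_tsv(ann, path)
  back <- read_airr_tsv(path)
  expect_identical(back$v_call, ann$v_call)
  expect_identical(back$aln_start_germ, ann$aln_start_germ)
  expect_identical(back$unassignable, ann$unassignable)
})
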