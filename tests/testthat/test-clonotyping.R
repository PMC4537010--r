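test_that("clonotypes are exact CDR3 identity groups with replicate counts", {
  ann <- fake_annotated(
    cdr3 = c("TGTAAA", "TGTAAA", "TGTAAA", "TGTCCC", "TGTCCC"),
    replicate = c("A", "A", "B", "A", "B"))
  tab <- group_by_cdr3(ann)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$count_total, c(3L, 2L))
  expect_identical(tab$count_repA, c(2L, 1L))
  expect_equal(sum(tab$freq_pct), 100)

  # one-base difference makes a distinct clonotype
  ann2 <- fake_annotated(cdr3 = c("TGTAAA", "TGTAAC"), replicate = c("A", "B"))
  expect_identical(nrow(group_by_cdr3(ann2)), 2L)

  # reads without a CDR3 are excluded and counted
  ann3 <- fake_annotated(cdr3 = c("TGTAAA", NA), replicate = c("A", "B"))
  t3 <- group_by_cdr3(ann3)
  expect_identical(nrow(t3), 1L)
  expect_identical(attr(t3, "n_no_cdr3"), 1L)

  empty <- group_by_cdr3(fake_annotated(cdr3 = character(0),
                                        replicate = character(0)))
  expect_identical(nrow(empty), 0L)
})

test_that("concordance filter removes replicate-exclusive variants", {
  tab <- data.frame(
    cdr3 = c("X", "Y", "Z"),
    count_repA = c(500L, 50L, 450L),
    count_repB = c(520L, 0L, 480L),   # Y present at 5% of A, absent from B
    stringsAsFactors = FALSE)
  tab$count_total <- tab$count_repA + tab$count_repB
  out <- concordance_filter(tab)
  expect_identical(out$cdr3, c("X", "Z"))

  # present at ~5% in both -> retained
  tab$count_repB[2] <- 48L
  tab$count_total <- tab$count_repA + tab$count_repB
  expect_identical(nrow(concordance_filter(tab)), 3L)

  # threshold 0 with min count 1 reduces to presence-in-both
  tab$count_repB[2] <- 1L
  out0 <- concordance_filter(tab, min_freq_each_replicate = 0,
                             min_count_each = 1L)
  expect_identical(out0$cdr3, c("X", "Y", "Z"))

  # an empty replicate is a configuration error
  bad <- data.frame(count_repA = 5L, count_repB = 0L)
  expect_error(concordance_filter(bad), "replicate")
})

test_that("dominant-clone calling uses a strict threshold", {
  mk <- function(freqs) data.frame(
    cdr3 = sprintf("C%d", seq_along(freqs)), freq_pct = freqs,
    count_total = round(freqs * 100), stringsAsFactors = FALSE)
  expect_identical(detect_dominant(mk(c(87.3, 5, 7.7)))$cdr3, "C1")
  expect_null(detect_dominant(mk(c(2.4, 1.1, 0.6))))
  expect_null(detect_dominant(mk(c(7.8, 2)), threshold_pct = 7.8))
  expect_identical(detect_dominant(mk(c(7.9, 2)),
                                   threshold_pct = 7.8)$cdr3, "C1")
  expect_null(detect_dominant(mk(numeric(0))))
})

test_that("raising the dominance threshold never creates a call", {
  set.seed(301)
  for (i in 1:20) {
    freqs <- as.numeric(prop.table(stats::rexp(8)) * 100)
    tab <- data.frame(cdr3 = paste0("C", 1:8), freq_pct = freqs)
    thr <- sort(stats::runif(2, 0, 20))
    lo <- detect_dominant(tab, thr[1]); hi <- detect_dominant(tab, thr[2])
    expect_true(is.null(hi) || !is.null(lo))
  }
})

test_that("variant enumeration groups full-length identity on the shared
           interval", {
  # 3 distinct variants over a 12 b window, planted counts 4/2/1
  seqs <- c(a = "AAAATTTTGGGG", b = "AAAATTTTGGGC", c = "AAAATATTGGGG")
  reads <- c("a", "a", "b", "a", "c", "b", "a")
  reps <- c("A", "B", "A", "B", "A", "B", "A")
  ann <- fake_annotated(cdr3 = rep("TGTX", 7), replicate = reps,
                        v_proj = unname(seqs[reads]), start = 0L, end = 12L)
  vt <- enumerate_variants(ann)
  expect_identical(vt$variant_seq[1], unname(seqs["a"]))
  expect_identical(vt$count_total, c(4L, 2L, 1L))
  expect_identical(vt$rank, 1:3)
  expect_identical(sum(vt$count_total), 7L)       # conservation

  # differing read offsets: truncation to the shared covered interval
  # merges variants that only differ outside it
  ann2 <- fake_annotated(cdr3 = rep("TGTX", 3), replicate = c("A", "B", "A"),
                         v_proj = c("AAAATTTT", "AATTTTGG", "AATTTTGC"),
                         start = c(0L, 2L, 2L), end = c(8L, 10L, 10L))
  vt2 <- enumerate_variants(ann2)
  expect_identical(attr(vt2, "interval"), c(2L, 8L))
  expect_identical(vt2$variant_seq, "AATTTT")
  expect_identical(vt2$count_total, 3L)

  expect_error(enumerate_variants(fake_annotated(
    cdr3 = c("TGTX", "TGTY"), replicate = c("A", "B"))), "share")
})

test_that("planted error-free lineage variants are recovered exactly", {
  cfg <- fast_sim_config(seed = 29L, total_read_pairs = 600L,
                         seq_error_rate = 0, pcr_error_rate = 0,
                         n_background_clones = 5L)
  sim <- simulate_repertoire(cfg, file.path(tempdir(), "vtruth"))
  ref <- read_germline_fasta(cfg$germline_ref)
  ann <- list()
  for (rp in c("A", "B")) {
    pairs <- read_fastq_pairs(sim$paths[[paste0("r1_rep", rp)]],
                              sim$paths[[paste0("r2_rep", rp)]])
    a <- annotate_reads(filter_reads(merge_pairs(pairs)), ref)
    a$replicate <- rp
    ann[[rp]] <- a
  }
  ann <- do.call(rbind, ann)
  members <- ann[ann$cdr3 %in% sim$truth$clone_cdr3, ]
  vt <- enumerate_variants(members)

  # expected: realized counts aggregated over identical variant sequences
  rl <- merge(sim$truth$realized[sim$truth$realized$origin == "clone", ],
              sim$truth$variants, by.x = "template_id", by.y = "variant_id")
  exp_counts <- tapply(rl$count_total, rl$v_seq, sum)
  exp_counts <- exp_counts[exp_counts > 0]
  expect_identical(nrow(vt), length(exp_counts))
  expect_identical(
    vt$count_total[match(names(exp_counts), vt$variant_seq)],
    as.integer(exp_counts))
})

test_that("germline usage summary recovers planted allele proportions", {
  expect_identical(
    germline_usage_summary(fake_annotated("TGTX", "A"))$freq_pct, 100)
  expect_identical(nrow(germline_usage_summary(
    fake_annotated(character(0), character(0)))), 0L)

  set.seed(302)
  n <- 5000L
  genes <- sample(c("IGHV1-S69*01", "IGHV3-S30*18"), n, replace = TRUE,
                  prob = c(0.6, 0.4))
  ann <- fake_annotated(cdr3 = rep("TGTX", n),
                        replicate = rep("A", n), v_call = genes)
  us <- germline_usage_summary(ann)
  expect_identical(us$gene[1], "IGHV1-S69")
  band <- stats::qbinom(c(0.005, 0.995), n, 0.6)
  expect_gte(us$n_reads[1], band[1]); expect_lte(us$n_reads[1], band[2])
})
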