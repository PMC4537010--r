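#' Pipeline configuration
#'
#' Collects the paths and per-stage parameters of an end-to-end run. Exactly
#' two technical replicates (read-pair file sets) per sample are required:
#' the replicate-concordance filter is a core part of the analysis.
#'
#' @param sample_id Sample identifier used in output file names.
#' @param r1_repA,r2_repA,r1_repB,r2_repB FASTQ paths, mates 1/2 of
#'   technical replicates A and B.
#' @param outdir Run directory (created).
#' @param germline_ref Germline allele FASTA path.
#' @param min_overlap,max_mismatch_density Merge parameters
#'   (see [merge_pair()]).
#' @param min_length Minimum combined read length (see [filter_reads()]).
#' @param min_mean_quality Optional mean-quality threshold (default off).
#' @param min_identity,min_aligned,max_gaps Annotation parameters
#'   (see [annotate_reads()]).
#' @param min_freq_each_replicate,min_count_each Concordance-filter
#'   parameters (see [concordance_filter()]).
#' @param dominant_threshold_pct Dominant-clone cut-off in percent (default
#'   5.0; 7.8 recommended for IgG myeloma calling).
#' @param top_n Top variants used for the ICV alignment and tree.
#' @param tumor_cells Total tumor cell mass for the burden extrapolation
#'   (default 0.5e12, the lower published estimate for IgG myeloma).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sample_id, r1_repA, r2_repA, r1_repB, r2_repB,
                            outdir, germline_ref = ighv_reference(),
                            min_overlap = 10L, max_mismatch_density = 0.25,
                            min_length = 300L, min_mean_quality = NULL,
                            min_identity = 0.5, min_aligned = 100L,
                            max_gaps = 3L, min_freq_each_replicate = 0.01,
                            min_count_each = 2L,
                            dominant_threshold_pct = 5.0, top_n = 10L,
                            tumor_cells = 0.5e12) {
  cfg <- as.list(environment())
  for (f in c("r1_repA", "r2_repA", "r1_repB", "r2_repB")) {
    if (is.null(cfg[[f]]) || !nzchar(cfg[[f]]))
      stop("missing replicate file: ", f,
           " (the pipeline requires two technical replicates)")
  }
  for (f in c("r1_repA", "r2_repA", "r1_repB", "r2_repB", "germline_ref")) {
    if (!file.exists(cfg[[f]])) stop("file not found: ", cfg[[f]])
  }
  stopifnot(cfg$dominant_threshold_pct >= 0,
            cfg$max_mismatch_density >= 0, cfg$max_mismatch_density <= 1)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' The YAML holds the [pipeline_config()] arguments, optionally nested under
#' per-stage sections (`input`, `merge`, `annotate`, `clonotype`, `icv`).
#'
#' @param path YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  flat <- do.call(c, c(unname(lapply(y, function(x)
    if (is.list(x)) x else NULL)),
    list(y[!vapply(y, is.list, TRUE)])))
  do.call(pipeline_config, flat[names(flat) %in%
                                  names(formals(pipeline_config))])
}

.stage_log <- function(stage, ...) {
  message(sprintf("[icvseq] %-12s %s", stage, sprintf(...)))
}

#' Run the full analysis pipeline
#'
#' simulate/merge/annotate/clonotype/ICV/tree orchestration over one sample
#' with two technical replicates: merges and length-filters both replicates,
#' annotates reads against the germline reference, groups reads into
#' CDR3-identical clonotypes, applies the replicate-concordance filter, calls
#' the dominant clonotype, and — when one is found — enumerates its sequence
#' variants, quantifies intraclonal variation, and builds the
#' neighbor-joining lineage tree of the top variants.
#'
#' All intermediate artifacts (merged FASTQ, AIRR TSV, clonotype and variant
#' TSVs, ICV report, Newick tree) are written into the run directory so that
#' stages are independently re-runnable; `summary.json` holds the
#' machine-readable result and is byte-identical across reruns of the same
#' inputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  ref <- read_germline_fasta(config$germline_ref)

  ann_all <- list(); qc <- list()
  for (rp in c("A", "B")) {
    pairs <- read_fastq_pairs(config[[paste0("r1_rep", rp)]],
                              config[[paste0("r2_rep", rp)]])
    merged <- merge_pairs(pairs, config$min_overlap,
                          config$max_mismatch_density)
    kept <- filter_reads(merged, config$min_length, config$min_mean_quality)
    fq <- attr(kept, "qc")
    write_merged_fastq(kept, file.path(config$outdir, sprintf(
      "%s_rep%s_merged.fastq", config$sample_id, rp)))
    ann <- annotate_reads(kept, ref, config$min_identity,
                          config$min_aligned, config$max_gaps)
    if (nrow(ann)) ann$replicate <- rp else ann$replicate <- character(0)
    ann_all[[rp]] <- ann
    qc[[rp]] <- data.frame(
      replicate = rp, n_pairs_input = nrow(pairs),
      n_merged = nrow(merged), n_merge_rejected = attr(merged, "n_rejected"),
      n_kept = fq$n_kept, n_short = fq$n_short,
      n_low_quality = fq$n_low_quality,
      n_assigned_cdr3 = sum(!ann$unassignable & !is.na(ann$cdr3)),
      n_cdr3_absent = sum(!ann$unassignable & is.na(ann$cdr3)),
      n_unassignable = sum(ann$unassignable))
    .stage_log("merge", "rep%s: %d pairs -> %d merged (%d rejected)",
               rp, nrow(pairs), nrow(merged), attr(merged, "n_rejected"))
    .stage_log("filter", "rep%s: %d kept, %d short", rp, fq$n_kept,
               fq$n_short)
    .stage_log("annotate", "rep%s: %d with CDR3, %d no CDR3, %d unassigned",
               rp, qc[[rp]]$n_assigned_cdr3, qc[[rp]]$n_cdr3_absent,
               qc[[rp]]$n_unassignable)
  }
  qc <- do.call(rbind, qc)
  utils::write.table(qc, file.path(config$outdir, paste0(
    config$sample_id, "_qc.tsv")), sep = "\t", quote = FALSE,
    row.names = FALSE)
  annotated <- do.call(rbind, ann_all)
  row.names(annotated) <- NULL
  write_airr_tsv(annotated, file.path(config$outdir, paste0(
    config$sample_id, "_rearrangements.tsv")))

  summary <- list(sample_id = config$sample_id, qc = qc,
                  dominant = NULL, icv = NULL)
  if (sum(qc$n_assigned_cdr3) == 0L) {
    .stage_log("clonotype", "no CDR3-bearing reads: writing empty report")
    summary$clonotypes <- list()
    jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA,
                         null = "null")
    return(invisible(summary))
  }

  clono <- group_by_cdr3(annotated)
  clono_f <- concordance_filter(clono, config$min_freq_each_replicate,
                                config$min_count_each)
  utils::write.table(clono_f, file.path(config$outdir, paste0(
    config$sample_id, "_clonotypes.tsv")), sep = "\t", quote = FALSE,
    row.names = FALSE)
  .stage_log("clonotype", "%d clonotypes (%d pass concordance filter)",
             nrow(clono), nrow(clono_f))
  summary$n_clonotypes <- nrow(clono)
  summary$n_clonotypes_concordant <- nrow(clono_f)
  summary$usage <- germline_usage_summary(annotated)

  dom <- detect_dominant(clono_f, config$dominant_threshold_pct)
  if (is.null(dom)) {
    .stage_log("dominant", "no clonotype above %.1f%%: oligoclonal profile",
               config$dominant_threshold_pct)
    summary$oligoclonal_top <- utils::head(clono_f, 10L)
  } else {
    .stage_log("dominant", "dominant clonotype at %.1f%% (%d reads)",
               dom$freq_pct, dom$count_total)
    summary$dominant <- as.list(dom)
    members <- annotated[!is.na(annotated$cdr3) & annotated$cdr3 == dom$cdr3 &
                           !annotated$unassignable, , drop = FALSE]
    vt <- enumerate_variants(members)
    vt_f <- concordance_filter(vt, config$min_freq_each_replicate,
                               config$min_count_each)
    vt_f$rank <- seq_len(nrow(vt_f))
    attr(vt_f, "interval") <- attr(vt, "interval")
    attr(vt_f, "v_call") <- attr(vt, "v_call")
    utils::write.table(vt_f, file.path(config$outdir, paste0(
      config$sample_id, "_variants.tsv")), sep = "\t", quote = FALSE,
      row.names = FALSE)
    germ_seq <- ref$seq[ref$name == dom$v_call]
    rep_icv <- icv_report(vt_f, germ_seq, config$top_n)
    .stage_log("icv", "%d variants, ICV fraction %.1f%%",
               rep_icv$n_variants, rep_icv$icv_fraction_pct)
    summary$icv <- list(
      dominant_variant_count = rep_icv$dominant_variant_count,
      clonotype_total = rep_icv$clonotype_total,
      icv_fraction_pct = rep_icv$icv_fraction_pct,
      n_variants = rep_icv$n_variants,
      n_trunk_mutations = nrow(rep_icv$shared_mutations),
      n_icv_mutations = nrow(rep_icv$icv_mutations),
      variant_burden_cells = variant_burden(rep_icv$icv_fraction_pct,
                                            config$tumor_cells))
    writeLines(format_icv_alignment(top_n_variants(vt_f, config$top_n),
                                    germ_seq),
               file.path(config$outdir, paste0(config$sample_id,
                                               "_icv_alignment.txt")))
    if (nrow(vt_f) >= 3L) {
      tree <- variant_tree(vt_f, config$top_n)
      write_lineage_newick(tree, file.path(config$outdir, paste0(
        config$sample_id, "_lineage.nwk")))
      .stage_log("tree", "NJ tree over top %d variants written",
                 min(config$top_n, nrow(vt_f)))
    }
  }
  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(summary)
}
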