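#' Simulation configuration
#'
#' Builds and validates the configuration of the synthetic SHM-lineage
#' repertoire generator. The generator emulates the library structure the
#' downstream analysis assumes: one dominant clonal lineage whose members share
#' an identical CDR3 but differ by ongoing-SHM substitutions, a polyclonal IgG
#' background of mutated reads with diverse CDR3s, PCR and sequencing
#' substitution errors, and an even split of read pairs into two technical
#' replicates.
#'
#' @param seed Integer seed; identical seed + config gives byte-identical
#'   FASTQ output.
#' @param germline_ref Path to a germline IGHV allele FASTA (see
#'   [read_germline_fasta()]); defaults to the bundled synthetic reference.
#' @param n_background_clones Number of polyclonal background clonotypes.
#' @param background_abundance_shape Power-law (Zipf) exponent for background
#'   clone sizes; clone k gets weight k^-shape.
#' @param dominant_clone_fraction Expected proportion of read pairs drawn from
#'   the expansion clonotype.
#' @param trunk_mutations Number of shared SHM substitutions planted in the
#'   lineage founder (acquired before the clone's last common ancestor).
#' @param n_subclone_generations Number of ongoing-SHM branching rounds; each
#'   round every extant variant spawns one mutated child, so the lineage holds
#'   `2^n_subclone_generations` variants.
#' @param per_generation_mutation_rate Mean substitutions per sequence per
#'   branching round (Poisson).
#' @param hotspot_weight Relative substitution weight (>= 1) at positions
#'   inside AID hotspot motifs (RGYW/WRCY) of the germline V region.
#' @param seq_error_rate Per-base substitution probability applied to each
#'   sequenced read. Default 2e-4, consistent with the constant Q37 quality
#'   strings the generator writes (10^-3.7 ~= 2e-4).
#' @param pcr_error_rate Per-base per-PCR-cycle substitution probability
#'   (default 4.4e-7, a high-fidelity polymerase).
#' @param pcr_cycles Number of PCR cycles (default 30).
#' @param read_length Read length in bases (default 250, paired-end).
#' @param amplicon_length_range Length-two integer vector, min/max amplicon
#'   length in bases (default c(400, 450), post size-selection).
#' @param total_read_pairs Total read pairs across both replicates.
#' @param replicate_split Probability a read pair is assigned to replicate A.
#' @param background_mutation_mean Mean SHM substitutions per background
#'   clone (Poisson), reproducing the 89-95\% germline homology typical of
#'   class-switched IgG transcripts.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       germline_ref = ighv_reference(),
                       n_background_clones = 50L,
                       background_abundance_shape = 1.5,
                       dominant_clone_fraction = 0.8,
                       trunk_mutations = 18L,
                       n_subclone_generations = 3L,
                       per_generation_mutation_rate = 2,
                       hotspot_weight = 3,
                       seq_error_rate = 2e-4,
                       pcr_error_rate = 4.4e-7,
                       pcr_cycles = 30L,
                       read_length = 250L,
                       amplicon_length_range = c(400L, 450L),
                       total_read_pairs = 1e4,
                       replicate_split = 0.5,
                       background_mutation_mean = 18) {
  cfg <- list(seed = as.integer(seed), germline_ref = germline_ref,
              n_background_clones = as.integer(n_background_clones),
              background_abundance_shape = background_abundance_shape,
              dominant_clone_fraction = dominant_clone_fraction,
              trunk_mutations = as.integer(trunk_mutations),
              n_subclone_generations = as.integer(n_subclone_generations),
              per_generation_mutation_rate = per_generation_mutation_rate,
              hotspot_weight = hotspot_weight,
              seq_error_rate = seq_error_rate,
              pcr_error_rate = pcr_error_rate,
              pcr_cycles = as.integer(pcr_cycles),
              read_length = as.integer(read_length),
              amplicon_length_range = as.integer(amplicon_length_range),
              total_read_pairs = as.integer(total_read_pairs),
              replicate_split = replicate_split,
              background_mutation_mean = background_mutation_mean)
  validate_sim_config(cfg)
  class(cfg) <- c("sim_config", "list")
  cfg
}

validate_sim_config <- function(cfg) {
  rates <- c(dominant_clone_fraction = cfg$dominant_clone_fraction,
             seq_error_rate = cfg$seq_error_rate,
             pcr_error_rate = cfg$pcr_error_rate,
             replicate_split = cfg$replicate_split)
  bad <- rates < 0 | rates > 1
  if (any(bad)) stop("rates/proportions outside [0,1]: ",
                     paste(names(rates)[bad], collapse = ", "))
  if (cfg$hotspot_weight < 1) stop("hotspot_weight must be >= 1")
  if (length(cfg$amplicon_length_range) != 2L ||
      diff(cfg$amplicon_length_range) < 0)
    stop("amplicon_length_range must be c(min, max) with min <= max")
  if (2L * cfg$read_length < cfg$amplicon_length_range[1L] + 10L)
    stop("2*read_length must exceed the minimum amplicon length plus the ",
         "minimum merge overlap (10 b)")
  neg <- c(n_background_clones = cfg$n_background_clones,
           trunk_mutations = cfg$trunk_mutations,
           n_subclone_generations = cfg$n_subclone_generations,
           total_read_pairs = cfg$total_read_pairs)
  if (any(neg < 0)) stop("counts must be non-negative")
  invisible(cfg)
}

# J segment used in every amplicon: starts with the in-frame TGG-GGC (W-G)
# CDR3-closing anchor, JH4-like.
.sim_j_segment <- "TGGGGCCAAGGGACCACGGTCACCGTCTCCTCA"
# Fixed 60 b IgG-like constant-region stub (CH1-like) so reverse reads
# originate outside the V region, as in the FR1 -> IgG constant amplicon.
.sim_constant_stub <-
  "GCCTCCACCAAGGGCCCATCGGTCTTCCCCCTGGCACCCTCCTCCAAGAGCACCTCTGGG"

#' Positions inside AID hotspot motifs
#'
#' Returns the 0-based positions of a sequence covered by an RGYW or WRCY
#' motif occurrence (R = A/G, Y = C/T, W = A/T), the classical AID
#' somatic-hypermutation hotspots.
#'
#' @param seq A nucleotide string.
#' @return Sorted integer vector of 0-based positions.
#' @export
hotspot_positions <- function(seq) {
  hits <- integer(0)
  for (motif in c("[AG]G[CT][AT]", "[AT][AG]C[CT]")) {
    m <- gregexpr(motif, seq)[[1]]
    if (m[1] > 0) {
      starts <- as.integer(m)
      hits <- c(hits, unlist(lapply(starts, function(s) s:(s + 3L))))
    }
  }
  sort(unique(hits)) - 1L
}

# Sample `k` distinct 0-based positions from `sites` with hotspot weighting,
# substituting each to a uniformly chosen different base. Returns data.frame
# pos (0-based), from, to. `v` is the character vector being mutated (1-based).
.draw_substitutions <- function(v, sites, k, weights) {
  k <- min(k, length(sites))
  if (k == 0L) {
    return(data.frame(pos = integer(0), from = character(0),
                      to = character(0), stringsAsFactors = FALSE))
  }
  pos <- sites[sample.int(length(sites), k, prob = weights)]
  from <- v[pos + 1L]
  bases <- c("A", "C", "G", "T")
  to <- vapply(from, function(b) sample(setdiff(bases, b), 1L), "",
               USE.NAMES = FALSE)
  data.frame(pos = pos, from = from, to = to, stringsAsFactors = FALSE)
}

.apply_substitutions <- function(v, subs) {
  v[subs$pos + 1L] <- subs$to
  v
}

# Random junction: length a multiple of 3 so the J anchor stays in frame,
# resampled until it contains no in-frame TGG-GG motif that would pre-empt
# the planted CDR3 anchor.
.draw_junction <- function(len_range, v_len) {
  fixed <- v_len + nchar(.sim_j_segment) + nchar(.sim_constant_stub)
  lens <- seq(6L, 90L, by = 3L)
  lens <- lens[fixed + lens >= len_range[1L] & fixed + lens <= len_range[2L]]
  if (length(lens) == 0L)
    stop("amplicon_length_range incompatible with V/J/constant segment sizes")
  len <- lens[sample.int(length(lens), 1L)]
  repeat {
    j <- paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                collapse = "")
    codons <- substring(j, seq(1L, len, 3L), seq(3L, len, 3L))
    nxt <- c(substring(j, seq(4L, len, 3L), seq(5L, len, 3L)), "")
    if (!any(codons == "TGG" & substr(nxt, 1L, 2L) == "GG")) return(j)
  }
}

#' Simulate a somatic-hypermutation lineage (ground truth)
#'
#' Builds the expansion clonotype: a founder sequence (germline V region plus
#' `trunk_mutations` shared substitutions and a random junction fixing the
#' clonal CDR3) spawns descendants over `n_subclone_generations` branching
#' rounds. Each round every extant variant produces one child carrying
#' Poisson(`per_generation_mutation_rate`) additional substitutions, drawn
#' per-site with `hotspot_weight` applied at RGYW/WRCY motif positions.
#' CDR3 positions are excluded from ongoing mutation, so every lineage member
#' keeps the identical CDR3 nucleotide sequence.
#'
#' Expected variant abundances follow a stick-breaking series in creation
#' order (the founder keeps ~50\% of the clone), giving a clone dominated by
#' one homogeneous sequence plus substantial subclonal variants.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A `sim_truth` list: `allele`, `cys104_pos`, `clone_cdr3`,
#'   `junction`, `variants` (data.frame: `variant_id`, `parent`, `generation`,
#'   `v_seq`, `n_edge_mut`, `weight`), `edge_muts` (per-variant substitution
#'   data.frames in germline coordinates), and `icv_planted_pct`, the expected
#'   percentage of clonal reads not carrying the founder sequence.
#' @export
simulate_lineage <- function(config, seed = config$seed) {
  validate_sim_config(config)
  if (!is.null(seed)) set.seed(seed)  # NULL: continue the current RNG stream
  ref <- read_germline_fasta(config$germline_ref)
  allele_i <- sample.int(nrow(ref), 1L)
  allele <- ref[allele_i, ]
  v_germ <- strsplit(allele$seq, "")[[1]]
  v_len <- length(v_germ)

  # ongoing SHM may hit any V position upstream of the Cys codon; the CDR3
  # (Cys codon onward) is invariant within the lineage
  sites <- 0:(allele$cys104_pos - 1L)
  hot <- hotspot_positions(allele$seq)
  w <- ifelse(sites %in% hot, config$hotspot_weight, 1)

  junction <- .draw_junction(config$amplicon_length_range, v_len)
  clone_cdr3 <- paste0(substr(allele$seq, allele$cys104_pos + 1L, v_len),
                       junction, "TGG")

  trunk <- .draw_substitutions(v_germ, sites, config$trunk_mutations, w)
  founder <- .apply_substitutions(v_germ, trunk)

  seqs <- list(founder)
  parent <- 0L
  gen <- 0L
  edge_muts <- list(trunk)
  if (config$n_subclone_generations > 0L) {
    for (g in seq_len(config$n_subclone_generations)) {
      for (i in seq_along(seqs)) {
        if (gen[i] < g) {  # only variants existing before this round branch
          k <- stats::rpois(1L, config$per_generation_mutation_rate)
          subs <- .draw_substitutions(seqs[[i]], sites, k, w)
          seqs[[length(seqs) + 1L]] <- .apply_substitutions(seqs[[i]], subs)
          parent <- c(parent, i)
          gen <- c(gen, g)
          edge_muts[[length(edge_muts) + 1L]] <- subs
        }
      }
    }
  }
  n <- length(seqs)
  weight <- 0.5 ^ seq_len(n)
  weight[n] <- weight[n] * 2  # close the stick so weights sum to 1
  variants <- data.frame(
    variant_id = sprintf("V%02d", seq_len(n)),
    parent = parent, generation = gen,
    v_seq = vapply(seqs, paste0, "", collapse = ""),
    n_edge_mut = vapply(edge_muts, nrow, 0L),
    weight = weight, stringsAsFactors = FALSE)
  # branches drawing zero mutations duplicate their parent's sequence, so
  # the planted ICV references the expected share of the most abundant
  # *distinct sequence*, not of the founder variant alone
  seq_w <- tapply(variants$weight, variants$v_seq, sum)
  structure(list(allele = allele$name, cys104_pos = allele$cys104_pos,
                 germline_seq = allele$seq, clone_cdr3 = clone_cdr3,
                 junction = junction, variants = variants,
                 edge_muts = edge_muts,
                 dominant_seq = names(seq_w)[which.max(seq_w)],
                 icv_planted_pct = 100 * (1 - max(seq_w))),
            class = "sim_truth")
}

# Polyclonal IgG background: clones on random alleles with Poisson-mutated V
# regions and private junctions/CDR3s; Zipf clone-size weights.
.simulate_background <- function(config, ref, exclude_cdr3) {
  n <- config$n_background_clones
  if (n == 0L) {
    return(data.frame(clone_id = character(0), allele = character(0),
                      v_seq = character(0), junction = character(0),
                      cdr3 = character(0), weight = numeric(0),
                      stringsAsFactors = FALSE))
  }
  allele_i <- sample.int(nrow(ref), n, replace = TRUE)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    al <- ref[allele_i[k], ]
    v <- strsplit(al$seq, "")[[1]]
    sites <- 0:(al$cys104_pos - 1L)
    w <- ifelse(sites %in% hotspot_positions(al$seq), config$hotspot_weight, 1)
    nm <- stats::rpois(1L, config$background_mutation_mean)
    v <- .apply_substitutions(v, .draw_substitutions(v, sites, nm, w))
    repeat {
      junction <- .draw_junction(config$amplicon_length_range, length(v))
      cdr3 <- paste0(paste0(v[(al$cys104_pos + 1L):length(v)], collapse = ""),
                     junction, "TGG")
      if (!cdr3 %in% exclude_cdr3) break
    }
    out[[k]] <- data.frame(clone_id = sprintf("BG%03d", k), allele = al$name,
                           v_seq = paste0(v, collapse = ""),
                           junction = junction, cdr3 = cdr3,
                           stringsAsFactors = FALSE)
  }
  bg <- do.call(rbind, out)
  wz <- seq_len(n) ^ -config$background_abundance_shape
  bg$weight <- wz / sum(wz)
  bg
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Apply substitution errors at per-base rate p to a character vector of
# sequences; returns the vector. Vectorized over reads with >= 1 error.
.apply_errors <- function(seqs, p) {
  if (p <= 0 || length(seqs) == 0L) return(seqs)
  nerr <- stats::rbinom(length(seqs), nchar(seqs), p)
  idx <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    v <- strsplit(seqs[i], "")[[1]]
    pos <- sample.int(length(v), nerr[i])
    for (p1 in pos) v[p1] <- sample(setdiff(bases, v[p1]), 1L)
    seqs[i] <- paste0(v, collapse = "")
  }
  seqs
}

#' Simulate a paired-end IgG repertoire (two technical replicates)
#'
#' Samples `total_read_pairs` amplicons from the expansion lineage (see
#' [simulate_lineage()]) and the polyclonal background, applies PCR
#' (`pcr_error_rate * pcr_cycles` per base) then sequencing
#' (`seq_error_rate` per base) substitution errors, assigns each pair to
#' technical replicate A or B independently with probability
#' `replicate_split`, and writes four FASTQ files plus machine-readable
#' ground truth.
#'
#' Each amplicon is variant V region + junction + J segment + a fixed 60 b
#' IgG-like constant stub; read 1 is the first `read_length` bases, read 2
#' the reverse complement of the last `read_length` bases. Quality strings
#' are constant Q37.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param prefix File-name prefix (default `"sim"`).
#' @return Invisibly, a list with the four FASTQ `paths`
#'   (`r1_repA`, `r2_repA`, `r1_repB`, `r2_repB`), `truth_json`,
#'   `config_yaml`, and `truth`: the `sim_truth` augmented with
#'   `background` and realized per-template per-replicate read counts
#'   (`realized`).
#' @export
simulate_repertoire <- function(config, outdir, prefix = "sim") {
  validate_sim_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  ref <- read_germline_fasta(config$germline_ref)

  truth <- simulate_lineage(config, seed = NULL)  # uses current RNG stream
  bg <- .simulate_background(config, ref, truth$clone_cdr3)
  truth$background <- bg

  nv <- nrow(truth$variants)
  templates <- data.frame(
    template_id = c(truth$variants$variant_id, bg$clone_id),
    origin = c(rep("clone", nv), rep("background", nrow(bg))),
    allele = c(rep(truth$allele, nv), bg$allele),
    v_seq = c(truth$variants$v_seq, bg$v_seq),
    junction = c(rep(truth$junction, nv), bg$junction),
    cdr3 = c(rep(truth$clone_cdr3, nv), bg$cdr3),
    stringsAsFactors = FALSE)
  templates$amplicon <- paste0(templates$v_seq, templates$junction,
                               .sim_j_segment, .sim_constant_stub)
  p_clone <- config$dominant_clone_fraction
  if (nrow(bg) == 0L && p_clone < 1) {
    warning("no background clones configured; all reads drawn from the clone")
    p_clone <- 1
  }
  tw <- c(p_clone * truth$variants$weight,
          if (nrow(bg) > 0L) (1 - p_clone) * bg$weight else numeric(0))

  n <- config$total_read_pairs
  if (n == 0L) warning("total_read_pairs = 0: writing empty FASTQ files")
  tmpl <- if (n > 0L) sample.int(nrow(templates), n, replace = TRUE,
                                 prob = tw) else integer(0)
  repl <- if (n > 0L) ifelse(stats::runif(n) < config$replicate_split,
                             "A", "B") else character(0)

  amp <- .apply_errors(templates$amplicon[tmpl],
                       config$pcr_error_rate * config$pcr_cycles)
  rl <- config$read_length
  r1 <- .apply_errors(substr(amp, 1L, rl), config$seq_error_rate)
  r2 <- .apply_errors(.revcomp(substr(amp, nchar(amp) - rl + 1L, nchar(amp))),
                      config$seq_error_rate)
  ids <- sprintf("%s_%07d", prefix, seq_len(max(n, 0L)))

  paths <- list(
    r1_repA = file.path(outdir, paste0(prefix, "_repA_R1.fastq")),
    r2_repA = file.path(outdir, paste0(prefix, "_repA_R2.fastq")),
    r1_repB = file.path(outdir, paste0(prefix, "_repB_R1.fastq")),
    r2_repB = file.path(outdir, paste0(prefix, "_repB_R2.fastq")))
  qual <- strrep(rawToChar(as.raw(37L + 33L)), rl)
  for (rp in c("A", "B")) {
    sel <- which(repl == rp)
    for (mate in 1:2) {
      sq <- if (mate == 1L) r1[sel] else r2[sel]
      lines <- if (length(sel)) {
        as.vector(rbind(sprintf("@%s/%d", ids[sel], mate), sq, "+",
                        rep(qual, length(sel))))
      } else character(0)
      writeLines(lines, paths[[paste0("r", mate, "_rep", rp)]])
    }
  }

  realized <- data.frame(template_id = templates$template_id,
                         origin = templates$origin,
                         count_repA = tabulate(tmpl[repl == "A"],
                                               nrow(templates)),
                         count_repB = tabulate(tmpl[repl == "B"],
                                               nrow(templates)),
                         stringsAsFactors = FALSE)
  realized$count_total <- realized$count_repA + realized$count_repB
  truth$realized <- realized
  truth$templates <- templates

  truth_json <- file.path(outdir, paste0(prefix, "_truth.json"))
  jsonlite::write_json(
    list(allele = truth$allele, clone_cdr3 = truth$clone_cdr3,
         icv_planted_pct = truth$icv_planted_pct,
         dominant_clone_fraction = config$dominant_clone_fraction,
         variants = truth$variants, background = bg, realized = realized),
    truth_json, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  config_yaml <- file.path(outdir, paste0(prefix, "_config.yaml"))
  yaml::write_yaml(unclass(config), config_yaml)

  invisible(list(paths = paths, truth_json = truth_json,
                 config_yaml = config_yaml, truth = truth))
}
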