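# Fixtures are built in code; nothing is read from disk except the bundled
# germline FASTA.

# two short in-frame alleles (150 b, Cys codon at 0-based 120), >= 10
# substitutions apart, deterministic
tiny_ref <- function() {
  base <- paste0(
    "GAGGTGCAGCTGGTGGAGTCTGGGGGAGGCTTGGTACAGCCTGGCAGGTCCCTGAGACTC",
    "TCCTGTGCAGCCTCTGGATTCACCTTTGATGATTATGCCATGCACTGGGTCCGGCAAGCT",
    "TGTGCACGTGATTTTTGGAGTGGTTATTAT")
  stopifnot(nchar(base) == 150, substr(base, 121, 123) == "TGT")
  v <- strsplit(base, "")[[1]]
  swap <- c(3, 12, 24, 33, 45, 57, 66, 78, 90, 102, 111, 117)
  v[swap] <- chartr("ACGT", "GTAC", v[swap])
  germline_set(c("TINYV1*01", "TINYV2*01"), c(base, paste0(v, collapse = "")),
               c(120L, 120L))
}

# paired 250 b (or shorter) reads from an amplicon string, constant quality
make_pair <- function(amplicon, read_length = min(250L, nchar(amplicon)),
                      qual_char = "F", id = "p1") {
  n <- nchar(amplicon)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(amplicon, n - read_length + 1L, n))))
  data.frame(id = id, seq1 = substr(amplicon, 1L, read_length), seq2 = r2,
             qual1 = strrep(qual_char, read_length),
             qual2 = strrep(qual_char, read_length),
             stringsAsFactors = FALSE)
}

# random DNA string
rand_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# small, fast simulation configuration for desk-scale tests
fast_sim_config <- function(seed = 7L, ...) {
  args <- list(seed = seed, total_read_pairs = 1500L,
               n_background_clones = 10L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# minimal AIRR-like annotated data.frame for clonotyping tests
fake_annotated <- function(cdr3, replicate, v_call = "TINYV1*01",
                           v_proj = NULL, start = 0L, end = 10L) {
  n <- length(cdr3)
  if (is.null(v_proj)) v_proj <- rep(strrep("A", end[1] - start[1]), n)
  r <- function(x) rep(x, length.out = n)
  data.frame(read_id = sprintf("r%03d", seq_len(n)), v_call = r(v_call),
             aln_start_germ = r(start), aln_end_germ = r(end),
             homology_pct = r(95), cdr3 = cdr3, cdr3_aa = r(NA_character_),
             n_mutations = r(0L), mutations = r("[]"), v_proj = v_proj,
             unassignable = r(FALSE), gap_flag = r(FALSE),
             replicate = replicate, stringsAsFactors = FALSE)
}

# one small MM-like simulated sample shared across pipeline and acceptance
# tests; simulated and analyzed once per session, cached on disk in tempdir
mm_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- fast_sim_config(seed = 57L, total_read_pairs = 2500L)
      sim <- simulate_repertoire(cfg, file.path(tempdir(), "mmfix"))
      pc <- pipeline_config("mmfix", sim$paths$r1_repA, sim$paths$r2_repA,
                            sim$paths$r1_repB, sim$paths$r2_repB,
                            outdir = file.path(tempdir(), "mmfix", "run"))
      s <- suppressMessages(run_pipeline(pc))
      cache <<- list(cfg = cfg, sim = sim, pc = pc, summary = s)
    }
    cache
  }
})

# exhaustive least-squares topology oracle for small NJ trees: enumerates all
# unrooted binary topologies over the label set, fits branch lengths by
# unconstrained least squares on the path-indicator system, and returns the
# topology (as an ape tree) with minimal residual sum of squares
ls_topology_oracle <- function(dm) {
  labs <- rownames(dm)
  n <- length(labs)
  topos <- all_unrooted_topologies(labs)
  best <- NULL; best_ss <- Inf
  pairs <- t(utils::combn(n, 2))
  for (tp in topos) {
    tr <- ape::read.tree(text = tp)
    tr$edge.length <- rep(1, nrow(tr$edge))
    # indicator matrix: which edges lie on the path between each leaf pair
    X <- matrix(0, nrow(pairs), nrow(tr$edge))
    for (r in seq_len(nrow(pairs))) {
      path <- tree_path_edges(tr, match(labs[pairs[r, 1]], tr$tip.label),
                              match(labs[pairs[r, 2]], tr$tip.label))
      X[r, path] <- 1
    }
    y <- dm[pairs]
    fit <- stats::lm.fit(X, y)
    ss <- sum(fit$residuals^2)
    if (ss < best_ss - 1e-12) { best_ss <- ss; best <- tr }
  }
  list(tree = best, ss = best_ss)
}

# all unrooted binary topologies as Newick strings; closed-form enumeration
# for n = 3 (1 topology), n = 4 (3: the pairing of the four leaves) and
# n = 5 (15: two cherries plus a middle leaf)
all_unrooted_topologies <- function(labs) {
  n <- length(labs)
  if (n == 3) return(sprintf("(%s,%s,%s);", labs[1], labs[2], labs[3]))
  if (n == 4) {
    return(vapply(list(c(2, 3, 4), c(3, 2, 4), c(4, 2, 3)), function(p)
      sprintf("((%s,%s),%s,%s);", labs[1], labs[p[1]], labs[p[2]],
              labs[p[3]]), ""))
  }
  if (n == 5) {
    out <- character(0)
    for (mid in seq_len(5)) {
      rest <- setdiff(seq_len(5), mid)
      for (p in list(c(2, 3, 4), c(3, 2, 4), c(4, 2, 3))) {
        out <- c(out, sprintf("((%s,%s),(%s,%s),%s);",
                              labs[rest[1]], labs[rest[p[1]]],
                              labs[rest[p[2]]], labs[rest[p[3]]], labs[mid]))
      }
    }
    return(out)
  }
  stop("only n in 3..5 supported")
}

# edge indices on the path between two nodes of a phylo tree
tree_path_edges <- function(tr, a, b) {
  # parents via edge list; walk up from both nodes to the root of the
  # (arbitrarily rooted) edge structure
  parent <- integer(max(tr$edge))
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  anc <- function(x) { out <- x
    while (parent[x] != 0) { x <- parent[x]; out <- c(out, x) }
    out }
  pa <- anc(a); pb <- anc(b)
  common <- intersect(pa, pb)[1]
  nodes <- c(pa[seq_len(which(pa == common) - 1)],
             pb[seq_len(which(pb == common) - 1)])
  which(tr$edge[, 2] %in% nodes)
}
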