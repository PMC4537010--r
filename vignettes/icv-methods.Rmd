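---
title: "Quantifying intraclonal variation in IGHV deep-sequencing repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intraclonal variation in IGHV deep-sequencing repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icvseq)
```

## The problem

Immunoglobulin heavy-chain variable (*IGHV*) gene transcripts carry the
imprint of somatic hypermutation (SHM), the AID-driven point-mutation process
that acts on B cells in the germinal center. In a plasma-cell neoplasm such
as IgG multiple myeloma, all tumor cells descend from one B cell, so their
*IGHV* transcripts share one CDR3 junction — the clone-specific barcode laid
down at V(D)J recombination. Deep sequencing of IgG transcripts from sorted
plasma cells can therefore (i) detect a monoclonal expansion as a dominant
CDR3-identical clonotype, and (ii) reveal whether SHM was still active after
the clone was founded: if it was, the clonotype contains *subclonal sequence
variants* — full-length V-region sequences that share the clonal CDR3 but
differ in their mutation patterns. This **intraclonal variation (ICV)** is
the package's central quantity.

`icvseq` implements the full analysis as a tested pipeline: FLASH-style
read-pair merging, germline allele assignment, CDR3 extraction, CDR3-identity
clonotyping with technical-replicate concordance filtering, dominant-clone
calling, variant enumeration, ICV statistics, and neighbor-joining lineage
trees. A bundled simulator generates paired-end FASTQ with known clonal
architecture so every stage can be validated against ground truth.

## The ICV statistic

For a clonotype with total read count $N$ whose most abundant (rank-1,
"dominant") full-length variant has count $n_1$,

$$\mathrm{ICV} = 100 \times \left(1 - \frac{n_1}{N}\right)\ \%$$

rounded half-up to one decimal. It is the proportion of clonal reads carrying
variant subclonal sequences *over and above the dominant sequence*. The
reference point is deliberately the dominant variant, not a consensus:
a consensus would absorb high-frequency variant positions and understate the
subclonal mass. `variant_burden()` converts the percentage into cells given a
total tumor mass (IgG myeloma carries an estimated $0.5$–$3.1\times10^{12}$
tumor cells per patient; the default uses the lower bound).

Mutations observed across the top variants are partitioned by
`mutation_partition()` into **trunk** mutations — position+base substitutions
present in *every* top variant, acquired before the clone's last common
ancestor — and **ICV** mutations (everything else). The two sets are disjoint
and exhaustive by construction; a variant that reverts a trunk position
demotes that mutation to the ICV set.

## Pipeline stages and tunable parameters

**Merging** (`merge_pair`, `merge_pairs`). Mate 2 is reverse-complemented and
all overlaps of at least `min_overlap` (default 10 b) are scored; the overlap
minimizing mismatch density wins, ties going to the longer overlap, and pairs
with no overlap below `max_mismatch_density` (default 0.25) are rejected.
Within the overlap the higher-quality base is taken, ties to mate 1. These
defaults mirror the published FLASH defaults because the original protocol
does not print its parameters. **Length filter**: merged reads shorter than
`min_length` = 300 b are excluded; the boundary is read as *strictly less
than* (a 300 b read is retained). No mandatory quality filter is applied
beyond merging — the upstream protocol's "quality criteria" are not
specified, so an optional mean-quality threshold exists but defaults off.

**Germline assignment** (`assign_germline`). The published analysis used a
profile-HMM tool; this package substitutes a deterministic semi-global
(free-end-gap) alignment against every allele (match +2, mismatch −1, gap
open −6, gap extend −1), best score winning with lexicographic tie-break.
This is transparent, testable, and sufficient for clonotyping; it does not
reproduce HMM behavior on heavily indel-mutated reads (a documented
limitation — the variant model here is substitution-only). Reads under 50%
identity or under 100 aligned bases are flagged unassignable; more than
3 alignment gaps flags a likely artifact. **Percent homology** is computed
over the sequenced, aligned V portion only (not full germline length, and
excluding the CDR3 junction): indel columns count as non-identity.

**CDR3 extraction** (`extract_cdr3`). The CDR3 runs from the codon aligned to
the allele's annotated conserved cysteine through the first downstream
in-frame TGG-GG (Trp-Gly) J-anchor, both codons inclusive; absent if no
anchor lies within 120 b. Coordinates are 0-based half-open throughout.

**Clonotyping and concordance** (`group_by_cdr3`, `concordance_filter`).
Clonotypes are *exact* CDR3 nucleotide identity groups — no fuzzy clustering.
Each sample is sequenced as two technical replicates split from the same RNA;
a clonotype or variant is only analyzed if present in **both** replicates at
≥ `min_freq_each_replicate` (default 0.01%) with ≥ `min_count_each` reads
(default 2) in each. The original report gives the filter's purpose but not
its numbers; these defaults exclude exactly the singleton/one-replicate
artifacts the filter exists for, and both knobs are exposed. Frequencies are
recomputed over the retained reads, and replicate counts are summed for all
subsequent reporting.

**Dominant-clone calling** (`detect_dominant`). The top clonotype is called
dominant iff its frequency *strictly exceeds* `threshold_pct`. The default
5% is the published cut-off for clonal *IGHV* use by deep sequencing; because
oligoclonal expansions in normal bone-marrow plasma cells were observed to
reach 7.8%, a stricter `threshold_pct = 7.8` is recommended when calling IgG
myeloma clones, and both values are surfaced in the CLI help.

**Variant enumeration** (`enumerate_variants`). Variants are exact-identity
groups over the germline-projected V-region string, truncated to the interval
covered by *every* member, so differing read offsets cannot inflate the
variant count. Ranking is by descending total count with lexicographic
tie-break.

**Lineage trees** (`nj_tree`, `variant_tree`). Distances are Hamming counts
over the projected alignment; a Clustal-style multiple alignment is
unnecessary because the substitution-only model keeps all variants in one
germline frame (gap-free projection — a documented limitation for
indel-bearing data). Neighbor joining follows Saitou–Nei: join the pair
minimizing $Q(i,j) = (m-2)\,d(i,j) - R_i - R_j$, branch lengths
$l_i = d(i,j)/2 + (R_i - R_j)/(2(m-2))$, deterministic tie-break on the
smallest index pair, and negative branch lengths clamped to zero with the
remainder moved to the sibling edge so path lengths are preserved. Leaves are
labelled `rank<r>_<count>` so node numbers indicate the read count of each
variant. For additive matrices the algorithm is exact (path-length matrix
reproduced to 1e-9; verified in the test-suite against an
exhaustive-topology least-squares oracle and a reference implementation).

## What the simulator emulates — and what it does not

`simulate_repertoire()` writes four FASTQ files (two technical replicates ×
two mates) plus machine-readable ground truth. Its stated world:

- **Amplicons** span the V region (FR1 start through the conserved Cys),
  a random in-frame junction, a JH-like segment beginning with the TGG-GGC
  anchor, and a fixed 60 b IgG-like constant stub; total length falls in
  `amplicon_length_range` = 400–450 b, matching the size-selected library,
  and reads are 250 b paired-end, so every pair overlaps by ≥ 50 b.
- **The expansion clonotype** holds `dominant_clone_fraction` (default 0.8,
  the magnitude seen in presentation myeloma) of read pairs. Its founder
  carries `trunk_mutations` = 18 substitutions (germline homology ≈ 93.9%,
  inside the observed 89.3–94.6% range). Ongoing SHM is modelled as
  `n_subclone_generations` = 3 branching rounds in which each extant variant
  spawns one child with Poisson(2) additional substitutions — per-site
  draws weighted `hotspot_weight` = 3 at RGYW/WRCY motifs, never touching
  the CDR3, so the clonal barcode is invariant. Expected variant abundances
  follow stick-breaking in creation order (founder ≈ 50% of the clone),
  placing the planted ICV fraction near the 50% reported for two of the four
  myeloma cases. When a branch draws zero mutations its sequence duplicates
  the parent's; the planted ICV therefore references the most abundant
  *distinct sequence*, exactly as the estimator does.
- **The polyclonal background** holds `n_background_clones` = 50 clonotypes
  with Zipf(`background_abundance_shape` = 1.5) sizes, Poisson(18) SHM each,
  and private junctions/CDR3s.
- **Errors**: PCR at `pcr_error_rate` = 4.4e-7/bp/cycle (the published
  polymerase fidelity) × `pcr_cycles` = 30, then sequencing at
  `seq_error_rate` = 2e-4/bp — chosen once for consistency with the constant
  Q37 quality strings the generator writes ($10^{-3.7} \approx 2\times
  10^{-4}$), since no sequencing error rate is published.
- **Replicates**: each pair is assigned to replicate A with probability
  `replicate_split` = 0.5, independently — technical replicates share
  templates but not errors, which is what the concordance filter exploits.
- The bundled germline reference holds four **synthetic** IGHV-like alleles
  (~300 b, annotated conserved Cys codon, pairwise ≥ 16 substitutions
  apart); they are stand-ins so tests run offline, not database sequences.

Not modelled: indels, clonal selection/affinity maturation, class-switch
mechanics, chimeric (PCR-recombination) reads, position-dependent quality
decay, and read-depth heterogeneity between replicates beyond binomial
splitting. A green test on simulated data therefore establishes that the
pipeline recovers the parameters of *this* generative world — substitution
SHM with replicate-independent errors — not that it is robust to indel
artifacts or chimera-driven CDR3 collisions in real libraries.

## Numerical choices and degenerate inputs

- Reported percentages round half-up to one decimal (matching the printed
  values); base R's round-half-even is not used. A 12-significant-digit
  normalization guards exact decimal halves against binary representation.
- Merging: ties in mismatch density resolve to the longer overlap; consensus
  quality ties resolve to mate 1. Periodic amplicons are inherently
  ambiguous under any overlap merger.
- Alignment identity floors (<50% identity, <100 aligned bases) mark reads
  unassignable rather than erroring; terminal mismatches may be clipped by
  the free-end-gap alignment, which is correct semi-global behavior.
- Empty inputs: zero read pairs produce empty FASTQ with a warning; an empty
  post-filter read set yields a structured empty report; an empty technical
  replicate is a hard error because the concordance filter is undefined.
- NJ ties break on the smallest (row, column) pair; n < 3 returns a trivial
  tree with a warning; asymmetric or negative matrices are errors.

## Known limitations

- Substitution-only variant model: indel-bearing subclones would be flagged
  as gap artifacts rather than enumerated.
- D-segment and J-allele calling are out of scope; only the CDR3 string is
  used for clonotyping.
- Percent homology excludes the junction, so values are not directly
  comparable to tools that include it.
- The dominant-clone fraction is computed over concordance-retained,
  CDR3-bearing reads; pipelines that divide by all raw reads will report
  slightly lower fractions.
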