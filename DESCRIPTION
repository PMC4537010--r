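Package: icvseq
Title: Intraclonal Variation Analysis of IGHV Deep-Sequencing Repertoires
Version: 0.1.0
Authors@R:
    person("ICVseq", "Developers", email = "icvseq@example.org", role = c("aut", "cre"))
Description: A tested pipeline for detecting monoclonal B-cell expansions and
    quantifying intraclonal variation (ICV) in somatic hypermutation patterns
    from paired-end IGHV amplicon deep sequencing. Provides FLASH-style
    read-pair merging with length filtering, germline IGHV allele assignment by
    semi-global alignment, CDR3 junction extraction, clonotyping by identical
    CDR3 nucleotide sequence with technical-replicate concordance filtering,
    dominant-clone calling, subclonal variant enumeration, ICV fraction and
    tumor-burden statistics, and neighbor-joining lineage trees with read-count
    node labels. Ships a synthetic somatic-hypermutation lineage simulator that
    emits paired FASTQ technical replicates with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
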