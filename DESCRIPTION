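Package: nanostr
Title: Reference-Database-Free STR Genotyping from Nanopore Amplicon Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genotypes forensic autosomal short tandem repeat (STR) markers
    from noisy nanopore amplicon sequencing without an allele reference
    database. Spanning reads are extracted from an indexed BAM, repeat cores
    are trimmed by flank-anchored local alignment with affine gap penalties,
    trimmed fragments are clustered under a one-substitution tolerance to
    obtain supporting-read numbers (SN) and ratios (SNR), and each candidate
    allele's repeat structure is inferred by a recursive motif-decomposition
    search that minimises non-motif content, yielding CE-compatible allele
    designations. Quality-control rules flag low-coverage ("Interpretation")
    and ambiguous minor-allele ("Imbalance") results, and stutter artifacts
    are filtered. Includes threshold-sweep calibration, five-category
    concordance classification against a benchmark, identity likelihood
    ratios and trio/duo paternity indices from allele-frequency tables, and
    a deterministic nanopore-like read simulator (substitution/indel noise,
    homopolymer-biased errors, stutter) emitting SAM/FASTQ so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
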