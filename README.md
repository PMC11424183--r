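# nanostr

Reference-database-free genotyping of forensic short tandem repeat (STR)
markers from nanopore amplicon sequencing.

Nanopore reads are long enough to span an entire STR amplicon, but their
per-base error rate — especially around homopolymers — breaks the
naive approach of counting repeat units in individual reads, and
database-driven callers fail whenever a sample carries an allele the
database lacks. `nanostr` calls STR genotypes directly from aligned reads
and the locus definition (coordinates, flanking sequences, repeat motifs),
with no allele database:

1. **Spanning-read extraction** — primary alignments covering the repeat
   core ±3 bp are pulled from an indexed BAM
   (`extract_spanning_reads()`).
2. **Flank trimming** — the prefix/suffix flanks are located in each read
   by Smith–Waterman local alignment with affine gap penalties and the
   enclosed core is excised, keeping 3 extra flank bases per side
   (`trim_reads()`).
3. **Clustering** — trimmed cores that are identical or differ by a
   single substitution are grouped; a group's size is the supporting-read
   number SN, and SNR = SN / SN(major). The top three groups become
   candidate alleles (`cluster_fragments()`, `select_candidates()`).
4. **Repeat-structure inference** — each candidate sequence is
   decomposed into tandem motif runs and literal interrupts by a
   recursive branch-and-score search that minimises
   `score = non-motif bases + non-motif parts`; the allele designation is
   the CE-compatible `n.r` form computed from the core length
   (`infer_structure()`, `designate_allele()`).
5. **Genotype calling** — stutter artifacts (one repeat unit short, low
   SNR) are filtered and an SN/SNR decision ladder yields the call with a
   QC status: `Pass` (HOM/HET), `Interpretation` (major SN < 10,
   inadequate coverage) or `Imbalance` (minor allele with convincing SNR
   but insufficient SN) (`filter_stutter()`, `call_genotype()`).

Around the caller the package provides threshold calibration by sweeping
the SN × SNR grid against a truth set (`sweep_thresholds()`), five-category
concordance classification (`classify_concordance()`), identity likelihood
ratios and trio/duo paternity indices under Hardy–Weinberg
(`identity_lr()`, `paternity_index()`), and a deterministic nanopore-like
read simulator (substitutions, indels with homopolymer boost, stutter)
that emits SAM/FASTQ (`simulate_reads()`, `write_sam()`), so the whole
pipeline can be exercised without external data.

## Worked example

Simulate a two-locus toy panel at 400× with realistic noise (3 %
substitutions, 2 % indels, 10 % stutter), write the reads to BAM, and call
genotypes — the true genotype at both loci is 10/12:

```r
library(nanostr)

tp <- build_toy_panel(n_loci = 2, period = 4, seed = 7)
reads <- do.call(rbind, lapply(tp$panel, function(l) {
  r <- simulate_reads(l, sprintf("[%s]%d", l$motifs[1], c(10, 12)),
                      depth = 400, error_model(seed = 3),
                      reference = tp$reference)
  r$read_id <- paste0(l$name, "_", r$read_id)
  r
}))
write_sam(reads, tp$reference, "demo.sam")
bam <- sam_to_bam("demo.sam")

res <- genotype_str(bam, tp$panel, threshold_config(), sample = "demo")
res
#> <str_genotypes> sample 'demo', 2 loci
#>  locus    status allele1 allele2 sn1 sn2
#>   TL01 Imbalance
#>   TL02      Pass      10      12  40  26
```

TL02 is a confident heterozygote: its two clusters carry 40 and 26
error-free-core reads, the minor SNR (26/40 = 0.65) clears the 0.30
heterozygosity threshold and the minor SN clears the confident-allele
floor of 25. At TL01 the minor candidate's SNR is convincing but its SN
falls below 25, so the locus is flagged `Imbalance` rather than risking a
wrong call — the deliberate behaviour of the QC ladder at marginal
coverage. The inferred repeat structure of a call is kept alongside the
designation:

```r
res$TL02$calls[[2]]$structure
#> <repeat_structure> ATC_[TCGT]12_GGT  (len 54, score 8: 6 non-motif bases in 2 parts)
```

(The 3-base pads retained on each side of the core appear as terminal
interrupts and shift the motif phase — `TCGT` is a rotation of the true
`GTTC` unit; designations are length-based, so neither affects the call.)

A variant allele with interior interruptions illustrates structure
inference and `n.r` designation — a 98-nt period-4 core designates
24.2 (24 full units, 2 leftover bases):

```r
core <- expand_structure("[GGAA]2_GGAG_AA_[AAAG]16_[AGAA]1_AAAA_[GAAA]3")
st <- infer_structure(core, c("GGAA", "AAAG", "AGAA", "GAAA"))
st
#> <repeat_structure> [GGAA]2_GG_[AGAA]1_[AAAG]16_[AGAA]1_AAAA_[GAAA]3  (len 98, score 8: 6 non-motif bases in 2 parts)
designate_allele(st, locus, pads = c(0, 0))
#> [1] "24.2"
```

## Command line

A thin Rscript front end wraps the package functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "nanostr.R", package = "nanostr"))')
Rscript $CLI call --bam demo.bam --panel panel.tsv --thresholds thr.yaml --out report.tsv
Rscript $CLI simulate --panel panel.tsv --locus TL01 \
    --genotype "[GTTC]10/[GTTC]12" --depth 100 --seed 7 --out-prefix sim
Rscript $CLI sweep --panel panel.tsv --n-train 50 --depth 100 --seed 1 --out surface.tsv
Rscript $CLI concordance --report report.tsv --truth truth.tsv
Rscript $CLI kinship --child C1 --father F1 --mother M1 \
    --freqs freqs.tsv --profiles profiles.tsv
```

Panel files are TSV/JSON (locus, chrom, start/end with declared
coordinate system, period, comma-separated motifs, flanks, designation
offset); thresholds are YAML; reports, frequency tables and profiles are
TSV.

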