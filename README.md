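# ldcheck

Sample-swap detection for sequencing data using linkage-disequilibrium
blocks.

## The problem

In any pipeline that handles sequencing data from many donors — consortium
databases, clinical genomics, multiplexed experiments — datasets
occasionally end up attributed to the wrong donor. Every genome carries an
endogenous barcode: its genotypes at common SNPs. Two datasets from the same
donor must agree at those SNPs; two datasets from different donors must not.
The difficulty is that many dataset pairs barely overlap: a shallow ChIP-seq
experiment and an RNA-seq experiment may share almost no covered positions,
so methods that require reads from both inputs over the *same* SNP run out
of evidence.

`ldcheck` addresses this with **haplotype maps**: a genome-wide set of LD
blocks, each an *anchor* SNP plus member SNPs in strong mutual linkage
(member–anchor r² ≥ 0.85) while anchors of different blocks are approximately
independent (r² ≤ 0.10). Under the approximation that linkage within a block
is perfect, a read over *any* SNP of a block is evidence about the block's
diploid genotype — so two reads that never overlap each other can still
agree or disagree about the donor.

## The statistic

For each block *i*, reads give per-genotype likelihoods
p(x<sub>i</sub> | θ<sub>i</sub>), θ ∈ {AA, AB, BB}, via the base-error model
(an observed allele is wrong with its Phred error probability e; a
heterozygote emits either allele with probability ½). With Hardy–Weinberg
priors p(θ) from the anchor's minor-allele frequency, the genome-wide
log-odds that two datasets x and y share a donor is

```
LOD' = Σ_i max( log10 [ Σ_θ p(x_i|θ) p(y_i|θ) p(θ) /
                        (Σ_θ p(x_i|θ)p(θ) · Σ_φ p(y_i|φ)p(φ)) ] , σ )
```

with a per-block floor σ = −3 guarding against single-locus artifacts, plus
a constant log10 prior-odds shift (default prior odds 1). LOD ≥ 5 is called
a donor **match**, LOD ≤ −5 a **mismatch**, anything between
**inconclusive**. Filters: only non-secondary, non-duplicate reads with
MAPQ > 20; bases with quality ≥ 20 that match the site's two known alleles;
at most one observation per read-pair genome-wide, so block evidence stays
independent.

The package covers the full workflow:

* `build_map()` — construct a haplotype map from a phased panel: MAF ≥ 10%,
  per-population MAF spread ≤ 10%, anchor LD-pruning (r² ≤ 0.10, 10 kb
  windows), greedy member assignment (r² ≥ 0.85 within 10,000 kb) in
  descending LD-score order.
* `build_fingerprint()` / `fingerprint_to_vcf()` — per-block genotype
  likelihoods from SAM/BAM, persisted as VCF bound to the map by checksum.
* `total_lod()`, `classify()` — the capped LOD and the match decision.
* `screen()` — database-scale screening: per-donor representative triplets
  chosen by self-LOD with single-swap repair, swap flagging, true-donor
  nomination, duplicate-donor clustering; cost linear in database size.
* `contamination_profile()` — LOD versus mixture fraction.
* `simulate_panel()`, `sample_individual()`, `simulate_reads()`,
  `make_cohort()` — seeded synthetic worlds (block-LD panels, relatives,
  Poisson-coverage reads) that drive the entire test suite.

## Worked example

```r
library(ldcheck)

panel <- simulate_panel(population_model(n_blocks = 500, n_haplotypes = 400, seed = 7))
map <- build_map(panel)
map
#> haplotype_map: 1325 SNPs in 500 blocks (77 singletons, largest 5)
nrow(validate_map(map, panel))
#> [1] 0

alice <- sample_individual(panel, id = "alice", seed = 1)
bob   <- sample_individual(panel, id = "bob",   seed = 2)

# two shallow assays covering 40% of blocks each
chip <- assay_model(depth_lambda = 8, covered_blocks = 0.4)
fp_chip  <- build_fingerprint(simulate_reads(alice, map, chip, seed = 11), map, sample_id = "alice_chip")
fp_rna   <- build_fingerprint(simulate_reads(alice, map, chip, seed = 12), map, sample_id = "alice_rna")
fp_other <- build_fingerprint(simulate_reads(bob,   map, chip, seed = 13), map, sample_id = "bob_rna")

total_lod(fp_chip, fp_rna, map)
#> LOD(alice_chip, alice_rna) = 33.017 [MATCH], 83 informative blocks
total_lod(fp_chip, fp_other, map)
#> LOD(alice_chip, bob_rna) = -117.434 [MISMATCH], 79 informative blocks
```

Even though the two "assays" only jointly cover ~83 of 500 blocks, the
same-donor pair scores far above +5 and the different-donor pair far below
−5. Mismatch magnitudes are larger than match magnitudes: a single
confidently contradicted homozygote is strong evidence against a shared
donor, while agreement at a common genotype is individually weak evidence
for one (each positive block contributes at most
−log10 p(θ) ≤ 1.5·log10 2 ≈ 0.45 in expectation).

## Command line

```sh
Rscript -e 'quit(status = ldcheck::run_cli())' extract \
    --map map.tsv --input sample.bam --sample S1 --output S1.vcf
Rscript -e 'quit(status = ldcheck::run_cli())' crosscheck \
    --map map.tsv --left S1.vcf --right S2.vcf --output report.tsv
```

Subcommands: `crosscheck`, `extract`, `build-map`, `screen`, `simulate`,
`contam`. Exit codes: 0 success, 2 usage error, 3 input/contract error.

## Scope notes

The LOD is a quality-control score, not a calibrated likelihood ratio: the
model ignores contamination, relatedness structure, reference bias and the
incomplete dependence within/between blocks. Related individuals (siblings,
parent–child) score as mismatches — the tool answers "same donor?", not
"related?". See the methods vignette (`vignettes/ldcheck-methods.Rmd`) for
the model, the synthetic world, and design decisions.
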