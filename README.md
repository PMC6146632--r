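# MetaDigest

Downstream toolkit for hybrid-assembly metagenomics of anaerobic-digestion
(biogas) microbiomes. Upstream tools assemble reads, call genes and align
fragments; MetaDigest takes their outputs — contig FASTA, Prokka-style
GFF3, BLAST/DIAMOND tabular hits, read-count tables — and implements the
bespoke downstream stages:

* **Genomic-bin quality control** — profile completeness from a
  single-copy marker-gene panel (`100·|found|/|panel|`, canonical panel
  size 137) and retention filtering: keep bins with completeness ≥ 10 %
  that are supported by ≥ 2 of 4 metagenomic samples; discard contigs
  < 1000 bp as singletons.
* **Fragment-vote LCA taxonomic classification** — contigs are split into
  1000 bp fragments, each fragment's top-scoring hit casts one vote, the
  score of taxon *t* is `votes(t) / n_fragments`, and the bin is assigned
  to the lowest common ancestor of the top-scoring taxon set. Bins whose
  top taxa span Bacteria **and** Archaea are flagged *hybrid*.
* **Bacteria/Archaea annotation merging** — annotated archaeal CDS
  complement (and, at unannotated loci, replace) the bacterial gene
  calls, using a reciprocal >50 % same-strand overlap rule. A CDS is
  *annotated* when a gene name or EC number is known.
* **EC-module functional profiling** — genes are mapped (with wildcard
  expansion, e.g. proteases `3.4.-.-`) onto an EC reference sequence
  collection organized into metabolic modules of the anaerobic-digestion
  pathway; per-module abundance is computed as
  `log2(RPM + 1)` or `log2(mean RPKM + 1)`, with annotation/expression
  coverage per module and deterministic hierarchical clustering
  (Euclidean, average linkage) of samples and modules.
* **Synthetic communities** — `simulateCommunity()` generates taxonomy,
  bins, markers, hits, genes and two-condition metatranscriptomic counts
  with known ground truth, so every stage is testable without downloads.

Intended users: bioinformaticians analysing digester/biogas microbiomes
who already run an assembly + binning + annotation stack and need the
bin-filtering, conservative taxonomy and pathway-module profiling glue
around it.

## Worked example

```r
library(MetaDigest)

sim <- simulateCommunity(simulationConfig(seed = 42, nBins = 12, epsilon = 0.05))
res <- runCommunityPipeline(sim)

head(res$filter$retained, 3)
#>   bin_id completeness_pct support
#> 1 bin001             21.2       4
#> 2 bin002             92.0       4
#> 3 bin003             48.2       2

head(res$classification, 3)
#>   bin_id assigned_node    rank score_max hybrid_flag
#> 1 bin001         t0066 species 0.8666667       FALSE
#> 2 bin002         t0111 species 0.8795181       FALSE
#> 3 bin003         t0044 species 0.8958333       FALSE

evaluateRecovery(sim, res)[c("exact_accuracy", "completeness_rmse",
                             "effect_sign_accuracy")]
#> $exact_accuracy        [1] 1
#> $completeness_rmse     [1] 0
#> $effect_sign_accuracy  [1] 0.952381

sim$ersc
#> ERSC: 235 unique ECs in 52 metabolic modules; 449 reference sequences
#>   19 ECs without known sequence
```

`bin001` reaches 21.2 % completeness (29 of 137 markers) with all 4
samples mapping ≥ 50 % of its contigs, so it passes both retention
thresholds; its fragment votes are 87 % unanimous for species `t0066`,
so the LCA stays at species rank. With only 5 % wrong-phylum hit noise
every bin recovers its true species, completeness is recovered exactly
(RMSE 0), and the sign of the simulated module-level expression effects
is recovered for 20 of 21 affected modules.

The module × sample abundance matrix is a `SummarizedExperiment`
(`assay(res$abundance)`, log2 RPM); `clusterSamples()` orders it for
heatmaps and `writeDendrogram()` exports the trees as Newick.

## Command line

A thin Rscript entry point exposes the same functions:

```sh
Rscript inst/scripts/metadigest.R simulate --seed 21 --n-bins 8 --out demo/
Rscript inst/scripts/metadigest.R bins-qc --markers demo/marker_panel.txt \
    --marker-hits demo/marker_hits.tsv --mapping demo/contig_mapping.tsv \
    --bins demo/bin_membership.tsv --out qc.tsv
Rscript inst/scripts/metadigest.R classify --hits demo/hits.tsv \
    --bins demo/bin_membership.tsv --contigs demo/contig_lengths.tsv \
    --tax demo/taxonomy.tsv --out classified.tsv
Rscript inst/scripts/metadigest.R profile --counts demo/counts.tsv \
    --totals demo/totals.tsv --ersc demo/ersc_modules.tsv \
    --genes demo/genes.gff3 --out abundance.tsv
```

Exit codes: 0 success, 1 data error, 2 usage error. Options can come
from a YAML config (`--config`); flags win. Primary outputs carry a
provenance header (version, seed, config digest) and are byte-identical
across re-runs on identical inputs.

## Further reading

The methods vignette (`vignettes/metadigest-methods.Rmd`) documents the
model, every tunable parameter with its default and rationale, what the
synthetic generator does and does not emulate, numerical choices and
known limitations.
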