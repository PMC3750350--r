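# aflpscan

In silico AFLP digestion and the genomic distribution of restriction-site
markers relative to gene locations.

## The problem

AFLP markers (amplified fragment length polymorphisms) are anonymous
restriction-site markers: a genome is digested with a rare cutter and a
frequent cutter (classically *Eco*RI, site GAATTC, and *Mse*I, site TTAA),
fragments carrying one end of each kind are amplified, and those in the
40–440 nt window (72–472 nt after the standard adapters/primers add 32 nt)
are scored as bands on a gel. Before using such markers for genome scans,
QTL mapping or selection-signature studies, one wants to know *where they
fall*: how evenly they cover chromosomes, whether apparent pericentromeric
marker pile-ups are real or an artefact of repeated sequence collapsing
into single electrophoretic bands, and what fraction of markers lies within
or near genes — which depends strongly on the GC content of the enzymes'
recognition sites, because genic DNA is GC-richer than intergenic DNA.

`aflpscan` answers these questions for any annotated genome (FASTA + GFF3
or BED), and ships a synthetic genome generator so the whole pipeline is
testable without downloads.

## What it computes

* **Digestion** — complete double digestion with any enzyme pair (built-in
  catalogue: EcoRI/MseI, BsmI/TaqI, SacI/HpaII; arbitrary enzymes
  configurable), cut-site lists on both strands, AFLP-type fragments
  (one rare + one frequent end), inclusive size selection, optional
  selective-nucleotide filtering, and collapse of identical-sequence
  fragments into electrophoretic **bands**.
* **Marker-to-gene statistics** — for marker set *M* and gene set *G*:
  the cumulative percentages of markers within distance *d* of the nearest
  gene (*d* = 0 meaning ≥ 1 bp overlap), the percentage of genes with a
  marker within *d*, the random-placement expectation (the fraction of the
  sequenced genome covered by the union of genes), and the Poisson
  expectation 100(1 − e^(−λ)) with λ the observed mean number of
  overlapping fragments per gene; per-gene marker-count histograms; all of
  the above restricted to candidate-gene subsets.
* **Landscapes** — non-overlapping windows (default 200 kb) of fragment,
  band, gene and cut-site counts plus GC content, exported as TSV/bedGraph.
* **Cross-species density** — OLS regression of marker count on genome
  size (markers/Mb) and the markers-per-centimorgan conversion.
* **Synthetic genomes** — i.i.d. composition with distinct genic and
  intergenic GC, log-normal gene lengths, pericentromeric tandem repeat
  arrays whose unit yields one AFLP fragment per copy, planted cut-site
  cassettes for deterministic tests, and N runs; every planted quantity is
  returned as a truth record.

## Worked example

```r
library(aflpscan)

cfg   <- synthetic_genome_config(chrom_lengths = c(chr1 = 2000000L, chr2 = 1000000L))
world <- generate_genome(cfg, seed = 42)

pairs <- list(enzyme_pair("EcoRI", "MseI"),
              enzyme_pair("BsmI", "TaqI"),
              enzyme_pair("SacI", "HpaII"))
build_table1(world$genome, world$genes, pairs, label = "synthetic")
```

```
<species summary> synthetic
  genome 3.0 Mb (0.00% un-sequenced), 840 genes, gene length 2.1 (1.7) kb
  GC genic 0.393 / intergenic 0.313
  EcoRI/MseI: 1306 markers, mean spacing 2.3 kb
<distance summary> 1306 markers vs 840 genes
  % markers within:  0 kb=66.31  1 kb=91.35  10 kb=100
    expected at 0 kb (random placement): 60.11
  % genes with marker within:  0 kb=46.67  1 kb=69.76  10 kb=100
    expected at 0 kb (Poisson, lambda=1.032): 64.38
  BsmI/TaqI: 1370 markers, %markers at 0 kb = 72
  SacI/HpaII: 232 markers, %markers at 0 kb = 84
```

Reading this: 66% of EcoRI/MseI markers overlap a gene, *above* the 60%
expected for random placement, because genic GC (0.393) exceeds intergenic
GC (0.313); the GC-rich SacI/HpaII system pushes that to 84% at the cost of
far fewer markers. Only 47% of genes contain a marker, *below* the Poisson
expectation of 64%, because gene lengths are unequal (the long-gene classes
soak up extra markers). These are the directions expected for real
eukaryotic genomes.

Cross-species marker density:

```r
set.seed(42)
panel <- generate_species_panel(c(3003, 382, 230, 120, 119, 100, 23, 13, 12),
                                density_per_mb = 152, noise_frac = 0.02)
density_regression(panel)
#> <density regression> slope 156.3 markers/Mb, intercept -488.6, R^2 = 1.000 (n = 9)
markers_per_cM(1/7, 210)
#> [1] 30
```

## Command line

```sh
Rscript inst/scripts/aflpscan digest    --genome g.fa --pair EcoRI,MseI --out frags.tsv
Rscript inst/scripts/aflpscan landscape --genome g.fa --genes g.gff3 --pair EcoRI,MseI --out win.tsv
Rscript inst/scripts/aflpscan table1    --genome g.fa --genes g.gff3 --out table1.tsv
Rscript inst/scripts/aflpscan table2    --genome g.fa --genes g.gff3 --ids ids.txt --pair EcoRI,MseI --out table2.tsv
```

Exit codes: 0 success, 2 input error, 3 infeasible configuration.

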