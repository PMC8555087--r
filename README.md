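# apaSwitch

Detection of temperature-dependent alternative polyadenylation (APA)
switches from 3' end sequencing data, for transcriptomics researchers
working with QuantSeq-style libraries where each read's 3' end marks a
cleavage-and-polyadenylation site.

The package covers the full path from per-read cleavage positions to
classified APA switch genes:

1. **PAS calling** — greedy clustering of read 3' ends within ±25 nt
   (highest-support position seeds each cluster, ties to the 5'-most
   coordinate).
2. **Artifact filtering** — a site is dropped if its sense-strand
   context holds ≥ 7 consecutive `A` within offsets −30..+10 of the
   cleavage site (oligo-dT internal priming), or no polyadenylation
   signal hexamer (canonically `AATAAA`) within −30..0.
3. **Gene assignment** — annotated 3' ends are extended by
   `min(5000, ⌊d/2⌋)` nt towards the next downstream same-strand gene
   (distance `d`); PASs are ranked proximal → distal per gene, and
   genes with ≥ 2 PASs are APA genes.
4. **Differential usage** — per PAS, a negative-binomial Wald test of
   pooled low- vs high-temperature CPM counts:
   `log2FC = log2((mean CPM_low + 0.5)/(mean CPM_high + 0.5))`, with a
   moments dispersion pooled across PASs and Benjamini–Hochberg FDR.
5. **Switch classification** — per gene, tiered selection of the most
   divergent opposite-sign proximal/distal pair; the sign of
   `log2FC(proximal) − log2FC(distal)` labels the gene *repressed /
   class I* (distal PAS preferred at low temperature) or *enhanced /
   class II* (proximal preferred). Gene-level counts feed the
   CoolUp/CoolDown differential-expression calls (fold change ≥ 2,
   FDR < 0.01).

Two companion modules round the toolkit out: a seeded synthetic-data
generator with planted ground truth (genomes, annotations, true PASs,
internal-priming artifacts, usage switches, expression shifts) and a
flow-cytometry module quantifying enhancer-reporter activity as
`median(GFP | gate 2) − median(GFP | gate 3)` within the mRuby-negative
population.

## Worked example

```r
library(apaSwitch)

sim  <- simulateApaDataset(ApaSimConfig(nGenes = 60, seed = 11))
pe   <- buildCountMatrix(clusterEvents(sim$events, w = 25),
                         sim$sampleSheet)
filt <- filterPas(pe, sim$genome)
kept <- rankPas(assignPas(filt$kept, extendThreePrime(sim$annotation)))
res  <- nbTest(kept)
switches <- callApaSwitches(res, alpha = 0.05)
```

With this seed the run prints:

```
clusters: 185 | removed by filters: 60 | APA genes: 43
 I II
 7  4
   gene_id pair_delta     label apa_class            tier
1 gene0001   2.155982 repressed         I one_significant
2 gene0005   2.825281  enhanced        II one_significant
3 gene0007   2.445773 repressed         I one_significant
4 gene0023   2.222529 repressed         I one_significant
```

185 clusters were called from the simulated read 3' ends; the 60
planted internal-priming sites are exactly the clusters the sequence
filters removed. Of the 43 genes with ≥ 2 surviving PASs, 11 are called
as temperature-dependent switches: `pair_delta` is the fold-change
distance between the chosen proximal and distal PAS, and class I genes
shift usage towards the distal site at low temperature (class II the
reverse).

The same chain runs from a single YAML config via `runPipeline()` (or
`Rscript inst/scripts/apaswitch.R --config cfg.yaml --outdir out/`),
which writes every stage table plus a reproducibility manifest with
parameters, input checksums and per-stage record counts.

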