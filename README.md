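# hirumine

Homology mining and classification of leech antithrombotic gene families.

Medicinal leeches secrete a cocktail of salivary antithrombotic proteins —
hirudin (a direct thrombin inhibitor), antistasin and therostasin
(Factor Xa inhibitors), the hirustasin superfamily of antistasin-fold
serine-protease inhibitors, Kazal-domain inhibitors (bdellin, LDTI),
elastase inhibitors (HMEI), platelet-aggregation inhibitors (saratin,
apyrase, lumbrokinase), fibrinolysis enhancers (destabilase, GGT, LCI)
and hyaluronidase. Standard whole-genome annotation pipelines routinely
miss these small, fast-evolving, multi-copy genes. `hirumine` implements
the targeted alternative: mine a genome assembly directly with a curated
registry of 21 archetype proteins, reconstruct spliced gene models from
transcript evidence, merge them with an ab-initio prediction set, validate
the protein products, and aggregate a per-family catalogue — with a seeded
synthetic-genome generator providing planted ground truth so that every
stage is benchmarked end to end.

## The method

1. **Six-frame archetype scan.** Every genome sequence is translated in
   all six frames; exact 4-mer protein seeds shared with an archetype that
   co-occur on one (frame, diagonal) trigger a Smith–Waterman extension
   (BLOSUM62, affine gaps). Extension alignments are split into compact
   segments at long gap runs, and segments scoring ≥ 60 become candidate
   loci.
2. **Spliced gene-model reconstruction.** Candidate loci are clustered
   into gene regions; evidence CDSs of the matching family are aligned to
   the region by an est2genome-style dynamic program whose intron moves
   are admitted only at `GT..AG` termini at a fixed penalty. Regions left
   unexplained (e.g. pseudogenes, absent from transcript evidence) are
   rescued by spliced mapping of a back-translated archetype.
3. **Merging.** Evidence and ab-initio models are deduplicated by CDS
   footprint Jaccard (≥ 0.5 on the same strand); the evidence tier wins.
4. **Validation and classification.** Each retained model must overlap a
   confirming scan locus; its protein is assigned to the best archetype
   family by the similarity index

   `SI = 100 × (positively scoring BLOSUM62 pairs) / (alignment length − gap columns)`

   computed on a local alignment under EMBOSS `water` defaults (gap open
   10, extend 0.5), with an assignment threshold of SI ≥ 50. Pseudogenes
   are flagged from the spliced genomic CDS (internal stop, frameshift, or
   missing start codon). Cysteine scaffolds, internal tandem repeats
   (LDTI-, antistasin- and granulin-style 6/10/12-cysteine units) and a
   signal-peptide heuristic validate each protein. Neighbor-joining trees
   over similarity distances resolve subtypes within the hirustasin
   superfamily and predict hirudin activity clades.
5. **Catalogue.** Classified models are tabulated per family and source,
   with totals and function-category summaries; the published per-family
   count comparison table ships as a packaged fixture.

The packaged archetypes are deterministic **synthetic stand-ins** carrying
each family's documented length class, cysteine scaffold and repeat
structure (`inst/extdata/archetypes_synthetic.faa`); the published
accession identifiers are kept as registry metadata.

## Worked example

```r
library(hirumine)

local_align("HEAGAWGHEE", "PAWHEAE")
#> # protein alignment  score: 17.5  length: 5
#> # identical: 4  similar: 4  gap columns: 1
#> # similarity index: 100.00%
#> query       5 AWGHE
#>               || ||
#> subject     2 AW-HE

## a small synthetic study: 8 planted genes (2 pseudogenes), 3 decoys
cfg <- generator_config(genome_length = 120000L,
                        planted = c(hirudin = 3L, lumbrokinase = 2L,
                                    destabilase = 2L, saratin = 1L),
                        pseudogene_count = 2L, decoy_count = 3L, seed = 1L)
ds  <- generate_genome(cfg)
ann <- annotate_genome(ds$genome, ds$evidence, ds$abinitio, seed = 1L)
#> <antithrombotic_annotation> 8 gene model(s) (2 pseudogene), 3 dropped
#>  destabilase      hirudin lumbrokinase      saratin
#>            2            3            2            1

score_recovery(ann$models, ds$truth)[c("precision", "recall")]
#> precision 1.00  recall 1.00   (family accuracy 1.00, pseudogenes 2/2)

ann$features[["hirudin_g01"]]
#> <protein_features> family=hirudin
#>   signal peptide: cleavage at offset 19
#>   cysteines (mature): 6 (expected 6: conforms)
#>   tandem repeats: 0 unit(s)
```

The three dropped models are the decoy genes from the ab-initio set: they
never acquire a confirming homology locus, so the catalogue contains
exactly the planted genes — with the two degraded copies (a lumbrokinase
and a destabilase) flagged as pseudogenes, mirroring the two pseudogenes
of the real catalogue.

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/hirumine.R simulate --out sim/ --seed 1
Rscript inst/scripts/hirumine.R mine --genome sim/genome.fa \
    --evidence sim/evidence.fa --abinitio sim/abinitio.gff3 --out out/ --seed 1
```

## Scope notes

The generator emulates study *conditions*, not a real leech genome:
uniform background composition, uniform-codon reverse translation and
synthetic archetypes. Laboratory quantities (recombinant hirudin
activities in U/mg) are not computable; only the titration formula
`U = C1·V1 / (C2·V2)` is provided. See the methods vignette
(`vignettes/antithrombotic-mining.Rmd`) for models, assumptions,
parameter defaults and limitations.
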