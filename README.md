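# njatlas

Discovery of public, cancer-specific RNA splicing neojunctions and
HLA-presented neoantigen candidates.

## What this package is for

Aberrant splicing in tumours creates junctions that are absent from the
reference transcript annotation — *neojunctions* (NJs). Those that
recur across patients ("public", tumour-cohort positive sample rate
PSR ≥ 10%), are essentially absent from normal tissue
("cancer-specific", normal-cohort PSR < 1%), and are expressed across
a whole tumour rather than a subclone can encode shared, targetable
neoantigens. `njatlas` is for computational cancer immunologists and
transcriptomics analysts who want that whole chain as composable,
tested R functions:

* parse per-sample splice-junction tables (STAR `SJ.out.tab` dialect),
  classify non-annotated junctions (A3/A5 gain/loss, exon skip,
  in-exon, in-intron) and their frame effect against a GTF;
* apply the cohort gates (tumour purity ≥ 0.60; coding,
  non-mitochondrial transcripts with median TPM ≥ 10; per-sample
  count ≥ 10 / depth ≥ 20 / spliced frequency ≥ 1%) and call public,
  cancer-specific NJs;
* quantify intron retention (IR ratio, |ΔIR| ≥ 0.10, BH-adjusted
  P < 0.05, IR PSR rules);
* classify intratumoural conservation across multi-region biopsies
  (tumour-wide / >70% / >30–≤70% / ≤30% tiers, region-downsampling
  curves, paired primary–metastasis persistence);
* translate neojunctions in silico, tile 8–11-mer junction-spanning
  peptides with up to 30-residue flanks, drop proteome matches, and
  intersect top-percentile calls from two pluggable presentation
  scorers over five common HLA-A alleles.

A first-class synthetic-cohort generator (`sim_config()`,
`generate_reference()`, `plant_and_emit_cohort()`,
`generate_score_tables()`) plants neojunctions with machine-readable
ground truth, so the whole pipeline is testable offline.

## The statistics at the core

For junction *j* in sample *s* with target reads *t* and canonical
partner reads *c*: spliced frequency *f = t/(t+c)*; the sample
expresses *j* iff *t* ≥ 10, *t+c* ≥ 20 and *f* ≥ 0.01; PSR is the
expressing fraction of gated cohort samples; public ⇔ PSR_tumour
≥ 0.10; cancer-specific ⇔ PSR_normal < 0.01. The canonical partner is
the annotated intron sharing the NJ's donor site (then acceptor, then
containment). IR ratio = intronic/(intronic+spliced). Presentation
selection keeps tumour-specific peptides ranking in the top *q*
(default 1%) of *both* scorers for at least one allele. Full formulas,
threshold provenance and the declared tie-break/boundary choices are
in the vignette (`vignettes/neojunction-discovery.Rmd`).

## Worked example

```r
library(njatlas)

cfg <- sim_config(seed = 1, n_genes = 10, n_tumour_samples = 12,
                  n_normal_samples = 20, n_cases = 2, regions_per_case = 6)
ref <- generate_reference(cfg)
cohort <- plant_and_emit_cohort(cfg, ref)
res <- discover_neojunctions(cohort$junctions,
                             build_annotation_index(ref$transcripts),
                             cohort$samples, cohort$expression)
res$calls[1:5, c("key", "splice_type", "nt_delta", "frame_status",
                 "psr_tumour", "psr_normal", "public", "cancer_specific")]
#>                  key splice_type nt_delta frame_status psr_tumour psr_normal
#> 1   chr1:9773:9784:+     in_exon      -12     in_frame  0.9090909       0.05
#> 2   chr1:7453:8133:+   exon_skip      -57     in_frame  0.8181818       0.05
#> 3 chr1:16480:16713:+     A5_loss       -4   frameshift  0.5454545       0.00
#> 4   chr1:5995:6385:+     A5_gain        6     in_frame  0.5454545       0.00
#> 5 chr1:14844:15024:-     A3_gain        7   frameshift  0.3636364       0.05
#>   public cancer_specific
#> 1   TRUE           FALSE
#> 2   TRUE           FALSE
#> 3   TRUE            TRUE
#> 4   TRUE            TRUE
#> 5   TRUE           FALSE
```

Each row is one called neojunction: its intron coordinates, splice
type, signed nucleotide change, frame effect, the tumour/normal PSRs
and the resulting flags — e.g. row 3 is a donor-side exonic loss of 4
nt causing a frameshift, expressed by 55% of gated tumour samples and
no normal sample, hence public *and* cancer-specific.

Translating one in-frame acceptor-side loss of 6 nt and tiling
peptides:

```r
tx <- ref$transcripts[[1]]
pc <- plant_junction_coords(tx, "A3_loss", -6)
m <- build_mutant_transcript(tx, list(chrom = tx$chrom,
                                      intron_start = pc$intron_start,
                                      intron_end = pc$intron_end), ref$genome)
nchar(m$reference_protein) - nchar(m$mutant_protein)
#> [1] 2     # the 6-nt in-frame loss deletes exactly two amino acids
tiles <- filter_tumour_specific(tile_peptides(m), ref$proteome)
head(tiles[, c("sequence", "position", "length", "tumour_specific")])
#>   sequence position length tumour_specific
#> 1 CYGGKQED       64      8           FALSE
#> 2 YGGKQEDV       65      8            TRUE
#> 3 GGKQEDVY       66      8            TRUE
#> 4 GKQEDVYN       67      8            TRUE
#> 5 KQEDVYNC       68      8            TRUE
#> 6 QEDVYNCY       69      8            TRUE
```

The first tile ends at the last residue before the fusion point, so it
is pure reference sequence and the proteome filter correctly marks it
non-specific; the remaining tiles cross the novel fusion.

A thin command-line wrapper with `simulate` / `discover` / `ir` /
`ith` / `neoantigen` / `correlate` subcommands is installed at
`inst/scripts/njatlas.R`.

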