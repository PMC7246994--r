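# extdata

Small plain-text reference tables used by the arithmetic identity checks
(tests and `scripts/acceptance.R`):

* `species_pangenome_counts.tsv` — per-species core/shell/cloud/pan
  cluster counts from a published comparative study of 32 *Geobacillus* /
  *Parageobacillus* genomes (four species, eight genomes each, plus the
  combined 32-genome row). At n = 8 genomes the softcore tier collapses
  onto the core, so core + shell + cloud must equal pan exactly for the
  per-species rows.
* `category_fold_extension_counts.tsv` — published KEGG Brite / pathway
  category counts for the same dataset's pan, softcore and core genomes
  with their printed 1-decimal fold-extension ratios.
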