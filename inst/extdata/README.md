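# extdata

Mock annotation tables for the candidate-gene worked examples:

- `zhongmu4_mock_fragments.tsv` — published GWAS fragment coordinates on the
  *Medicago sativa* cv. Zhongmu-4 assembly (trait, fragment number,
  -log10 p, contig, 1-based inclusive interval).
- `zhongmu4_mock_genes.tsv` — coordinates of the gene models reported inside
  the ±50 kb windows of those fragments.

These are *mock* annotation inputs (a handful of printed coordinates, not
the real assembly or its GFF) used to exercise the window/gene-intersection
logic at desk scale.
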