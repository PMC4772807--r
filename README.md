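# npscan

Discovery and annotation of neuropeptide precursor proteins in de novo
transcriptome assemblies.

Secreted neuropeptides are produced from larger precursor proteins
(preproproteins) with a stereotyped architecture: an N-terminal **signal
peptide**, one or more bioactive peptide sequences flanked by basic
**prohormone-convertase cleavage sites** (dibasic KR/RR/KK/RK, tribasic runs,
or monobasic R with a basic residue 2/4/6 positions upstream), and commonly a
C-terminal glycine that is enzymatically converted to an **amide** on the
mature peptide. An N-terminal glutamine frequently cyclises to
**pyroglutamate** (pQ). npscan implements this processing grammar as a
reusable toolkit for invertebrate (especially echinoderm) neural
transcriptomes, where large neuropeptide repertoires — vasopressin/oxytocin-,
GnRH-, TRH-, CCK-, luqin-, kisspeptin-, tachykinin-type peptides,
SALMFamides, relaxin/insulin-like peptides and more — are routinely mined
from assembled contigs.

The toolkit covers:

- **ORF extraction** — six-frame translation, stop-to-stop segments,
  leftmost-longest start selection, optional edge-partial ORFs, forward-strand
  coordinate bookkeeping (`six_frame_orfs()`).
- **Signal peptides** — a deterministic rule-based heuristic (n-region
  charge ≥ 0, a ≥ 7-residue hydrophobic core with mean Kyte–Doolittle
  hydropathy ≥ 1.5, small residues at −3/−1), plus import of externally
  produced prediction tables which take precedence (`predict_signal()`,
  `import_signal_table()`).
- **Cleavage-site grammar** — mono-/di-/tribasic site detection with
  deterministic run splitting and segment excision that exactly tiles the
  precursor (`find_cleavage_sites()`, `segment_between_sites()`).
- **Peptide maturation** — single-glycine amidation, pyroglutamate
  flagging, cysteine/disulfide capacity, conditional tyrosine sulfation;
  structural detectors for the 14-cysteine neurophysin domain, acidic
  spacers and the insulin/relaxin B-chain | C-peptide | A-chain layout
  (`mature()`, `detect_neurophysin()`, `detect_insulin_architecture()`).
- **Family classification** — an extensible registry of anchored motifs
  (e.g. SALMFamide L-type `S/TxLxF/Y-NH2`, luqin `KFMRW-NH2`, GnRH-type
  `WxxG-NH2`, kisspeptin `NxxSxxLxF-NH2`, insulin A-chain
  `CCxxxCxxxxxxxxC`), multi-label by design (`classify()`,
  `registry_load()`).
- **Homology screening** — an exact affine-gap Smith–Waterman local
  aligner (BLOSUM62, gap open 11 / extend 1) over the translated ORF set,
  as a desk-scale stand-in for translated-BLAST searches (`smith_waterman()`,
  `screen()`).
- **Candidate ranking** — a transparent composite precursor-likeness
  score (signal, site count, amidation glycines, peptide coverage, copy
  number, acidic spacer, length penalty) with deterministic ranking
  (`score_precursor()`, `rank_candidates()`).
- **Synthetic fixtures** — a seeded generator that plants precursor genes
  with known ground truth inside decoy contigs, plus exact-match
  precision/recall evaluation (`synthetic_transcriptome()`,
  `evaluate_predictions()`).
- **Reporting** — legend-styled rendering (signal blue, peptides red,
  amidation glycines orange, cleavage sites green, neurophysin purple) in
  plain/ANSI/HTML, and TSV/FASTA/GFF3 export (`render_annotation()`,
  `export_tables()`, `write_gff3()`).

## Worked example

Generate a small synthetic transcriptome (four planted precursors modelled
on classic architectures, six decoys), run de novo discovery, and check the
result against the ground truth:

```r
library(npscan)

st  <- synthetic_transcriptome(seed = 42)
res <- discover(st$contigs)
res
#> Discovery result: 11 ORF(s) scanned, 4 candidate(s) ranked
#>  rank                    protein_id length signal_end n_sites n_peptides n_amide     score
#>     1     synthetic_multi_copy_orf1    112         23      11         12      12 46.505618
#>     2    synthetic_neurophysin_orf2    101         21       1          2       1  6.950000
#>     3 synthetic_insulin_layout_orf1     90         21       2          3       0  6.884058
#>     4  synthetic_acidic_spacer_orf1     75         20       1          2       0  6.427273

summary(res$annotations[[1]])
#> Precursor annotation: synthetic_multi_copy_orf1 (112 residues, denovo mode, score 46.51)
#> Signal peptide: residues 1-23 (score 6.06, heuristic)
#> Cleavage sites: 11; peptides: 12; features: 0
#>
#> Predicted mature peptides:
#>    1.   24-35   pQYPGGAPIGLD-NH2
#>    2.   38-42   pQWYT-NH2                       [TRH-type]
#>    ...
#>   12.  108-112  pQWYT-NH2                       [TRH-type]

evaluate_predictions(res, st)[, 1:6]
#>         tp n_pred n_truth precision recall f1
#> peptide 19     19      19         1      1  1
#> site    15     15      15         1      1  1
```

The top candidate is the planted multi-copy precursor: a 23-residue signal
peptide followed by one long peptide and eleven identical copies of a
glycine-extended tetrapeptide, each flanked by KR dibasic sites and maturing
to `pQWYT-NH2` (pyroglutamate + C-terminal amide). All planted peptides and
cleavage sites are recovered with exact coordinates (precision = recall = 1).

Single proteins can be annotated directly, e.g. the classic
vasopressin/oxytocin-type processing:

```r
p <- mature("CLVQDCPEGG")
peptide_notation(p)        # "CLVQDCPEG-NH2"
p$max_disulfides           # 1  (Cys at positions 1 and 6)
classify(p)                # "VP/OT-type"
```

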