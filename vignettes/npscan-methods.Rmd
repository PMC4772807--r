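---
title: "Methods: the precursor-processing model behind npscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the precursor-processing model behind npscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npscan)
```

# The biological model

npscan treats a neuropeptide precursor as a string generated by a small
grammar:

```
precursor := signal_peptide (segment basic_site)* segment
```

where `basic_site` is a mono-, di- or tribasic run of K/R recognised by
prohormone convertases, and each `segment` is either a candidate bioactive
peptide or a spacer. Two post-translational rules map excised segments to
mature peptides:

* **Amidation.** A segment ending in glycine donates exactly one G to
  peptidyl-glycine alpha-amidating monooxygenase, yielding a des-Gly
  peptide with a C-terminal amide. A segment ending `...GG` therefore
  matures to `...G-NH2` — consistent with the classic
  vasopressin/oxytocin-type example, where the nonapeptide retains an
  internal glycine after amidation.
* **Pyroglutamate.** A mature peptide starting with glutamine may cyclise
  to pyroglutamate. This is recorded as a flag; the sequence is unchanged
  (pQ is still written `Q` in the one-letter sequence).

Additional structure is detected on top of the grammar: a C-terminal
**neurophysin domain** is called when the region downstream of the last
cleavage site contains exactly 14 cysteines (the conserved neurophysin
complement); an **acidic spacer** when a segment has ≥ 6 D/E residues at
≥ 20 % of its length; and the **insulin/relaxin layout** when segments
matching the B-chain (`CxxxxxxxxxxxC`) and A-chain (`CCxxxCxxxxxxxxC`)
cysteine spacings bracket at least one connecting segment (the C-peptide).

Known observed forms anchor these rules: `QWYTG -> pQWYT-NH2`,
`NGFFYG -> NGFFY-NH2`, `CLVQDCPEGG -> CLVQDCPEG-NH2` (one disulfide-capable
Cys pair), `EEKTRFPKFMRWG -> EEKTRFPKFMRW-NH2`. One published GnRH-type
case reports an amidated mature peptide whose precursor peptide does not
carry a spare glycine beyond its final `...GPG`; under strict single-G
donation the written mature form and the precursor disagree by one residue.
npscan keeps the mechanistic rule and leaves such cases to curation rather
than special-casing the chemistry.

# Operating modes

Two modes reflect the two ways the toolkit is used:

* **de novo** (default): monobasic cleavage sites off, matured peptides
  shorter than 3 residues discarded (tetrapeptides such as TRH-type
  peptides are the shortest classes routinely reported; tripeptides are
  the floor). Maximises precision in blind scans.
* **curation**: monobasic sites on (a lone R with K/R at −2/−4/−6), no
  length floor. Maximises agreement with expert annotation of known
  precursors. Note that monobasic processing is precursor-specific in
  practice: for peptides that themselves contain internal basic residues
  (e.g. luqin-type `EEKTRFPKFMRW`), reproduction of expert annotation
  requires the dibasic-only dialect, which is why `annotate_protein()`
  accepts explicit `cleavage_rules()` independent of the mode.

# Parameter defaults and why

| parameter | default | rationale |
|---|---|---|
| ORF `min_len` | 60 residues | reported precursors run roughly 80–360 residues; 60 keeps partial/compact precursors while suppressing spurious short ORFs |
| signal window | cleave after residue 15–45 | secreted-precursor signal peptides cluster at 16–44 residues |
| h-region | ≥ 7 consecutive residues, mean Kyte–Doolittle ≥ 1.5 | the shortest functional hydrophobic cores; 1.5 separates L/I/V/F-rich cores from mixed sequence |
| −3/−1 set | A, G, S, C, T, V | the von Heijne small/neutral constraint on signal-peptidase positions |
| dibasic pairs | KR, RR, KK, RK | KR dominates curated annotations (`confidence = "canonical"`); the others are accepted consensus pairs (`"extended"`) |
| alignment | BLOSUM62, gap open 11, extend 1 | translated-BLAST defaults; raw-score screening with a permissive `min_score` replaces e-value statistics, mirroring recall-oriented homology screens |
| ranking weights | signal 3, site 1 (≤ 10), amide-G 1, coverage 2, extra copy 2, spacer 0.5, −0.01/residue > 500 | evidence-monotone: every hallmark adds score; the cap and length penalty bound pathological inputs |
| top_n | 500 | conventional size of a curation short-list |

The signal-peptide heuristic is a deterministic stand-in for dedicated
predictors, not a reimplementation of them: it captures the tripartite
n/h/c architecture at desk scale. Where exact published boundaries matter,
externally produced predictions are imported via `import_signal_table()`
and override the heuristic — that import path, not the heuristic, is the
supported route to reproducing curated boundaries. When several cleavage
positions satisfy all three rules with equal score (adjacent small residues
often create such ties), the smallest position is chosen, so the heuristic
is conservative about signal length.

# Numerical and tie-break choices

* Nucleotide coordinates are 0-based half-open internally; 1-based
  inclusive only at GFF3 emission. Residue-to-nucleotide projection is
  exact codon arithmetic on the forward strand for both orientations.
* Within a stop-to-stop segment the ORF starts at the first methionine
  (leftmost-longest); segments abutting the contig edge are reported from
  the segment start only when `allow_partial = TRUE`. Ambiguity code N
  translates to X; X never satisfies any motif. Other ambiguity codes are
  rejected at parse time with the offending line number.
* Runs of ≥ 4 basic residues split deterministically: leftmost three as a
  tribasic site, remainder re-examined under the same rules.
* The Smith–Waterman tie-break among co-optimal alignments is smallest
  target start, then smallest query start, then shortest alignment;
  traceback prefers diagonal over gap moves. A gap of length *k* costs
  `open + k * extend`.
* Family patterns are written in a small motif language (`x` any residue,
  `h` hydrophobic A/V/L/I/M/F/W/Y, bracketed classes) anchored at one
  terminus. Two families whose published signature is an internal cysteine
  spacing (insulin A/B chains) and the relaxin receptor-binding motif are
  expressed as bounded-offset anchored patterns (e.g. `^.{0,12}C.{11}C`),
  keeping the one-anchor rule without losing the internal motif.
* The tachykinin `x` is published as L/I only; the registry uses the wider
  hydrophobic class and marks the entry `extended`. Likewise the CCK-type
  octapeptide generalisation `[DQ]YGxGLF[WF]-NH2` is marked `extended`.
  Tyrosine sulfation candidates are flagged only on CCK-type-classified
  peptides unless requested globally.

# The synthetic generator: what it emulates and what it does not

`synthetic_transcriptome()` plants four default architectures, one per
structural detector: a multi-copy precursor (one long peptide + 11
identical glycine-extended copies), an amidated disulfide peptide followed
by a 14-cysteine neurophysin-like tail, an insulin/relaxin B|C|A layout,
and an acidic-spacer precursor. Signals are built to satisfy the heuristic
with a unique boundary (the n- and h-regions contain no small residues, so
no earlier cleavage candidate passes the −3/−1 rule); proteins are
reverse-translated with uniform synonymous codon choice and embedded in
random UTRs behind an in-frame upstream stop. Decoys are length-matched
random ORFs rejection-sampled to lack signal architecture and planted
peptide substrings; contigs are additionally rejection-sampled so no
incidental ORF presents a signal peptide. All randomness is a pure function
of the seed; regeneration is byte-identical.

Passing end-to-end tests on these fixtures therefore demonstrates that the
pipeline inverts its own generative grammar exactly — coordinates, sites,
maturation states and ranking — under clean conditions. It does **not**
demonstrate performance on real assemblies, which add fragmented and
chimeric contigs, non-canonical processing, signal peptides the heuristic
mis-scores, codon bias, and families defined only by homology. Those
effects are why the homology-screening and imported-signal paths exist.
One instructive artefact the fixtures do expose: reverse-strand ORFs of
cysteine-rich genes are arginine-rich (Cys codons reverse-complement to
Arg codons) and can accumulate spurious cleavage-site score; they lack a
signal peptide and are removed by the pipeline's signal gate, and the
planted-vs-decoy separation property is defined over the generated decoys,
not these incidental ORFs.

Problem sizes used in the validation suite — 1,000 aligner-oracle pairs at
lengths ≤ 8, 10,000 fuzzed proteins for the tiling invariant, 10,000 fuzzed
peptides for the classifier oracle, 20 generator seeds for end-to-end
recovery — were chosen as comfortably exhaustive for structures this small
while keeping the whole suite at desk scale.

# Known limitations

* The signal heuristic has no cleavage-site probability model; boundaries
  within a run of small residues resolve to the earliest candidate.
* E-value statistics are deliberately absent; `screen()` thresholds raw
  scores. Results are comparable within a matrix/penalty setting only.
* Disulfide *connectivity* is not predicted, only capacity
  (`floor(nCys / 2)`).
* Families without a sequence motif (PDF-, CRH-, orexin-, MCH-,
  somatostatin-type, glycoprotein-hormone dimers) are reachable only via
  homology screening with user-supplied queries; somatostatin/MCH-type
  structural hints (a Cys pair at the precursor C-terminus) are noted in
  classification docs but not auto-assigned.
* Assembly-scale inventories (hundreds of thousands of contigs, HMM-based
  candidate lists) are out of scope; the composite score is a documented,
  configurable surrogate for trained precursor models, calibrated only by
  the fixture separation property.

# Reproducibility

`scripts/acceptance.R --seed S --out results/acceptance.json` recomputes
every quantity above from scratch: worked maturation/classification
examples, the aligner-vs-oracle agreement rate, the tiling rate, the
classifier agreement rate, mean peptide-level F1 across 20 fixture seeds
derived from `S`, the ranking separation rate, and the multi-copy
reconstruction counts. The testthat suite runs the same checks plus
module-level oracles (brute-force six-frame enumeration, Biostrings
`pairwiseAlignment` cross-checks, dot-product score oracle, render/parse
round-trips).
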