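---
title: "Methods: genome plasticity analysis and rhodopsin screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome plasticity analysis and rhodopsin screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genoplast)
```

`genoplast` implements a desk-scale pipeline for comparing pairs of closely
related bacterial genomes — motivated by highly plastic genomes such as the
polar sea-ice *Octadecabacter* species — together with seeded synthetic-data
generators so that every stage can be exercised and validated offline. This
vignette documents the model behind each stage, the parameters and their
defaults, and the numerical and design decisions a reader needs in order to
interpret (or distrust) the results.

## 1. Genome data model and GenBank I/O

A genome is an `annotated_genome`: an ordered list of `replicon`s
(chromosome or plasmid, linear or circular), each carrying a nucleotide
sequence and a list of `feature`s (`CDS`, `pseudogene`, `rRNA`, `tRNA`)
with 0-based half-open coordinates and strand. `read_genbank()` /
`write_genbank()` round-trip a minimal GenBank flat-file dialect
(LOCUS/DEFINITION/SOURCE, FEATURES with location, `/locus_tag`,
`/product`, `/translation`, `/pseudo`, ORIGIN). The parser is deliberately
small and hand-written: it accepts only the constructs the package emits
plus common variants (`complement(..)`, multi-line qualifiers) and errors
on anything else rather than guessing.

`extract_proteome()` translates all non-pseudo CDS features (bacterial
code; a supplied `/translation` wins over re-translation). A CDS whose
translation contains an internal stop is *skipped with a warning* — it is
treated as an annotation error, not silently truncated. Pseudogenes are
excluded from the proteome by definition and handled separately by the TE
census (section 5). `summarize_genome()` produces the per-genome summary
row (GC %, Mb, CDS/pseudogene/RNA counts, TE genes and TE genes per Mb).

GC content is `100 * (G+C) / (A+C+G+T)`; ambiguous bases are excluded
from the denominator rather than counted as AT.

## 2. Pairwise alignment engine

The engine (`global_align()`, `local_align()`, C++ core) is a
Needleman–Wunsch / Smith–Waterman implementation with affine gaps (Gotoh
three-state recurrence). Conventions, all of which are pinned by tests:

* **Scoring**: BLOSUM62 with gap open 11 / extend 1 for proteins;
  +1/−2 with gap open 5 / extend 2 for nucleotides
  (`scoring_scheme("protein")`, `scoring_scheme("nucleotide")`). A gap of
  length $L$ costs $open + L \cdot extend$.
* **Traceback tie-breaking** is fixed: diagonal over up (gap in query)
  over left, so the reported alignment is deterministic.
* **Identity denominator**: identity is *identities / all alignment
  columns including gap columns*. For global alignments of unequal
  lengths this is strictly harsher than identities/matched-columns; it is
  the convention used throughout (ortholog filtering, ANIb, synthetic
  truth tables), so thresholds like 30 %/60 % are comparable across
  modules.
* **Significance**: `evalue_surrogate()` computes the Karlin–Altschul
  form $E = K m n e^{-\lambda S}$ with published gapped parameters
  (BLOSUM62 11/1: $\lambda = 0.267$, $K = 0.041$; nucleotide +1/−2 5/2:
  $\lambda = 1.28$, $K = 0.46$). This is a calibrated surrogate, not a
  fitted statistic: tests and downstream thresholds rely on its ordering
  and cutoff behaviour, not on exact agreement with any external tool.

A batch score-only Smith–Waterman kernel (`sw_score_batch()`) processes
16 queries per pass in 16-bit lanes; it exists purely for throughput (the
metagenome screen aligns hundreds of thousands of translated frames) and
is tested for exact equality against the scalar kernel.

```{r align-example}
al <- global_align("HEAGAWGHEE", "PAWHEAE", scoring_scheme("protein"))
al$score
al$identity_fraction
```

## 3. Orthology, pan-genome and MLSA

`bbh_orthologs()` implements the bidirectional best-hit criterion: a pair
is kept iff each protein is the other's best local-alignment hit with
E-value strictly below `evalue_cutoff` (default `1e-10`), then a global
Needleman–Wunsch identity filter removes pairs below `identity_cutoff`
(default 30 %) — this catches best hits driven by a short conserved
domain — and pairs at or above `high_identity_cutoff` (60 %) are flagged
`high_confidence`. Best-hit ties are broken by global identity, then
lexicographic subject id, keeping the whole pipeline deterministic.

`pan_genome()` partitions gene complements into *shared* (in all
genomes), *exclusive-to-pair*, and *unique* classes from the pairwise
ortholog tables. `single_copy_markers()` selects shared genes with no
within-genome paralog (no second self-hit above the ortholog thresholds)
as MLSA markers; `mlsa_concat()` aligns each marker family with a
center-star progressive alignment (center = sequence minimizing summed
distance), concatenates, and removes every column containing a gap, so
the distance matrix is computed on unambiguous columns only.
`p_distance()` + `nj_tree()` (neighbor joining via `ape`) give the tree;
labels are sorted before tree construction so output is
topology-deterministic.

## 4. Windowed GC profiles and regions of enhanced genome plasticity

`gc_deviation_profile()` slides a `window` (default 5 kb) in `step`s
(1 kb) and standardizes each window's GC against the whole-replicon mean.
The scale is the **binomial sampling deviation**
$\sqrt{\mu(1-\mu)/\text{window}}$, *not* the empirical SD of the window
GC values. This is deliberate: a genome with a large compositionally
deviant island has a broadened, bimodal window-GC distribution, so
standardizing by the empirical SD lets islands mask themselves (in
testing, a 50 kb planted island dragged its own $|z|$ down to the flag
threshold). The binomial scale depends only on the genome mean and the
window size.

`call_rgp()` calls regions of enhanced genome plasticity (RGPs, the
genomic-island analogue) from three indicators per window:

1. **Atypical GC**: $|z| \ge$ `gc_z` (default 1.5);
2. **Ortholog poverty**: at least `poverty_frac` (60 %) of the window's
   genes lack an ortholog in every supplied close-relative table;
3. **TE clustering**: at least `te_min` (3) TE-classified genes in the
   window.

Windows reaching `min_indicators` (default 2 of 3) are merged when closer
than `merge_gap` (5 kb), regions shorter than `min_length` (10 kb) are
dropped, and ids are assigned in coordinate order. Plasmids are emitted
whole as RGPs regardless of signals, reflecting their wholesale
mobility.

## 5. TE census

`classify_te()` assigns a protein to an insertion-sequence family by its
best local hit against a labelled reference library (`te_library()`),
requiring identity ≥ 0.30 and **query** coverage ≥ 0.50. Coverage is
measured on the classified protein, a package choice: pseudogene
fragments (classified via their longest ORF across six frames) would
rarely cover a full-length reference transposase, but a fragment that is
half transposase should still count. `te_census()` tabulates per-family
gene and pseudogene counts and the TE density in TE genes per Mb
(pseudogenes excluded from density, included in the tables).

## 6. Synteny anchors, inversions and ANIb

`find_anchors()` computes maximal unique matches (MUMs): exact matches,
maximal in length, occurring exactly once in each genome, on either
strand (a match and its reverse complement count as the same string; a
sequence present forward in A and reverse in B is still repeated).
Multi-replicon genomes are concatenated with `N` spacers so anchors never
bridge replicons. A post-filter (`filter_repeat_anchors()`) trims 10 bp
from each anchor end and re-checks uniqueness of the core: this removes
"technically unique" anchors made of a repeat copy plus a few chance
flanking bases, the classic failure mode of repeat-rich genomes, without
which identical IS copies spawn spurious rearrangement blocks.
`chain_blocks()` chains co-linear anchors on the same diagonal trend
(gap ≤ `max_gap`, default 10 kb) into blocks labelled `forward` or
`reverse`; planted inversions are recovered as exactly that many reverse
blocks in the controlled-recovery tests.

`anib()` implements fragment-based average nucleotide identity: genome A
is cut into 1,020 bp fragments, each fragment is located in B by exact
15-mer seeding and aligned locally within a bounded window; fragments
with ≥ 30 % identity over ≥ 70 % of their length are accepted and
averaged; the comparison is run in both directions and the two values
averaged. Fewer than 20 % accepted fragments in either direction marks
the pair `not comparable` (unrelated genomes yield `NA`, not a misleading
number). Identity here uses the same all-columns denominator as
everywhere else. Note the seeding: the alignment engine itself is
heuristic-free, but ANIb *localizes* fragments with the package's own
anchoring machinery before aligning — exhaustive local alignment of every
fragment against a whole genome would add nothing but runtime.

## 7. Two-stage metagenome rhodopsin screen

`run_screen()` reproduces a two-stage homology screen against a labelled
rhodopsin reference set (`rhodopsin_refs()`, ≥ 2 members per main group):

* **Stage 1** (`stage1_screen()`): six-frame translation of every read,
  batch Smith–Waterman against the concatenated references, candidates
  kept at E ≤ 1 (deliberately permissive). Samples with ≤ 100,000 reads
  are **refused**, not silently processed: per-mille abundances from
  small surveys are noise.
* **Stage 2** (`stage2_validate()`): candidates re-aligned per reference;
  the E-value cutoff is a step function of the sample's mean read length
  — `1e-20` if mean > 150 bp, else `1e-10` (short reads cannot reach
  extreme E-values, so a fixed strict cutoff would discard true
  positives). A hit must additionally cover **≥ 60 % of the reference OR
  ≥ 80 % of the query** (disjunction, both boundaries inclusive).

`classify_hits()` normalizes counts per mille of *total* sample reads and
reports the xanthorhodopsin subgroup II share. `assign_subgroup()`
assigns I/II by nearest reference identity with a margin; a nearest
identity below 0.30 (the ortholog floor) yields `unassigned` — the
margin rule alone would force every random protein into some subgroup.
`binding_site_profile()` checks the keto-carotenoid binding pocket
positions against a subgroup-I reference: a small residue (G/A/S/C) at
the Gly156-equivalent position leaves antenna binding `possible`; bulky
tryptophan — the subgroup II hallmark — marks it `abolished`.

## 8. Synthetic data generators

`simulate_genome_pair()` builds an annotated genome pair with a truth
table: core genes planted at controlled protein identity (mutation at
codon level so identity-1 genes keep their exact nucleotide sequence),
identical IS copies from `simulate_te_library()` spliced into both
genomes, optional GC-shifted islands (AT-rich synonymous codon choice,
foreign genes, interiors carrying *tandem* IS pairs so islands genuinely
contain TE clusters), TE-anchored inversions in genome B (each inverted
segment must contain a non-TE gene, so an inversion is never just a
repeat flip), and optional pseudogenization. `mutate_to_identity()`
targets a global identity and records the realized value in the truth
table; tests assert realized ≈ target within 0.02–0.03.

`simulate_metagenome()` plants labelled rhodopsin gene fragments into a
random-read background under two regimes: `"454"` draws right-skewed
lengths with most mass at 100–150 bp (mean ≈ 120 bp — the regime is
designed to land on the short-read side of the screen's 150 bp rule) and
`"sanger"` draws 700–1,000 bp reads. Truth tables map planted read ids to
group/subgroup. Both generators are byte-deterministic per seed: the RNG
state is saved and restored around every seeded call, so generation order
does not leak between calls.

**Scope and limits.** The generators make no attempt at realistic
sequencing error, quality values, codon usage, or phylogenetic structure
beyond the planted parameters; they exist to make recovery properties
testable (planted identity classes, inversion counts, island boundaries,
group shares), not to imitate real data. Genome sizes in tests
(150–200 genes, ~0.2 Mb) and oracle case counts (300 brute-force
alignment cases at length ≤ 8; 20 kb anchor-oracle pairs) are the
package's own choices, sized so the full validation suite runs in
minutes on one CPU while exercising every code path at a scale where
independent oracles are still affordable.

## 9. Determinism

Every analysis function is deterministic given its inputs (fixed
tie-breaks, sorted iteration orders); every generator is deterministic
given its seed. The only nondeterminism in the package is the user's own
R session RNG, which the generators protect by save/restore.
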