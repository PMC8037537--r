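---
title: "Methods: SOM-based miRNA target prediction and ceRNA network construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SOM-based miRNA target prediction and ceRNA network construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernaweaver)
```

`cernaweaver` implements a ceRNA (competing endogenous RNA) analysis of a
transcriptome in which microRNAs, their mRNA targets and pseudogenes form a
regulatory network: pseudogenes retain the miRNA response elements (MREs) of
their parent genes and can titrate miRNAs away from coding transcripts. This
vignette documents the models behind each stage, the parameters that matter,
the numerical conventions, and what the synthetic benchmark does and does not
establish.

## Sequence conventions

All sequences live on the RNA alphabet (ACGU); DNA-convention input (T) is
mapped to U on read. Coordinates are 1-based, fully closed intervals
throughout — annotations, truth tables, motif hits and predicted sites alike.
The seed of a mature miRNA is defined as nucleotides 2–8 (7 nt). The
literature variously describes seeds as 6 or 7 nt; we adopt 2–8 because the
checkable let-7 example works out under it: positions 2–8 of
`UGAGGUAGUAGGUUGUAUAGUU` give the canonical family seed `GAGGUAG`.

## The target predictor

The predictor runs in four stages.

**1. Seed clustering on a self-organizing map.** Seeds are one-hot encoded
(4 slots per position, 28 dimensions), which makes Euclidean distance an
isometry of Hamming distance (`d = sqrt(2·H)`). A rectangular lattice of
neurons — default side `ceiling(sqrt(5·sqrt(n)))`, the usual SOM sizing
heuristic — is trained for 100 epochs by *batch* competitive learning:
each epoch assigns every seed to its best-matching unit (BMU), then moves
each neuron toward the Gaussian-neighborhood-weighted mean of its inputs.
Learning rate (0.5 → 0.01) and neighborhood radius (`max(rows, cols)/2` →
0.5) decay linearly. Batch mode was chosen deliberately: it makes the result
independent of input order, so only the weight-initialization seed matters
for reproducibility. BMU distance ties break to the lowest row-major neuron
index.

**2. Fragment projection.** A 7-nt window slides with stride 1 over the
searchable region of each target — the annotated 3′UTR for protein-coding
transcripts (MREs are a 3′UTR phenomenon), the full sequence for pseudogenes,
which carry no UTR annotation. Each window is reverse-complemented, encoded
and assigned a BMU; the window is a candidate site for every catalogued miRNA
whose seed shares that BMU. "Shares the BMU" is the strictest reading of
cluster compatibility; a `neighborhood` radius is exposed for a looser one.
A window that exactly complements a catalogued seed encodes to that seed's
own vector, so exact seed matches can never be missed (a property the test
suite checks against an exhaustive substring scan).

**3. Tail dissimilarity.** Antiparallel duplex geometry places tail pairing
(mature positions 9 to the end) immediately 5′ of the seed-complement window
on the target. The site extension is therefore taken 5′-ward, `|tail| +
max_bulge` nt long, and the dissimilarity is the minimum unit-cost edit
alignment of the tail against the reverse complement of that extension, with
at most `max_bulge` (default 4) total gap nucleotides modeling bulges on
either strand, normalized by tail length and clipped to [0, 1]. Candidates
with `d ≤ τ` survive; τ defaults to 0.3, i.e. at least ~70% of the tail must
pair, matching the tail complementarity the synthetic generator plants. An
empty tail has `d = 0` by convention.

**4. Free-energy filter.** The duplex free energy of the full mature against
the site plus its 5′ context is computed by dynamic programming under a
nearest-neighbor model: initiation (+4.09 kcal/mol) plus stack energies over
contiguous base pairs (Watson–Crick and GU wobble) plus a loop/bulge penalty
of +3.0 kcal/mol per event and +0.5 per extra unpaired nucleotide, with at
most 8 unpaired nucleotides per strand between consecutive pairs. The
Watson–Crick stack energies follow the Turner-style unified values;
GU-containing stacks are simplified to a uniform −0.5 kcal/mol so that every
stack is stabilizing. All parameters live in one editable file
(`inst/extdata/stack_energies.tsv`), so the semantics of the retention rule —
**ΔG < −12 kcal/mol**, strict — are transparent. With this table, a perfect
7-bp seed helix alone reaches only about −9 kcal/mol on average; clearing the
−12 cut requires genuine tail pairing, which is what separates planted sites
from background seed matches. The DP is verified in the tests against
exhaustive enumeration of all co-linear pairings on short duplexes, and the
filter's monotonicity (tightening the cut never adds interactions) is a
tested invariant.

Open choices the method leaves unspecified — the dissimilarity threshold, the
extension length, the lattice dimensions, whether ΔG covers seed and tail
jointly (here: yes, the full mature) — are exposed as arguments with the
defaults above.

## The synthetic benchmark

`gen_transcriptome()` emits the study conditions the analysis assumes:

* mRNAs with a coding region (200–400 nt) and an annotated 3′UTR (150–300
  nt); background sequence i.i.d. uniform over ACGU (the true UTR base
  composition of *C. robusta* is not documented; a composition vector is
  configurable).
* One planted MRE per 3′UTR (configurable count or distribution): a perfect
  7-nt seed complement preceded 5′-ward by the reverse complement of the
  miRNA tail at 70% complementarity. The mismatching tail positions are
  placed at the seed-distal end by default, emulating canonical seed pairing
  with 3′-supplementary pairing that decays with distance; random placement
  is available. Background occurrences of a planting miRNA's seed complement
  and of planted element patterns are scrubbed from the same UTR, so truth
  tables are exhaustive.
* Planted cis-elements drawn from the motif table (hairpin elements get a
  complementary stem), at non-overlapping positions.
* Hairpin precursors: mature + loop (15 nt) + near-reverse-complement arm
  with 1–3 substitutions, 59 nt at the defaults, inside the 59–77 nt band of
  catalogued precursors.
* Pseudogenes as substitution-only mutated copies of parent mRNAs with target
  identity uniform in [0.94, 1.00]; the realized identity is exactly
  `round(len·identity)/len` and is recorded in the truth table.

What passing the benchmark shows: every stage recovers exactly what was
planted, the filters behave monotonically, and the statistics control error
under the stated null. What it does not show: performance on real
transcriptomes, where UTR composition is biased, sites are imperfect and
overlapping, expression is unobserved, and pseudogene/parent relationships
involve indels — none of which the generator emulates. Reference problem
sizes used by the tests and the acceptance script: 100 mRNAs × 20 miRNAs with
one site per UTR (target prediction), 100 UTRs × 7 element classes
(scanning), 20 precursors (annotation), 1,000 replicates on a 200-gene
population (enrichment null).

## Statistical conventions

Enrichment is one-sided (enrichment only, the DAVID convention): `p_fisher`
is the hypergeometric upper tail `P(X ≥ k)`; the EASE score recomputes the
tail at `k − 1` (defined as 1 for `k ≤ 1`), which is always ≥ the Fisher
p-value and discounts single-gene overlaps; Benjamini–Hochberg is the
standard step-up. Rows are filtered at `p < 0.05` AND `Benjamini < 0.05` AND
`EASE ≤ 0.1`. The background defaults to all protein-coding transcripts of
the annotation. Two parallel enrichment routes (Fisher-style and EASE-style)
exist in common practice without a stated winner; both statistics are always
reported and all three gates apply.

Precursor annotation reports two gates for the same reason: the conventional
Blast significance threshold `E < 10⁻⁵` accepts by default, and the looser
`E < 0.05 AND S > 100` gate is carried as a labelled column. λ = 0.625 and
K = 0.41 are ungapped nucleotide Karlin–Altschul values matched to the
+2/−3/−5 scoring; a Monte-Carlo test confirms the resulting E-values track
empirical exceedance within a factor of 3 over E ∈ [0.01, 10].

Pseudogene-to-parent identity uses global Needleman–Wunsch (match +1,
mismatch −1, gap −2) with Blast-style identity = matches / alignment columns,
gaps included. The study's own identity values came from Blastn local
alignments of unknown parameters, so this is a stated stand-in convention;
on the synthetic (substitution-only) pseudogenes the two coincide.

## Numerical choices and tie-breaks

* Local alignment: co-optimal hits break to lowest subject start, then lowest
  query start; traceback prefers diagonal, then up, then left. Score 0 means
  no hit (empty intervals).
* Global identity: symmetry in the two arguments is enforced by aligning them
  in canonical lexicographic order; the traceback is deterministic.
* SOM: BMU ties to the lowest row-major index; weights stay in [0, 1]
  because batch updates are convex combinations of one-hot data.
* Motif scan: per element, all leftmost non-overlapping matches (greedy);
  different elements may overlap. The GAIT hairpin gate requires ≥ `min_stem`
  consecutive complementary base pairs between flanks within 30 nt — a
  stem-loop heuristic, not secondary-structure prediction.
* Degenerate inputs: empty transcript lists, empty term maps, all-zero
  censuses and empty graphs all return typed empty results rather than
  errors; genuinely contradictory configuration (negative counts, a
  non-negative ΔG cut, unknown biotypes or config keys) errors with the
  offending value named.
* Duplicate interactions collapse to one network edge keeping the minimum
  (most stable) ΔG.

## Pipeline reproducibility

`run_all()` snapshots the validated config, logs every derived seed (the
primary seed drives generation and SOM initialization; `seed + 1` the
synthetic term map; `seed + 2` the synthetic pathway sets), writes TSV
sidecars for every stage and records MD5 digests and record counts in a JSON
manifest. Reports contain no timestamps, so identical configs reproduce
identical bytes — a property the acceptance tests check file by file.

## Known limitations

* The energy model is a duplex nearest-neighbor approximation: no partition
  function, no suboptimal ensembles, no target-site accessibility, and a
  simplified uniform GU stack term.
* The SOM stage is a recall-oriented pre-filter; with small catalogues most
  lattice clusters host a seed, so precision rests on the dissimilarity and
  energy filters.
* Percent identity by global alignment differs from Blastn local identity on
  sequences with large indels or only locally homologous regions.
* The motif patterns are consensus simplifications (documented per element in
  `inst/extdata/motifs.tsv`); structural elements beyond the GAIT stem
  heuristic are out of scope, as is any live database query.
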