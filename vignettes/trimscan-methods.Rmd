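---
title: "Methods: models and design choices in trimscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices in trimscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`trimscan` annotates and characterizes miniature non-autonomous LTR
retrotransposons (TRIMs). This vignette documents the models behind each
stage, the tunable parameters and their defaults, the conventions adopted
where the underlying methodology left choices open, and what the
synthetic-data validation does and does not demonstrate.

## Coordinates and formats

All internal coordinates are 0-based, half-open `[start, end)`; GFF3
output is 1-based inclusive per the format standard, and converting twice
is the identity. FASTA is read through Biostrings, GFF3 through
rtracklayer/GenomicRanges, Newick through ape. Sequences are uppercased
on input; characters outside `{A,C,G,T,N}` are rejected (strict mode,
default) or masked to N.

## Structural detection

A complete TRIM is a pair of co-oriented LTRs (direct repeats) within a
size window, so the detector searches a single strand for repeated
substrings:

1. **Seeding.** Exact k-mers (`seed_k = 15`) occurring at two positions
   whose offset lies in the admissible window
   (`min_ltr + min_internal` to `max_element − min_ltr`; defaults 150 to
   900 bp). Any k-mer containing N is unmatchable, so assembly-gap runs
   cannot seed spurious repeats. K-mers with more than 12 occurrences are
   skipped as low-complexity.
2. **Chaining.** Seed pairs are clustered on (diagonal, position) with a
   ±20 bp diagonal band and a 400 bp position gap.
3. **Extension.** Each cluster is extended by local alignment
   (match +2, mismatch −3, gap open −5, extend −2 — a conventional
   nucleotide parameterization approximating BLASTN-style scoring). The
   two alignment windows each cover a full LTR length around the seeds
   but are split disjointly at the midpoint between the seed blocks:
   overlapping windows would let the aligner lock onto the trivial
   self-match of the shared span instead of the diverged repeat.
4. **Boundary refinement.** Within ±`refine_bp` (10 bp) of the aligned
   boundaries, the placement is chosen that maximizes
   4·[identical flanking 4-mers] + [`TG` at each expected start] +
   [`CA` at each expected end], with a 0.01/bp penalty on the shift so
   ties resolve to the nearest placement. Local alignment can overshoot a
   boundary through chance matches by more than 10 bp; when no placement
   with full TSD-plus-termini evidence exists in the ±10 window the
   search widens once to ±30 bp. For library hits whose alignment ends at
   an interior library position (a truncation cut), no terminus motif is
   expected at that end and none is scored — otherwise chance
   full-evidence placements would outcompete the true cut boundary.
5. **Calls.** A 4-bp TSD is called iff the refined flanking 4-mers are
   exactly identical (no-mismatch rule, keeping downstream TSD statistics
   unambiguous). Candidates failing `TG…CA` at both ends are kept but
   flagged (`termini5_ok`/`termini3_ok`), since termini are conserved
   only "generally" in real families. Overlapping candidates resolve to
   the higher alignment score. Identity is computed from a global
   alignment of the two refined LTRs; candidates below
   `min_ltr_identity = 0.80` are dropped.

**PBS**: the first `pbs_window = 25` bp of the internal region is matched
against the reverse complement of each tRNA's 3′ terminal segment;
minimum contiguous match 10 bp, at most 1 mismatch; ties go to the longer
match, then the earlier offset, then tRNA input order. **PPT**: 15-bp
windows in the last 30 bp of the internal region with purine fraction
≥ 0.8; the qualifying window nearest the 3′ LTR wins (proximity over
purity, since the PPT primes plus-strand synthesis at the LTR junction).

**Solo-LTRs and truncated copies** are recovered by scanning library
sequences (detected complete elements and their LTRs by default) against
both strands, k-mer-seeded and locally aligned; hits overlapping a
complete candidate (including its TSD copies) are absorbed into it.
Remaining hits with LTR coverage ≥ `solo_min_coverage = 0.80` and a span
consistent with a single LTR are `solo_ltr`; everything else is
`truncated`, subtyped `element` (fragment of a full element) or `solo`
(partial LTR). An LTR's reverse complement still reads `TG…CA`, so
terminus scoring is strand-aware through the library mapping.

## Insertion dating

The dating model assumes the two LTRs of a copy were identical at
integration and accumulated substitutions independently. The LTR pair is
globally aligned (match +1, mismatch −1, gap −2, end gaps penalized;
alignment by Biostrings, whose traceback is deterministic —
library-defined rather than a hand-specified tie rule, with scores
verified against an exhaustive DP oracle in the tests). Columns with gaps
or N are excluded from the site counts — the estimator is
substitution-based, and counting indel columns would mix processes; a
config switch (`count_indel_sites`) records the choice. With transition
proportion P and transversion proportion Q over comparable sites,

K = −½ · ln((1 − 2P − Q) · √(1 − 2Q)),    T = K / (2r),

with `r = 0.54e-8` substitutions/site/year by default (the host-lineage
synonymous rate; r is a constant input here, not something the package
estimates). Saturation (non-positive log arguments) is an explicit error,
never a clamped value: silently capping ages would corrupt age
histograms. K = 0 ⟺ T = 0, so identical-LTR copies date to zero.

## Genomic distribution and insertion-site statistics

The randomization test re-assigns `n_elements` positions uniformly over
the concatenated genome (scaffold drawn proportionally to its length —
the natural reading of "a random position in the genome") and counts
distinct scaffolds hit per replicate; `p = (1 + #{null ≤ observed}) /
(n_reps + 1)`, the finite-sample correction keeping p strictly positive.
Elements are assigned to scaffolds/regions by interval midpoint.

TSD contexts are 14-mers — 5-bp upstream flank, the 4-bp TSD, 5-bp
downstream flank — read around the upstream TSD copy and after the
downstream copy, i.e. the site as it existed before integration; records
with incomplete flanks or N are excluded. Logo information content per
position is `R = 2 − H` bits (Shannon entropy over A/C/G/T), with the
small-sample correction `e_n = 3/(2·ln 2·n)` off by default (the upstream
logo tool is unspecified; both modes are exposed).

## Phylogenetics

**TN93 distances** use the Tamura–Nei (1993) closed form with two
transition classes, computed per pair after dropping that pair's gap/N
columns (pairwise deletion). Base frequencies are the pair's empirical
frequencies by default (`tn93_frequencies = "pairwise"`); whether the
reference tooling pools frequencies across the alignment is ambiguous, so
a `"global"` switch exists. Saturated or compositionally degenerate pairs
raise errors naming the pair. **Neighbor-joining** is the Saitou–Nei
agglomeration via `ape::nj`, with negative branch lengths clamped to zero
and the clamped deficit recorded (an attribute), following common
practice. **Bootstrap** resamples alignment columns with replacement,
rebuilds the tree per replicate, and reports bipartition frequencies on
the full-data tree; replicates whose resampled distances are undefined
are skipped and removed from the denominator. **Subfamily cutting** walks
the tree from the root and labels maximal clades with support
≥ `min_support` and mean within-clade distance ≤ `max_within_distance`;
tips outside every qualifying clade stay `unassigned` — divergent
singletons are a real feature of TRIM families, not an error state.

**Parsimony.** Fitch's downpass gives the minimal change count on the
rooted binary host tree. MPRs are enumerated exhaustively over internal
node states (trees up to 16 internal nodes), each annotated with its
gains (absent→present) and losses. Two conventions deserve note:

- *Root anchoring.* By default (`root_state = "outgroup"`) the basal node
  is fixed to the observed state of a leaf attached directly to the root.
  Without it, enumeration on an outgroup-rooted tree also admits
  reconstructions placing the derived state above the outgroup split —
  histories that assert the character arose before the outgroup diverged,
  which outgroup-based ancestral-state practice excludes. A `"free"` mode
  drops the constraint.
- *Tracings.* ACCTRAN is selected from the MPR set as the reconstruction
  maximizing the number of internal nodes in the derived (non-root)
  state — accelerating changes toward the root makes the derived state's
  subtree maximal; DELTRAN minimizes it, delaying changes toward the
  tips. Ties break deterministically by enumeration order. For binary
  characters with an anchored root this reproduces the classical
  tracings.

The packaged 13-taxon host tree (`pbtrim_host_tree()`) encodes the
genus-level ant phylogeny used for the published reconstruction —
Myrmicinae (Pogonomyrmex; Aphaenogaster+Messor;
Crematogaster+Solenopsis sister to Pheidole), Formicinae (Camponotus,
Lasius), Linepithema (Dolichoderinae) branching below them, Apis rooting
the tree. The source figure specifies the topology graphically; this
rendering reproduces the published parsimony results exactly (4 steps,
3 MPRs, gains 1–4 / losses 0–3, ACCTRAN 1 gain + 3 losses, DELTRAN 4
gains), which is the validation available for it.

Multiple alignment construction is deliberately out of scope: the module
accepts pre-aligned FASTA, and `align_star` (center-star over pairwise
global alignments) covers synthetic data; real datasets should be aligned
with a dedicated MSA tool.

## The synthetic-genome generator

The generator is the package's test substrate and defines its study
conditions:

- Background scaffolds are i.i.d. nucleotides at 37% GC (the host
  genome's composition); optional AT-rich hotspot blocks (default 19%
  GC, matching the composition observed at real insertion flanks) are
  placed at registry-recorded positions.
- Insertion at site *s* duplicates the host 4-mer at `[s, s+4)` on both
  sides of the inserted copy — the staggered-cut convention — so planted
  TSDs are host-derived and each insertion grows the scaffold by the
  element length plus 4 bp. A spec may instead dictate the TSD, in which
  case the site's 4-mer is overwritten before duplication.
- LTR pairs are diverged by a K2P substitution process calibrated so the
  expected pairwise distance equals `2·r·age`; the transition:transversion
  event ratio defaults to 2, an unstated free parameter chosen so both P
  and Q are exercised. Divergence is substitution-only (no indels), which
  matches the dating model; the internal region is planted undiverged.
- Truncated copies are prefix/suffix fragments of a complete copy.
- `simulate_homolog_set` evolves a consensus along a host species tree
  and lets horizontal-transfer events overwrite a recipient tip with a
  near-identical copy of the donor — producing the
  high-cross-species-identity / tree-incongruence signature that
  bootstrap analysis should flag.

What passing tests therefore show: the detector recovers planted copies
coordinate-exactly (recall and precision ≥ 0.95 at LTR identity ≥ 85%),
dating is calibrated over 0.5–10 My, the randomization test holds its
nominal type-I error and detects planted clustering, NJ reconstructs
additive inputs, and HT pairs attract ≥ 95% bootstrap support. What they
do not show: robustness to indel-rich divergence, nested insertions,
tandem arrays, sequencing/assembly artifacts, or base-composition
heterogeneity beyond the two-component hotspot model — real-genome
performance on those axes is untested by construction. Truncated copies
are planted undiverged (recent truncation products): a coordinate-exact
criterion on a diverged cut end would be ill-posed, since the cut carries
no TSD or terminus anchor.

Validation problem sizes (the package's chosen study conditions): planted
genomes of 12 scaffolds × 25–35 kb with 48 copies across categories and
ages to 10 My; 200 null datasets (199 replicates each) for the type-I
check; cohorts of 120 per age point for dating recovery; 100 additive
matrices for NJ consistency; 100–300 bootstrap replicates in tree tests.

## Degenerate inputs and numerical conventions

Empty element sets produce valid empty outputs (header-only GFF3, empty
tables). Zero-length scaffolds, colliding insertion positions, unknown
taxa in HT events, non-binary trees for parsimony, and observed scaffold
counts outside their bounds raise immediate parameter errors. All
stochastic operations take explicit seeds and are bit-reproducible under
them. Tie-breaks are deterministic throughout (label order, input order,
smallest-shift, smallest-member-id family labels). Family grouping
follows the 80/80 rule — ≥ 80% identity over ≥ 80% of the LTR *or* the
internal domain, coverage measured against the shorter sequence — with
single-linkage components, matching the standard family definition's
"or" structure.

## Known limitations

- The detector targets the miniature regime (element ≤ 1 kb by default);
  full-size LTR retrotransposons need wider windows and would benefit
  from a banded long-range aligner.
- Exhaustive MPR enumeration is exponential and capped at 16 internal
  nodes; larger host trees need a dedicated MPR algorithm.
- Boundary refinement trusts TSD/termini evidence; elements that lost
  both (old, highly eroded copies) keep alignment-derived boundaries,
  which can be off by a few bp.
- `align_star` is adequate for near-identical sets only; it makes no
  attempt at iterative refinement.
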