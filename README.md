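# trimscan

Discovery and evolutionary analysis of **TRIMs** — terminal-repeat
retrotransposons in miniature — in genome assemblies.

TRIMs are small (< 1000 bp) non-autonomous LTR retrotransposons: two short
long terminal repeats (LTRs, ~100–350 bp, canonically `TG ... CA`) flank a
non-coding internal region carrying a primer binding site (PBS) and a
polypurine tract (PPT), the whole copy bracketed by a 4-bp target site
duplication (TSD) left by the integrase. First described from plants, a
TRIM family (PbTRIM) was later characterized from the red harvester ant
*Pogonomyrmex barbatus*. `trimscan` re-implements that discovery and
characterization pipeline as a reusable, tested R package for anyone
annotating miniature LTR elements in an assembly:

- **Structural detection** (`find_ltr_pairs`, `detect_trims`): exact
  k-mer seeds shared by two positions within the element-size window,
  chained by diagonal, extended by local alignment (+2/−3, affine gaps),
  with boundaries refined against identical flanking 4-mers (the TSD) and
  `TG ... CA` termini. `detect_pbs` matches the internal region against
  the reverse complement of tRNA 3′ ends; `detect_ppt` finds purine-rich
  windows ahead of the 3′ LTR. `scan_solo_and_truncated` recovers
  solo-LTRs (relics of unequal recombination between an element's LTRs)
  and truncated copies by library scanning on both strands.
- **Insertion dating** (`align_ltr_pair`, `k2p_distance`,
  `insertion_age`): the two LTRs of a copy are identical at integration
  and diverge independently afterwards, so the Kimura two-parameter
  distance K between them dates the insertion as **T = K / (2 r)**, with
  r the substitution rate per site per year (default 0.54 × 10⁻⁸, the
  ant synonymous rate).
- **Genomic distribution** (`randomization_test`, `region_density`,
  `find_clusters`): a permutation test of scaffold occupancy (elements
  re-assigned uniformly over the concatenated genome, scaffolds drawn
  length-proportionally) and density/cluster summaries.
- **Insertion-site profiling** (`tsd_context_table`,
  `composition_stats`, `logo_information`): position frequency tables
  over the TSD and its 5-bp flanks, GC/modal-nucleotide statistics and
  sequence-logo information content in bits.
- **Phylogenetics** (`tamura_nei_distance`, `neighbor_joining`,
  `bootstrap_support`, `cut_subfamilies`, `fitch_parsimony`,
  `enumerate_mprs`): TN93 distances with pairwise deletion,
  neighbor-joining with bootstrap supports, subfamily clade cutting, and
  Fitch parsimony on a host phylogeny with exhaustive enumeration of
  most-parsimonious reconstructions (MPRs) and ACCTRAN/DELTRAN tracings —
  the machinery behind inferring horizontal transfer from element/host
  tree incongruence.
- **Synthetic genomes** (`generate_background`, `plant_elements`,
  `diverge_ltr_pair`, `simulate_homolog_set`): assemblies with planted
  copies and a ground-truth registry (coordinates, TSDs, realized
  divergence), so every stage is validated against known truth.

## Worked example

Simulate a small genome with three planted copies, detect them, and date
the complete elements:

```r
library(trimscan)

asm <- generate_background(3, c(15000, 20000), gc = 0.37, seed = 7)
set.seed(8)
ltr      <- paste0("TG", random_dna(156, 0.37), "CA")
internal <- random_dna(300, 0.37)
specs <- list(
  plant_spec(ltr, internal, age_years = 0,   category = "complete",
             scaffold = "scaf001", position = 4000),
  plant_spec(ltr, internal, age_years = 3e6, category = "complete",
             scaffold = "scaf002", position = 6000),
  plant_spec(ltr, tsd = "ATAT", age_years = 1e6, category = "solo_ltr",
             scaffold = "scaf003", position = 5000))
sim <- plant_elements(asm, specs, seed = 9)

elements <- detect_trims(sim$assembly)
elements[, c("id", "scaffold", "start", "end", "category",
             "tsd", "ltr_identity")]
#>        id scaffold start  end category  tsd ltr_identity
#> 1 trim001  scaf001  4004 4624 complete GACT      1.00000
#> 2 trim002  scaf002  6004 6624 complete CCCA      0.95000
#> 3  hit001  scaf003  5004 5164 solo_ltr ATAT      0.99375
```

All three copies are recovered at their exact planted coordinates
(0-based half-open), with the host-derived TSDs called from the identical
flanking 4-mers. Dating the complete elements:

```r
estimate_ages(elements, sim$assembly)[, c("element_id", "P", "Q", "K", "T_my")]
#>   element_id      P      Q      K T_my
#> 1    trim001 0.0000 0.0000 0.0000 0.00
#> 2    trim002 0.0375 0.0125 0.0521 4.83
```

The copy planted with identical LTRs dates to 0; the 3-My copy is dated
from its realized divergence (P transitions, Q transversions per aligned
site; single-copy ages scatter around the truth — cohort means converge).
Ancestral-state reconstruction of element presence/absence on the
packaged 13-taxon ant host tree:

```r
enumerate_mprs(pbtrim_host_tree(), pbtrim_host_presence())
#> parsimony reconstruction: 4 steps, 3 MPR(s); gains 1-4, losses 0-3
#> ACCTRAN: 1 gain(s) + 3 loss(es); DELTRAN: 4 gain(s) + 0 loss(es)
```

Four changes explain the patchy distribution of the element across the
twelve ant genera: either four independent gains (DELTRAN), or one early
gain followed by three losses (ACCTRAN), or an intermediate history —
the ambiguity itself is the signature that vertical inheritance alone
fits the data poorly.

See `vignettes/trimscan-methods.Rmd` for the models, parameter choices
and limitations.

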