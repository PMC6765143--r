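---
title: "Comparative discovery of telomerase RNAs and prediction of the telomere repeats they template"
author: "teloseeker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative discovery of telomerase RNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teloseeker)
```

## The problem

Telomerase adds telomere DNA by copying a short template carried by its RNA
subunit (TR). TRs diverge so fast in length and sequence that homology search
alone rarely finds them, and the only part of a TR whose sequence can be
predicted from first principles is the template region: it must contain a
permutation of the C-strand repeat unit of the organism's telomere motif,
elongated by at least one nucleotide so that the telomere 3' end can anneal
before elongation. `teloseeker` turns that observation into a screening
toolkit: enumerate every admissible template window for a given telomere
motif, pull out all transcripts containing one, intersect the candidate sets
of several related species by local alignment, and keep what is shared in all
of them. The same algebra run backwards predicts, from a candidate TR's
template region, the telomere repeat its telomerase would synthesize.

## Circular-permutation algebra of template regions

A telomere motif is a *circular* word: `TTAGGG`, `TAGGGT` and `GGGTTA` all
denote the same repeat. The package therefore keeps three spellings:

* the unit as given (`g_strand_unit`, 5'→3' on the G-rich strand),
* the **canonical form** — the lexicographically minimal rotation — used for
  all identity comparisons, and
* the **display form**, the field's convention of ending the spelling with
  the G-tract. It is computed, not looked up: start the unit immediately 3'
  of the longest circular run of G (ties resolved to the lexicographically
  smallest candidate). This single rule reproduces every conventional plant
  motif spelling (`TTTAGGG`, `TTAGGG`, `CTCGGTTATGGG`, `TTCAGG`, `TTTCAGG`,
  `TTTTTTAGGG`, `ATTAGGG`, `TTTAGG`, `TTTACGG`) without a hard-coded list.

Units must be *primitive* — not a power of a shorter word — or permutation
sets and spans would be ambiguous. Primitivity is checked
rotation-invariantly (all rotations distinct), so any rotation of a valid
unit is accepted and identifies the same motif. A deliberately stronger,
internal notion matters for testing: a unit is *circularly unambiguous* when
every window of length L+1 of its circular repeat has smallest period
exactly L. Near-homopolymer units such as `AAAAC` are primitive but fail
this: some of their windows genuinely carry a shorter period, so **no**
method could recover the unit from such a window. The simulator and the
round-trip property tests draw motifs from the unambiguous class; real
telomere motifs are comfortably inside it.

The minimal-template permutation set for an L-bp motif and extension *e*
(default 1) is the set of all distinct windows of length L+*e* of the doubled
C-strand unit — exactly L windows for a primitive unit and *e* < L. For
`TTAGGG` these are the six 7-mers `CCCTAAC, CCTAACC, CTAACCC, TAACCCT,
AACCCTA, ACCCTAA`; for the 12-bp Allium motif, twelve 13-mers.

```{r perms}
template_permutations("TTAGGG", extension = 1)
```

Template→motif prediction inverts this: `predict_telomere_motif()` infers
the repeat period by smallest-period computation, takes the first
period-length prefix as the C-strand unit, and reverse-complements it into
the G-strand motif. The **anchor** is defined as the template length minus
the period while the span is below two units, and as length mod period
beyond that; the **span** is length/period. For the Arabidopsis-type
template `CTAAACCCT` this gives motif `TTTAGGG` with a 2-nt anchor; for the
18-nt Allium template `AACCGAGCCCATAACCGA`, motif `CTCGGTTATGGG` at 1.5
units.

```{r predict}
predict_telomere_motif("CTAAACCCT")
```

`enumerate_compatible_motifs()` generalizes prediction to *all* maximal
periodic windows for every period in `[min_unit, max_unit]`, which is how
mixed-type templates (compatible with both human- and Arabidopsis-type
repeats) are represented. Defaults `min_unit = 5`, `max_unit = 15`: the
shortest plant telomere-like unit handled is 6 bp, so 5 leaves one unit of
slack while rejecting homopolymer and dinucleotide artifacts; 15 covers the
12-bp Allium unit with slack. Windows containing `N` are non-periodic by
definition — matching is strictly literal.

## Screening transcript sets

`scan_transcripts()` is the in-memory equivalent of running `grep` over a
one-line-per-record FASTA, with two deliberate differences: matching is done
on whole records (so wrapped FASTA cannot hide a match that spans a line
break) and sequences are upper-cased on read (soft-masked regions are kept).
The default searches the sense strand only, because stranded RNA-seq
assemblies place transcripts on their coding strand; `strand_mode = "both"`
is available for non-stranded assemblies. Exact matching uses a
Biostrings `PDict` over the permutation set.

## Cross-species intersection

Candidate sets from two or more species are compared all-to-all with an
affine-gap Smith–Waterman aligner written for this package (Rcpp), scored
BLASTN-style: reward +2, penalty −3, a k-base gap costing 5 + 2k, best over
both strands of the subject. Because no E-value statistics are invoked, a
hit passes on three explicit, tunable thresholds: raw score ≥ 40, identity ≥
0.70 over aligned columns (gap columns count), aligned length ≥ 40 nt. The
per-pair comparison short-circuits through a score-only pass and only runs
traceback on pairs that clear the score threshold. The aligner is a
TR-scale tool: inputs above a configurable cap (100 kb) are refused rather
than silently slow. Traceback ties resolve diagonal > up > left, making
output deterministic.

A candidate's presence profile across datasets classifies it as
`shared_in_all`, `shared_in_some` or `unique`; ortholog groups are
single-linkage connected components over passing hits, and the final TR
candidate set consists of groups covering every dataset. The judgment the
original workflow left to manual curation — "does the hit look like a TR?" —
is replaced by an explicit annotation: `extend_orthologs()` flags each hit
for the presence of a periodic template-domain window. The relaxed search
mode switches scoring to +1/−1 and halves the score threshold, the standard
permissive second pass for deeply diverged orthologs.

`identity_to_consensus()` implements the family-identity summary: consensus
by per-column majority over non-gap residues (ties alphabetical, all-gap
columns stay gaps), per-sequence identity over that sequence's non-gap
columns, mean across sequences. Because the literature is ambiguous about
whether such figures mean identity-to-consensus or mean pairwise identity,
both are provided (`mean_pairwise_identity()` uses columns where both rows
are non-gap).

## Annotating TR gene architecture

Plant TR genes share a recognizable layout: 5' G-rich region, template
domain, a conserved box downstream of it, C-rich region, AT-rich region near
the 3' end, with USE and TATA promoter elements upstream and a Pol III
poly-T terminator downstream. `annotate_tr()` orchestrates:

* `find_template_domain()` — periodic windows filtered to template-like
  ones: span ≥ 9/7 units (the one-unit-plus-2-nt anchor geometry), C content
  of the unit ≥ 0.25, ≥ 3 distinct bases in the unit.
* `composition_scan()` — sliding 15-nt windows flagged G-rich (G ≥ 0.5),
  C-rich (C ≥ 0.5) or AT-rich (A+T ≥ 0.8); merged intervals are trimmed to
  their first/last contributing base so a qualifying window cannot drag the
  reported block past its edge. The thresholds are declared defaults, all
  config-overridable; no published cutoffs exist for these blocks.
* `build_pwm()` / `scan_pwm()` — log-odds (base 2) matrices with pseudocount
  0.5 over a uniform background, built from user-supplied aligned sites. No
  USE or TATA matrix ships as ground truth, because no machine-readable
  matrices are published; when no TATA PWM is given, a clearly labelled
  heuristic (`TATAAA`, ≤ 1 mismatch) stands in.
* `find_pol3_terminator()` — first run of ≥ 4 T within 200 nt downstream,
  the standard plant Pol III terminator signature; both parameters
  configurable.
* `end_support()` — reads containing the transcript's terminal k-mers (k =
  20, either orientation) count as TSS/TTS support. Exact containment is
  used rather than full alignment; `max_mismatch` enables fuzzy terminal
  matching.

Promoter scans run only on upstream context and the terminator scan only on
downstream context; features are emitted in coordinate order and export to
GFF3 (1-based inclusive there; everything else in the package is 0-based
half-open). Identical input yields byte-identical GFF3.

## TRAP products and TRF profiles

`parse_trap_product()` decomposes a sequenced TRAP product as substrate
primer (≤ 1 mismatch at the product start) + tandem repeat units + optional
trailing partial + reverse-primer segment. Units are parsed greedily left to
right against all rotations of the motif, accepting the fewest-mismatch
rotation within a per-unit budget (default 1); mismatch ties keep the phase
of the previous unit, which is what tandem synthesis produces. Greedy
phase-preserving parsing was chosen over a global DP decomposition: products
of a working telomerase are phase-coherent, and the greedy parse is
reconstruction-exact (the concatenation of the parsed parts reproduces the
input byte for byte, an invariant the tests enforce on every product).

`ladder_periodicity()` reduces a product-length ladder to the modal
successive difference (ties toward the smallest), and `trf_weighted_median()`
computes the weighted median of a TRF intensity profile: the smallest
fragment size at which cumulative normalized weight reaches 0.5. The exact
weighting convention behind published TRF medians is not printed anywhere
usable, so both are implemented: molar correction (weight = intensity/size,
the default, compensating for label scaling with fragment length) and raw
intensity weighting.

## What the simulator emulates — and what it does not

`simulate_datasets()` is the package's test bed, emulating the statistical
structure of a comparative TR screen: a handful of species datasets, each a
haystack of background transcripts in which rare telomere-like k-mers are
common but true TRs are single; one planted TR per dataset, all descended
from a common ancestral TR. Defaults are the study conditions used
throughout the tests, chosen once:

* 4 datasets × 500 decoys, decoy lengths uniform on 200–600 nt, uniform
  base composition;
* the 12-bp Allium-type motif with a 1.5-unit (18-nt) template in a 240-nt
  TR — the size regime of a real plant TR transcript;
* planted architecture: G-rich block, template, conserved box, C-rich and
  AT-rich blocks at fixed offsets, recorded in a truth table;
* per-ortholog substitution rate 0.15 from the ancestor. This is the rate
  that puts family identity-to-consensus in the ~85% regime (identity to
  consensus tracks the per-branch rate, not the pairwise distance, which is
  roughly twice it);
* the template itself is mutation-protected by default: an intact template
  is both the biology of a conserved template domain and the premise of the
  k-mer screen;
* 10% of decoys are contaminated with one random minimal-template
  permutation, so the screen's candidate lists contain realistic decoy
  noise.

One mandatory seed drives every stochastic stage (threaded via
`withr::with_seed`, no global RNG state is left behind), and identical seeds
give byte-identical FASTA output.

The simulator deliberately does **not** model indels between orthologs,
assembly errors, chimeric transcripts, coverage gaps, expression levels or
quality scores. Consequently a passing end-to-end test shows that the
screen–align–intersect–predict chain is correct and well-calibrated under
substitution-only divergence with intact templates; it does not show
robustness to fragmented or indel-riddled assemblies, which real Trinity
output can produce.

Problem sizes used by the automated checks were likewise fixed once: the
full pipeline property runs at the default 4 × 500 scale; the aligner is
verified exhaustively against an independent oracle on all two-letter
sequence pairs up to length 8 (and against explicit gap-length enumeration
on the shorter ones); TRAP reconstruction runs on 1,000 simulated products.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere in R objects; only GFF3
  export is 1-based inclusive.
* Comparisons of motifs always go through the canonical rotation; display
  spellings are presentation only.
* Deterministic tie-breaks throughout: alignment traceback diagonal > up >
  left; best alignment cell first-encountered in row-major order; consensus
  ties alphabetical; TRAP rotation ties keep phase; ladder-periodicity ties
  take the smallest difference; ortholog-group representatives are the
  longest member, then smallest id.
* The screen's candidate subsets, not whole transcriptomes, are what the
  aligner sees; the optional exact k-mer pre-filter exists for unusually
  large candidate sets but full dynamic programming is the default.

## Known limitations

* Template-window boundaries are reported as maximal periodic windows; no
  published rule fixes where a biological template ends relative to its
  conserved flanks, so boundary trimming is left to the user.
* No E-value model: raw-score acceptance is transparent but not
  length-normalized across wildly different transcript sizes.
* The conserved box downstream of the template domain has no published
  consensus sequence; it is only representable through a user-supplied PWM.
* RNA secondary structure is out of scope, as is degenerate (IUPAC) motif
  algebra and read-level assembly simulation.
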