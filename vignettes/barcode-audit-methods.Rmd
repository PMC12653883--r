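---
title: "Auditing DNA-barcode species identification: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing DNA-barcode species identification: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barcodeaudit)
```

## The problem

DNA barcoding identifies specimens by comparing a short standardized marker
(here the ~658 bp COI fragment) against a reference library of sequences that
already carry Linnaean names. Two distinct things can go wrong. First, the
*clustering* step can fail: conspecific barcodes may not form a tight group
(anomalous, often Wolbachia-associated haplotypes), or different species may
share barcodes (introgression, incomplete lineage sorting). Second — and in
well-sampled faunas far more often — the *naming* step fails: the reference
library contains mislabeled specimens, contaminated sequences filed under the
wrong genus or family, unresolved synonyms, or simply no conspecific entry at
all. A query then comes back identified only to genus, or at species rank with
less than full confidence.

`barcodeaudit` implements this audit as a reproducible pipeline: a BOLD-style
nearest-sequence identification engine over a labeled COI library, cluster
delimitation by nearest-neighbor distance, a six-category classification of
problematic identifications, a geographic-correction rule, cluster-level
aggregation — and a synthetic library generator that injects each error
process at known rates so every stage can be tested offline against ground
truth.

## Distances

All comparisons assume co-aligned barcode-region sequences (equal lengths; no
internal aligner). Sites carrying a gap or any IUPAC ambiguity code in either
sequence are excluded pair by pair (*pairwise deletion*); ambiguity codes
never count as matches or mismatches, even when compatible (an `R` never
pairs with an `A`) — simpler and deterministic. On the compared sites,
transitions (A↔G, C↔T) and transversions are counted separately, giving
proportions $P$ and $Q$ and

* percent similarity $= 100\,(1 - (P+Q))$, printed to two decimals, rounding
  half away from zero (the print convention of BOLD-style hit tables);
* the Kimura 2-parameter distance
  $d = -\tfrac12 \ln\!\big[(1-2P-Q)\sqrt{1-2Q}\,\big]$, in substitutions per
  site. When the log argument is non-positive the pair is *saturated*: the
  entry becomes `NA` and the matrix is flagged; clustering and tree building
  refuse to proceed on saturated entries rather than guessing.

`distance_matrix()` computes whole matrices through indicator cross-products
(four 0/1 site matrices and a handful of BLAS calls), so pooled matrices of a
few hundred records are essentially free; `compare_pair()` is the per-pair
reference path, and the two are tested against each other and against an
independent K2P implementation.

## Identification

`top_k_search()` mirrors a rapid-search identification engine: at most
`k = 25` hits at or above the search depth (`depth_pct = 94`% similarity),
sorted by similarity then reference id. The query never matches its own
record id, but exact sequence duplicates under other ids are legitimate hits.
Hit labels are canonicalized through the synonymy table before consensus, so
pure junior synonyms never masquerade as conflicts; the raw label is kept for
the classifier.

`consensus_identify()` reconstructs a deterministic version of the final
naming step (the production engines do not publish theirs):

1. The *co-best* names are the distinct species within `delta_top_pct = 0.5`
   of the best similarity. The window is chosen so that a discordant hit tied
   at the top forces escalation while one well below the best does not.
2. One co-best species whose best hit reaches `species_match_pct = 99`%
   (conspecific grade) gives a species-rank identification with confidence
   `round(100 × share of retained hits carrying that name)`.
3. Otherwise the identification escalates to the lowest rank on which the
   co-best names agree — genus, then subfamily, then family — with confidence
   computed over retained hits at that rank; no agreement even at family
   level leaves the query unidentified.

The conspecific-grade gate in step 2 is deliberate: a lone hit list whose
best same-name similarity is only ~98% is evidence for the *genus*, not for
the species — exactly the situation of a species missing from the library
whose congener scores 98.7%, which real engines report as "genus only, 100".
Without the gate such queries would come back clean at species rank and the
incompleteness and anomalous-barcode categories below could never apply to a
problematic record.

An identification is *problematic* when its rank is coarser than species or
its confidence is below 100.

## Cluster delimitation

`delimit()` forms single-linkage connected components on the pooled
reference+query K2P matrix, linking records strictly below
`merge_threshold = 0.03`. Strict inequality means a pair at exactly 3% stays
split, so every between-cluster nearest-neighbor distance exceeds 3% — the
operational criterion for discrete barcode groups. Single linkage is the
right operationalization here because the criterion itself is a
nearest-neighbor one: the resulting partition satisfies "each group's NN
distance > 3%" by construction. Clusters are numbered by their smallest
member position, making output deterministic. `split_census()` counts how
many clusters each morphospecies occupies; a count of 2 is the signature of
an anomalously diverged haplotype group (the classic case is a conspecific
pair 7.2% apart).

## The six problem categories

`classify()` assigns every problematic query all matching categories, using
the hit list, the pooled clusters, the synonymy table and the reference
library. Let the *majority name* be the most frequent species among the hits
(ties broken by best similarity, then alphabetically), and call a discordant
name *well-represented* when it has at least `min_represented = 2` hits *and*
a hit share of at least `mislabel_max_fraction = 0.20`, *sporadic* otherwise.

* **CROSS_GENUS_CONTAMINATION** — some hit at or above
  `conspecific_floor_pct = 99`% belongs to a different genus or family than
  the majority name. Conspecific-grade similarity across genera is almost
  always contamination or a label swap.
* **SPECIES_MISLABEL** — a sporadic discordant congeneric name whose hits lie
  inside the query's cluster: isolated wrong names scattered among correct
  identifications.
* **UNDIFFERENTIATED** — a well-represented discordant congeneric name
  sharing the query's cluster, and not explained by the synonymy table: the
  two species genuinely share barcodes (introgression or recent divergence).
* **TAXONOMY_UNCERTAINTY** — a discordant name forming a flagged
  unresolved pair with the majority name, or a raw hit label that
  canonicalizes onto it: the conflict is nomenclatural, not molecular.
* **ANOMALOUS_BARCODE** — the best same-name hit falls below conspecific
  grade although same-name references exist and share the query's cluster:
  the query belongs to a divergent conspecific haplotype group.
* **DB_INCOMPLETE** — no same-name reference exists anywhere in the library
  and no hit reaches conspecific grade. Distinguished from the anomalous case
  precisely by the absence of conspecific references.

The sporadic/well-represented dichotomy is exact (each discordant congeneric
name is one or the other). With short hit lists — a handful of conspecific
references is typical for local faunas — the share alone is too coarse: a
single wrong name among five hits already holds a 20% share, so a name seen
fewer than `min_represented` times counts as sporadic regardless of share.
The real audit resolves mislabel-vs-undifferentiated-vs-synonymy by expert
judgment over voucher photos and literature; the package resolves it by these
thresholds plus a *curated* synonymy/uncertainty table supplied as input —
photo checks are out of scope, and the table is where expert knowledge
enters.

### Geographic correction

When two species genuinely share barcodes, a local identification can still
be rescued if the conflicting species does not occur in the focal region.
`geographic_correction()` returns **Yes** only when the record is
undifferentiated *and* every conflicting species has a known range excluding
the focal region; a conflicting species present locally — or with an unknown
range — gives **No** (species turn up far beyond their recorded ranges, so
unknown is treated conservatively); any other problem gives **N/A**.
Indeterminate labels ("Genus sp.") are not species names and are ignored.
Region codes are opaque strings and the focal region is configuration, not a
constant.

## Aggregation

Audits are reported per specimen but counted per cluster:
`to_cluster_level()` makes one record per cluster containing a query
(problematic if any member is; categories are the union), and
`summarize_audit()` produces the headline numbers. Printing conventions
follow the field: problematic/clean percentages to zero decimals (so 41 of 76
prints as 54% / 46%), the share of clusters whose problems are *not* due to
library incompleteness to one decimal (75 of 76 → 98.7%). Unrounded values
are retained internally. Per-category percentages are computed over all
category assignments (a multi-category cluster contributes once per
category); they are reported but not asserted anywhere, because the counting
unit for multi-reason records is genuinely ambiguous.

## The synthetic library generator

`simulate_library()` generates the study conditions the audit assumes, plus
per-record ground truth. Defaults: 2 families × 5 genera × 5 species = 50
species, 5 references and 2 queries per species, 658 bp, transition weight
κ = 2, and all corruption rates zero (a clean library).

**Geometry.** Sequences evolve down a star-within-hierarchy phylogeny: family
ancestors 0.15 below the root, genus ancestors 0.10 below their family,
species ancestors 0.04 below their genus, haplotypes radiating from the
species ancestor at half the expected conspecific pairwise distance of
0.005. Deep branches substitute an *exact* `round(L·d)` count of distinct
sites, so congeneric species sit ~8% apart — outside the 94% search depth —
and the divergence ladder (conspecifics ≪ 3% threshold < congeners <
confamilials) holds on *every* generated library, not merely in expectation;
with untruncated Poisson branch lengths, tail draws would put congeners
inside the search depth in a few percent of runs and the clean-library
contract below would fail sporadically. Within species, branch lengths are
Poisson but truncated at conspecific grade (<1% of sites), and each species'
first reference is the ancestral haplotype itself — the modal haplotype of a
well-sampled species — which corruption passes spare. Consequence, and
design contract: **a library with no injected errors audits perfectly clean**
(every query at species rank, confidence 100, zero problematic clusters).

**Error processes**, applied in a fixed order so the ground truth is
unambiguous (synonyms → introgression → anomalies → mislabels → cross-genus
swaps → deletions; a record touched twice keeps the last corruption and a
multi-flag):

1. *Unresolved names*: selected species have two of their references renamed
   to a second name registered as an uncertain pair. (True junior synonyms
   are canonicalized away before consensus and therefore cannot produce a
   problematic record; the unresolved-pair mechanism is what generates
   taxonomy-uncertainty conflicts.)
2. *Introgression*: congeneric pairs share a haplotype — copies of the
   donor's modal haplotype replace two recipient references.
3. *Anomalous haplotypes*: an anomalous ancestor 0.07 below the species
   ancestor spawns two reference haplotypes and one query, radiating at
   0.012 — so the anomalous query sits 1–3% from its anomalous conspecific
   references: inside the cluster link and the search depth but below
   conspecific grade, which is exactly the anomalous-barcode geometry.
4. *Mislabels*: references are relabeled to a random congener.
5. *Cross-genus swaps*: references are relabeled to a species of another
   genus; the displayed name carries its own (wrong) genus and family into
   the metadata, as a real label swap would.
6. *Deletions*: selected species lose all references but keep their queries.

Queries always carry their true species as the morphology label, mirroring a
study design in which queries are identified independently from morphology.
All randomness flows from the single config seed; identical configs are
byte-identical.

**Scoring.** `score_recovery()` compares flagged categories against the
truth. A query counts as truly affected by a corruption when its hit list
contains a corrupted record *whose displayed label differs from the query's
morphology label* — a corrupted record that agrees with the query's own name
cannot mislead its identification, and a classifier is right to stay silent
about it (the recipient species of an introgressed copy, for instance, sees
only extra same-name hits). The anomalous category keys on the query itself
being anomalous, and incompleteness on the query's species having been
deleted. `single_fault_config()` builds one-process-at-a-time configurations
(mislabels and swaps at 4% of references, five introgression and five
unresolved pairs, anomalies and deletions at 10% of species), rates chosen to
give tens of affected queries per run at the default 50-species shape.

**What the simulator does not emulate.** Real reference libraries have
wildly uneven sampling per species, geographic haplotype structure,
alignment gaps and ambiguity codes, NUMTs, and correlated errors (one
submitter mislabeling many specimens). Passing recovery tests on synthetic
libraries therefore shows the decision rules are internally consistent and
detectable faults are detected — not that the thresholds are optimal for any
particular real library. The in-paper aggregation fixture (45 problematic
specimen rows of a real Volga-region butterfly audit, shipped under
`inst/extdata/`) anchors the aggregation and geographic-correction stages to
real published verdicts; the upstream engine stages cannot be anchored the
same way because they depend on an 8.9-million-record online library.

## Numerical and degenerate-case choices

* Neighbor joining (the identification tree) is implemented with the
  Saitou–Nei Q-criterion; ties on Q are broken by the lowest (row, column)
  pair and negative branch estimates are clamped to zero with the excess
  moved to the sister branch, so results are deterministic and lengths
  non-negative. On additive matrices recovery is exact (checked to 1e-9 up
  to 12 taxa); an independent NJ implementation is the topology cross-check.
* Newick output always prints branch lengths to six decimals, no internal
  labels; a single-leaf tree serializes as `(label:length);`.
* Confidence and similarity rounding is half-away-from-zero (print
  convention); all comparisons and thresholds use unrounded values.
* One-record inputs: a singleton cluster has an infinite nearest-neighbor
  distance; an empty hit list yields rank `none`, which is problematic and,
  with no conspecific references, classifies as incompleteness.
* `filter_min_length()` counts non-gap characters (default floor 500 bp of
  the 658 bp region) and is idempotent and order-preserving.

## Problem sizes in the test suite

The shipped tests run the brute-force identification oracle on 100 random
libraries (up to 200 references), the union-find clustering oracle on 100
random matrices (up to 300 records), NJ recovery on 200 random additive
trees (up to 12 taxa), and classifier recovery on six single-fault
configurations × 10 seeds at the default 50-species shape; the acceptance
script repeats the headline computations at 5 seeds. These sizes keep a full
run in the low minutes while exercising every code path at the study's own
scale (a few hundred pooled records).

## Known limitations

* The consensus-confidence formula is a deterministic reconstruction; real
  engines retain hits by undocumented rules, so per-hit confidences from an
  online audit are reproduced in pattern, not digit by digit.
* Sequences must be co-aligned; there is no internal aligner, and unequal
  lengths are an error.
* The synonymy/uncertainty table is an input, not an inference: the package
  detects that a conflict is nomenclatural only if curation says so.
* Range tables rescue identifications conservatively; they cannot detect
  range expansions or unrecognized cryptic species.
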