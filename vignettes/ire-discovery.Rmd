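---
title: "Predicting iron-responsive elements in gene-flanking UTR windows"
author: "irescout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting iron-responsive elements in gene-flanking UTR windows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irescout)
```

## The problem

Cellular iron homeostasis is regulated post-transcriptionally: iron
regulatory proteins (IRPs) bind iron-responsive elements (IREs), short RNA
stem-loops in the untranslated regions of mRNAs. A 5'-UTR IRE represses
translation when bound; a 3'-UTR IRE stabilises the transcript. Genomes of
non-model insects frequently lack UTR annotation, so a practical screen
substitutes fixed-length genomic flanks — by default 1000 nt up- and
downstream of each CDS — as proxy UTR windows and searches them for
IRE-like hairpins.

`irescout` implements that screen end to end, together with the analyses a
study of this kind layers on top: scanning for known UTR regulatory
elements, discovering over-represented motifs de novo, checking 5' calls
against experimentally mapped transcription start sites (TSS), and
categorising cross-species ortholog support. A seeded synthetic-genome
generator with a machine-readable truth table validates every stage.

## The IRE structural model

The package models the canonical IRE as, reading 5' to 3':

* a **lower stem** of contiguous base pairs (Watson–Crick, plus G·U wobble),
* an unpaired **C8 bulge** — a single conserved cytosine,
* an **upper stem** of exactly five base-pair positions,
* an apical **loop** matching `CAGUGH` (H = A, C or U, never G),
* the complementary upper- and lower-stem strands.

Two features are recorded but not required: the pseudo-triloop (pairing of
the first loop C with the fifth loop G, leaving an apparent AGU triloop),
and the loop's terminal base identity. Non-canonical variants carry either
one **mismatch** in the upper stem or one extra unpaired nucleotide
(**bulge**) on the 3' strand of the upper stem.

Rather than free-energy minimisation, the package evaluates candidates with
a combinatorial geometry checker: every admissible layout around an
anchored loop is enumerated, and the layout with fewest defects, then
longest lower stem, then the bulge placed nearest the loop, wins
(`check_ire_geometry()`). A Nussinov maximum base-pairing engine
(`nussinov_fold()`) with an exhaustive enumeration oracle
(`enumerate_structures()`, length ≤ 16) provides general-purpose folding
support and the test bed for the pairing rules. Thermodynamic folding is a
deliberate non-goal: the geometry of an IRE is fixed enough that a
combinatorial check is both faster and exactly reproducible.

## Scanning and scoring

Scanning is two-stage, prescreen then geometry:

1. **Anchor prescreen** (`scan_candidates()`): IUPAC-degenerate anchors of
   the form `C·N5·CAGUGH` locate every potential loop, overlaps included.
   On i.i.d. uniform RNA a position matches with probability
   (1/4)(3/4)(1/4)^5 ≈ 1.8 × 10⁻⁴, which the acceptance checks verify
   empirically. Pattern mode `"all"` additionally admits a U in the
   C8-anchor role, covering SELEX-derived pyrimidine-bulge variants; mode
   `"canonical"` is the strict subset.
2. **Geometry ladder** (`score_ire_geometry()`): each anchor is evaluated
   under three grammars in order. The strict grammar (literal C bulge,
   lower stem ≥ `min_lower_bp`, at most one defect) yields **HIGH**; the
   relaxed grammar (pyrimidine bulge, any lower-stem support ≥ 1 bp, at
   most one defect) yields **MEDIUM**; tolerating two defects yields
   **LOW**; otherwise there is no call.

The retention filter (`apply_filters()`) keeps every HIGH call and keeps
MEDIUM calls only when they contain no mismatch — bulges do not disqualify
a MEDIUM call. This asymmetry follows the biology of the reference
ferritin IRE, which scores MEDIUM in this scheme class yet is a true IRE;
mismatch-free MEDIUM calls are its analogues. LOW calls are dropped.

Key tunables, all in `ire_grammar()`:

| parameter | default | meaning |
|---|---|---|
| `min_lower_bp` | 3 | contiguous lower-stem pairs required for HIGH (1–10) |
| `max_defects` | 1 | upper-stem mismatches + bulges tolerated |
| `allow_gu` | TRUE | G·U wobble counts as a pair, never as a mismatch |

The default `min_lower_bp = 3` quantifies "sufficient pairing below the
bulge" as the shortest stem that stabilises a bulged hairpin; it is
deliberately conservative and configurable.

## Known UTR elements and enrichment

`element_db()` ships simplified consensus descriptors for the common UTR
elements (PAS and its AUUAAA variant, ARE, K-box, Brd-box, GY-box, CPE,
SXL- and UNR-binding sites) plus a procedural uORF detector: every AUG
whose first in-frame stop lies inside the window, with a 9-nt minimum
(start + one codon + stop) and no Kozak filtering. Elements whose published
descriptors are secondary-structure models (IRES, GAIT, FIE3) are not
encoded — approximate user-supplied patterns can be added through a TSV.
Enrichment (`element_enrichment()`) counts windows-with-a-hit rather than
raw hit totals, avoiding window-length bias, tests each element with a
two-sided Fisher exact test and adjusts across elements by
Benjamini–Hochberg.

## De novo motif discovery

`em_discover()` fits a ZOOPS (zero-or-one occurrence per sequence) motif
model by expectation-maximisation at each width in 6–30 (every second
width by default), against a k-order Markov background
(`estimate_markov_background()`, order 2, pseudocount 0.1, single-strand
counting since UTR windows are oriented RNA).

Design choices that matter:

* **Seeding.** Random-site seeding gets trapped in poor optima; restarts
  are therefore seeded from the most over-represented exact w-mers in the
  corpus (plus one random-site start), and the converged model is refined
  by a ±1 column phase-shift hill-climb. In validation corpora this
  recovers a planted 8-mer exactly, at the planted register.
* **Significance.** The motif's log-likelihood ratio is calibrated against
  EM re-runs — same seeding, same restarts — on within-sequence shuffled
  copies of the corpus (`null_B = 10`), and the p-value is the upper
  t-tail of that null. An empirical rank p from a few hundred shuffles
  could never fall below the 10⁻⁴ reporting cutoff, so the tail is fitted;
  the optimisation bias of EM is charged to the null because the null gets
  the identical optimisation effort.
* **Monotonicity.** The M-step uses Dirichlet-pseudocount smoothing, i.e.
  a MAP update, so the quantity asserted non-decreasing at every iteration
  is the penalised (posterior) log-likelihood.

Discovered motifs are annotated against the element database
(`annotate_motifs()`) by the best log-odds alignment of the PWM to each
descriptor. Significance there is a self-calibrating permutation null: the
PWM's columns are order-shuffled and each column's probabilities permuted,
so an uninformative PWM is its own null and reports q ≈ 1. MEME's exact
E-value machinery, position priors and reverse-complement model are
non-goals; `write_meme_motifs()` emits minimal MEME-format text for
interoperability.

## Evidence layers

`tss_support()` classifies each retained five-prime call by whether its
genomic span lies between the gene's TSS and CDS start (strand-oriented),
with a tolerance — default 200 nt — extending the TSS boundary outward to
absorb approximate TSS mapping. Genes without a TSS record are reported
`no_tss`, and enlarging the tolerance can only move calls inward, never
outward.

`ortholog_support()` consumes an ortholog map and per-species retained-call
sets (it performs no orthology inference) and buckets each focal gene as
`multi` (≥ 2 supporting species–ortholog pairs), `single` (exactly 1) or
`none`, flagging genes whose support is exclusively from *Glossina*
species. The worked examples shipped in `inst/extdata` — a ferritin heavy
chain orthogroup supported across six species, and a lysozyme gene with a
single supporting ortholog — exercise both categories.

## The synthetic-data generator

`generate_dataset()` builds multi-contig genomes of single-CDS genes with
an even strand mix and plants, at recorded coordinates: canonical or
non-canonical IREs (via `make_ire_sequence()`, whose construction is
verified by round-trip through the geometry checker), UTR element
instances, an over-represented motif, TSS positions at known distances,
and ortholog-support categories. Defaults are the package's standard
validation conditions: 200 genes, 1000-nt flanks, GC 0.40 (a typical
AT-rich dipteran genome composition), one canonical IRE per gene in a
randomly chosen window, PAS/ARE/uORF planting rates of 0.3/0.2/0.3, an
8-mer motif at per-window rate 0.9, and TSS for half the genes at 100–900
nt upstream.

Each window is rejection-sampled so that no accidental loop anchor falls
within 30 nt of a plant and no unplanted anchor would survive the
retention filter; planted-truth recovery on such genomes is therefore an
exact test of recall and precision rather than a statistical one. What the
generator does **not** emulate: real genome composition beyond a GC dial
(an i.i.d. background, optionally dinucleotide-shuffled controls via
`dinucleotide_shuffle()`), transcript isoforms, polymorphism, sequencing
error, or realistic UTR length distributions. Passing the planted-truth
tests demonstrates the machinery is correct, not that real genomes contain
cleanly separable IREs — on real data the MEDIUM tier and the TSS layer
exist precisely because the signal is weaker.

## Numerical and procedural choices

* Coordinates are 1-based inclusive throughout the R API; BED output is
  0-based half-open as the format requires.
* Candidates whose potential hairpin extent contains `N` are dropped and
  logged; `N` never pairs and never matches an anchor.
* Tie-breaks are total and deterministic: geometry layouts by fewest
  defects → longest lower stem → bulge nearest the loop; per-gene best
  calls by HIGH > MEDIUM → fewer defects → 5'-most anchor.
* EM: relative LLR tolerance 10⁻⁶, iteration cap 60, γ clamped to
  (10⁻⁶, 1 − 10⁻⁶); all randomness runs inside a seeded RNG scope, so a
  seed fixes every byte of the output.
* Degenerate inputs: an empty genome or a zero-gene annotation produces an
  empty, schema-valid report; a zero or negative flank length fails
  configuration validation before any I/O.

## Problem sizes used in the test suite

The shipped tests validate folding against exhaustive enumeration on 200
random sequences (both wobble settings), planted-IRE recovery on five
200-gene genomes, anchor-rate calibration on 5 × 10⁵ positions, scanner
oracles on 100 random 1000-nt windows, Markov-background resampling at
10⁶ bases, and motif discovery across 25 planted and 20 null corpora of
50 × 200 nt. These sizes were chosen to make the statistical assertions
sharp at desk scale; all scale linearly if enlarged.

## Limitations

* The geometry grammar is this package's quantification of the IRE
  literature; the exact thresholds of earlier IRE scanners are not
  reproduced, and score classes are deterministic functions of defect
  counts rather than learned scores.
* Proxy windows ignore transcript structure: a flank may overlap a
  neighbouring gene (reported in a QC column, not masked) and need not be
  transcribed at all — that is what the TSS layer is for.
* Enrichment treats windows as exchangeable; it does not model covariates
  beyond the hit/no-hit dichotomy.
* The motif p-value is a calibrated tail estimate, suitable for the 10⁻⁴
  reporting gate, not an exact E-value.
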