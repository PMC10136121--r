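---
title: "Screening for rhodoquinone-based anaerobic mitochondria: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for rhodoquinone-based anaerobic mitochondria: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rqscreen)
```

## The biological question

Purely aerobic mitochondria hand electrons from NADH down the full electron
transport chain to oxygen, using ubiquinone (UQ) as the mobile carrier.
Facultatively anaerobic mitochondria, widespread among intertidal and
parasitic animals, can instead run part of the Krebs cycle backwards and
use fumarate as the terminal electron acceptor. That mode requires
rhodoquinone (RQ), a quinone whose amine group (in place of one of UQ's
methoxy groups) gives it a much stronger electron-donor potential.

RQ capability leaves a detectable trace in four proteins, each with one or
two diagnostic residues in C. elegans reference coordinates:

| marker | accession | diagnostic residue(s) | role |
|--------|-----------|----------------------|------|
| COQ-2  | NP_871684.1 | L204, S243 | alternative splicing of the quinone-biosynthesis enzyme; the two residues sit close to the substrate in the active site |
| MEV-1  | NP_001366681.1 | G71 | Complex II subunit; the residue lines the quinone-binding pocket that must dock both UQ and RQ |
| TDO-2  | NP_498284.1 | P133 | RQ synthesis pathway; part of the PLD loop required for activity |
| ETFDH  | NP_001379625.1 | F437 | direct RQ docking site; near the quinone binding site |

`default_panel()` encodes exactly these five sites. Given a proteome (or a
genome assembly) the package finds the best homolog of each marker, reads
the five positions through the alignment, and classifies the species; given
a published residue table it applies the same classification directly.

## Homolog search and residue calling

The search is a full dynamic-programming stand-in for a translated
database search: Smith–Waterman local alignment with affine gaps under
BLOSUM62 (as shipped with Biostrings), gap open −11 and gap extend −1 — the
conventional protein-search scoring. A gap of length $L$ scores
$g_{open} + (L-1)\,g_{ext}$. The ambiguity residue X scores 0 against
everything. There is no heuristic seeding, E-value model or banding: at
marker-protein scale exact DP is fast enough, and exactness is what the
test suite leans on (scores are checked against exhaustive enumeration
over all alignments on short sequences).

Determinism matters for reproducible screens, so ties are resolved by a
fixed rule: in the traceback, diagonal (substitution) beats a gap in the
target beats a gap in the reference; the local end cell is the first
best-scoring cell in row-major order; and among equal-scoring hits the one
with larger reference coverage, then the lexicographically smallest record
id, wins.

A hit is accepted when identity (identical columns over alignment columns)
is at least 0.30 and reference coverage at least 0.60 — conservative
homology-screen conventions, both overridable everywhere including the
command line. Each diagnostic position is then mapped through the
alignment: a position outside the aligned span or aligned to a gap is
`MISSING`; otherwise the observed target residue either equals the
anaerobic residue (`ANAEROBIC_MATCH`) or not (`VARIANT`). There is
deliberately no similarity grading of variants — a conservative
substitution still counts as a variant, since the published residue tables
treat it that way.

Nucleotide input is routed through six-frame translation under the
standard genetic code (`N` → `X`, other ambiguity codes rejected);
every stop-free peptide segment of at least 30 residues becomes a search
target and the best segment wins. The protein route and the six-frame
route agree on every synthetic input, which the tests assert as a
strand/frame-invariance property.

## Classification rules

Per species the five calls are reduced to counts
(`n_match`, `n_variant`, `n_missing`) and one label:

* `FULL_SIGNATURE` — all five sites match;
* `NO_SIGNATURE` — no match and nothing missing;
* `INSUFFICIENT_DATA` — no match but at least one site missing;
* `PARTIAL_SIGNATURE` — everything else.

The granularity is a package decision (the underlying survey literature
uses prose); the per-site counts are always reported so users can apply
their own rules. Missing cells (`"-"` in the TSV dialect) are kept
distinct from alignment gaps and are not interpreted as to cause: the
published table does not say whether a dash means "no homolog" or
"assembly gap", so the package represents both as missing and classifies
rows with missing sites as at most `PARTIAL_SIGNATURE`/`INSUFFICIENT_DATA`
rather than guessing.

On the packaged 18-species survey this yields exactly one cnidarian with
the full signature (*Nematostella vectensis*) and no cnidarian without any
signature — every cnidarian row carries the ETFDH match.

## Ancestral states

`fitch()` implements equal-cost, unordered small parsimony on a rooted
bifurcating tree: bottom-up intersection/union with the change count equal
to the number of unions, then a top-down pass that resolves each node's
preferred set by intersection with its parent's resolved set. Missing tips
(`"?"`) carry the full observed-state alphabet; tied state sets are
reported as sets and never arbitrarily resolved. Parsimony was chosen over
likelihood because the question — is a single anaerobic-capable common
ancestor with subsequent losses the simplest reading? — is a
minimum-change question, and because it needs no branch lengths, which the
candidate species trees do not agree on anyway. Topology is therefore user
input; `reconstruct_all()` makes it cheap to rerun over alternative
topologies. Unrooted binary trees are rooted deterministically at their
first tip (the parsimony length is unaffected); hard polytomies are
rejected rather than silently resolved, because equal-cost parsimony on a
polytomy is a different optimization problem.

In the recovery simulations we call a root state *recovered* when the
simulated state is among the maximum-parsimony root states. A stricter
definition (the root set is exactly the simulated singleton) would count
every tie as a failure, i.e. would penalize exactly the ambiguity the
reconstruction is designed to report honestly.

## Pathway energetics

`pathway_yield()` builds a redox-balanced ledger per mole of glucose for
three fermentation strategies. Homolactate fermentation and opine
formation both reduce 2 pyruvate to reoxidize the 2 glycolytic NADH: net
2 ATP. In malate dismutation, glycolysis stops at phosphoenolpyruvate;
PEP carboxykinase fixes CO~2~ to oxaloacetate, malate dehydrogenase
reoxidizes the cytosolic NADH, and mitochondrial malate is split between
an oxidative branch (to acetate, 2 NADH per malate) and a reductive branch
(fumarate reduction to succinate through the RQ-dependent truncated
chain, 1 NADH per fumarate). Closure of the mitochondrial NADH ledger
forces the 1:2 oxidized:reduced split computed by `dismutation_split()`.

The ATP terms are per-step coefficients, all user-overridable: +1 per PEP
at the carboxykinase step, +1 per acetate (substrate-level), +1 per
succinate carried on to propionate, and a chemiosmotic coefficient per
fumarate reduced. Two conventions deserve an explicit note:

* The carboxykinase is ATP-dependent in the direction written, yet the
  classical yield accounting of this pathway nets +1 ATP-equivalent at
  that step; the package follows the yield-generating convention and
  documents rather than resolves the discrepancy. Users who prefer the
  opposite sign can set `pepck_atp_per_pep` accordingly and will see the
  full ledger.
* The chemiosmotic coefficient's default of 0.75 ATP per fumarate reduced
  is a calibration: it is the value at which the default ledger reproduces
  the classical figures of 5 ATP/glucose for malate dismutation and a
  2.5-fold advantage over lactate fermentation. The literature reports the
  ratio, not a per-step proton ledger, so the package pins the free
  coefficient to the reported total and prints every term.

Succinate excretion (`reduced_end_product = "SUCCINATE"`) zeroes the
propionate term; propionate is the default because succinate is typically
converted further before excretion. All quantities are IEEE doubles; with
the default coefficients the thirds cancel exactly (net 5.0 and ratio 2.5
to machine precision) and reports render three decimals.

## The synthetic-data generator

Real genome screens cannot be reproduced at desk scale, so the generator
emulates the statistical structure the screen assumes: one homolog per
marker with the genotype's residues planted at the reference-mapped
positions, background divergence (i.i.d. substitutions; geometric-length
indels), and unrelated decoy proteins drawn i.i.d. from the reference
set's amino-acid composition. Reference stand-ins are random sequences of
realistic lengths (370/260/300/620 residues) with the anaerobic residues
planted — they are synthetic, and are labelled as such. By default indels
are kept out of a ±2-column window around each diagnostic site so that
position-mapping failures can be studied separately by setting
`protect_window = 0`. Genotypes evolve on a tree by per-branch,
per-site state toggling with a fixed flip probability — the simplest
gain/loss model.

What the generator does *not* emulate: realistic substitution processes
(no rate matrices or site heterogeneity), domain architecture or repeats
in decoys, paralogy, assembly fragmentation, or annotation error. Passing
the simulation suite therefore demonstrates the pipeline's correctness and
calibration under its own assumptions, not sensitivity on real genomes —
the published observation that one hydrozoan genome yielded no marker hits
at all is a reminder that real-data sensitivity is method- and
assembly-dependent.

Default study conditions used by the validation suite: 2% substitution
rate (roughly the within-phylum divergence at which diagnostic-residue
reads should be unproblematic), indel rate 0.005 where indels are studied,
10–20 decoys per proteome, 50 replicates for screen-level recovery, all 32
pure binary genotypes at zero noise, and 100 replicates of a 12-tip random
tree at branch flip probability 0.05 for root-state recovery. Observed
rates: 100% screen recovery at 2% substitution and with sparse indels, and
94% genotype-level root recovery (98.6% per site) under the
MPR-consistency definition above.

## Numerical and degenerate-input choices

* Gap convention: opening a gap costs `gap_open` for its first column and
  `gap_extend` for each further column; switching gap sides reopens.
* Scores are recomputable from the gapped strings
  (`alignment_score()`), and the tests assert this on every alignment
  they produce.
* An empty local alignment (no positive-scoring pair) has score 0 and NA
  spans; mapping through it yields an empty position map.
* FASTA parse errors name the offending line; matrix parse errors name
  line and site; Newick input is validated for balanced parentheses and
  duplicate tips before ape parses it.
* A character with fewer than two informative tips is an error, as is an
  all-missing character ("uninformative character").
* The command line maps condition classes to exit codes (0 success,
  2 usage, 3 parse, 4 degenerate data/threshold) and writes a provenance
  sidecar without timestamps so reruns are byte-identical.

## Worked example

```{r survey}
survey <- read_character_matrix(rq_survey_path())
res <- classify_matrix(survey)
res
res$profiles[["Hydra vulgaris"]]
```

```{r yield}
pathway_yield(pathway_spec("MALATE_DISMUTATION"))
yield_ratio(pathway_spec("MALATE_DISMUTATION"), pathway_spec("LACTATE"))
```

```{r ancestral}
cn <- gsub("[^A-Za-z]", "_", setdiff(rownames(survey), rq_reference_species))
tree <- ape::multi2di(read_newick(
  sprintf("((%s),Homo_sapiens);", paste(cn, collapse = ","))))
mat <- survey[c(setdiff(rownames(survey), rq_reference_species),
                "Homo sapiens"), ]
rownames(mat) <- gsub("[^A-Za-z]", "_", rownames(mat))
reconstruct_all(tree, mat, clade_tips = cn)
```

## Known limitations

* One best hit per marker: paralogs beyond the best hit are logged, not
  called, and ortholog/paralog disambiguation is out of scope.
* The screen cannot distinguish "gene absent" from "region unassembled";
  both surface as missing data.
* Parsimony reports minimum-change scenarios only; gains and losses of a
  complex trait are not equally likely in reality, and no attempt is made
  to model that asymmetry.
* The stoichiometric ledger is an accounting model — no kinetics, no
  thermodynamics, no flux balance — and its chemiosmotic coefficient is a
  calibration, not a measurement.
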