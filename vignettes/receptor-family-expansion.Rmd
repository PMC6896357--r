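---
title: "Methods: analysing massive receptor gene-family expansion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing massive receptor gene-family expansion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Nicotinic acetylcholine receptors (nAChRs) are pentameric ligand-gated ion
channels of the Cys-loop superfamily. Each subunit carries an extracellular
ligand-binding domain (LBD) with the Cys-loop signature — two cysteines
separated by exactly 13 residues — and a four-helix transmembrane channel
domain (NTM). While vertebrates and ecdysozoans hold their nAChR repertoires
at 10–30 subunit genes, some lophotrochozoan genomes, bivalve molluscs in
particular, carry repertoires an order of magnitude larger, produced by
retroposition (reverse-transcribed mRNA reinserted as an intronless
retrogene) and by tandem duplication (unequal crossing-over producing runs
of adjacent paralogs).

`nachrex` packages the comparative-genomics workflow used to characterize
such expansions: candidate calling from homology plus domain architecture,
exon–intron structure analysis, similarity clustering into families,
gene trees with bootstrap, ancestral family-size reconstruction on a
species tree, tandem-array detection, and expression classification. A
synthetic-cohort simulator with known event histories provides ground truth
for end-to-end validation.

# Candidate calling and architectures

A gene is accepted as a receptor candidate when (i) its best homology
e-value against a user-supplied receptor reference set is at or below a
threshold (default `1e-5`) and (ii) its domain architecture contains at
least one LBD or one NTM. The call records whether both domains or only one
were present, since inventories report that distinction. The architecture
string orders domain hits along the protein ("LBD-NTM",
"TM-LBD-NTM-TM", ...); overlapping same-label hits are merged when the
overlap covers at least 50% of the shorter hit — domain databases
frequently emit near-duplicate calls for one physical domain, and without a
merge rule a single LBD would be counted twice. The 50% value is a design
choice: small overlaps between genuinely tandem copies of a domain
(e.g. "LBD-LBD") must survive the merge.

Alpha subunits are called by the vicinal-cysteine criterion: an adjacent
`CC` dipeptide (loop C) inside the LBD, downstream of the Cys-loop. The
Cys-loop itself is located as the leftmost `C-X{13}-C` match, restricted to
the LBD interval when one is available. Binding-site conservation is an
exact residue comparison at caller-supplied alignment columns, with gaps
counted as mismatches.

# Intron structure and retrogene signatures

Introns are derived from the gaps between CDS segments, walked in
translation order (descending genomic coordinate on the minus strand). Each
intron carries a 0-based offset from the CDS start and a phase
(`offset mod 3`). Genes are classed `intronless` (0), `intron-poor` (1–2)
and `intron-rich` (>2); intronless genes are the retroposition signature,
and 1–2-intron genes are interpreted as retrogenes that subsequently gained
introns. Only CDS-interrupting introns are visible to this representation;
UTR introns are deliberately out of scope since the input is CDS segments.

For conserved-versus-novel calls, each intron is projected onto a shared
protein alignment: phase-0 introns anchor on the residue immediately before
the intron, phase-1/2 introns on the residue whose codon they interrupt. A
position is *conserved* when at least two distinct genes share the same
alignment column **and** phase; everything else is novel. Requiring the
phase to match is the conservative choice — a same-column/different-phase
pair cannot be one inherited intron. A `column_slack` relaxation is not
offered: zero tolerance is exactly testable, and on the no-indel simulator
any slack would only blur the ground truth.

In the arrayed-versus-single-copy contrast the "intron-poor" stratum means
at most two introns (intronless genes included), matching how
retrogene-derived copies are bulked when inventories compare tandem-arrayed
with single-copy receptors.

# Family clustering

Pairwise similarity is computed by local alignment (BLOSUM62, affine gap
open 11 / extend 1, via `Biostrings::pairwiseAlignment`) and converted to a
BLAST-style bitscore with the standard gapped Karlin–Altschul parameters
(lambda = 0.267, K = 0.041). The H-score normalizes the pairwise bitscore
by the smaller of the two self-scores,

$$H(a,b) = \frac{S(a,b)}{\min(S(a,a),\, S(b,b))},$$

symmetrized by taking the larger of the two alignment directions and
clipped to [0, 1]. This is the Treefam-style normalization: 1 for identical
sequences, monotonically decreasing with divergence, and insensitive to
protein length. Families are average-linkage clusters on the distance
`1 - H`, cut strictly below `1 - cutoff` (default cutoff 0.5). The strict
cut gives clean limiting behaviour: cutoff 1 isolates every gene even when
sequences are identical; cutoff 0 returns the connected components of the
positive-H graph. Gene identifiers are sorted before clustering so the
assignment cannot depend on input order. The 0.5 default is a package
default, not an empirical constant; on simulated cohorts at default
divergence the truth partition is recovered with adjusted Rand index 1.0,
and the cutoff is exposed for real data where family granularity is a
scientific decision.

A separate homology filter (percent identity strictly greater than 30) is
provided for edge-list style analyses; the strict inequality follows the
convention that 30.0% exactly is not homologous.

# Trees, bootstrap, ancestral counts

Gene trees use classical neighbor joining on p-distances (gap-excluded
pairwise fraction of differing residues; Poisson correction `-ln(1-p)`
optional). Negative branch lengths, which NJ can produce on non-additive
input, are clamped to zero with the deficit transferred to the sister edge,
preserving path lengths through the parent. Bootstrap support resamples
alignment columns with replacement, rebuilds the NJ tree per replicate, and
reports the percentage of replicates containing each internal bipartition;
the default is 1000 replicates and the resampling stream is fully
determined by the seed argument.

Ancestral family sizes on the species tree are reconstructed by linear
(Wagner) parsimony: Sankoff dynamic programming over integer states `0..max
leaf count` with branch cost `|parent - child|`. Ties are broken toward the
smaller count, a deliberate (and arbitrary) preference for losses over
gains that is applied consistently and documented here. Each branch is then
labelled expansion (+k), contraction (−k) or stable. This is a parsimony
summary, not a birth–death likelihood model: it has no rates, no branch
lengths, and cannot distinguish one large jump from many small ones. It is
chosen because it is exactly checkable against exhaustive enumeration and
has no tuning parameters.

The lineage-specificity statistic of a gene tree is the fraction of genes
inside maximal monophyletic same-species clades of size at least two — near
1 when paralogs cluster within species (expansion after speciation), 0 when
orthologs interleave.

# Tandem arrays

A tandem array is a maximal run of target genes along one scaffold in which
each adjacent member pair is separated by at most `max_intervening`
non-member genes (default 1 — real annotations nest unrelated genes inside
arrays, while large values dissolve the concept; the value is recorded with
every run). Strand is ignored: tandem duplicates commonly invert. Two
target modes exist: `family` (members must share a family; a target gene of
another family counts as intervening) and `geneset` (the whole candidate
set is one pool), the latter matching how whole-repertoire array
inventories are tabulated. Runs of one gene are discarded, membership is a
partition, and the size histogram's total is asserted on every run.

# Expression

RPKM is `count x 1e9 / (length_bp x library_size)`; the package implements
RPKM rather than TPM because the low-expression rule it applies — a gene is
"low expressed" when *every* sample is below 1 RPKM — is defined on that
scale (a TPM column can be derived by the caller). Low expression in all
samples is the pseudogene signature used in the intron-class contrast.
Specificity is the tau index, `sum(1 - x_i/max x)/(n-1)`: 0 for uniform
profiles, 1 for single-sample expression, invariant to rescaling. The
reporting thresholds (tau at least 0.8, peak at least 10 RPKM for calling a
gene "specifically expressed") are configurable report cosmetics and are
never used in any validation. Heat-map export is `log2(RPKM+1)` with
optional per-row z-scores; plotting is left to the caller.

# The synthetic cohort

The simulator is the package's reference instrument, not a fixture. Root
families start with intron-rich genes (3–9 introns, uniform) and a shared
family protein; genes then evolve along the species tree:

* **tandem duplication** (rate 0.3 per gene per branch-length unit) copies
  the parent's CDS-segment structure and inserts the copy immediately after
  the parent on the same scaffold;
* **retroposition** (rate 0.25) creates a single-segment, zero-intron copy
  at a uniformly random genome position; 30% of retrocopies are born
  pseudogenized;
* **intron gain** (rate 0.08) inserts an intron at a uniformly random CDS
  offset, by default only on retrocopy lineages — whether ancestral
  intron-rich genes also gain introns is an explicit switch
  (`intron_gain_on_ancestral`), off by default so the retrogene signal
  stays interpretable;
* **gene loss** (rate 0.03) removes a gene;
* proteins evolve by i.i.d. per-site substitution (probability 0.06 per
  site per branch-length unit), with no indels, so percent identity is a
  clean monotone proxy for divergence and every family is trivially
  alignable.

These defaults were chosen once as a modest bivalve-like regime — enough
events on unit branches that every event type appears in a cohort of ~100
genes, with within-family identity staying far above the between-family
background — and are not revisited per analysis. Expression counts use a
lognormal baseline on a random "on" sample subset; pseudogene counts are
drawn strictly below the 1-RPKM line for their gene length and library
size, so the low-expression rule has recall 1 by construction, and
expressed genes are drawn strictly above it, so precision is 1 on clean
simulations. What the simulator does *not* emulate — indels, codon-level
selection, rearrangements, alternative splicing, UTR introns, mapping noise
in expression — bounds what passing tests can claim about real data: they
validate the operations' logic and their composition, not robustness to
annotation error.

The built-in `bivalve_expansion` scenario (fixed seed) contrasts two sister
ingroup species carrying elevated tandem + retroposition rates with an
outgroup carrying none (per-species rate multipliers; a branch uses the
mean multiplier of its descendant species). Because the shared ingroup
branch is also elevated, part of the expansion predates the ingroup split;
the resulting cross-species ortholog pairs legitimately depress the
lineage-specificity statistic, which pools to roughly 0.5–0.7 on this
scenario versus exactly 0 for a no-expansion cohort. The validation
threshold (>0.4, and above the matched no-expansion baseline) was frozen
from that derivation.

# Numerical and degenerate-input conventions

* Coordinates: genomic and protein 1-based inclusive; intron CDS offsets
  0-based. CDS segments are stored in ascending genomic order regardless of
  strand; translation order is derived from strand at use sites.
* Multi-transcript genes collapse to the longest-CDS transcript (analyses
  count genes); a CDS length not divisible by 3 sets a flag rather than
  erroring.
* Percentages are reported to one decimal via `round(x, 1)`.
* Duplicate BLAST rows keep the best bitscore; missing pairs score H = 0;
  a missing or zero self-score is an error, not a silent 1.
* Empty inputs return empty outputs (empty architecture, empty family
  assignment, zero-row array table); parse errors name the offending line.
* Tie-breaks are deterministic everywhere: hit ordering by start/end/label,
  transcript choice by id, parsimony ties toward the smaller count, family
  renumbering by sorted gene id.

# Problem sizes used in validation

The shipped test-suite and validation runs use cohorts of roughly 100–150
genes over 3 species, 8 root families, 150-aa proteins, 10 replicate seeds
for recovery statistics, 50 random trees for additive-matrix recovery, and
100–1000 bootstrap replicates; these sizes make every brute-force oracle
(exhaustive alignment DP, O(n^3) clustering recomputation, exhaustive
parsimony enumeration) exact and fast while exercising every event type.

# Known limitations

* The H-score normalization is one of several in use; with the bitscore
  floor at zero, very short or very divergent pairs can saturate at 0.
* Wagner parsimony has no branch-length awareness; rapid expansions on
  short terminal branches cost the same as slow ones on long branches.
* The tandem detector's intervening-gene tolerance interacts with
  annotation completeness on real data; the recorded per-run parameter is
  the only defence.
* `lineage_specificity` is rooting-sensitive; gene trees from NJ should be
  rooted (e.g. with an outgroup gene) before interpretation.
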