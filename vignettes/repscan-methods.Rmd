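---
title: "Methods: structure-based initiator-family delineation and bipartite origin detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structure-based initiator-family delineation and bipartite origin detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`repscan` implements a desk-scale version of two analyses used to
characterize rolling-circle replication (RCR) initiator proteins of the
kind encoded by haloarchaeal pleolipoviruses and their relatives:

1. **Family delineation by predicted-structure comparison** — sequence
   redundancy filtering, a model-confidence (pLDDT) gate, all-vs-all
   TM-score comparison of domains, block delineation on the similarity
   matrix, nearest-family ranking, and a structural-alphabet dendrogram
   (UPGMA with column-bootstrap supports).
2. **Bipartite origin detection** — locating the upstream inverted repeat
   (the initiator *bind* site) and the distal hairpin (the *nick* site)
   downstream of the rep ORF, and classifying the structural effect of
   substitution series on those elements.

Both analyses are driven by a synthetic-data generator with known ground
truth, so every stage is testable without downloading structure models or
genome sequences. Real PDB/mmCIF models and FASTA/GFF3 replicons can be
substituted at any stage through the same readers.

# Sequence redundancy filtering

Pairwise identity uses a global alignment with free terminal gaps
(match +1, mismatch -1, a gap of length $k$ costs $5 + k$). Identity is
the fraction of identical pairs over aligned columns between the first
and last aligned pair; coverage of each sequence is the fraction of its
residues inside that region. Greedy clustering sorts records by
decreasing length (ties by identifier), makes the first unassigned
record a representative, and joins each later record to the first
representative reaching both thresholds. Coverage is **bidirectional**
(the minimum of both coverages) — the stricter reading of "identity over
a fraction of protein length"; with one-sided coverage a short fragment
could join a long representative it barely covers.

The model-confidence gate retains structures with mean pLDDT strictly
greater than 70. Structures without pLDDT (experimental models) pass
with a warning: they carry no model-confidence estimate to filter on.

# Rigid-body superposition and TM-score

Superposition is the least-squares Kabsch fit (SVD with the sign
correction that excludes reflections). The TM-score of a correspondence
of aligned pairs with distances $d_i$ is

$$\mathrm{TM} = \frac{1}{L_{\mathrm{norm}}} \sum_i
  \frac{1}{1 + (d_i/d_0)^2},\qquad
  d_0 = 1.24\,(L_{\mathrm{norm}} - 15)^{1/3} - 1.8\ \text{Å},$$

with $d_0$ floored at 0.5 Å (the floor also covers
$L_{\mathrm{norm}} < 16$, where the formula is undefined or negative).
The score is evaluated in the superposition that *maximizes* it, found by
iterative subset refinement: superpose on a subset, collect the pairs
within a distance cutoff, repeat until stable, starting from several
contiguous fragments (and, for correspondences of at most 10 pairs, from
every 3-subset, which makes the evaluation effectively exact at that
scale). Default normalization is by the target (second) chain; `shorter`
is available as an option.

The alignment search is TM-align-like: correspondences are seeded by
gapless threading at every offset and by fragment pairs (length-8
windows, stride 4; the stride degenerates to 1 when a chain is shorter
than the window), and each seed alternates (superpose) →
(Needleman–Wunsch on $S_{ij} = 1/(1 + (d_{ij}/d_0)^2)$ with linear gap
penalty $-0.6$ and free terminal gaps) until the correspondence is
stable. The best final TM-score wins; ties keep the earliest seed, so
the search is deterministic. Because the refinement map is a
deterministic function of the correspondence, transitions are cached and
shared between seeds.

For chains of at most 12 residues the search is finished by hill-climbing
directly on the TM objective (add, drop, or move one pair, keeping
monotonicity; for chains of at most 8 residues every size-3 monotone
correspondence is also a start). The NW stage's gap penalty refuses
gapped correspondences whose TM gain is smaller than the penalty — a
correct trade at protein scale, but at oracle scale (where tests compare
against exhaustive enumeration over all monotone correspondences) those
small gains matter. The finishing stage is size-gated and does not touch
protein-scale behavior or runtime.

The all-vs-all similarity matrix stores
$\tfrac{1}{2}[\mathrm{TM}(i{\to}j) + \mathrm{TM}(j{\to}i)]$ (both
normalized by the target), which removes the normalization asymmetry for
unequal lengths; the matrix is symmetric by construction with unit
diagonal. This package does not aim to reproduce TM-align's exact
alignments on real proteins — only score-level agreement is targeted.

# The geometric structural alphabet

Trained structural alphabets (such as the 20-state alphabet used by
structure search tools) embed a learned model; this package instead uses
a fully specified geometric alphabet. Each interior residue $i$
($3 \le i \le L-1$) is described by the CA pseudo bond angle $\theta_i$
at $(i{-}1, i, i{+}1)$ and the pseudo dihedral $\tau_i$ over
$(i{-}2, \dots, i{+}1)$, discretized as

* $\theta$: $[0°, 90°)$, $[90°, 105°)$, $[105°, 120°)$, $[120°, 180°]$
* $\tau$: $[-180°, -90°)$, $[-90°, 0°)$, $[0°, 90°)$, $[90°, 180°)$

giving 16 states `A`–`P` (state = $4\,\mathrm{bin}(\theta) +
\mathrm{bin}(\tau)$); the two leading and one trailing residue are `X`
(undefined). The alphabet is exactly invariant under rigid motion. An
ideal helix ($\theta \approx 92°$, $\tau \approx +50°$) encodes as a
constant `G`.

**Noise sensitivity.** The $\theta$ bins near the helical region are 15°
wide, while per-atom coordinate noise of scale $\sigma$ perturbs
$\theta$ by roughly $\sqrt{2}\,\sigma/r$ radians per arm (bond length
$r = 3.8$ Å). At the generator's default $\sigma = 0.8$ Å this exceeds
the bin width, so the encoded state of a helical residue is close to
random across family members and the alphabet retains only a weak family
signal (carried mostly by loop geometry). The consequence, computed by
the acceptance checks, is that within-family bootstrap supports of the
structural dendrogram stay well below 95% at the default noise even
though the TM-score analysis separates the families perfectly. At
$\sigma \le 0.4$ Å the alphabet signal survives and the dendrogram
recovers every family as a monophyletic clade with full support — the
regime the property tests certify. The alphabet tree should therefore be
read as corroborating evidence at moderate model noise, with the
TM-score matrix carrying the primary classification.

# Structural-string alignment and dendrogram

Progressive alignment uses the identity substitution matrix (1 for equal
states, 0 otherwise, `X` scoring 0 against everything) with affine gaps:
extension fixed at 0.1 (the one parameter the source protocol fixes),
opening exposed as a sensitivity knob with function default 1.0. Guide
distances are $1 -$ (shared 3-mer fraction, normalized by the smaller
3-mer set); the guide tree is UPGMA on those distances; profiles are
merged with column score equal to the expected identity (dot product of
state frequencies), tie-breaking diagonal first. **The pipeline default
for gap opening is 5.0**: identity scores are capped at 1 per column, so
an opening cost of 1.0 barely penalizes a gap and fragments alignments of
noisy strings; with equal-length backbones the stiffer penalty yields the
near-rigid alignments the p-distance expects. Plain progressive
alignment is used — no sequence weighting or divergent-row deferral as in
full ClustalW.

UPGMA joins the cluster pair with minimal average linkage; the new node
sits at half the joining distance (heights in the same units as the
distance), and ties are broken by the lexicographically smallest pair of
cluster labels (a cluster's label is its smallest leaf label), making
the topology deterministic. Bootstrap supports resample alignment
columns with replacement; the distance is the p-distance (mismatch
fraction over columns where neither row has a gap or `X`; among the
distances a dendrogram program could use, the p-distance is the simplest
and is stated here as our choice). The support of an internal node is
the percentage of replicate trees containing the same leaf clade. Rows
are sorted by identifier before any sampling, so supports are invariant
to input order. Inside replicates a row pair can lose all comparable
columns; its distance is then set to the maximum (1) rather than
erroring, which would abort a replicate for a sampling accident.

# Blocks, agreement and nearest family

"Similarity blocks" of a clustered heatmap are given an operational
definition: average-linkage (UPGMA) clustering of $1 - \mathrm{TM}$, cut
at the height maximizing the mean silhouette width over candidate cut
heights (midpoints between consecutive merge heights, $2 \le k \le
n-1$ clusters; ties prefer fewer blocks). This definition is our
construction — the visual blocks of a heatmap imply no unique threshold.
Agreement with the true family labels is scored by the adjusted Rand
index (contingency closed form) and purity. Nearest-family ranking sorts
the other families by mean symmetrized TM to the query family, ties
alphabetical.

# Sequence-logo conservation and catalytic sites

Per column over $n$ non-gap residues with frequencies $p_a$:
$H = -\sum_a p_a \log_2 p_a$ and information content
$IC = \log_2 20 - H - e_n$ with the small-sample correction
$e_n = 19/(2 n \ln 2)$, floored at 0 (the correction is applied by
default, as logo tools do, and can be disabled; at very small $n$ it
exceeds $\log_2 20$ and the floor dominates). Letter heights are
$p_a \cdot IC$. Motif search supports patterns over letters and `x`
(any residue), with overlapping hits reported. Catalytic-site checks map
1-based positions in an ungapped reference sequence through the
reference row's gaps to alignment columns and report the fraction of
rows carrying the expected residue (gaps excluded).

# The bipartite origin model

**Inverted repeats.** All maximal IRs with arm length $\ge$ `min_arm`
(default 4), spacer $\le$ `max_spacer` (default 10) and at most
`max_mismatch` (default 1) arm mismatches are reported, sorted by arm
length then position. A repeat whose span lies inside the span of a
strictly longer-armed reported repeat is suppressed as a sub-repeat;
equal-armed repeats never suppress each other, which keeps the output
exactly mirror-symmetric under reverse complement.

**Hairpin folding.** Full thermodynamic folding is replaced by a
maximum-weight nested-pairing dynamic program with weights GC = 3,
AU = 2, GU = 1 and minimum loop 3 (a pair $(i, j)$ requires
$j - i \ge 4$); the origin analysis uses only stem/loop topology, which
this model preserves. The scanner's default restricts structures to a
single helix with one terminal loop (bulges allowed, no bifurcation);
general nested folding with bifurcation is available. Co-optimal ties
resolve to the structure whose outermost pair is most 5'.

**Scanning.** The window downstream of the rep ORF stop codon (default
270 nt, matching the intergenic region the model organism provides) is
searched for candidate (IR, hairpin) pairs: hairpin nuclei are perfect
complementary stems (arm $\ge 4$, spacer $\le 10$ — spacer-0 palindromes
included, since folding re-imposes the minimum loop), the folded hairpin
must score at least `min_score` (default 12, the score of the weakest
all-AT planted stem), and the gap from IR end to hairpin start must be
at most `max_gap` (default 40 nt, covering the 9-nt spacing of the model
layout). Candidates are ranked by composite score = hairpin score + IR
arm length − IR mismatches. Coordinates are reported 1-based relative to
the first nucleotide after the stop codon, with absolute coordinates
alongside. Minus-strand ORFs are handled by scanning the reverse
complement and mirroring coordinates.

A 270-nt i.i.d. background contains many admissible pairs (tens of
candidates per replicon is typical), and the composite score does not —
and cannot — always rank the planted pair first: random stems with
several G–C pairs outscore a planted stem of average composition.
*Recovery* therefore means detection: some reported candidate overlaps
both planted elements. Under that definition recovery is 100% across
seeded replicons; the ranked list is a prioritization, not a verdict.

**Mutation classes.** Substitutions are classified against an origin
element: hits on stem positions are re-paired (all affected pairs still
Watson–Crick or GU ⇒ `structure_preserving`, else `stem_disrupt`); hits
entirely inside the loop are `loop_mutation`; hits inside IR arms
re-check dyad symmetry (`symmetry_preserving` if the arm-mismatch count
does not increase, else `symmetry_disrupting`); anything else is `none`.
Note that a C→T change at a G–C stem position leaves a G·T wobble and is
classified preserving — by design, since the folding model accepts GU.

**The canonical mutation fixture.** The published substitution series
references region positions 186–197 with the compensatory pair 188↔195.
Inside the conserved span 176–197, the only hairpin layout with
188 paired to 195 is a 4-bp stem at 186–189/194–197 around the loop
190–193 (a reflection argument: paired positions must sum to 383). The
package ships this layout as a canonical synthetic element — base
identities at the mutated sites match the published reference alleles,
all other positions are filler, since the true region sequence is not in
the public main text. The generator's default planted hairpin (6-bp
stem at the start of the span) is used for recovery statistics; the
canonical element is used for mutation classification. The IR default
span follows the main text (156–166; a figure legend says 152–166, and
the main text is taken as authoritative).

# The synthetic-data generator

* **Protein families.** One rigid scaffold per family: alternating ideal
  helical segments (CA–CA 3.8 Å, $\theta = 92°$, $\tau = +50°$; segment
  length 4–8) and random turns (length 3–6, $\theta \in [100°, 140°]$,
  $\tau$ uniform), self-avoiding by rejection (no CA pair under 3 Å).
  Scaffolds are kept loop-rich deliberately: all families share ideal
  helix geometry, so in the structural alphabet the family signature
  lives in the loops. Members apply a uniformly random rigid motion
  (quaternion method), per-atom isotropic Gaussian noise
  ($\sigma = 0.8$ Å default), substitutions at rate 0.3 with uniform
  replacement over the 20 residues, and sequence-only indels at rate
  0.02 — structures keep the template length so true correspondences
  remain known and can serve as alignment oracles (testability over
  realism). A `related_pair` option derives one family's scaffold from
  another's by coordinate noise (1.5 Å default), planting a known
  nearest-family relationship.
* **Replicons.** A rep ORF (ATG + random non-stop codons + TAA, 1200 nt
  default) followed by a 270-nt noncoding region with an exact IR
  filling positions 156–166 (4-bp arms, 3-nt spacer) and a perfect
  hairpin (6-bp stem, 4-nt loop) planted at the start of 176–197; all
  other positions i.i.d. uniform.

What the generator does **not** emulate: realistic protein energetics or
secondary-structure statistics, evolutionary substitution models (the
sequence divergence is uniform), compositional bias of real intergenic
DNA, and hairpins/IRs embedded in conserved context rather than i.i.d.
background. Passing tests therefore demonstrate the pipeline's
correctness and its behavior under controlled signal/noise, not its
error rates on real genomic data.

All generators are pure functions of their seed. One global seed fans
out to per-stage seeds by stable string hashing of stage names, so
adding a stage never shifts another stage's randomness.

# Problem sizes and numerical choices

The shipped analyses and acceptance checks use: 5 families × 4 members
of 120 residues (the similarity matrix and dendrogram), 200 bootstrap
replicates (the protocol's 1500 scaled to desk size), 10 datasets of
4 families × 3 members of 100 residues (nearest-family recovery), and
50 replicons (origin recovery). Kabsch degeneracy (fewer than 3 points,
collinear configurations) is an error; TM ties keep the earliest seed;
UPGMA ties follow the lexicographic label rule; folding ties keep the
most-5' outermost pair; all-gap logo columns are flagged with IC 0.

# Known limitations

* The structural dendrogram loses family resolution at the generator's
  default coordinate noise (see the alphabet section); the TM-score
  matrix is the robust classifier.
* The alignment heuristic targets score-level agreement, not exact
  reproduction of reference-tool alignments on real proteins.
* The folding model ignores stacking thermodynamics; scores are not free
  energies.
* mmCIF support is minimal (`atom_site` loop only); multi-model NMR
  entries and ligands are out of scope.
* The origin scanner's candidate list on random background is long by
  design; on real replicons conservation across related genomes, not the
  composite score alone, should prioritize candidates.
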