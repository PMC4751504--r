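---
title: "Methods: models and design choices behind ap2erf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models and design choices behind ap2erf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`ap2erf` characterizes an AP2/EREBP-like transcription-factor superfamily
genome-wide: it discovers family members from a proteome by profile
scanning and similarity search, collapses splice variants, classifies
domain architectures into the AP2 / RAV / DREB–ERF subfamilies, resolves
the DREB/ERF split phylogenetically, names members by chromosomal order,
detects tandem and segmental duplications, maps orthologs through synteny
blocks, calls stress-responsive differential expression with a SAM-style
permutation FDR, and classifies duplicate-pair expression divergence. A
synthetic-study generator plants ground truth for every one of those
stages, so the whole pipeline is testable without any external download.

This vignette documents the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

# Domain discovery: the PSSM scan

## The model

A `DomainProfile` is a position-specific scoring matrix built from a
domain seed alignment (e.g. an AP2 seed). Columns with at least 50% gaps
are dropped; each retained match column $i$ scores residue $a$ as

$$ s_{i,a} = \log_2 \frac{(c_{i,a} + 0.1)/(n_i + 2.1)}{b_a}, $$

with $c_{i,a}$ the residue count in the column, $n_i$ the column depth,
and $b_a$ the overall seed residue frequency under the same add-0.1
pseudocounting (0.1 for each of 21 symbols — the 20 amino acids plus X —
hence 2.1). The X column is pinned to zero so unknown residues are
score-neutral. A gapless PSSM was chosen over a profile HMM deliberately:
the downstream classification needs the presence, count and position of
domains, not alignment detail, and a PSSM is an order of magnitude
simpler to specify, calibrate and test exhaustively.

Scanning slides the profile across the protein. Placements that hang off
either sequence end are allowed while they still cover at least half the
profile columns (or the whole sequence, when the sequence is shorter than
half the profile); these are flagged `truncated` and can never count as a
"complete" domain during architecture classification. The half-profile
floor matters: without it, one- or two-column end placements with a lucky
positive score would litter every scan with junk truncated hits.
Candidate placements with positive score are accepted greedily,
best-score-first, discarding any placement overlapping an accepted one by
more than $L/2$ residues — so two genuine domain copies separated by a
linker are both kept, while jittered variants of one hit are not.

## Significance

E-values come from a shuffle calibration: `calibrateNull()` draws
sequences i.i.d. from the profile background, records each sequence's
maximum placement score, and fits a Gumbel distribution by the method of
moments ($\beta = s\sqrt 6/\pi$, $\mu = \bar x - \gamma\beta$). Method of
moments was preferred over maximum likelihood because it is closed-form,
deterministic, and accurate enough at the default 500 shuffles for a
retention rule as loose as $E < 1$; the fitted null and the raw shuffle
scores are both kept on the object so the fit can be audited. The E-value
of a score $s$ against a database of $D$ sequences is
$D\,(1 - \exp(-e^{-(s-\mu)/\beta}))$, with $D$ set to the number of
scanned proteins. Calibration length defaults to the mean scanned-protein
length, since the null maximum grows with the number of windows.

A consequence worth knowing: the background is estimated *from the seed*.
If the seed is tiny, residues absent from it get inflated log-odds, and
sequences drawn from a different composition (e.g. uniform) can score
spuriously well. Seeds of a dozen sequences over 50+ columns, as the
generator produces, are comfortably past this regime; single-digit seeds
over short domains are not, which is why `buildProfile()` refuses fewer
than five sequences and a profile length below 10.

# Family identification

Candidates enter by either of two routes: (a) a profile hit with
$E < 1.0$ — the classical retention threshold for this family — or (b) a
local alignment to a known family query reaching 40% identity over 60%
coverage. Route-(b)-only proteins are scanned anyway, so every candidate
carries a hit list and a protein with strong whole-sequence similarity
but no detectable domain is excluded later as `no_domain` rather than
kept — the behaviour matching how published surveys discard such genes.

Splice variants are collapsed to one protein per gene by keeping the
longest isoform (ties: lexicographically smallest protein id). Published
surveys report discarding variants without stating a rule; "longest
isoform" is the field's de-facto convention and is deterministic. The
exclusion filter then mirrors the manual curation such surveys describe:
`short_domain` when the best family-domain hit covers less than half the
profile, `divergent_domain` when it misses the E threshold, `no_domain`
when there is no hit. All thresholds are explicit `identifyParams()`
knobs, and every excluded protein is reported with its reason so the
"manual review" step stays visible instead of silent.

Architectures map to subfamilies as: two complete (non-truncated) AP2
domains → AP2; one AP2 plus a B3 domain → RAV; exactly one AP2 →
DREB/ERF, unresolved until phylogeny. Three or more AP2 hits classify as
AP2 with a warning. Names are assigned within each subfamily by
chromosome (natural numeric order on the trailing integer, so Bd1 < Bd2 <
Bd10), then gene start, end and id: `<prefix><SUBFAMILY>-<k>`.

# Phylogeny

## Profile-anchored alignment

Instead of a general-purpose aligner, member domain regions are each
globally aligned to the profile consensus (BLOSUM62, gap open 10 / extend
0.5 — EMBOSS-needle-like defaults used everywhere in the package) and
projected onto the L match columns: insertions relative to the consensus
are discarded, deletions become gaps. Column homology is thus inherited
from the profile, the alignment is deterministic and dependency-free, and
NJ operates on match columns only. The cost is that insertion signal is
invisible to the tree — acceptable for a domain family whose homologous
core is the profile itself. Rows occupying under 30% of columns are
dropped with a warning.

## Distances, NJ, bootstrap

Distances default to the p-distance with pairwise deletion (compared
sites are columns where both rows have residues); a Poisson-corrected
variant ($-\ln(1-p)$) is available behind the `model` option, because the
distance model used by the classical MEGA workflow this emulates is not
standardized. Trees come from a canonical Saitou–Nei neighbor joining:
join the pair minimizing $Q(i,j) = (n-2)d(i,j) - r_i - r_j$, ties broken
by the smallest index pair; standard branch-length and reduction
formulas; negative branch lengths clamped to zero with the raw tree
retained in `attr(tree, "rawTree")`. The implementation is validated two
independent ways in the tests: topology recovery on additive matrices,
and exact agreement (topology and branch lengths) with a separately coded
plain-loop transcription of the formulas, with `ape::nj` as a third-party
topology cross-check.

Bootstrap supports resample alignment *columns* with replacement
(B = 1000 by default; the pipeline default is 200 to keep runs snappy),
rebuild the NJ tree per replicate, and count replicates containing each
internal-edge bipartition of the full-data tree. Supports are stored as
integer counts with B recorded, leaving percentage display to the caller.
`bootstrapSupport()` sorts rows by id before anything else: p-distances
on finite alignments are ratios of small integers, ties in $Q$ are
common, and the index tie-break would otherwise let the caller's row
order leak into tied joins — canonicalizing makes supports a function of
the alignment content alone.

## Group labels

DREB vs ERF (and any finer subgroup scheme) is decided by anchoring:
labelled reference domains are included in the alignment, and each query
leaf takes the label of the smallest bipartition side containing it and
at least one anchor — if all anchors in that side agree. Mixed-anchor
sides leave the query `unclassified`; groups are never forced, matching
how published analyses leave aberrant members unplaced. An anchor leaf
trivially keeps its own label.

# Duplications and orthologs

All pairwise alignment metrics share one vocabulary: **identity** =
identical aligned residue pairs / aligned residue pairs; **similarity** =
aligned pairs with positive BLOSUM62 score / aligned pairs (classic
percent-similar); **coverage** = aligned pairs / length of the longer
sequence. Coverage against the *longer* sequence is the conservative
reading of a "sequence matching length" criterion. Because the published
wording of "similarity" is ambiguous, `dupParams(metric=)` can swap the
thresholded quantity between similarity and identity; both are always
reported.

Tandem clusters are connected components of a graph over family members
with edges requiring: same chromosome; at most one intervening gene in
the *full annotation's* gene order (not just family members — the
published rule counts all genes); and similarity/coverage above
threshold. Two modes exist side by side: relaxed uses the published
40%/60% thresholds; stringent (70%/80%) stands in for the unrestated
criteria of the original authors' earlier work and is the default.
Relaxed events are a superset of stringent events by construction.
Segmental pairs must sit in one intra-species synteny block (as anchors
or inside its two regions), pass the same thresholds, and not already
share a tandem cluster. Ortholog mapping is purely block-driven: every
cross-species block anchoring a member yields one row, so a duplicated
pair can legitimately map to the same ortholog.

# Expression

RPKM is the textbook
$\mathrm{rpkm} = 10^9 c_{gs} / (\ell_g N_s)$ with $\ell_g$ the exon
length of the gene's longest transcript. Tissue profiles are
$\log_2(\mathrm{RPKM} + 1)$ averaged over replicates on the log scale.
Probe retention follows the strict published rule: zero mismatches,
unique genomic hit, exonic, unique target gene.

Differential expression per stress × timepoint contrast uses the
SAM-style moderated statistic $d = (\bar x_s - \bar x_c)/(s + s_0)$ with
the two-sample pooled standard error $s$ and fudge factor $s_0$; $s_0$
defaults to the median pooled SE of the contrast (the full SAM quantile
search is out of scope; the knob is exposed, with a $10^{-8}$ floor so
degenerate zero-variance genes stay finite). Significance is by balanced
label permutation: when the number of distinct splits
$\binom{n_1+n_2}{n_1}$ is at most `nPermutations` (it is 70 for the
default 4 vs 4 design) all splits are enumerated exactly — deterministic
and strictly better than sampling; otherwise seeded random splits are
drawn. For threshold $t = |d_g|$, FDR$(g)$ is the median over
permutations of the null exceedance count divided by the observed count,
and $q(g)$ is the minimum FDR over thresholds $t' \le |d_g|$, which makes
q monotone non-increasing in $|d|$ and capped at 1. No $\pi_0$
multiplier is applied, keeping the estimate conservative.

A call is `up` iff $\log_2\mathrm{FC} > 1$ **and** $q \le 0.05$ (and
symmetrically `down`). Whether the published analysis gated on both
jointly or on fold change alone is ambiguous; both-gates is the default
and `fcOnly` switches to the fold-change-only reading. Contrasts with
fewer than one degree of freedom per group cannot be permuted: they fall
back to fold-change-only calls with `NA` q-values and a loud `FALLBACK`
warning, since array series of this design era often lack replication.

Divergence of duplicate pairs is the Pearson correlation of the two
genes' log2 fold-change profiles across the stress × timepoint grid (20
points under the default 4 × 5 design), on pairwise-complete points.
PCC ≥ 0.5 → subfunctionalization, the published threshold. The published
analysis names no numeric neofunctionalization cutoff — it discusses
negative and near-zero correlations — so the default `neoMaxPcc = 0.1`
reproduces the discussed pairs at −0.491 and 0.002 while deliberately
leaving 0.361 unclassified rather than forcing it; the cutoff is a
parameter. Pairs with fewer than 10 complete points are unclassified
with a reason.

# The synthetic study

The generator's defaults *are* the study conditions every test and the
acceptance script run under; they are chosen once, not tuned:

* 5 chromosomes, 200 decoy genes, ~60 members (12 AP2, 8 RAV, 20 DREB,
  20 ERF) — the size regime of a real AP2/EREBP survey, desk-scale.
* domains of 60 (AP2-like) and 50 (B3-like) residues; planted copies
  mutated at 5% per site; the DREB and ERF domain variants sit 25% from
  the base consensus so the subfamilies are separable but still
  comfortably detected by one AP2 profile.
* seed alignments of 12 sequences at 15% divergence, plus both variants,
  so the profile background covers the alphabet.
* tandem clusters of 3 and 2 genes at target identities 0.85 and 0.80,
  built by duplicating a founder with i.i.d. substitutions and a
  rejection loop that re-mutates until the measured global-alignment
  identity lands within ±0.03 of target (unattainable targets error out
  rather than drift); adjacency planted with 0 or 1 intervening decoys.
  Substitution-only duplication keeps the identity arithmetic exact; no
  indels are planted inside domains.
* 20% of member genes emit a truncated (75%) second isoform that retains
  the domains, so variant collapse is actually exercised.
* expression: baseline $\log_2$ abundance Normal(5, 1); 4 stresses ×
  {1, 2, 5, 10, 24} h × 4 replicates, with per-timepoint control
  replicates; replicate noise SD 0.5 — a typical array spread; planted
  effects of ±2 log2 units on 40% of non-duplicated members.
* correlated duplicate pairs by latent mixing: founder effect profile
  $e_a$ is Normal(0, $\sigma_e^2$) over the grid; the partner gets
  $e_b = \tilde\rho\, e_a + \sqrt{1-\tilde\rho^2}\, e'$. Observed fold
  changes add mean-difference noise with variance $2\sigma^2/R$, so the
  expected observed correlation is
  $\tilde\rho\,\sigma_e^2 / (\sigma_e^2 + 2\sigma^2/R)$ and
  $\tilde\rho$ is solved from the target $\rho$ in closed form
  (targets requiring $|\tilde\rho| > 1$ error out). Defaults:
  $\sigma_e = 2$, tandem pairs at $\rho = 0.9$, segmental pairs at
  −0.5 and 0.
* everything is generated under an isolated RNG seed and restores the
  caller's RNG state; identical seeds give bit-identical outputs.

What the generator does **not** emulate — and what green tests therefore
do not certify about real data: real AP2 domains have conserved motif
structure rather than a random consensus; real proteomes contain
compositional bias, repeats and partial gene models; array intensities
have probe effects and heteroscedastic noise; real synteny blocks are
inferred, not given. The generator establishes that the *algorithms*
recover planted truth under their stated assumptions, not that those
assumptions exhaust real genomes.

# Problem sizes and determinism

The default test-suite and acceptance problem sizes — 272 proteins, 500
calibration shuffles, 100 additive and 200 oracle NJ cases, 100
enumeration alignment pairs, 50 + 50 tandem margin seeds, 50 null
expression datasets of 200 genes at 4 vs 4, 1000 divergence trials, and a
reduced bootstrap (B = 25–200) inside pipeline runs — were chosen as the
smallest sizes at which each property is a sharp pass/fail check rather
than a noisy estimate. Every stochastic step takes an explicit seed, and
the pipeline writes a manifest with the config hash so a re-run with the
same config and seed reproduces every artifact byte for byte.

# Known limitations

* The PSSM has no insert states: a domain with a large internal
  insertion scores as two truncated halves at best.
* Background-from-seed E-values are calibrated against the seed's
  composition, not the target proteome's; strongly biased proteomes
  would warrant an external background.
* The permutation FDR needs two replicates per group; the fold-change
  fallback reports no significance.
* Subgroup labelling can only ever return labels present among the
  anchors; novel subgroups surface as `unclassified`.
* Exact reproduction of the published member list and counts requires
  the original genome release and array series, which the pipeline can
  consume but does not ship.
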