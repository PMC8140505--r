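---
title: "Polyphasic taxon delineation and culture-collection analytics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polyphasic taxon delineation and culture-collection analytics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PolyphasicTaxa)
```

# The problem

Large cultivation programs isolate thousands of bacterial strains from
complex communities such as the human gut. Before a strain can be named and
deposited, it must be placed taxonomically: is it a strain of a known
species, or a new species — possibly a new genus or family? Modern practice
is *polyphasic*: no single metric decides; instead 16S rRNA gene identity,
whole-genome metrics (ANI, dDDH, POCP), tree topology and phenotype all
contribute, each with a conventional threshold. This package implements that
decision machinery, the pairwise metrics feeding it, and the downstream
ecology — how prevalent the resulting taxa are across surveys and how much
of existing gene catalogs their genomes cover — as testable, deterministic
code.

# The metrics

## 16S identity and K2P distance

All nucleotide comparisons use one declared identity dialect: a global
(Needleman–Wunsch) alignment with unit match/mismatch scores and affine gaps
(open 2, extend 1), with identity = matches / compared sites, where compared
sites are the ungapped columns in which both bases are unambiguous A/C/G/T.
Terminal gap columns are gap columns, so overhangs never count against
identity; IUPAC ambiguity codes are tolerated in the input but excluded from
the counts, so sequencing ambiguity is never penalized. The tools used in
practice for this step expose several subtly different identity definitions;
fixing one and using it everywhere (assignment, clustering, coverage
queries) keeps every threshold comparison internally consistent.

The Kimura 2-parameter distance is computed from the same compared sites:
with transition proportion $P$ and transversion proportion $Q$,

$$d = -\tfrac{1}{2}\,\ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big).$$

Gapped and ambiguous columns are simply excluded pair by pair (pairwise
deletion — the external phylogenetics programs used for this calculation do
not document their choice, so ours is declared). When the log argument is
non-positive the pair is saturated and `k2pDistance()` raises a dedicated
`k2pSaturationError` rather than returning a number; consumers such as
`crossOverlap()` catch it and treat the pair as beyond any sharing
threshold, with a warning.

One caveat worth knowing: a pairwise aligner may thread gaps through a dense
run of substitutions when a shifted alignment happens to score better, which
slightly deflates distances for adversarially clustered mutations. Scattered
substitutions — the realistic case for 16S divergence — are unaffected, and
the test suite pins this behavior.

## Greedy centroid clustering

Species-level dereplication clusters 16S sequences at 98.7% identity with a
greedy centroid strategy: sequences are processed in decreasing length order
(ties keep input order), and each joins the first existing centroid at or
above the threshold, else founds a new cluster. The field's standard tool
sorts internally and does not document tie handling; pinning
length-then-input order makes the result reproducible. Clustering is
invariant to duplicating a sequence, and thresholds of 0 or 1 degenerate to
one cluster or all-singletons respectively.

## Fragment-based ANI

Both genomes are cut per contig into consecutive, non-overlapping 1020-bp
windows (trailing remainders discarded). Each fragment is matched into the
other genome in two stages: seed 11-mers (canonical, hashed by the same
routine as the MinHash sketches) vote for the candidate window — at 80%
identity a homologous window still shares about
$1000 \times 0.8^{11} \approx 35$ seeds against a background below one — and
the fragment pair is then aligned exactly. Only reciprocal best pairs whose
alignment covers at least 70% of the fragment are retained (the original
ANI tool's internal coverage cutoff is undocumented, so it is a parameter),
and ANI is the mean alignment identity over retained pairs. Ties in the
vote go to the lowest subject coordinate. Unrelated fragments fail the
coverage gate, and a pair with no reciprocal fragments raises an error
rather than reporting 0.

On synthetic pairs diverged by substitutions placed without replacement the
recovery is sharp: the acceptance checks require the target within ±1
percentage point (±1.5 at 80%) on 100-kb genomes and observe errors an
order of magnitude smaller.

## dDDH estimate

The digital DNA–DNA hybridization value is an *estimate*, not a
re-implementation of the reference web service (whose regression model and
formula variant are not reproducible from its description). We reuse the ANI
fragment machinery: the genome-pair distance is
$d_{f} = 1 - \sum \text{matches} / \sum \text{alignment lengths}$ over
retained fragment alignments, and

$$\mathrm{dDDH} = 100 \cdot \mathrm{logistic}(a + b\,d_{f}),\qquad b < 0.$$

The shipped calibration $a = 5.35$, $b = -100$ places identical genomes near
100% and the 70% species boundary at $d_f \approx 0.045$, i.e. ANI around
95–96%, matching the conventional agreement between the two species
criteria. Both coefficients are exposed (`coef =`) so a laboratory
calibration can replace ours; the package's own guarantees are monotonicity
in $d_f$, symmetry, and the boundary behavior on well-separated synthetic
pairs — exactly what the tests assert.

## POCP

POCP follows the count definition
$100\,(C_1 + C_2)/(T_1 + T_2)$: a protein is conserved when some local
(Smith–Waterman, BLOSUM62, gap open 11 / extend 1) hit in the other
proteome has E-value < $10^{-5}$, identity > 40% and an alignable region
covering > 50% of the query. These hit criteria come from the method's
original definition, not from any one implementation. E-values use
Karlin–Altschul statistics with the standard gapped BLOSUM62 parameters
($\lambda = 0.267$, $K = 0.041$) and the subject proteome's total residue
count as the database length. On proteome pairs built with a designed
conserved fraction, POCP equals the closed-form truth exactly.

## MinHash sketches and Mash distance

Canonical k-mers (the lexicographic minimum of a k-mer and its reverse
complement, 2-bit encoded) are hashed in C++ with a splitmix64 finalizer
truncated to 53 bits so hashes round-trip exactly through R doubles; a
sketch keeps the smallest 1000 distinct hashes at $k = 21$ (the
conventional defaults). The Jaccard index $j$ is estimated over the merged
bottom sketch and

$$d = -\tfrac{1}{k}\,\ln\frac{2j}{1+j},$$

with disjoint sketches assigned the sentinel distance 1. Genome pairs at
distance < 0.05 (strict) are called the same species; a query matching no
reference is a valid result and flags a "dark species" candidate.

# The decision engine

`delineate()` is a total function of nine evidence fields. Numeric evidence
(16S identity, dDDH, ANI, POCP) comes from the metrics above; clade
independence, the neighbour-family count and the three phenotype flags are
boolean/integer *inputs*, because trees and phenotyping are produced by
instruments and software outside this package's scope. Encoding them as
inputs keeps the rule engine enumerable: the test suite checks it against
an independently written clause-by-clause oracle on a grid of 560 boundary
combinations and on 2000 random evidence vectors (rank nesting and 16S
monotonicity).

Three deliberate boundary choices:

- All comparisons are strict, as the conventions are printed ("< 98.7%",
  "< 70%", "< 95%", "< 50%", "< 90%").
- A best 16S identity of *exactly* 98.7% is contradictory under the printed
  rules (the assignment rule says ≤ 98.7% is a novel-taxon candidate; the
  species clause requires < 98.7%). The engine surfaces `ambiguous` instead
  of silently resolving the conflict.
- The ANI exception window "between 95~96%" is closed on both ends, and the
  numbered species clauses must hold *simultaneously* — the window does not
  waive the dDDH requirement.

# Prevalence statistics

Study tables are samples × taxa matrices of relative abundances. QC removes
samples with fewer than 10,000 reads (strict; 10,000 itself is retained).
Per study, FO is the percentage of samples where the taxon's abundance
exceeds 0 (the presence floor is exposed as `minRa` but defaults to 0, and
the same convention covers metagenome FO usage, where no floor is stated),
and the mean RA includes absent samples as zeros — RA and FO are separate
statistics, so zero-inclusion is the interpretation that keeps them
independent; it is documented rather than assumed silently.

The *equally weighted* average is the mean of per-study means: a study with
3,000 samples counts exactly as much as one with 120. The regression suite
encodes the consequences deliberately: duplicating samples within a study
changes nothing, merging two studies does. Dominant means equally weighted
RA > 0.1%, common means equally weighted FO > 30%, both strict; core is the
intersection.

Accumulation curves are computed by explicit permutation (mean richness of
the first $k$ studies over `nPerm` random orderings) rather than by the
closed-form estimator, because the permutation definition extends unchanged
to the catalog-coverage curves below; the tests cross-check the permutation
mean against the analytic estimator from the community-ecology package
vegan and pin the exact endpoint (union richness) for every seed.

# Collections and gene catalogs

Cross-collection overlap first dereplicates each collection (dropping
sequences under 1 kb, clustering at 98.7%), then connects representatives
whose K2P distance is strictly below 0.013 and takes connected components as
taxa. The < 0.013 relation is not transitive; components make the sharing
call *single-linkage*, which is declared and tested (a–b and b–c close with
a–c distant forms one component). Saturated pairs count as distant.

Protein catalogs are built greedily: length-sorted sequences join the first
representative at ≥ 95% identity with the alignment covering ≥ 90% of the
shorter sequence. The word-index heuristics of the standard clustering tool
are not replicated — the declared greedy semantics are the contract, and
identity is matches / alignment length with gapped columns counted (a
documented difference from BLAST-style identities). Catalog-versus-catalog
coverage marks a subject entry as hit when some query aligns at the identity
cutoff with ≥ 70% of the *query* length aligned; 60% identity is the
conventional functional-conservation cutoff and 40% the structural one.
Unknown-function ("dark gene") queries are just another subject catalog.

# The synthetic-data generators

The generators exist so that every stage has ground truth. Divergence is
introduced by sampling substitution sites **without replacement**, so
realized identity equals the target exactly and parameter-recovery tests
can be sharp rather than statistical. Genome pairs realize
`round(L(1 − ANI))` substitutions on a uniform random ancestor; 16S pairs
the same at gene scale; proteome pairs plant an exact number of conserved
homolog pairs above the POCP hit criteria; community tables draw per-sample
presence from per-study Bernoulli probabilities and give present taxa
heavy-tailed lognormal abundances renormalized to sum to one (read counts
lognormal around 30,000 to exercise QC). Everything is bit-reproducible
from `seed`, and generators restore the caller's RNG state.

Defaults chosen once: uppercase A/C/G/T only (no ambiguity codes unless
corruption is requested explicitly); `indelRate = 0` — when indels are
requested they are short (1–3 bp) and uniform, and ANI recovery on
indel-bearing pairs is only expected within about two points because
fragment windows no longer tile homologously; lognormal
(`meanlog = 0`, `sdlog = 2`) abundances are a conventional stand-in for
amplicon abundance distributions, which the multi-study compilations this
emulates do not characterize. The generators deliberately do **not**
simulate gene content, codon usage, GC skew, 16S secondary structure, or
chimeras — so a passing test shows the *metrics and rules* behave as
specified, not that the pipeline is robust to every artifact of real
sequencing data.

# Problem sizes and runtime choices

The unit tests run genome metrics at 20–30 kb and the end-to-end ANI
recovery at 100 kb per pair (about ten seconds each; four pairs in the
acceptance path), proteomes of 4–40 proteins at 150–300 residues,
16S panels of 6–10 sequences, two-to-six-study communities with up to
1,000 samples per study for the FO-recovery checks, and 50–400 permutations
for curve comparisons. These sizes were chosen so the whole suite settles
in a few minutes while keeping every statistical tolerance comfortably
non-trivial (e.g. binomial FO at $n = 1000$ has a standard error near 1.5
points against a ±3-point band).

# Known limitations

- The dDDH logistic is a package calibration, not the reference service's
  regression; only monotone, symmetric, boundary-consistent behavior is
  claimed.
- Fragment ANI assumes assemblies without massive rearrangement *within*
  1020-bp windows; inversions at window scale would break reciprocal
  matching (real tools share this fragility to a lesser degree).
- The K2P aligner caveat above: densely clustered substitutions can be
  shift-aligned, deflating distances slightly.
- Protein E-values use fixed Karlin–Altschul constants rather than
  composition-adjusted statistics; for the short-protein fixtures used here
  the criterion is dominated by the identity and coverage gates.
- Taxa in prevalence tables are matched by exact name; no taxonomy-aware
  merging is attempted.
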