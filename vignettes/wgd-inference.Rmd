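---
title: "Inferring ancient genome duplications and germline-specific DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring ancient genome duplications and germline-specific DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Early vertebrate genomes went through a rapid series of polyploidizations:
a shared auto-tetraploidization on the vertebrate stem (1R), an
allo-tetraploidization on the jawed-vertebrate stem (2R, jawed
vertebrates), and a hexaploidization on the cyclostome stem (2R,
cyclostomes). Because these events are ancient and closely spaced, and
because duplicate copies were massively lost afterwards, single-gene
phylogenies rarely resolve them. The chromosome-scale approach implemented
here instead leans on synteny: genes that sit on paralogous chromosome
segments descending from one pre-duplication chromosome (a *paralogon*)
can be concatenated into a single long alignment per ancestral linkage
group (CLG), and the resulting tree is read for duplication versus
speciation nodes, dated, and tested against competing rediploidization
scenarios. A second, independent component detects programmed DNA
elimination: genomic intervals present in germline but absent from soma
are called from the ratio of paired sequencing-depth tracks.

The package supplies every stage as a tested function, plus a genome
evolution simulator whose scripted history plays the role of ground truth,
so the full pipeline can be exercised and validated end to end without any
external data.

## The simulator and what it emulates

`default_scenario()` scripts the history the simulator realizes:

* a dated species tree `(outgroup, ((hagfish, lamprey), (gar, frog)))`
  with the outgroup divergence at 600 Ma, the cyclostome–gnathostome
  split at 520 Ma, the hagfish–lamprey split at 457 Ma and the
  gnathostome crown at 430 Ma;
* 1R auto-tetraploidy on the vertebrate stem whose paralogon divergence
  (the completion of rediploidization) is scheduled at 527 Ma;
* gnathostome allo-tetraploidy with the alpha/beta progenitor divergence
  at 508 Ma — for an allopolyploid the paralogue divergence *is* the
  progenitor divergence, so no rediploidization schedule applies;
* cyclostome two-step hexaploidy with paralogon divergences at 511 and
  493 Ma (hybridization of a diploid with a related tetraploid);
* one designated CLG (default `CLGB`) that retains 1R tetrasomy through
  both splits and rediploidizes lineage-specifically: on the gnathostome
  stem at 515 Ma, in hagfish at 431 Ma and in lamprey at 442 Ma. Its
  surplus hexaploid copies are treated as lost, which mirrors the heavy
  post-hexaploidy losses of real cyclostome genomes.

Gene families descend from a per-CLG template tree in which every
duplication node sits exactly at its scheduled age; loss prunes each tip
independently with one minus the event's retention probability (0.85 for
1R, 0.80 for the gnathostome event, 0.65 for the cyclostome event —
chosen once to reproduce the sparse copy retention typical of these
lineages). Protein sequences evolve without indels under a strict clock at
5e-4 substitutions/site/Ma, a standard vertebrate protein rate that keeps
the deepest pairwise distances (~0.6 substitutions/site) well below
saturation. Indel-free evolution makes per-family alignments columnwise by
construction, so no aligner sits between the simulator and the
concatenation stage. The default substitution model has equal
exchangeabilities and uniform frequencies; its transition probabilities
and maximum-likelihood distances have closed forms, which is what makes
exact oracle tests possible. Empirical matrices can be supplied via
`substitution_model()` or `read_rate_matrix()`, and discrete-gamma rate
heterogeneity is available but off by default (the simulator itself is
homogeneous).

Karyotypes assign every gene a 0-based, half-open interval on a
chromosome. The outgroup, lamprey and the gnathostomes carry one ancestral
unit per chromosome; hagfish chromosomes fuse 2–6 units from distinct
CLGs, and within-chromosome gene order is shuffled, reproducing the
"fusion with scrambling" architecture of real hagfish karyotypes. Depth
tracks are negative binomial around modal depths of 32 (germline) and 54
(soma) with a single overdispersion parameter (variance
`mu + 0.02 mu^2`); planted germline-specific regions have soma depth zero
and a ten-fold germline copy ratio by default.

What the simulator does *not* emulate: indels and alignment error,
rate variation across sites and lineages, rearrangement breakpoints
within units, repeat sequence content, and read-level artifacts. Passing
recovery tests on these data therefore demonstrates the correctness and
calibration of the inference machinery under its own model assumptions,
not robustness to every complication of real data.

## Study conditions and problem sizes

Two gene densities are used. The tree and rediploidization stages run on
20 families per CLG at 300 sites per family (17 CLGs), the conditions the
end-to-end recovery checks are defined at; the synteny stage uses 40 genes
per CLG, the module's default, because exact chromosome-level CLG recovery
by Fisher enrichment needs roughly that density — at 20 genes/CLG a small
surviving unit on a large fused chromosome can miss Benjamini–Hochberg
significance even when every one of its genes is correctly labeled. The
coverage scan runs on ten 1-Mb contigs with twenty 20–60 kb planted
regions.

## Orthology and synteny

`similarity_search()` ranks candidate homologs by shared k-word count
(k = 4) and rescores equal-length candidates by ungapped identity —
adequate for indel-free sequences and pluggable for real data.
`mutual_best_hits()` keeps reciprocal top hits, breaking score ties by
lexicographic gene id so results are deterministic. A caveat the
vertebrate chronology itself imposes: with only ~7 Ma between the 1R paralogon
divergence and the cyclostome–gnathostome split, a gene's nearest
paralogue and true ortholog differ by well under one percent expected
identity, so no pairwise score can separate them reliably. Top hits and
MBH pairs are therefore validated at the gene-family level, which is
exactly the granularity the downstream synteny tests consume — this
limitation of per-gene orthology is the reason the method works at
chromosome scale in the first place.

`chromosome_association_test()` computes, for every chromosome pair, the
one-sided Fisher exact test (hypergeometric tail) on the 2x2 table of
ortholog-pair membership, adjusted by Benjamini–Hochberg across all
chromosome pairs at 0.05; the multiple-testing procedure and level are
this package's choice and are configurable.
`assign_clgs()` applies the same test per chromosome x CLG and reports
20-gene bin compositions, zeroing genes of non-enriched CLGs; the final
partial bin is kept and labeled by its actual size. CLG labels transfer
through each focal gene's top reference hit rather than through MBH,
because a single-copy reference can anchor at most one mutual pair per
family, which would starve the enrichment test of labeled genes.

## Paralogons and supermatrices

`classify_paralogons()` is a lookup of each gene's chromosome segment in
the reference classification (gnathostome labels alpha1/alpha2/beta1/beta2,
where alpha/beta is the allopolyploid subgenome and 1/2 the 1R copy;
cyclostome labels are the chromosome-derived segment ids; unplaced is a
value, not an error). `select_families()` implements the strict (at least
three distinct gnathostome paralogons) and relaxed (at least two) data
sets, both additionally requiring derivatives of both 1R copies; strict is
provably a subset of relaxed. `build_supermatrix()` concatenates one row
per observed (species, segment), filling absent family blocks with gaps;
when tandem duplicates compete for one row the longest sequence wins (ties
by gene id), and rows under 20% occupancy are dropped with a warning so
all-gap rows cannot destabilize likelihoods.

## The likelihood core

`log_likelihood()` is a plain Felsenstein pruning implementation with
site-pattern compression and per-node rescaling; gaps are missing data.
`optimize_branch_lengths()` does per-branch Brent optimization in
postorder/preorder sweeps with incremental outside partials; each sweep's
total log-likelihood is verified and a non-improving sweep is rolled back,
so the per-sweep trace is non-decreasing. Branch lengths are clamped to
[1e-8, 10] and the default stopping rule is a sweep gain below 1e-6
log-likelihood units.

Starting trees come from `neighbor_joining()` on closed-form ML distances
(saturated pairs are flagged and replaced by a large finite distance).
Because the informative deep branches here are a few Ma long
(~0.003–0.01 substitutions/site) while pairwise-distance noise at these
depths is about twice that, distance topologies systematically miss them.
`refine_topology()` therefore evaluates, for every internal edge, the two
nearest-neighbor-interchange candidates by the exact local quartet
likelihood (five local branch lengths re-optimized, everything else
fixed), applies non-conflicting improvements, and repeats for a bounded
number of rounds. This is candidate evaluation around a distance starting
tree, not a general tree search: there is no SPR, no randomized restarts,
and the candidate set is the NNI neighborhood only.

Supports on pipeline trees are RELL-vote bootstrap proportions: per-site
log-likelihoods are computed once for the final tree and each of its NNI
neighbors, sites are resampled with replacement, each replicate votes for
its best candidate, and a bipartition's support is the percentage of votes
for candidates containing it. Splits that are trivial in the unrooted
sense (the root split) hold by construction and get support 100. The
generic rebuild-per-replicate bootstrap (`bootstrap_support()`) is also
provided with the NJ builder as default. Supports from a bounded candidate
pool can overstate certainty when a relevant alternative lies outside the
pool; the NNI neighborhood contains precisely the local rearrangements
that compete for each weak edge, which is where the reading of the 1R node
is decided.

`topology_test()` implements RELL-based tests: the two-sided
Kishino–Hasegawa test for a candidate pair, the Shimodaira–Hasegawa
worst-case procedure for larger sets, and a per-candidate one-sided KH
against the maximum-likelihood candidate (`method = "KH"`), which mirrors
"rejected when significantly less likely than the ML tree" and is what the
rediploidization tests use — the SH procedure is so conservative at 300
sites that it rejects almost nothing. The usual KH caveat applies (the
best tree is selected from the same data); a full multiscale-bootstrap AU
test would remove it and the interface leaves room for such a plug-in.

## Dating

`date_nodes()` fits a strict clock by constrained least squares: node ages
minimize the squared differences between branch lengths and rate times
duration, subject to parent-older-than-child ordering and calibration
bounds, with the global rate profiled in closed form. Three numerical
choices matter. First, only cherries joining two species of one lineage
*with matching segment keys* are calibrated: a matching key certifies
chromosomal orthology, whereas a mismatched cherry may be hidden paralogy
(older than the speciation) or lineage-specific rediploidization
(younger), and calibrating those corrupts the whole fit. Second, the two
edges of a binary root are merged into a single clock residual, because
the root's position along that path is unidentifiable (pulley principle)
and a zero-length rooting artifact would otherwise drag its neighbors
toward the root age. Third, ages are exactly recovered on clock-like
input, and are scale-invariant in the branch lengths given one absolute
calibration. The pipeline calibrates the root (600 Ma), the
hagfish–lamprey cherries (457 Ma) and the gnathostome cherries (430 Ma) —
the analogue of fossil calibrations on speciation nodes — and estimates
the 1R, alpha/beta and hexaploidy divergence ages plus the
cyclostome–gnathostome split.

The bimodality of cyclostome paralogon divergences is assessed by fitting
one- and two-component equal-variance normal mixtures (deterministic
hierarchical initialization, BIC preference). Only duplication ages older
than the hagfish–lamprey calibration enter the fit: a cyclostome
duplication younger than the species split cannot reflect a shared
polyploidy and is lineage-specific by definition.

## Rediploidization tests

A family is informative when (i) some gnathostome species retains both 1R
copies, (ii) both cyclostome species are present, (iii) an outgroup gene
exists, and (iv) at most 10 constrained ancestral topologies can be
derived — criterion (iv) is evaluated by literally running the enumerator.
The enumerator seeds two clades with the gnathostome 1R_1 and 1R_2 copies
and assigns cyclostome segment-orthology groups to the clades, honoring
two kinds of chromosomal knowledge: *orthology* constraints (hagfish and
lamprey derivatives of one segment are placed jointly) and *exclusion*
constraints (segments classified as descending from different duplication
copies must be split across the clades). Exclusions are what make the
test sharp: without them, the assignment that puts every cyclostome gene
into one clade is topologically almost identical to the lineage-specific
tree and can never be rejected. With two hagfish and two lamprey segments
and mutual exclusions, the ancestral set reduces to the two cross-species
pairings — the classic paired enumeration for duplications inside one 1R
copy, also available through `balanced = TRUE`.

`test_family()` builds an unconstrained tree (NJ + branch-length
optimization), optimizes every constrained topology, and applies the
one-sided RELL-KH test at alpha = 0.05. The verdict is *ancestral* only
if every lineage-specific topology is rejected and at least one ancestral
topology is not, and symmetrically for *lineage-specific*; everything
else, including alignments without variable sites, is *inconclusive*.
This unanimity rule is deliberately conservative; a majority variant would
be easy to add, but under unanimity a false lineage-specific call requires
rejecting a true topology at level alpha several times over, which keeps
the per-CLG tallies clean. A CLG is flagged lineage-specific when its
lineage-specific verdicts outnumber its ancestral ones.

## The coverage scan

`modal_depth()` is the most frequent positive depth (ties toward the
smaller value). Positions are masked when both samples are low (below one
third of modal, or below an absolute cutoff of 10 in the higher-copy
variant) or both are high (above three times modal; 30x in the
higher-copy variant); the conjunction keeps germline-specific regions,
where only the soma collapses, unmasked. Unmasked positions are grouped
left-to-right into intervals of exactly 500 valid bases that may span
masked gaps; the final interval of a contig may be partial. Interval means
are computed over valid bases only, clamped into [a, A] and [b, B]
(defaults a = b = 10, A = B = 1e8, the documented roles of the stage-2
parameters of this analysis style; the minimum clamp substitutes for zero
soma coverage), and scored as log2 of the modal-normalized depth ratio.
Score sequences are segmented by recursive binary splitting on the maximal
two-sample t statistic with a permutation test (p < 0.01, no
pre-smoothing), and segments at or above the call threshold are merged
into regions. The threshold defaults to 2.0 (four-fold normalized
enrichment); there is no field-standard value for this cutoff, so it is a
configurable parameter here, and a planted soma-free region scores about
log2(10 x 54/10) = 5.75 at a ten-fold germline ratio, far above it. Repeat-oriented helpers implement the
genomic-span formula (normalized mean depth times covered bases), the
3x-modal k-mer abundance threshold, the 80% alignment-coverage
disjunction, and the 200-hits-per-1-Mb clustered-window flag with an
optional every-chromosome ("centromeric") mode.

## Reproducibility

Every stochastic operation takes a seed; `run_pipeline()` derives
per-stage seeds from one global seed by hashing stage names, writes every
artifact with an MD5 manifest, and produces byte-identical outputs for
identical configuration and seed. `scripts/acceptance.R` re-runs the
default study conditions from scratch and emits the recovered ages,
fractions and precision/recall values as JSON.

## Known limitations

Topology search is local by design (NNI neighborhood of an NJ tree);
pathological starting trees more than a few interchanges from the optimum
are not guaranteed to be repaired. The KH-based topology test inherits
the selection caveat noted above. Strict-clock least squares is a
deliberate stand-in for Bayesian relaxed-clock dating: adequate for
clock-like simulations, it will be biased on rate-heterogeneous real
data. The RELL-vote supports are neighborhood-conditional. The simulator's
idealizations (no indels, no rate heterogeneity, clean segment labels)
mean the recovery results bound what the machinery can do under its own
assumptions, not under real-data noise.
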