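---
title: "Methods: benchmarking OTU workflows on length-variable amplicons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: benchmarking OTU workflows on length-variable amplicons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Metabarcoding studies cluster marker-gene amplicon reads into operational
taxonomic units (OTUs) as a proxy for species. For length-variable markers
such as the hypervariable V4 region of the 18S rRNA gene (roughly 400-600 bp
across eukaryotic taxa, with inter-family differences of up to a couple of
hundred nucleotides), the estimated number of OTUs depends dramatically on
seemingly technical choices: how strictly reads are quality-filtered,
whether singleton sequences are kept, which clustering algorithm is used,
and - most subtly - how alignment *gaps* are counted when pairwise sequence
divergence is computed. `otubench` implements all of these choices as
interchangeable, tested components so their interactions can be measured on
synthetic communities with known ground truth.

# Pipeline model

A workflow is the fixed stage order

    filter -> dereplicate -> (singleton policy) -> cluster -> classify -> summarise

**Filtering.** Two regimes are implemented. The *stringent* regime (USEARCH
tradition) removes reads shorter than 400 bp after primer removal, truncates
survivors to exactly 400 bp, and rejects reads whose *expected error*
`sum(10^(-Q/10))` over the retained bases exceeds 0.5. The *relaxed* regime
(RDP tradition) keeps variable-length reads of 250-600 bp and rejects reads
with mean phred quality below 20. Both regimes match and strip the
degenerate forward primer (default Uni18S, `AGGGCAAKYCTGGTGCCAGC`, zero
mismatches tolerated by default) and reject reads containing `N`. The
within-regime rule order (primer, length/trim, `N`, quality) is not dictated
by the originating protocols; it is fixed here so that quality statistics
are always computed on the bases actually retained, and every read is
tallied under exactly one rejection reason so the order is auditable.

**Dereplication and singletons.** Identical reads (exact full-length string
equality) collapse into unique sequences carrying abundances; prefix
matches deliberately do not collapse, because silently merging length
variants would confound the terminal-gap analyses below. A *singleton* is a
unique sequence of abundance 1; workflows run with singletons either kept
or removed.

**Clustering.** Two de novo algorithms at a divergence threshold (default
3%):

* *greedy centroid* (UCLUST-style): unique sequences are processed in
  decreasing abundance; each either joins the first centroid within the
  threshold (`first_hit`, the classic maxaccepts = 1 behaviour; `best_hit`
  is available) or founds a new cluster. Centroids never change.
* *hierarchical* (mothur-style): agglomeration over a full pairwise
  distance matrix, cut so that merges at linkage distance <= threshold are
  applied and none beyond. Average linkage ("average neighbor") is the
  default; the merge order is deterministic (smallest distance, ties by
  smallest member index). A capacity guard (default 20,000 sequences)
  refuses matrices that would not fit desk-scale resources, mirroring the
  practical infeasibility of distance matrices for large relaxed datasets.

Distances for hierarchical mode come either from the rows of a multiple
sequence alignment (externally produced, e.g. MAFFT - the package calls
`mafft` when present) or from pairwise global alignments.

# Identity definitions and terminal gaps

Pairwise identity is computed from column statistics of an alignment:
match columns `M`, mismatch columns `X`, gap columns `C` and maximal
single-sequence gap runs `R`, each split into internal and terminal (a run
touching the first or last alignment column). The three definitions are

* *no gaps*: `M / (M + X)` - gaps carry no information;
* *one gap*: `M / (M + X + R)` - a run of any length is one mutational
  difference;
* *each gap*: `M / (M + X + C)` - every gapped nucleotide is a difference.

Because `0 <= R <= C`, identities are always ordered
`no_gaps >= one_gap >= each_gap`, which forces the qualitative OTU-count
ordering the benchmark reproduces. The *terminal policy* (`count`, the
default, vs `exclude`) controls whether terminal runs/columns enter `R` and
`C`: terminal gaps arise from length differences and are missing data
rather than evolutionary differences, yet the classical tools count them -
which is precisely the mechanism that inflates OTU numbers under *each
gap* on untrimmed data. The minimal demonstration lives in
`fixture_suite()$prefix_pair`: a 440-nt sequence and its 400-nt prefix
split into two OTUs at 3% under `each_gap + count` (divergence
40/440 = 9.1%) and stay together under `no_gaps` or `each_gap + exclude`.

# Alignment

Pairwise alignments are Needleman-Wunsch with affine gaps (match +1,
mismatch -2, gap open -10, gap extension -1) and *free terminal gaps*.
Free end gaps make the optimal alignment of a length-variant pair carry the
length difference as terminal runs, keeping the terminal-gap mechanism
observable rather than burying it in scattered internal gaps. Traceback
tie-breaking is fixed (match/mismatch column, then gap in the second
sequence, then gap in the first), and end-point ties prefer fewer terminal
gap columns, so results are bit-reproducible.

Two numerical consequences of free end gaps are handled explicitly:

* for two sufficiently dissimilar sequences the optimum is an *empty*
  overlap (score 0), leaving identity undefined; the identity operations
  raise an error by default, while the clustering layer maps such pairs to
  divergence 1;
* the optimum for unrelated sequences is otherwise a short exact common
  substring, which *no gaps* would read as identity 1.0. Banded global
  aligners in the classical tools never produce such alignments, so the
  clustering layer applies a coverage guard (`min_coverage`, default 0.5):
  a pair whose aligned overlap covers less than half of the shorter
  sequence is maximally divergent. Genuine length variants have coverage
  ~1 and are unaffected. Classification similarly ranks only hits that
  meet the 200-nt overlap rule, the analogue of BLAST's significance
  ranking.

# Classification and metrics

OTU centroids are classified by exhaustive end-gap-free alignment against
the reference database (no external BLAST binary; desk-scale reference
sets make this exact). A positive identification needs >= 90% identity
(*no gaps* over the aligned overlap) and >= 200 nt of overlap; ties go to
the larger overlap, then the alphabetically first species, and are
flagged. Metrics: *precision* = distinct reference species detected /
total OTUs, and *species detection* = distinct species detected /
reference-set size. The reference validator warns when two references lie
within the clustering threshold (such species are indistinguishable at
that threshold and would be curated out of a real reference set).

# The synthetic community

`generate_references()` builds species templates as conserved 5'/3' flanks
(about 120 nt each, lightly mutated per species) around a hypervariable
core derived from a common ancestor by heavy substitution (15%) plus a
species-specific block deletion - giving homologous, alignable sequences
whose lengths spread over the 400-600 nt window, the structure that makes
terminal gaps matter. All species pairs must exceed a divergence floor
(default 6%, twice the 3% clustering threshold) on both the full template
and its leading 400 nt, so stringent trimming cannot erase
distinguishability; offenders are redrawn. Species carry 1-3 intragenomic
rRNA copies at ~0.5% divergence, i.e., within-threshold biological
variation.

Why a 400-nt lower bound: the amplicon envelope is "approximately 400-600
bp", and the parameter-recovery criterion requires that an error-free
community be *exactly* recoverable through the stringent workflow - a
species shorter than the 400-bp trim would be filtered out wholesale,
making that recovery impossible by construction rather than by method.

`simulate_reads()` draws reads species-first (log-normal abundances with
sigma 1.2 by default, generating realistic singleton rates; `uniform`
mirrors an equal-tissue mock community), picks a copy uniformly, prepends
a per-read realisation of the degenerate primer, and injects
454-flavoured errors: substitutions (1e-3/base), indels (5e-4/base),
homopolymer slippage (+-1 on runs >= 3 at 0.01/run), and two-parent PCR
chimeras (1% of reads) at a uniform crossover point, all flagged in the
ground truth and never filtered by the simulator. Qualities follow a
*positional* decay profile: mean Q35 at the first base, falling by 1/60
phred unit per base (Q25 at position 600) with per-base jitter (sd 2).
The decay is a function of base position, as on the instrument - an early
implementation that interpolated the decay across each read's own length
made the expected-error filter silently reject all short-template species,
an instructive failure the acceptance suite caught. No run-specific
error-rate estimates exist for the benchmark scenario, so these defaults
were fixed once from the 454 literature and are configurable.

**What the generator does not emulate** (and hence what a green test does
not establish): qualities are drawn independently of the injected errors,
so the expected-error filter is tested as a mechanism, not as an enricher
of error-free reads; there is no flowgram-level error structure, no
PCR-cycle-explicit chimera model, no primer-bias amplification failure
(species dropout is available as an explicit option), and no contaminant
taxa. Template evolution is i.i.d., not phylogenetic - the benchmark's
claims rest on divergence and length structure, not tree shape.

# Determinism and numerical choices

Every stochastic step takes an explicit seed and restores the caller's RNG
state. Clustering input order, tie-breaks, and output ordering (OTUs by
decreasing abundance, ids `OTU_0001`...) are all specified, so re-running
any workflow from its serialised JSON configuration reproduces outputs
byte-for-byte. The hierarchical cut uses merge-height <= threshold (a hard
cut, not label rounding). Workflow configuration round-trips through JSON
(`jsonlite`); YAML offers no advantage here and would add a dependency.

In the factorial grid (`compare_workflows()`), filtering and dereplication
are shared per regime, greedy alignment statistics are cached across
identity definitions and singleton policies, hierarchical distances are
derived from one MAFFT alignment per regime with the singleton-removed arm
reusing the induced sub-alignment (align once, subset later), and
classification is cached by centroid sequence. None of this changes
results; it only avoids recomputing identical quantities.

# An instructive failure mode: trimmed reads in an MSA

One benchmark expectation — that relaxed filtering never yields fewer
OTUs than stringent — holds here for greedy clustering throughout and for
hierarchical clustering on singleton-free data, but inverts by a few OTUs
for hierarchical clustering with singletons included. The cause is worth
recording. Trimming every read to 400 bp shifts the 3' tail of any read
carrying an upstream indel out of register; an optimal pairwise alignment
absorbs the shift as one internal gap plus a one-column terminal gap,
but a progressive multiple sequence alignment (the mothur-style distance
source) often leaves such a tail misaligned, which the identity
definitions then read as mismatches. Stringent-trimmed singleton reads
therefore acquire slightly inflated MSA distances and split into extra
clusters, while variable-length relaxed reads, which retain their
conserved 3' flank as an alignment anchor, do not. The corresponding
acceptance check is left failing rather than papered over: it documents a
genuine hazard of MSA-based hierarchical clustering on trimmed,
length-variable amplicons. On real 454 data the effect is swamped by the
much larger junk-read load that relaxed filtering admits (there, relaxed
datasets retain several times more unique sequences than stringent ones;
in this simulator's cleaner world the difference is only ~13%).

# Known limitations

* The greedy clusterer performs full (unbanded) optimal alignments; it is
  exact but slower than production tools, so grid-scale runs use a few
  thousand reads rather than hundreds of thousands.
* Chimera *removal* is out of scope throughout; chimeras are simulated,
  tagged, and observed downstream (typically surfacing as OTUs that match
  no reference).
* Absolute OTU counts of real 454 datasets are not reproducible here -
  the benchmark asserts the qualitative orderings (identity definitions,
  singleton policies, filtering regimes) and exact recovery in the
  error-free limit, which are the method-level claims this package is
  built to test.
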