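---
title: "Methods: comparative analysis of bacterial sister genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative analysis of bacterial sister genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sistercomp)
```

# Scope and model

`sistercomp` analyses pairs of *sister genomes*: bacterial chromosomes that
diverged from a close common ancestor so recently that they are collinear
and nearly identical (core identity on the order of 99.9%) outside a
handful of structurally variable regions. The motivating biological setting
is a pair of organohalide-respiring *Dehalobacter*-like strains whose
specialization onto different chlorinated substrates is driven by a small,
strongly selected cluster of substitutions around their reductive
dehalogenase (*rdhA*) genes, against an otherwise almost invariant genomic
background. The pipeline quantifies exactly the signals that distinguish
such a pair:

* collinear whole-genome alignment and the identity of the aligned core;
* the per-region balance of synonymous and non-synonymous substitutions
  (the selection signal);
* GC-skew structure, replication origin/terminus calls, and candidate
  repeat-mediated inversions that would restore replichore symmetry;
* insertion-sequence (IS) copy numbers and strain-specific transpositions;
* reciprocal-best-hit (RBH) orthology between the two proteomes;
* the census of transcriptional-regulator protein domains in the gene
  neighborhoods of *rdhA*-like anchor genes.

Every stage is exercised against a synthetic sister-genome generator that
plants each of these phenomena with a recorded truth table, so the whole
pipeline is testable end to end without any sequence downloads.

# Whole-genome alignment

## Anchors

Anchors are maximal exact matches seeded by k-mers whose occurrence count
— forward and reverse strand combined — is exactly one in each genome
(MUM-style). The default seed length is `k = 20`: long enough that a 3 Mb
genome contains essentially no chance duplicate 20-mers, short enough that
anchors persist between substitutions spaced ~770 bp apart (the spacing at
99.87% identity). Multi-copy sequence (IS elements, rRNA operons) carries
no unique k-mers and is therefore naturally anchor-free; alignment of those
regions is recovered by gap closure between flanking anchors.

## Chaining

Anchors are chained per orientation by maximum-weight collinear
subsequence (weight = summed anchor length), extracted greedily: the best
forward or reverse chain is accepted, conflicting anchors are trimmed to
their non-overlapping part, and extraction repeats until no chain of at
least 40 bp remains. Trimming rather than discarding matters at repeat
boundaries: an anchor seeded outside an identical repeat extends *through*
the repeat copy, so after an inversion mediated by a repeat pair, forward
and reverse chains legitimately overlap inside the repeat. Trimming
resolves the overlap without losing the flanking alignment. A consequence
is that inversion breakpoints are only localized up to the mediating
repeat — which is also the biological truth, since homologous
recombination resolves somewhere within the repeat.

## Gap closure and unaligned segments

Gaps between consecutive chained anchors are closed by banded global
alignment with unit scores (match +1, mismatch −1, gap −2, no affine
extension; band half-width 200). At ≥99% identity the scoring choice is
immaterial — the banded result is checked against unrestricted dynamic
programming in the tests — and the simple scheme keeps the kernel fast.
The traceback prefers continuing an open gap on score ties so that a long
insertion appears as one contiguous gap run rather than being scattered
across chance matches; run-length masking downstream (16S insertion
masking) depends on this.

A gap whose larger side exceeds `max_gap` (default 5000 bp) is not forced
into an alignment: it interrupts the block and is reported as an unaligned
segment, reason `strain_specific_insertion` for a side above the
threshold, `below_threshold` for a short opposite side. This
operationalizes "removing large insertions" — a phrase the source
literature of such analyses leaves undefined — with `max_gap` as the
declared, tunable threshold.

Circular genomes are aligned on the linearized sequence with the
coordinate origin as the cut point. The simulator derives both sisters
from one ancestor, so their origins coincide; for real data a rotation
that moves the cut into a collinear region should be applied first. A
block spanning the cut is not reconstructed; the cost is at most one
spurious block boundary at the origin.

## Identity accounting

The paper-style figures come in two denominator conventions, and both are
provided rather than guessing which one an alignment GUI reported:

* **core**: matches / (match + mismatch columns) — indel columns and
  unaligned segments excluded. This is the convention under which a pair
  planted at 99.87% identity measures 99.87%.
* **whole**: gap columns and the lengths of unaligned segments of both
  genomes join the denominator, giving a whole-genome average identity
  that a large island visibly depresses.

# SNP classification

Substitutions are read directly from the mismatch columns of the alignment
blocks (columns involving N are excluded and counted). Classification is
codon-local and mutation-path-free: the codon is read from genome A
(strand-aware), the single alternate base substituted, and the two codons
compared under translation table 11. A codon hit by more than one SNP is
classed `multi_hit_codon` for all its SNPs instead of assuming a mutation
pathway, because the counts of interest are per-site, not per-codon-event.
Nonsense changes are reported as their own class; `fold_nonsense = TRUE`
folds them into the non-synonymous count for the two-way accounting used
in regional summaries. SNPs in CDSs with compound locations, nonzero
phase, or lengths not divisible by three are flagged `ambiguous` rather
than silently dropped.

The independent check is built into the simulator: at planting time the
class of every coding SNP is established by translating the full CDS
before and after the substitution and comparing the proteins — a different
code path (batch `Biostrings::translate` on whole sequences) from the
codon-local classifier. The acceptance suite demands 100% agreement on
single-hit codons over 10^4 planted SNPs.

A region summary (counts of synonymous / non-synonymous / other over an
interval or an inclusive locus-to-locus span) deduplicates SNPs that fall
in overlapping CDSs by keeping the highest-impact record, so totals always
conserve the SNP count. "Between gene X and gene Y" is read as the span
from the 5'-most to the 3'-most coordinate of the two loci, which matches
how such regions are drawn in genome-neighborhood figures.

# GC skew, origin calls and inversion ranking

Windowed skew is (G−C)/(G+C) (defaults: 10 kb windows, 1 kb step — sized
to resolve Mb-scale replichore arms without noise; tests on 80–100 kb
genomes use 2 kb windows for the same windows-per-arm resolution). The
cumulative curve adds +1 per G and −1 per C per base; its global minimum
is called as the replication origin and its maximum as the terminus. When
a *dnaA* position is supplied and a local minimum of the curve lies within
50 kb, that minimum is preferred (refined to the exact minimum within one
window) and the choice is reported. A flat curve (range < 0.001·L) yields
"no confident call".

Replichore symmetry is scored as the Pearson correlation between the
cumulative-skew curve of arm 1 (origin→terminus) and the mirrored curve of
arm 2, after resampling both arms to 200 points. Both traversals rise from
the origin minimum to the terminus maximum, so two clean opposite-signed
arms score near 1 while an inversion inside an arm produces a kink that
lowers the correlation. Correlating per-window *increments* instead would
carry no signal for clean arms — the increment expectation is constant
within an arm, leaving only sampling noise — so the cumulative curve is
the quantity correlated. This score is a constructed operationalization of
the qualitative notion of "a more symmetrical GC skew" and is labelled as
such in reports.

Candidate rearrangements are generated from inverted repeat pairs: for
each pair the segment between the repeat midpoints is tentatively
inverted (midpoints, because recombination resolves within the repeat and
the exact point is unobservable) and the candidate is scored by the change
in symmetry plus, when a reference genome is given, the change in
anchor-chain collinearity against it (equal weights). Ordering is
deterministic, ties broken towards the smaller breakpoint. Translocations
are not searched genome-wide; the biological case that motivates them was
identified manually via a recombinase locus, and candidate sites would be
user-supplied.

# Repeats and IS copy numbers

Maximal repeat discovery is seed-and-extend: exact 16-mer seeds in both
orientations, ungapped x-drop extension (match +1, mismatch −3, x-drop
30), per-diagonal merging, and containment filtering. Copy counting
aligns the element against each candidate window (element ends fixed,
window ends free) and accepts placements greedily by score, without
overlap, requiring identity ≥ 0.95 over ≥ 0.90 of the element length.
These thresholds are a declared operationalization — the genuine IS
totals of real genomes depend on annotation conventions the literature
does not state — so family-level summaries (clustering elements at ≥ 90%
identity over ≥ 90% length) are reported alongside raw counts. Flanking
direct repeats around a candidate cassette are searched only in windows
upstream of its start and downstream of its end, direct orientation only,
which is the signature of target-site duplication at an integration site.

# Orthology

The built-in protein search seeds candidate pairs by exact 5-mers and
scores them with affine-gap Smith–Waterman under BLOSUM62 (gap open 11,
extend 1); scores are checked against unrestricted Smith–Waterman in the
tests. Bit scores use fixed Karlin–Altschul parameters (λ = 0.267,
K = 0.041, the ungapped BLOSUM62 defaults), recorded in output headers so
the e-value provenance is explicit; e-values are m·n·2^(−S′). Externally
computed 12-column tabular hits can be supplied instead and are
authoritative when given, since real-data ortholog totals derive from
BLASTP. RBH applies the e-value filter first and then best-hit selection
(lowest e-value, ties by bit score, then lexicographic subject id) in both
directions; filter-then-best is the declared reading of the
underspecified order, and the monotonicity of pair counts in the cutoff
is a tested invariant.

# Neighborhood census

The neighborhood of an anchor (rdhA-like) gene contains the protein-coding
genes strictly fewer than five gene-order positions away on each side —
i.e. up to four per side, the literal reading of "less than 5
protein-coding genes upstream or downstream" — regardless of strand or
intergenic distance; RNA and repeat features do not consume a position,
and circular genomes wrap. A member counts towards a regulator category
when it carries at least one Pfam-style domain hit below the 0.001
e-value cutoff from that category's list: Crp/Fnr ⇐ {cNMP_binding,
HTH_Crp_2}; histidine-kinase/response-regulator ⇐ {HisKA, ATPase_c,
Response_reg, Trans_reg_C, PAS}; MarR ⇐ {MarR_2}; plus a configurable
"other regulatory" list. The category map ships as editable YAML rather
than code because signaling-domain vocabularies evolve. A member with
domains from several categories increments each, and the multi-counted
members are reported.

# The synthetic generator: what it emulates, and what it does not

`simulate_ancestor()` builds a circular chromosome of non-overlapping
random-codon CDSs (150–400 codons, both strands, G+C 0.45), rRNA-operon
placeholders (4 kb, one copy inverted so an inverted repeat pair exists),
IS elements (1 kb with 25 bp terminal inverted repeats) at specified copy
numbers with one copy of each multi-copy family inverted, and an
rdhA-like anchor gene with a Crp/Fnr-style regulator neighbor.
`derive_sisters()` plants, per region, an exact number of SNPs with an
exact non-synonymous (missense) count — constructive rejection sampling
against the translate-and-compare oracle, never approximate — plus
strain-specific IS transpositions, low-GC islands, intergenic deletions,
and inversions between planted inverted repeat pairs, and records
everything in final coordinates of both strains. SNPs avoid initiator and
stop codons, multi-copy elements, and codons already hit, keeping anchors
unambiguous and counts exact. Island junction bases are forced to differ
from the abutting ancestral bases so insertion boundaries are sharp at
base resolution. Structural events are placed in intergenic space (30 bp
clearance) so codon analyses stay clean — consistent with transposable
elements mostly residing in non-coding regions of real genomes.

The generator reproduces the *structure* of real sister-genome data, not
its full realism: no sequencing error, no assembly gaps, no
context-dependent mutation spectrum, random (not phylogenetically
structured) protein sequences, identical repeat copies rather than
diverged families, and single-contig genomes. Passing tests therefore
demonstrate that the algorithms recover what was planted under realistic
geometry and divergence, not that they are robust to annotation error or
assembly artifacts in arbitrary real data.

Study conditions used by the tests and the acceptance script, chosen to
mirror the motivating system: core identity planted at 99.87% on a ~2.8 Mb
pair (about 3,650 SNPs) with a 64 kb low-GC island; a selection hotspot of
70 SNPs with 67 non-synonymous against a background region of 25 SNPs
with 7; IS families at 9, 2, 1 and 0 copies; 100-protein proteomes with
10% paralog decoys at ~80% identity; 1.55 kb markers differing by 10
substitutions plus a 5' insertion; two-arm skew genomes of 80–100 kb with
|skew| 0.1–0.12 per arm. Smaller replicates (12-gene, ~20 kb genomes) are
used where a quantity is estimated over 100 seeded fixtures.

# Numerical and degenerate-input choices

* All coordinates are 0-based half-open on the forward strand throughout;
  strand is a flag, and no feature sequence is ever stored
  reverse-complemented.
* Alternative initiator codons translate as M at position 0 only.
* All-A/T windows give skew 0 with a degeneracy flag; an all-A/T genome
  gives "no confident call" instead of an arbitrary origin.
* Ties in chaining break towards smaller coordinates; ties in ranking
  towards smaller breakpoints; ties in best-hit selection towards higher
  bit score then lexicographic id — every ranked output is deterministic.
* One integer seed drives each generator invocation; the RNG state is
  restored afterwards, so library calls never perturb a caller's
  randomness.

# Known limitations

* Rearrangement handling is per-orientation chaining: nested or
  overlapping inversions, and translocations, are not decomposed into
  event sequences (no Hannenhalli–Pevzner machinery).
* The aligner assumes collinearity at the chain level; a genome pair with
  many rearrangements will fragment into chains without an ordering
  interpretation.
* E-values from the built-in protein search use fixed ungapped
  Karlin–Altschul constants; they are reproducible and internally
  consistent but not calibrated to BLAST's gapped statistics, which is
  why external tabular hits take precedence when supplied.
* Inversion breakpoints are reported at repeat midpoints; the true
  resolution point within the repeat is unknowable from sequence.
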