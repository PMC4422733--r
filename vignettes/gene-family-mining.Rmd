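---
title: "Mining gene families from de novo transcriptome assemblies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining gene families from de novo transcriptome assemblies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gstmine)
```

# The problem

A de novo transcriptome assembly is the only sequence resource for most
marine invertebrates, and mining it for a multi-gene family — here the
glutathione S-transferase (GST) detoxification superfamily of a calanoid
copepod — raises three coupled problems. First, homology search must be
*translated*: contigs are nucleotide sequences of unknown strand and
frame, queries are proteins from related species. Second, assemblies
truncate transcripts, so the deduced proteins must be classified as full
length or partial before any identity percentage is meaningful. Third,
when two independent assemblies of the same species exist, differences
between them mix assembly artifacts, population-level divergence of the
same gene, and genuinely distinct paralogs; separating those requires
explicit, reproducible identity thresholds. `gstmine` implements this
workflow end to end, with every step exposed as a testable function.

# The pipeline

## Translated search

Each panel protein is aligned by Smith–Waterman (BLOSUM62, gap open 11,
extension 1; a gap of length $k$ costs $11 + k$) against all six frame
translations of every contig; the best frame per contig is the candidate
hit. Significance uses the Karlin–Altschul form
$E = K\,m\,n\,e^{-\lambda S}$ with the ungapped BLOSUM62 parameters
($\lambda = 0.3176$, $K = 0.134$), $m$ the query length and $n$ the
total translated residues of the assembly. Ungapped parameters applied
to gapped scores make these E-values smaller than a properly calibrated
gapped model would give, so only their ordering is interpreted, never
their absolute scale. The default cutoff of $10^{-5}$ is deliberately
permissive: in the synthetic study
true hits score $S \gtrsim 125$ where the cutoff sits near $S \approx
86$, while decoy contigs peak around 75. Raw-score ranking is available
(`rank = "score"`) for users who distrust the E-value model entirely.

## ORF deduction and completeness

Within each frame translation, every maximal stop-free stretch of at
least `min_orf_len` residues (default 40) is a candidate ORF, reported
both as the full stretch and as its first-methionine form. Three
booleans — upstream in-frame stop, start methionine, downstream stop —
classify it:

| upstream stop | start Met | downstream stop | class |
|---|---|---|---|
| yes | yes | yes | full_length |
| no  | yes | yes | putative_full_length |
| —   | no  | yes | c_terminal_partial |
| —   | yes | no  | n_terminal_partial |
| —   | no  | no  | internal_fragment |

`putative_full_length` records proteins whose methionine cannot be
anchored by an upstream stop (typically the transcript begins at or near
the start codon). When the chosen ORF's methionine aligns with the
query's initial methionine, the classification is promoted to
`full_length` — the query anchors the start. The default `min_orf_len`
of 40 aa keeps genuine partial fragments (real partials in this family
are ≳ 90 aa) while discarding the very short spurious ORFs that random
UTR sequence produces.

Ties among candidate ORFs are broken by local-alignment score against
the query, then ORF length, then frame order (+1, +2, +3, −1, −2, −3);
the ordering is arbitrary but fixed, so results are deterministic.

## Identity, similarity and the region of overlap

Percent identity between two proteins is the number of identical aligned
residues divided by the length of the *longer* sequence (×100); percent
similarity additionally counts conservatively substituted residues,
defined by the Clustal strong and weak conservation groups (the `:` and
`.` line under an alignment). `X` and gap columns never count. For pairs
involving a partial protein the same counts are restricted to the region
of overlap — the closed column interval where both rows carry residues —
with the denominator the larger residue count within that span. Global
(Needleman–Wunsch) alignments underlie these percentages; because
co-optimal global alignments of weakly related sequences can differ by
pattern/subject order, the pair is aligned in a canonical orientation so
the metric is exactly symmetric. Reports round to whole percent;
full precision is kept internally and used for all threshold decisions.

## Reciprocal annotation and domain vetting

A deduced protein takes the class/subclass of its best local alignment
in a labeled reference panel, provided the score clears a floor (default
100, far above the empirical null of shuffled proteins, which stays
below ~75 at these lengths); anything below is `unassigned` and dropped
from family reports — this, not domain content, is the decoy filter.
Domain vetting is evidence, not a filter: each protein is scanned with
log-odds position-specific scoring matrices (PSSMs) for the GST
N-terminal, GST C-terminal, thioredoxin-like and MAPEG domains, built
from seed alignments shipped with the package, with presence thresholds
calibrated at the 99th percentile of a shuffled-protein null (so the
false-positive rate is ≤ 1%). Because scoring is position-specific, a
protein retaining only part of a domain scores near the null — which is
exactly the behaviour wanted for truncated termini: full-length
cytosolic proteins must show GSTN + GSTC, Kappa the thioredoxin-like
domain, microsomal proteins MAPEG, while partials may lack the domain at
the truncated end. The shipped seed alignments are *synthetic*
constructions (see below); users with curated seeds can point
`load_domain_profiles()` at their own directory.

The MAPEG motif `VERVRRxHLNDxENIx` (three `x` wildcards) is scanned
exhaustively; every window within the mismatch budget is reported with
its substitution list, each substitution classified conservative or not
by the same Clustal groups — a leucine→glutamine replacement at motif
position 9, for example, shares no group and is non-conservative.

## Cross-assembly correspondence

Annotated proteins from two assemblies are paired by bidirectional best
hit *within subclass* (pairing across subclasses would invite chimeric
matches), scored by overlap identity. Verdicts encode two field-standard
thresholds: overlap identity ≥ 90% (`t_same`) is the same gene; < 50%
(`t_distinct`, the top of the typical 30–50% within-subclass paralog
band) is a distinct gene; between the two the pair is reported as a
divergent ortholog — deliberately without asserting gene identity, since
an 88%-identical pair is more alike than any paralog pair yet short of
one-to-one correspondence. An unmatched protein whose identity to every
same-assembly subclass member is below `t_distinct` is an
additional-gene candidate; a targeted re-search of the other assembly
with the candidate as query either leaves it additional or, if a ≥
`t_same` (possibly partial) match surfaces, upgrades it to a same-gene
pair noted "present in both". Merging counts one gene per pair at or
above `t_distinct`, two for a distinct-gene pair, one per unmatched
protein; completeness merges to the best evidence (full beats partial).

One caveat the tests make explicit: when a cross-population pair is
*less* identical than the most similar within-subclass paralog, the
bidirectional best hit may pair the variant with the paralog instead.
Real GST data rarely meet this case (a 48%-identical pair typically has no closer
paralog); the verdict-mapping tests therefore keep paralogs below the
lowest cross-population target.

## Expression

RPKM is computed per library as
$\mathrm{rpkm} = c \,/\, (L/10^3 \cdot M/10^6)$ with $c$ the reads
mapped to the transcript, $L$ its length and $M$ the library's total
mapped reads — the total over the whole reference transcriptome, not
just the family, so the family's summed $\mathrm{rpkm} \cdot L_{kb}$
equals $10^6$ times its share of mapped reads (an identity the tests
check to $10^{-6}$ relative). Stage summaries are means and SDs of
$\log_2(\mathrm{rpkm} + 1)$ over replicates; the pseudocount of 1 puts
zero counts at zero on the log scale and only matters for low-expressed
transcripts. Read mapping and quality filtering are out of scope — the
count table is the interface.

# The synthetic study design

The generator exists so that every pipeline claim can be tested against
a known truth. Its default design mirrors the family structure the
workflow recovers from the real first-population assembly: Delta 11,
Theta 1, Mu 5, Omega 3, Sigma 10, Zeta 2, Kappa 1, mGST-1 2, mGST-3 4 —
39 genes — plus one population-private Delta and one private Omega gene
in the second population, so the merged catalog holds 41 genes.

Families are simulated by accept/reject point substitution on a class
architecture (M + leader + GSTN + linker + GSTC + tail for cytosolic,
similar single-domain layouts for Kappa and microsomal). Substitutions
prefer a same-strong-group residue 70% of the time, so percent
similarity always exceeds percent identity, as in real protein families.
Three kinds of positions are never mutated:

* *global anchors* — every 6th domain column, shared by all subclasses
  (catalytic/structural residues); they keep domains detectable by the
  PSSMs while leaving cross-subclass identity near 25%, and the MAPEG
  motif's fixed columns are anchored so the motif survives divergence
  (the mGST-1 lineage carries the planted glutamine at motif position 9);
* *lineage signatures* — 6.5% of positions, drawn per subclass after the
  ancestor diverges; they keep even heavily diverged paralogs closer to
  their own subclass panel than to any other, which is what makes
  reciprocal annotation recoverable at 30% within-subclass identity;
* the start methionine and short leader, so every family member keeps an
  alignable, query-matching N-terminus (this is what lets the
  query-anchored promotion of putative full-length proteins fire
  deterministically).

Each subclass ancestor is diverged to ~40% of the base architecture; one
labeled panel member branches off at ~80% of the ancestor; paralogs form
a star whose radii are set from the per-gene within-subclass identity
target (default band 30–60%, the divergence typical of same-subclass GST paralogs) and then
trimmed until the maximum pairwise identity to the other members falls
at the target. The two microsomal subclasses use a 50–77% band instead:
reported same-top-hit microsomal pairs sit near 77% identity, and
the short single-domain MAPEG architecture leaves no annotation margin
at cytosolic-style divergence — with a 30–60% band the two microsomal
subclasses blur into each other, which the real data say they do not.
Population-B variants are diverged from the population-A protein to a
per-gene cross-population target (default uniform 88–100%, the typical
between-population range); private genes use a 30–45% within band so
they read as additional genes rather than divergent orthologs.

Proteins are embedded by back-translation with uniform codon choice,
wrapped in random UTRs (30–90 nt) with an in-frame stop planted directly
upstream of the start codon; 25% of full-length plants keep no 5′ UTR
(the putative-full-length case), and 15% of plants are truncated
codon-aligned into C- or N-terminal partials (10–30% of the ORF
removed). Transcripts land on a random strand with a random frame shift.
Decoys are random nucleotide contigs plus back-translations of shuffled
planted proteins — the latter match the family's residue composition, so
they exercise the score floor rather than trivial composition
differences. Counts are multinomial over planted transcripts plus a
fixed background mass (the rest of the transcriptome, ~95% of reads),
with sampling weight level × length, log-normal replicate noise
(σ = 0.25), and class-specific stage profiles (cytosolic: embryo-low,
late-copepodite/adult-high; mitochondrial/microsomal: flat after a lower
embryo level).

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: codon usage bias, indels and frameshifts
within ORFs, chimeric or fragmented assembly artifacts, isoforms,
sequencing error, and any read-level process (counts are drawn, not
mapped). Real mining additionally depends on the richness of the
reference panel (the synthetic panel is one member per subclass; NCBI nr
is not), so synthetic recovery rates are upper bounds, not estimates, of
real-data performance.

# Problem sizes and runtime choices

The shipped study uses ~140 contigs per population (39–41 planted + 100
decoys), a 9-member panel, and 18 libraries (6 stages × 3 replicates) at
2 × 10⁶ reads — sizes chosen so the full two-population pipeline runs in
well under a minute per seed and the complete validation (ten seeded
scenario replicates plus the alignment and metric oracles) stays within
a casual desk session. All randomness flows from explicit seeds; the
same seed gives byte-identical FASTA output.

# Known limitations

* E-values borrow ungapped Karlin–Altschul parameters for gapped scores;
  only their ordering is meaningful, and no composition-based correction
  is applied.
* The search is exhaustive Smith–Waterman per frame — right for
  hundreds of contigs, wrong for millions; there is no k-mer seeding.
* Domain calls are presence/absence with approximate spans; PSSMs have
  no insert states, so domain boundaries are not trustworthy to the
  residue, and the shipped seed alignments are synthetic stand-ins, not
  curated family seeds.
* Frame-local alignment only: a frameshifted ORF is recovered as two
  candidates, never stitched.
* The correspondence verdicts inherit their default thresholds (90/50) from this
  family's reported identity structure; they are configurable but no
  attempt is made to estimate them from data.
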