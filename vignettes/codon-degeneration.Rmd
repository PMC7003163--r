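---
title: "Codon degeneration, alignment scoring, and supermatrix hygiene"
author: "codonDegen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Codon degeneration, alignment scoring, and supermatrix hygiene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonDegen)
```

## The problem

Deep phylogenies built from concatenated protein-coding genes suffer from two
recurring artifacts. First, third codon positions evolve so fast that their
nucleotide composition converges between unrelated lineages (GC3 in a single
arthropod supermatrix can range from roughly 38% to 80% among close relatives),
so silent sites carry homoplasy rather than signal. Second, multiple sequence
alignments of divergent sequences are rarely checked for quality, and a poor
alignment biases everything downstream.

A classical remedy is to *degenerate* codons: replace them with IUPAC-ambiguous
triplets so that synonymous codons become identical or inter-convertible. The
widely used Degen1 protocol degenerates every varying position of an amino
acid's codon set, which can overshoot: all six leucine codons become YTN, but
YTN also contains the phenylalanine codons TTT and TTC, so the distinction
between two *different* amino acids is erased along with the silent variation.

This package implements a purity-preserving alternative alongside Degen1, plus
the machinery a codon-aware supermatrix workflow needs around it: ambiguity-
aware alignment scoring, PWM-based refinement, protein-guided codon threading,
concatenation, serine-site filtering, GC3 diagnostics, and Fitch parsimony
switch counting.

## Synonymous subfamilies and the two protocols

An amino acid's codons split into *subfamilies* sharing their first two
positions: standard-code leucine is CT{T,C,A,G} plus TT{A,G}, serine is
TC{T,C,A,G} plus AG{T,C}. Within each subfamily the third position is freely
degenerated (CTN, TTR, TCN, AGY) — that much is always synonymous.

The protocols differ in how subfamilies are merged:

* **Principled.** Only the *smaller* subfamily is degenerated at the one
  prefix position where it differs from the largest subfamily, and only if
  every codon in the resulting class is still synonymous. Leucine becomes
  CTN / YTR: the two classes share CTA and CTG ("compatible"), giving a
  single-substitution path between them, while YTR excludes the phenylalanine
  codons. If the subfamilies differ at both prefix positions (serine) or are
  equally sized, no merge is attempted and the family is reported as
  incompatible. In NCBI code 24, where lysine is AAA/AAG/AGG, the protocol
  yields AAR / ARG — and correctly refuses ARR, which would swallow the
  serine codon AGA.
* **Degen1.** All subfamilies that agree at one prefix position are merged by
  taking the IUPAC union at every varying position over the full codon set:
  leucine YTN, arginine MGN. No purity constraint is applied.

```{r degen}
code <- geneticCode(1)
mp <- principledMap(code)
degenMapping(mp)[c("CTC", "TTG", "TCA", "AGT")]
incompatibleFamilies(mp)
degenMapping(degen1Map(code))[c("TTA", "CTT", "TTT")]
```

Both builders work for every NCBI translation table shipped with
`Biostrings` (`supportedGeneticCodes()`), and the principled map is verified
exhaustively in the test suite: for every codon of every table, its image
resolves only to synonymous codons, and all non-flagged degenerate classes of
an amino acid pairwise share codons.

Design choices where the protocol definition is open:

* Subfamilies of equal size: no merge, the family is flagged. The merge rule
  is stated for unequal sizes only, and an arbitrary direction would be
  asymmetric.
* More than two subfamilies: the merge is attempted pairwise between the
  largest subfamily and each smaller one, followed by a pairwise
  compatibility check over the final images (no shipped table actually
  trips it).
* Stop codons map to themselves and form no subfamilies; codons containing
  input ambiguity pass through `degenerateMsa()` unchanged, which also makes
  the operation idempotent.

## Ambiguity-averaged alignment scoring

Scores start from a match/transition/transversion scheme (+1 / −1 / −2 by
default) and are extended to all 15 IUPAC symbols by averaging over resolved
pairs: the A/R entry is the mean of A/A and A/G, i.e. 0; A/Y is always a
transversion, −2.

```{r score}
m <- expandScoreMatrix(scoreScheme())
m[c("A", "R", "Y", "N"), c("A", "R", "Y", "N")]
```

The canonical three-sequence example — leucine codons CTC and TTG plus
phenylalanine codon TTC — shows why degeneration protocol choice matters.
Undegenerated, the two synonymous codons score *worse* with each other (−2)
than either does with the nonsynonymous codon (1 and 0). Degen1 flattens all
three pairs to 0. The principled coding gives 0 for the synonymous pair and
−1 for both nonsynonymous pairs, the ordering homology intuition demands:

```{r walkthrough}
plain <- Msa(c(S1 = "CTC", S2 = "TTG", S3 = "TTC"))
sapply(list(plain = plain,
            degen1 = degenerateMsa(plain, degen1Map(code)),
            principled = degenerateMsa(plain, principledMap(code))),
    function(x) {
        s <- msaSeqs(x)
        c(AS12 = pairScore(s[1], s[2]), AS13 = pairScore(s[1], s[3]),
          AS23 = pairScore(s[2], s[3]))
    })
```

`spScore()` sums all pairwise scores of an MSA and is the quality criterion
used to pick among candidate alignments of the same content
(`selectBestAlignment()`; exact ties keep the first candidate). Gap handling:
each maximal residue-versus-gap run is penalized affinely (gap open −5, gap
extension −1 by default; both configurable), runs are identified per
gap-bearing sequence within each pair, and columns gapped in both sequences
are free and do not re-open a run. The defaults are conventional; the worked
examples above are gap-free, so they do not depend on them. Published
large-scale SP values for this kind of data depend on unstated gap penalties,
so the package treats such pairs relationally — the better alignment must
score higher — rather than as numeric targets.

## PWM refinement

`buildPwm()` computes, per site and nucleotide, the log (base 2 by default)
of the smoothed site frequency over the background frequency across all
non-gap residues. Zero means indifferent, positive preferred, negative
avoided. Counts get an add-one pseudocount by default (both cadence and base
are unstated in the refinement literature this follows; add-one and log2 are
the standard choices); the background is smoothed with the same pseudocount
so the ratio is always defined, and with pseudocount 0 the definition reduces
to the raw one. Gaps, `?` and ambiguity codes are excluded from counts; a
symbol absent from the whole alignment scores 0 everywhere rather than
propagating infinities.

`refineMsa()` uses the PWM to repair a common aligner artifact: a residue
stranded at the wrong end of a gap run. The only move is sliding a
gap-bordering residue to the opposite end of its run, accepted only when it
strictly increases the PWM-sum objective, so ungapped content and alignment
width are invariant by construction. The PWM is rebuilt once per pass (not
per move, for determinism and stability); scanning is deterministic
(sequences in order, runs left to right, left border before right, first
improvement taken; ties never move); passes repeat to a fixpoint or
`maxIter`.

```{r refine}
r <- refineMsa(Msa(c(a = "AG--T", b = "A--GT", c = "A--GT", d = "A--GT")))
msaSeqs(r$msa); r$moves
```

## Threading, supermatrix assembly, filtering, GC3

`translateCodons()` / `threadCodons()` implement the align-by-protein,
map-back-to-codons workflow: codons are threaded onto a protein alignment
after an exact translation check, gaps expanding to whole triples, so
degapping the result recovers the input codon sequences byte for byte.
Ambiguous codons translate to their amino acid only when every resolution
agrees, else `X`; terminal stops are stripped with a warning and internal
stops fail by default (a loud frame-error guard).

`concatenateGenes()` assembles per-gene alignments over partially overlapping
taxon sets, filling absent taxa with `?` (distinct from the `-` gap;
configurable) and reporting 1-based partition coordinates. The conventional
`NNNNNN` gene separator is written only on request and belongs to no
partition — it is a file convention, not signal.

`serineSiteFilter()` removes codon sites at which one row carries an
AG-prefixed codon and a different row a TC-prefixed codon. Such sites are
identical at the amino-acid level (both classes encode serine in the standard
code) but maximally divergent at the nucleotide level, dragging
nucleotide-based trees away from the amino-acid tree. The literal two-letter
prefix rule is the default reading; `strict = TRUE` restricts it to rows
whose codon actually translates to serine, since AGR is arginine in the
standard code. Both readings are supported because published descriptions of
the filter say "AGN" while standard-code serine is AGY.

`gc3()` reports the percentage of G+C at third codon positions, excluding
`-`, `?` and `N` from the denominator (partial ambiguity codes remain in it,
with G/C/S counted as G+C) — the compositional diagnostic that motivates
degeneration in the first place.

## Fitch parsimony switch counting

`stateTree()` wraps a rooted, strictly binary `ape` tree with one discrete
state per tip (`?` marks unknown, reconstructed over the full alphabet);
multifurcations are rejected rather than silently resolved, because silent
resolution changes counts. `fitchCount()` runs the post-order
intersection-else-union reconstruction; the number of union events is the
minimum number of state switches the tree requires. On the chelicerate
habitat example (aquatic Xiphosura and Eurypterida among terrestrial
relatives), placing Eurypterida sister to Scorpiones or to Arachnopulmonata
needs two habitat switches, while the aquatic-clade topology (Eurypterida
sister to Xiphosura — the unique placement among those discussed that is most
parsimonious) needs one:

```{r fitch}
states <- c(Xiphosura = "W", Eurypterida = "W", Scorpiones = "L",
    Tetrapulmonata = "L", Outgroup = "L")
fitchCount(stateTree(
    "((Xiphosura,((Eurypterida,Scorpiones),Tetrapulmonata)),Outgroup);",
    states))$switches
fitchCount(stateTree(
    "(((Eurypterida,Xiphosura),(Scorpiones,Tetrapulmonata)),Outgroup);",
    states))$switches
```

The tests check the union count against an exhaustive minimum over all
internal-state assignments on random trees of up to 8 tips, and against
`phangorn::fitch` as an independent implementation.

## Synthetic fixtures: what they emulate and what they do not

`makeFixture()` generates seed-deterministic multi-gene codon alignments
with: per-taxon GC3 targets (defaulting to the 0.35–0.80 range typical of
deep arthropod supermatrices), a known number of injected AGN/UCN
co-occurrence sites (background codons avoid AG/TC prefixes and stop codons,
so the injected sites are provably the only removable ones), whole-codon gap
triples, and partial taxon overlap across genes. `makeRefineFixture()`
produces a conserved alignment with a shared gap run and a known number of
residues slid to the wrong end of it; the run's border columns are kept
conserved so the propensity signal is unambiguous.

These fixtures make ground truth exact, which is what the property suites
need; they are *not* realistic sequence evolution. There is no substitution
model, no indel process, no among-site rate variation, and conservation is
far higher than in real deep-divergence data. Passing tests demonstrate that
the operations implement their definitions (counts exact, content preserved,
coordinates right), not that the protocols resolve any particular phylogeny.

## Numerical and degenerate-input choices

Scores are sums and means of small rationals computed in doubles; all worked
examples are exact integers or halves, and the test oracles recompute matrix
entries by brute-force averaging to 1e-12. Frame violations (length not a
multiple of 3, a gap breaking a triple) are errors naming the sequence and
codon site. An alignment-wide empty column yields a zero PWM row with a
warning; GC3 of a sequence with no countable third positions is `NA` with a
warning. Problem sizes in the tests (alignments up to a few hundred codons,
trees to 8 tips for the exhaustive oracle, 25 randomized replicates) keep
every exhaustive check cheap while covering all code paths.

## Limitations

* No aligner is included: the package scores, selects, refines and threads
  alignments but never builds one (the `align-aa` CLI hook shells out to
  MAFFT/MUSCLE when present).
* No tree inference: likelihood and Bayesian analyses of degenerated
  supermatrices are downstream of this package.
* Refinement is nucleotide-only and single-residue-slide only, per its
  defining use case.
* Fitch counting is unweighted and ignores branch lengths; ancestral-state
  sets are the standard first-pass sets, not the full MPR enumeration.
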