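# codonDegen

Codon-aware supermatrix utilities for deep phylogenomics: principled codon
degeneration, ambiguity-averaged alignment scoring, PWM alignment refinement,
codon-onto-protein threading, supermatrix assembly with serine-site filtering
and GC3 diagnostics, and Fitch parsimony state-switch counting.

## The problem and the core idea

Third codon positions of protein-coding genes accumulate compositional
convergence (GC3 varying by tens of percentage points among related taxa),
which injects homoplasy into nucleotide-based deep phylogenies. Degenerating
codons with IUPAC ambiguity codes suppresses this, but the widely used Degen1
protocol merges too aggressively: all six standard-code Leu codons become
YTN, a class that also contains the Phe codons TTY, erasing a genuine
amino-acid difference.

The *principled* protocol implemented here degenerates codon positions 1–2
only in the smaller synonymous subfamily, and only when the resulting class
stays pure (contains nothing but synonymous codons). Writing an amino acid's
codon subfamilies as prefix + third position (Leu = CTN ∪ TTR), the rule
produces classes that are *compatible* — they share at least one codon, e.g.

    Leu:  CTN, YTR        (YTR ∩ CTN ⊇ {CTA, CTG};  TTY excluded)
    Lys (code 24):  AAR, ARG   (ARG ∩ AAR = {AAG};  Ser codon AGA excluded)

Alignment quality is judged by the sum-of-pairs (SP) criterion under an
ambiguity-averaged match/mismatch matrix: entry(X,Y) is the mean of the base
scores (+1 match, −1 transition, −2 transversion by default) over all
resolved pairs, so entry(A,R) = 0 and entry(A,Y) = −2, with affine gap
penalties and shared gaps free.

## Worked example

```r
library(codonDegen)

code  <- geneticCode(1)
plain <- Msa(c(S1 = "CTC", S2 = "TTG", S3 = "TTC"))  # Leu, Leu, Phe

s <- msaSeqs(plain)
c(pairScore(s[1], s[2]), pairScore(s[1], s[3]), pairScore(s[2], s[3]))
#> [1] -2  1  0

pr <- msaSeqs(degenerateMsa(plain, principledMap(code)))
pr
#>    S1    S2    S3
#> "CTN" "YTR" "TTY"
c(pairScore(pr[1], pr[2]), pairScore(pr[1], pr[3]), pairScore(pr[2], pr[3]))
#> [1]  0 -1 -1
```

Undegenerated, the two synonymous Leu codons score worse with each other
(−2) than with the nonsynonymous Phe codon — exactly backwards. Degen1
(`degen1Map`) flattens all three pairs to 0. The principled coding restores
the right ordering: synonymous pair 0, nonsynonymous pairs −1.

Further down the workflow:

```r
fx <- makeFixture(nTaxa = 6, nCodons = 40, nGenes = 3, seed = 1)
sm <- concatenateGenes(fx$genes, separator = "NNNNNN")
sm$partitions                       # 1-based per-gene coordinates
serineSiteFilter(fx$genes[[1]])$removedCount   # AGN/UCN co-occurrence sites
gc3(fx$genes[[1]])                  # per-taxon GC3 percentages

st <- stateTree("(((Eurypterida,Xiphosura),(Scorpiones,Tetrapulmonata)),Outgroup);",
    c(Xiphosura = "W", Eurypterida = "W", Scorpiones = "L",
      Tetrapulmonata = "L", Outgroup = "L"))
fitchCount(st)$switches
#> [1] 1
```

A command-line front end covering the same operations ships at
`inst/scripts/degenphy.R` (subcommands: `codes degen sp sp-compare refine
thread align-aa concat filter-ser gc3 fitch fixture`).

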