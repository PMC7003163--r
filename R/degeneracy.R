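# Third-position image of a subfamily: prefix + IUPAC symbol over its thirds.
.thirdImage <- function(sf) paste0(sf@prefix, iupacSymbol(sf@third))

#' Are two degenerate codons compatible?
#'
#' Two IUPAC-degenerate codons are compatible when their resolved codon sets
#' share at least one codon, i.e. there is a single-substitution evolutionary
#' path between the classes. CTN and YTR are compatible (CTA, CTG in both);
#' YTR and TTY are not.
#'
#' @param a,b IUPAC codon strings.
#' @return logical.
#' @examples
#' codonsCompatible("CTN", "YTR")  # TRUE
#' codonsCompatible("YTR", "TTY")  # FALSE
#' @export
codonsCompatible <- function(a, b) {
    length(intersect(resolveCodon(a), resolveCodon(b))) > 0L
}

#' Build the purity-preserving ("principled") degeneration map
#'
#' Within each amino acid, every subfamily's third position is degenerated to
#' the IUPAC symbol covering its third positions. For each subfamily strictly
#' smaller than the amino acid's largest one, if its prefix differs from the
#' largest subfamily's prefix at exactly one of positions 1-2, that position
#' is degenerated to the IUPAC union of the two subfamilies' symbols there --
#' accepted only if every codon in the resulting class remains synonymous
#' (purity). Otherwise the subfamily keeps its unambiguous prefix and the
#' amino acid is recorded as incompatible.
#'
#' Standard-code leucine thus becomes CTN / YTR; serine (subfamilies differing
#' at both prefix positions) stays TCN / AGY and is flagged; in code 24 the
#' lysine family AAA, AAG, AGG becomes AAR / ARG.
#'
#' @param code a \linkS4class{GeneticCode}.
#' @return a \linkS4class{DegenerationMap} with \code{protocol = "principled"}.
#' @examples
#' m <- principledMap(geneticCode(1))
#' degenMapping(m)[c("CTC", "TTG", "TCA", "AGT")]
#' incompatibleFamilies(m)   # includes "S"
#' @export
principledMap <- function(code) {
    stopifnot(is(code, "GeneticCode"))
    ct <- code@codonToAa
    mapping <- setNames(names(ct), names(ct))   # identity, incl. stops
    incompat <- character(0)
    for (aa in sort(unique(ct[ct != "*"]))) {
        subs <- subfamilies(code, aa)
        images <- vapply(subs, .thirdImage, character(1))
        if (length(subs) > 1L) {
            L <- subs[[1L]]
            lch <- strsplit(L@prefix, "")[[1]]
            for (k in seq_along(subs)[-1L]) {
                S <- subs[[k]]
                merged <- FALSE
                if (length(S@codons) < length(L@codons)) {
                    sch <- strsplit(S@prefix, "")[[1]]
                    dpos <- which(sch != lch)
                    if (length(dpos) == 1L) {
                        sch2 <- sch
                        sch2[dpos] <- iupacSymbol(c(sch[dpos], lch[dpos]))
                        cand <- paste0(paste(sch2, collapse = ""),
                            iupacSymbol(S@third))
                        if (all(ct[resolveCodon(cand)] == aa)) {
                            images[k] <- cand
                            merged <- TRUE
                        }
                    }
                }
                if (!merged) incompat <- union(incompat, aa)
            }
            # all final classes of a non-flagged amino acid must pairwise share
            # codons; no table 1-26 case fails this, but guard anyway
            if (!aa %in% incompat && length(images) > 1L) {
                prs <- utils::combn(images, 2L)
                ok <- all(apply(prs, 2L, function(p)
                    codonsCompatible(p[1L], p[2L])))
                if (!ok) incompat <- union(incompat, aa)
            }
        }
        for (k in seq_along(subs))
            mapping[subs[[k]]@codons] <- images[k]
    }
    new("DegenerationMap", code = code, protocol = "principled",
        mapping = mapping, incompatibleFamilies = sort(incompat))
}

#' Build the Degen1 degeneration map
#'
#' The classical protocol of Regier and colleagues: within each amino acid,
#' if all subfamilies agree at one of codon positions 1-2, every codon is
#' degenerated at each varying position to the IUPAC union over the amino
#' acid's full codon set (standard-code leucine: all six codons become YTN;
#' arginine becomes MGN). If subfamilies differ at both positions 1 and 2
#' (standard-code serine), each subfamily is degenerated at the third position
#' only (TCN and AGY; no cross-subfamily merge). Purity is not enforced: YTN
#' resolves to phenylalanine codons as well as leucine ones.
#'
#' @param code a \linkS4class{GeneticCode}.
#' @return a \linkS4class{DegenerationMap} with \code{protocol = "degen1"}.
#' @examples
#' m <- degen1Map(geneticCode(1))
#' degenMapping(m)[c("TTA", "CTT", "TTT", "CGA")]
#' @export
degen1Map <- function(code) {
    stopifnot(is(code, "GeneticCode"))
    ct <- code@codonToAa
    mapping <- setNames(names(ct), names(ct))
    incompat <- character(0)
    for (aa in sort(unique(ct[ct != "*"]))) {
        subs <- subfamilies(code, aa)
        codons <- unlist(lapply(subs, subfamilyCodons))
        p1 <- unique(substr(codons, 1L, 1L))
        p2 <- unique(substr(codons, 2L, 2L))
        if (length(p1) == 1L || length(p2) == 1L) {
            img <- paste0(iupacSymbol(p1), iupacSymbol(p2),
                iupacSymbol(unique(substr(codons, 3L, 3L))))
            mapping[codons] <- img
        } else {
            # subfamilies differ at both of positions 1-2: degenerate each
            # subfamily independently at the third position only
            for (sf in subs)
                mapping[sf@codons] <- .thirdImage(sf)
            incompat <- union(incompat, aa)
        }
    }
    new("DegenerationMap", code = code, protocol = "degen1",
        mapping = mapping, incompatibleFamilies = sort(incompat))
}

#' @describeIn principledMap the codon-to-IUPAC-triplet mapping.
#' @param x a \code{DegenerationMap}.
#' @export
degenMapping <- function(x) x@mapping

#' @describeIn principledMap amino acids whose subfamilies could not be made
#'   compatible.
#' @export
incompatibleFamilies <- function(x) x@incompatibleFamilies

#' @describeIn principledMap the protocol tag.
#' @export
degenProtocol <- function(x) x@protocol

#' @export
setMethod("show", "DegenerationMap", function(object) {
    cat(sprintf("DegenerationMap: protocol '%s' on NCBI table %d\n",
        object@protocol, object@code@tableId))
    changed <- sum(object@mapping != names(object@mapping))
    cat(sprintf("  %d of %d codons degenerated; incompatible families: %s\n",
        changed, length(object@mapping),
        if (length(object@incompatibleFamilies))
            paste(object@incompatibleFamilies, collapse = ", ") else "none"))
})

#' Apply a degeneration map to a codon alignment
#'
#' Every unambiguous in-frame sense codon is replaced by its degenerate image.
#' Gap/missing triples, stop codons, and codons already containing ambiguity
#' codes pass through unchanged, so the operation is idempotent. Sequence
#' identifiers, lengths, and gap positions are preserved.
#'
#' @param msa a nucleotide \linkS4class{Msa}; sequence lengths must be
#'   divisible by 3 and gaps must occupy whole codon triples.
#' @param map a \linkS4class{DegenerationMap}.
#' @return the degenerated \linkS4class{Msa}.
#' @examples
#' m <- principledMap(geneticCode(1))
#' msaSeqs(degenerateMsa(Msa(c(a = "CTC", b = "TTG", c = "TTC")), m))
#' @export
degenerateMsa <- function(msa, map) {
    stopifnot(is(msa, "Msa"), is(map, "DegenerationMap"))
    if (msa@alphabet != "DNA")
        stop("degeneration is defined on nucleotide alignments")
    mp <- map@mapping
    out <- vapply(seq_along(msa@seqs), function(i) {
        triples <- .codonSplit(msa@seqs[i], msa@ids[i])
        hit <- triples %in% names(mp)
        triples[hit] <- mp[triples[hit]]
        paste(triples, collapse = "")
    }, character(1))
    new("Msa", ids = msa@ids, seqs = out, alphabet = "DNA")
}
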