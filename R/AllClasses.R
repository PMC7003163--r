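#' @import methods
#' @importFrom stats setNames
NULL

# Gap and missing symbols shared across the package. '-' is an alignment gap,
# '?' is supermatrix missing data; they are distinct everywhere (PWM counts,
# GC3 denominators) but both denote "no residue" when scoring.
.GAP_CHARS <- c("-", "?")

#' Multiple sequence alignment container
#'
#' An \code{Msa} holds equal-length gapped sequences with unique identifiers
#' and an alphabet tag (\code{"DNA"} or \code{"AA"}). It is the unit of
#' scoring, refinement, degeneration and concatenation throughout the package.
#'
#' @slot ids character vector of unique sequence identifiers.
#' @slot seqs character vector of gapped sequences, all the same width.
#' @slot alphabet either \code{"DNA"} or \code{"AA"}.
#' @export
setClass("Msa",
    representation(ids = "character", seqs = "character", alphabet = "character"))

setValidity("Msa", function(object) {
    msg <- character()
    if (length(object@ids) != length(object@seqs))
        msg <- c(msg, "ids and seqs must have equal length")
    if (anyDuplicated(object@ids))
        msg <- c(msg, sprintf("duplicate identifiers: %s",
            paste(unique(object@ids[duplicated(object@ids)]), collapse = ", ")))
    if (length(object@seqs) > 0L) {
        w <- nchar(object@seqs)
        if (length(unique(w)) > 1L)
            msg <- c(msg, "ragged alignment: sequences differ in length")
    }
    if (length(object@alphabet) != 1L || !object@alphabet %in% c("DNA", "AA"))
        msg <- c(msg, "alphabet must be \"DNA\" or \"AA\"")
    if (length(msg)) msg else TRUE
})

#' Genetic code table
#'
#' Wraps one NCBI translation table: the mapping of all 64 unambiguous codons
#' (alphabet T, C, A, G) to one-letter amino acids, with \code{"*"} as the
#' stop marker.
#'
#' @slot tableId integer NCBI translation-table number.
#' @slot name human-readable table name.
#' @slot codonToAa named character vector of length 64.
#' @export
setClass("GeneticCode",
    representation(tableId = "integer", name = "character",
        codonToAa = "character"))

setValidity("GeneticCode", function(object) {
    msg <- character()
    ct <- object@codonToAa
    if (length(ct) != 64L)
        msg <- c(msg, "codonToAa must map exactly 64 codons")
    if (!all(grepl("^[TCAG]{3}$", names(ct))))
        msg <- c(msg, "codon keys must be triplets over {T,C,A,G}")
    if (anyDuplicated(names(ct)))
        msg <- c(msg, "duplicate codon keys")
    if (!all(grepl("^[A-Z*]$", ct)))
        msg <- c(msg, "each codon must map to one amino acid letter or \"*\"")
    if (length(msg)) msg else TRUE
})

#' Synonymous codon subfamily
#'
#' The set of an amino acid's codons sharing their first two positions, e.g.
#' leucine in the standard code splits into the CT subfamily (third position
#' T/C/A/G) and the TT subfamily (third position A/G).
#'
#' @slot aminoAcid one-letter amino acid code.
#' @slot prefix the shared two-nucleotide prefix (codon positions 1-2).
#' @slot third sorted character vector, the subfamily's third positions.
#' @slot codons the implied codon set.
#' @export
setClass("SynonymousSubfamily",
    representation(aminoAcid = "character", prefix = "character",
        third = "character", codons = "character"))

setValidity("SynonymousSubfamily", function(object) {
    msg <- character()
    if (!grepl("^[TCAG]{2}$", object@prefix))
        msg <- c(msg, "prefix must be two unambiguous nucleotides")
    if (length(object@third) < 1L || !all(object@third %in% c("T", "C", "A", "G")))
        msg <- c(msg, "third positions must be a nonempty subset of {T,C,A,G}")
    if (!setequal(object@codons, paste0(object@prefix, object@third)))
        msg <- c(msg, "codons must equal prefix x third positions")
    if (length(msg)) msg else TRUE
})

#' Codon degeneration map
#'
#' Maps every sense codon of a genetic code to an IUPAC-degenerate codon under
#' either the purity-preserving \code{"principled"} protocol or the classical
#' \code{"degen1"} protocol. Stop codons map to themselves. Amino acids whose
#' subfamilies could not be made mutually compatible are recorded in
#' \code{incompatibleFamilies}.
#'
#' @slot code the underlying \linkS4class{GeneticCode}.
#' @slot protocol \code{"principled"} or \code{"degen1"}.
#' @slot mapping named character vector, unambiguous codon to IUPAC triplet.
#' @slot incompatibleFamilies character vector of one-letter amino acids.
#' @export
setClass("DegenerationMap",
    representation(code = "GeneticCode", protocol = "character",
        mapping = "character", incompatibleFamilies = "character"))

setValidity("DegenerationMap", function(object) {
    msg <- character()
    if (!object@protocol %in% c("principled", "degen1"))
        msg <- c(msg, "protocol must be \"principled\" or \"degen1\"")
    ct <- object@code@codonToAa
    sense <- names(ct)[ct != "*"]
    if (!all(sense %in% names(object@mapping)))
        msg <- c(msg, "every sense codon must appear as a key")
    ok <- vapply(names(object@mapping), function(cd)
        cd %in% resolveCodon(object@mapping[[cd]]), logical(1))
    if (!all(ok))
        msg <- c(msg, "each codon must be contained in its image's resolved set")
    if (length(msg)) msg else TRUE
})

#' Alignment scoring scheme
#'
#' Base nucleotide match/transition/transversion scores plus affine gap
#' penalties. Defaults follow the +1/-1/-2 convention with gap open -5 and
#' gap extension -1.
#'
#' @slot match score for identical unambiguous bases.
#' @slot transition score for a purine-purine or pyrimidine-pyrimidine mismatch.
#' @slot transversion score for a purine-pyrimidine mismatch.
#' @slot gapOpen penalty for the first column of a residue-vs-gap run.
#' @slot gapExtend penalty for each further column of the run.
#' @export
setClass("ScoreScheme",
    representation(match = "numeric", transition = "numeric",
        transversion = "numeric", gapOpen = "numeric", gapExtend = "numeric"))

#' Position weight matrix over an alignment
#'
#' Per-site log ratios of smoothed site-specific symbol frequencies over
#' background frequencies: positive means preferred at a site, negative
#' avoided, zero neither.
#'
#' @slot values numeric matrix, one row per alignment site, columns A,C,G,T.
#' @slot background smoothed per-symbol frequencies over all non-gap residues.
#' @slot pseudocount smoothing pseudocount added to counts.
#' @slot logBase base of the logarithm.
#' @export
setClass("Pwm",
    representation(values = "matrix", background = "numeric",
        pseudocount = "numeric", logBase = "numeric"))

#' Rooted binary tree with discrete tip states
#'
#' Carrier for Fitch parsimony: an \code{ape} \code{phylo} tree, strictly
#' binary and rooted, plus a state symbol per tip (\code{NA} or \code{"?"}
#' marks an unknown tip, reconstructed over the full alphabet).
#'
#' @slot tree an \code{ape::phylo} object.
#' @slot tipStates named character vector, one state per tip label.
#' @slot alphabet sorted unique known states.
#' @export
setClass("StateTree",
    representation(tree = "ANY", tipStates = "character", alphabet = "character"))

setValidity("StateTree", function(object) {
    msg <- character()
    tr <- object@tree
    if (!inherits(tr, "phylo"))
        msg <- c(msg, "tree must be an ape phylo object")
    else {
        if (!ape::is.rooted(tr))
            msg <- c(msg, "tree must be rooted")
        tab <- tabulate(tr$edge[, 1L])
        bad <- which(tab > 2L)
        if (length(bad))
            msg <- c(msg, sprintf(
                "multifurcation at internal node(s) %s: only binary trees are supported",
                paste(bad, collapse = ", ")))
        if (!setequal(names(object@tipStates), tr$tip.label))
            msg <- c(msg, "tipStates names must match tip labels exactly")
    }
    if (length(object@alphabet) < 1L)
        msg <- c(msg, "alphabet must contain at least one known state")
    if (length(msg)) msg else TRUE
})
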