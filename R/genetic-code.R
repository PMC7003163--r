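#' Supported NCBI genetic code tables
#'
#' @return data.frame with columns \code{id} (integer) and \code{name}.
#' @export
supportedGeneticCodes <- function() {
    tab <- Biostrings::GENETIC_CODE_TABLE
    data.frame(id = as.integer(tab$id), name = tab$name,
        stringsAsFactors = FALSE)
}

#' Build a genetic code from its NCBI translation-table number
#'
#' Codon keys use the DNA alphabet (T, not U). The standard code is table 1;
#' table 24 is the one where AGG codes lysine, so that the lysine family is
#' AAA, AAG, AGG.
#'
#' @param tableId integer NCBI translation-table number.
#' @return a validated \linkS4class{GeneticCode}.
#' @examples
#' gc1 <- geneticCode(1)
#' codonTable(gc1)[["CTT"]]   # "L"
#' @export
geneticCode <- function(tableId) {
    tableId <- as.integer(tableId)
    sup <- supportedGeneticCodes()
    if (length(tableId) != 1L || is.na(tableId) || !tableId %in% sup$id)
        stop(sprintf(
            "unsupported genetic code table '%s'; supported NCBI tables: %s",
            paste(tableId, collapse = ","), paste(sup$id, collapse = ", ")))
    ct <- Biostrings::getGeneticCode(as.character(tableId))
    ct <- setNames(as.character(ct), names(ct))
    new("GeneticCode", tableId = tableId,
        name = sup$name[match(tableId, sup$id)], codonToAa = ct)
}

#' @describeIn geneticCode the 64-codon translation vector.
#' @param x a \code{GeneticCode}.
#' @export
codonTable <- function(x) x@codonToAa

#' @describeIn geneticCode the NCBI table number.
#' @export
tableId <- function(x) x@tableId

#' @export
setMethod("show", "GeneticCode", function(object) {
    cat(sprintf("GeneticCode: NCBI table %d (%s)\n", object@tableId, object@name))
    aas <- sort(unique(object@codonToAa))
    cat(sprintf("  %d amino acids + stop; %d stop codon(s)\n",
        sum(aas != "*"), sum(object@codonToAa == "*")))
})

#' Synonymous codon subfamilies of an amino acid
#'
#' Partitions an amino acid's codon set by shared first-two-position prefix.
#' Leucine in the standard code yields the CT subfamily (4 codons) and the TT
#' subfamily (TTA, TTG); serine yields TC (4 codons) and AG (AGT, AGC).
#' Subfamilies are ordered by descending size, ties broken by prefix
#' lexicographic order.
#'
#' @param code a \linkS4class{GeneticCode}.
#' @param aminoAcid one-letter amino acid code present in \code{code}.
#' @return list of \linkS4class{SynonymousSubfamily} objects.
#' @examples
#' subfamilies(geneticCode(1), "L")
#' @export
subfamilies <- function(code, aminoAcid) {
    stopifnot(is(code, "GeneticCode"))
    aminoAcid <- toupper(aminoAcid)
    ct <- code@codonToAa
    codons <- names(ct)[ct == aminoAcid]
    if (length(codons) == 0L)
        stop(sprintf("amino acid '%s' is not encoded in genetic code table %d",
            aminoAcid, code@tableId))
    pref <- substr(codons, 1L, 2L)
    groups <- split(codons, pref)
    ord <- order(-lengths(groups), names(groups))
    groups <- groups[ord]
    lapply(names(groups), function(p) {
        third <- sort(substr(groups[[p]], 3L, 3L))
        new("SynonymousSubfamily", aminoAcid = aminoAcid, prefix = p,
            third = third, codons = paste0(p, third))
    })
}

#' @describeIn subfamilies the subfamily's two-nucleotide prefix.
#' @param x a \code{SynonymousSubfamily}.
#' @export
subfamilyPrefix <- function(x) x@prefix

#' @describeIn subfamilies the subfamily's third positions.
#' @export
subfamilyThird <- function(x) x@third

#' @describeIn subfamilies the subfamily's codon set.
#' @export
subfamilyCodons <- function(x) x@codons

#' @describeIn subfamilies the owning amino acid.
#' @export
subfamilyAA <- function(x) x@aminoAcid

#' @export
setMethod("show", "SynonymousSubfamily", function(object) {
    cat(sprintf("SynonymousSubfamily: %s = %s{%s} (%d codon(s))\n",
        object@aminoAcid, object@prefix, paste(object@third, collapse = ","),
        length(object@codons)))
})
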