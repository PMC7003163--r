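# translate one codon triple under a code table; resolves ambiguity
.translateTriple <- function(tr, ct) {
    if (grepl("^[-?]{3}$", tr)) return("-")
    if (grepl("^[TCAG]{3}$", tr)) return(unname(ct[tr]))
    aa <- unique(unname(ct[resolveCodon(tr)]))
    if (length(aa) == 1L) aa else "X"
}

#' Translate a codon sequence
#'
#' Each in-frame codon becomes a one-letter amino acid; gap/missing triples
#' become a single gap. A codon containing ambiguity codes translates to its
#' amino acid if all resolutions are synonymous, otherwise to \code{"X"}.
#' Stop codons translate to \code{"*"} with a warning, or raise an error when
#' \code{strict = TRUE}.
#'
#' @param codonSeq a (possibly gapped) nucleotide sequence string; length
#'   divisible by 3, gaps in whole triples.
#' @param code a \linkS4class{GeneticCode}.
#' @param strict error on stop codons instead of warning.
#' @param id sequence name used in error messages.
#' @return amino-acid sequence string of one third the length.
#' @examples
#' translateCodons("TTATTT---", geneticCode(1))   # "LF-"
#' @export
translateCodons <- function(codonSeq, code = geneticCode(1), strict = FALSE,
                            id = "<seq>") {
    stopifnot(is(code, "GeneticCode"))
    s <- .normalizeSeq(codonSeq, "DNA")
    triples <- .codonSplit(s, id)
    ct <- code@codonToAa
    aa <- vapply(triples, .translateTriple, character(1), ct = ct,
        USE.NAMES = FALSE)
    stops <- which(aa == "*")
    if (length(stops)) {
        if (strict)
            stop(sprintf("sequence '%s': stop codon at codon site %d",
                id, stops[1L]))
        warning(sprintf("sequence '%s': %d stop codon(s), first at codon site %d",
            id, length(stops), stops[1L]))
    }
    paste(aa, collapse = "")
}

#' Thread codon sequences onto a protein alignment
#'
#' The standard align-by-protein / map-back-to-codons construction: each
#' amino-acid column of the alignment expands to the corresponding codon
#' triple of that sequence, and each gap or missing symbol expands to a
#' triple of the same symbol. Every codon sequence must translate exactly to
#' its degapped amino-acid row. A terminal stop codon is stripped with a
#' warning before threading; internal stops fail by default.
#'
#' @param aaMsa an amino-acid \linkS4class{Msa}.
#' @param codonSeqs named character vector (or list) of ungapped nucleotide
#'   sequences; names must cover the alignment's identifiers.
#' @param code a \linkS4class{GeneticCode}.
#' @param internalStop \code{"fail"} (default) or \code{"warn"}.
#' @return a codon \linkS4class{Msa} of width \code{3 * msaWidth(aaMsa)};
#'   degapping any row recovers its input codon sequence.
#' @examples
#' aa <- Msa(c(x = "M-K"), alphabet = "AA")
#' msaSeqs(threadCodons(aa, c(x = "ATGAAA")))[["x"]]   # "ATG---AAA"
#' @export
threadCodons <- function(aaMsa, codonSeqs, code = geneticCode(1),
                         internalStop = c("fail", "warn")) {
    stopifnot(is(aaMsa, "Msa"), is(code, "GeneticCode"))
    internalStop <- match.arg(internalStop)
    if (aaMsa@alphabet != "AA")
        stop("aaMsa must be an amino-acid alignment")
    codonSeqs <- setNames(as.character(codonSeqs), names(codonSeqs))
    missing <- setdiff(aaMsa@ids, names(codonSeqs))
    if (length(missing))
        stop(sprintf("codon sequence missing for identifier '%s'", missing[1L]))
    out <- character(length(aaMsa@ids))
    for (i in seq_along(aaMsa@ids)) {
        id <- aaMsa@ids[i]
        nt <- .normalizeSeq(codonSeqs[[id]], "DNA")
        if (grepl("[-?]", nt))
            stop(sprintf("codon sequence for '%s' must be ungapped", id))
        triples <- .codonSplit(nt, id)
        aaNt <- vapply(triples, .translateTriple, character(1),
            ct = code@codonToAa, USE.NAMES = FALSE)
        if (length(aaNt) && aaNt[length(aaNt)] == "*") {
            warning(sprintf("sequence '%s': terminal stop codon stripped", id))
            triples <- triples[-length(triples)]
            aaNt <- aaNt[-length(aaNt)]
        }
        intStop <- which(aaNt == "*")
        if (length(intStop)) {
            msg <- sprintf("sequence '%s': internal stop codon at codon site %d",
                id, intStop[1L])
            if (internalStop == "fail") stop(msg) else warning(msg)
        }
        aaRow <- strsplit(aaMsa@seqs[i], "")[[1]]
        resCols <- !aaRow %in% .GAP_CHARS
        aaDegap <- aaRow[resCols]
        if (length(aaDegap) != length(aaNt))
            stop(sprintf(
                "translation mismatch for '%s': %d aligned residues vs %d codons",
                id, length(aaDegap), length(aaNt)))
        diff <- which(aaDegap != aaNt)
        if (length(diff))
            stop(sprintf(
                "translation mismatch for '%s' at residue %d: alignment has '%s', codons give '%s'",
                id, diff[1L], aaDegap[diff[1L]], aaNt[diff[1L]]))
        expanded <- character(length(aaRow))
        expanded[resCols] <- triples
        expanded[!resCols] <- strrep(aaRow[!resCols], 3L)
        out[i] <- paste(expanded, collapse = "")
    }
    new("Msa", ids = aaMsa@ids, seqs = out, alphabet = "DNA")
}
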