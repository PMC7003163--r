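# IUPAC nucleotide ambiguity alphabet. The internal alphabet is T, never U;
# readers normalize U/u on input, writers emit T.

.IUPAC <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# set (sorted, collapsed) -> symbol
.IUPAC_REV <- local({
    keys <- vapply(.IUPAC, function(s) paste(sort(s), collapse = ""), character(1))
    setNames(names(.IUPAC), keys)
})

#' Resolve an IUPAC codon or symbol to its unambiguous set
#'
#' For a single IUPAC nucleotide symbol, returns the set of bases it denotes;
#' for an IUPAC triplet, returns the Cartesian expansion into unambiguous
#' codons (e.g. \code{"YTR"} resolves to CTA, CTG, TTA, TTG).
#'
#' @param x a single string of IUPAC nucleotide symbols (length 1 or 3).
#' @return character vector of unambiguous symbols or codons.
#' @examples
#' resolveCodon("R")
#' resolveCodon("YTR")
#' @export
resolveCodon <- function(x) {
    stopifnot(is.character(x), length(x) == 1L)
    ch <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
    bad <- setdiff(ch, names(.IUPAC))
    if (length(bad))
        stop(sprintf("non-IUPAC symbol(s): %s", paste(bad, collapse = ", ")))
    sets <- .IUPAC[ch]
    out <- Reduce(function(a, b) as.vector(outer(a, b, paste0)), sets)
    sort(out)
}

#' IUPAC symbol covering a set of bases
#'
#' @param bases character vector over \{T,C,A,G\}.
#' @return the single IUPAC symbol whose resolution is exactly that set.
#' @examples
#' iupacSymbol(c("A", "G"))  # "R"
#' @export
iupacSymbol <- function(bases) {
    bases <- unique(toupper(bases))
    if (!all(bases %in% c("T", "C", "A", "G")))
        stop("bases must be a subset of {T,C,A,G}")
    .IUPAC_REV[[paste(sort(bases), collapse = "")]]
}

# normalize a sequence string: uppercase; U->T for DNA
.normalizeSeq <- function(s, alphabet) {
    s <- toupper(s)
    if (alphabet == "DNA") s <- gsub("U", "T", s, fixed = TRUE)
    s
}

# split sequences into a character matrix (rows = sequences)
.charMatrix <- function(seqs) {
    if (length(seqs) == 0L) return(matrix(character(0), 0L, 0L))
    do.call(rbind, strsplit(seqs, "", fixed = TRUE))
}

.degap <- function(s) gsub("[-?]", "", s)

# split one sequence into codon triples; frame-validates
.codonSplit <- function(s, id = "<seq>") {
    n <- nchar(s)
    if (n %% 3L != 0L)
        stop(sprintf("sequence '%s': length %d is not divisible by 3", id, n))
    if (n == 0L) return(character(0))
    triples <- substring(s, seq(1L, n, 3L), seq(3L, n, 3L))
    partial <- grepl("[-?]", triples) & !grepl("^[-?]{3}$", triples)
    if (any(partial))
        stop(sprintf(
            "sequence '%s': gap/missing symbol breaks a codon at codon site %d",
            id, which(partial)[1L]))
    triples
}
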