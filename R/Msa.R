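#' Construct an Msa
#'
#' @param seqs character vector of (gapped) sequences; names are used as
#'   identifiers when \code{ids} is missing.
#' @param ids character vector of unique identifiers.
#' @param alphabet \code{"DNA"}, \code{"AA"}, or \code{"auto"} to guess from
#'   content (letters such as E, F, I, L, P, Q occur only in protein).
#' @return an \linkS4class{Msa}.
#' @examples
#' Msa(c(s1 = "CTC", s2 = "TTG", s3 = "TTC"))
#' @export
Msa <- function(seqs, ids = names(seqs), alphabet = c("auto", "DNA", "AA")) {
    alphabet <- match.arg(alphabet)
    if (is.null(ids))
        ids <- paste0("seq", seq_along(seqs))
    seqs <- unname(as.character(seqs))
    if (alphabet == "auto")
        alphabet <- if (any(grepl("[EFILPQJZXO*]", toupper(seqs)))) "AA" else "DNA"
    seqs <- vapply(seqs, .normalizeSeq, character(1), alphabet = alphabet,
        USE.NAMES = FALSE)
    new("Msa", ids = as.character(ids), seqs = seqs, alphabet = alphabet)
}

#' @describeIn Msa sequence identifiers.
#' @param x an \code{Msa}.
#' @export
msaIds <- function(x) x@ids

#' @describeIn Msa named character vector of the aligned sequences.
#' @export
msaSeqs <- function(x) setNames(x@seqs, x@ids)

#' @describeIn Msa alignment width (number of columns).
#' @export
msaWidth <- function(x) if (length(x@seqs)) nchar(x@seqs[1L]) else 0L

#' @describeIn Msa alphabet tag (\code{"DNA"} or \code{"AA"}).
#' @export
msaAlphabet <- function(x) x@alphabet

#' @export
setMethod("length", "Msa", function(x) length(x@seqs))

#' @export
setMethod("show", "Msa", function(object) {
    cat(sprintf("Msa: %d %s sequence(s), %d column(s)\n",
        length(object), object@alphabet, msaWidth(object)))
    n <- min(length(object), 6L)
    if (n > 0L) {
        s <- object@seqs[seq_len(n)]
        s <- ifelse(nchar(s) > 60L, paste0(substr(s, 1L, 57L), "..."), s)
        cat(sprintf("  %-12s %s\n", object@ids[seq_len(n)], s), sep = "")
        if (length(object) > n) cat(sprintf("  ... and %d more\n", length(object) - n))
    }
})

#' @export
setMethod("[", "Msa", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@ids)
    new("Msa", ids = x@ids[i], seqs = x@seqs[i], alphabet = x@alphabet)
})

#' @export
setMethod("as.matrix", "Msa", function(x, ...) {
    m <- .charMatrix(x@seqs)
    rownames(m) <- x@ids
    m
})
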