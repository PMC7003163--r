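#' Concatenate per-gene alignments into a supermatrix
#'
#' Rows are the union of identifiers across genes in order of first
#' appearance; a taxon absent from a gene receives a fill of that gene's
#' aligned width (\code{'?'} by default, distinguishing missing genes from
#' alignment gaps). An optional separator string (conventionally
#' \code{"NNNNNN"}) is inserted between gene blocks for every row; separator
#' columns belong to no partition.
#'
#' @param geneMsas named (or unnamed) list of \linkS4class{Msa} objects, one
#'   per gene, in concatenation order.
#' @param separator optional string inserted between gene blocks
#'   (default none).
#' @param fill single character used for missing taxa (\code{"?"} or
#'   \code{"-"}).
#' @return list with \code{msa} (the supermatrix) and \code{partitions}
#'   (data.frame of gene, start, end; 1-based inclusive supermatrix
#'   coordinates).
#' @examples
#' g1 <- Msa(c(A = "ATGATG", B = "ATGCTG"))
#' g2 <- Msa(c(B = "AAATTTGGG", C = "AAATTTGGC"))
#' sm <- concatenateGenes(list(G1 = g1, G2 = g2), separator = "NNNNNN")
#' sm$partitions
#' @export
concatenateGenes <- function(geneMsas, separator = NULL, fill = "?") {
    stopifnot(is.list(geneMsas), length(geneMsas) >= 1L,
        all(vapply(geneMsas, is, logical(1), "Msa")))
    stopifnot(is.character(fill), nchar(fill) == 1L)
    genes <- names(geneMsas)
    if (is.null(genes) || any(genes == ""))
        genes <- paste0("gene", seq_along(geneMsas))
    ids <- unique(unlist(lapply(geneMsas, msaIds)))
    sepLen <- if (is.null(separator)) 0L else nchar(separator)
    blocks <- vector("list", length(geneMsas))
    starts <- integer(length(geneMsas)); ends <- integer(length(geneMsas))
    pos <- 0L
    for (g in seq_along(geneMsas)) {
        msa <- geneMsas[[g]]
        w <- msaWidth(msa)
        rows <- setNames(rep(strrep(fill, w), length(ids)), ids)
        rows[msa@ids] <- msa@seqs
        blocks[[g]] <- rows
        starts[g] <- pos + 1L
        ends[g] <- pos + w
        pos <- pos + w + if (g < length(geneMsas)) sepLen else 0L
    }
    sep <- if (is.null(separator)) "" else separator
    seqs <- vapply(ids, function(id)
        paste(vapply(blocks, `[[`, character(1), id), collapse = sep),
        character(1), USE.NAMES = FALSE)
    alph <- geneMsas[[1L]]@alphabet
    list(msa = new("Msa", ids = ids, seqs = seqs, alphabet = alph),
        partitions = data.frame(gene = genes, start = starts, end = ends,
            stringsAsFactors = FALSE))
}

#' Remove codon sites where serine is encoded by both AGN and UCN classes
#'
#' A codon site is removed when at least one row carries a codon with
#' first-two-position prefix AG and a different row carries one with prefix
#' TC. Such sites are identical at the amino-acid level (both classes encode
#' serine in the standard code) but maximally divergent at the nucleotide
#' level, and distort nucleotide-based trees. The default applies the literal
#' AG/TC prefix rule; \code{strict = TRUE} counts a row only when its codon
#' is unambiguous and actually translates to serine under \code{code}
#' (AGY versus TCN in the standard code).
#'
#' @param msa a codon-aligned nucleotide \linkS4class{Msa}.
#' @param code a \linkS4class{GeneticCode} (used by \code{strict}).
#' @param strict restrict the rule to serine-coding codons.
#' @return list with \code{msa} (filtered), \code{removedCount}, and
#'   \code{removedSites} (1-based codon-site indices).
#' @examples
#' r <- serineSiteFilter(Msa(c(a = "AGC", b = "TCA", c = "TTT")))
#' r$removedCount   # 1
#' @export
serineSiteFilter <- function(msa, code = geneticCode(1), strict = FALSE) {
    stopifnot(is(msa, "Msa"), is(code, "GeneticCode"))
    if (msa@alphabet != "DNA") stop("serine-site filtering needs codon data")
    tripList <- lapply(seq_along(msa@seqs), function(i)
        .codonSplit(msa@seqs[i], msa@ids[i]))
    nSites <- if (length(tripList)) length(tripList[[1L]]) else 0L
    trip <- do.call(rbind, tripList)            # rows x codon sites
    flagged <- logical(nSites)
    if (nSites > 0L && nrow(trip) >= 2L) {
        ct <- code@codonToAa
        isSer <- function(cd) grepl("^[TCAG]{3}$", cd) & unname(ct[cd] == "S") &
            !is.na(ct[cd])
        for (j in seq_len(nSites)) {
            cods <- trip[, j]
            pref <- substr(cods, 1L, 2L)
            agRows <- pref == "AG"
            tcRows <- pref == "TC"
            if (strict) {
                agRows <- agRows & isSer(cods)
                tcRows <- tcRows & isSer(cods)
            }
            flagged[j] <- any(agRows) && any(tcRows)
        }
    }
    keep <- which(!flagged)
    seqs <- vapply(seq_along(msa@seqs), function(i)
        paste(tripList[[i]][keep], collapse = ""), character(1))
    list(msa = new("Msa", ids = msa@ids, seqs = seqs, alphabet = "DNA"),
        removedCount = sum(flagged), removedSites = which(flagged))
}

#' GC content at third codon positions (GC3)
#'
#' The percentage of G + C among countable third codon positions. Gap
#' (\code{-}), missing (\code{?}) and fully ambiguous (\code{N}) third
#' positions are excluded from the denominator; the symbols G, C and S count
#' as G/C.
#'
#' @param x a (gapped) nucleotide sequence string, a character vector of
#'   them, or an \linkS4class{Msa}; lengths must be divisible by 3 with gaps
#'   in whole triples.
#' @return named numeric vector of percentages; \code{NA} with a warning for
#'   a sequence with no countable third positions.
#' @examples
#' gc3("ATGGCA")   # 50
#' @export
gc3 <- function(x) {
    if (is(x, "Msa")) {
        if (x@alphabet != "DNA") stop("GC3 needs nucleotide data")
        seqs <- msaSeqs(x)
    } else {
        seqs <- as.character(x)
        if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
    }
    vapply(names(seqs), function(id) {
        triples <- .codonSplit(.normalizeSeq(seqs[[id]], "DNA"), id)
        third <- substr(triples, 3L, 3L)
        third <- third[!third %in% c("-", "?", "N")]
        if (length(third) == 0L) {
            warning(sprintf("sequence '%s': no countable third codon positions", id))
            return(NA_real_)
        }
        100 * sum(third %in% c("G", "C", "S")) / length(third)
    }, numeric(1))
}
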