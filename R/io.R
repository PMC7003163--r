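#' Read an alignment from FASTA, PHYLIP or NEXUS
#'
#' FASTA is read with \pkg{Biostrings}; PHYLIP (sequential or interleaved,
#' relaxed names; the dialect is auto-detected against the header) and NEXUS
#' DATA/CHARACTERS blocks are read with \pkg{ape}. Sequences are uppercased
#' and, for nucleotide data, U is normalized to T. \code{'?'} is read as
#' missing data, distinct from the \code{'-'} gap.
#'
#' @param path input file.
#' @param format \code{"fasta"}, \code{"phylip"} or \code{"nexus"}; default
#'   guesses from the file extension.
#' @param alphabet \code{"auto"}, \code{"DNA"} or \code{"AA"}.
#' @return an \linkS4class{Msa}.
#' @export
readAlignment <- function(path, format = c("auto", "fasta", "phylip", "nexus"),
                          alphabet = c("auto", "DNA", "AA")) {
    format <- match.arg(format)
    alphabet <- match.arg(alphabet)
    if (format == "auto") {
        ext <- tolower(tools::file_ext(path))
        format <- switch(ext,
            fa = , fas = , fasta = , fna = , faa = "fasta",
            phy = , phylip = "phylip",
            nex = , nexus = , nxs = "nexus",
            stop(sprintf("cannot guess format from extension '.%s'", ext)))
    }
    seqs <- switch(format,
        fasta = {
            x <- Biostrings::readBStringSet(path)
            setNames(as.character(x), names(x))
        },
        phylip = .readPhylip(path),
        nexus = {
            x <- ape::read.nexus.data(path)
            vapply(x, paste, character(1), collapse = "")
        })
    Msa(seqs, alphabet = alphabet)
}

# ape::read.dna needs the dialect named; try both and keep the one that
# matches the header dimensions
.readPhylip <- function(path) {
    hdr <- strsplit(trimws(readLines(path, n = 1L)), "[[:space:]]+")[[1]]
    if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
        stop(sprintf("'%s': malformed PHYLIP header", path))
    nseq <- as.integer(hdr[1L]); nsite <- as.integer(hdr[2L])
    for (fmt in c("sequential", "interleaved")) {
        m <- tryCatch(
            ape::read.dna(path, format = fmt, as.character = TRUE,
                as.matrix = TRUE),
            error = function(e) NULL)
        if (!is.null(m) && !anyNA(m) && !anyNA(rownames(m)) &&
                nrow(m) == nseq && ncol(m) == nsite)
            return(setNames(apply(m, 1L, paste, collapse = ""), rownames(m)))
    }
    stop(sprintf(
        "'%s': sequences do not match the PHYLIP header (%d x %d)",
        path, nseq, nsite))
}

#' Write an alignment to FASTA, PHYLIP or NEXUS
#'
#' @param msa an \linkS4class{Msa}.
#' @param path output file.
#' @param format \code{"fasta"}, \code{"phylip"} or \code{"nexus"}.
#' @param interleaved write NEXUS matrices interleaved.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(msa, path, format = c("fasta", "phylip", "nexus"),
                           interleaved = FALSE) {
    stopifnot(is(msa, "Msa"))
    format <- match.arg(format)
    switch(format,
        fasta = {
            x <- Biostrings::BStringSet(setNames(msa@seqs, msa@ids))
            Biostrings::writeXStringSet(x, path)
        },
        phylip = {
            m <- as.matrix(msa)
            ape::write.dna(m, path, format = "sequential", nbcol = -1L,
                colsep = "")
        },
        nexus = {
            lst <- setNames(strsplit(msa@seqs, "", fixed = TRUE), msa@ids)
            fmt <- if (msa@alphabet == "DNA") "dna" else "protein"
            ape::write.nexus.data(lst, path, format = fmt,
                interleaved = interleaved)
        })
    invisible(path)
}

#' Read or write unaligned sequences (FASTA)
#'
#' Convenience pair for ungapped inputs such as the codon sequences fed to
#' \code{\link{threadCodons}}; unlike \code{\link{readAlignment}} the
#' sequences need not be of equal length.
#'
#' @param path FASTA file.
#' @return named character vector of uppercased sequences (U normalized to T
#'   when the content is nucleotide).
#' @export
readSequences <- function(path) {
    x <- Biostrings::readBStringSet(path)
    seqs <- setNames(as.character(x), names(x))
    alph <- if (any(grepl("[EFILPQJZXO*]", toupper(seqs)))) "AA" else "DNA"
    vapply(seqs, .normalizeSeq, character(1), alphabet = alph)
}

#' @rdname readSequences
#' @param seqs named character vector of sequences.
#' @export
writeSequences <- function(seqs, path) {
    Biostrings::writeXStringSet(
        Biostrings::BStringSet(setNames(as.character(seqs), names(seqs))), path)
    invisible(path)
}
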