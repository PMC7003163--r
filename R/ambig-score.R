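#' Construct a scoring scheme
#'
#' @param match,transition,transversion base match/mismatch scores; a warning
#'   is issued (not an error) if \code{match > transition >= transversion} is
#'   violated.
#' @param gapOpen,gapExtend affine penalties for residue-versus-gap runs.
#' @return a \linkS4class{ScoreScheme}.
#' @examples
#' scoreScheme()                     # +1 / -1 / -2, gaps -5 / -1
#' @export
scoreScheme <- function(match = 1, transition = -1, transversion = -2,
                        gapOpen = -5, gapExtend = -1) {
    if (!(match > transition && transition >= transversion))
        warning("unusual scheme: expected match > transition >= transversion")
    new("ScoreScheme", match = match, transition = transition,
        transversion = transversion, gapOpen = gapOpen, gapExtend = gapExtend)
}

#' @export
setMethod("show", "ScoreScheme", function(object) {
    cat(sprintf(
        "ScoreScheme: match %+g, transition %+g, transversion %+g, gap open %+g, gap extend %+g\n",
        object@match, object@transition, object@transversion,
        object@gapOpen, object@gapExtend))
})

# base (unambiguous) 4x4 score lookup
.baseMatrix <- function(scheme) {
    b <- c("A", "C", "G", "T")
    purine <- c("A", "G")
    m <- matrix(scheme@transversion, 4L, 4L, dimnames = list(b, b))
    for (x in b) for (y in b) {
        if (x == y) m[x, y] <- scheme@match
        else if ((x %in% purine) == (y %in% purine)) m[x, y] <- scheme@transition
    }
    m
}

#' Expand a scheme into the 15x15 ambiguity-averaged matrix
#'
#' Each entry for IUPAC symbols X, Y is the arithmetic mean of the base
#' match/transition/transversion scores over all resolved pairs (x in X,
#' y in Y). Under the default scheme the A/R entry is (1 - 1)/2 = 0, and A/Y
#' (always a transversion) is -2. Restricted to A, C, G, T the matrix
#' reproduces the base scheme exactly.
#'
#' @param scheme a \linkS4class{ScoreScheme}.
#' @return symmetric numeric matrix over A,C,G,T,R,Y,S,W,K,M,B,D,H,V,N.
#' @examples
#' expandScoreMatrix(scoreScheme())["A", "R"]   # 0
#' @export
expandScoreMatrix <- function(scheme) {
    stopifnot(is(scheme, "ScoreScheme"))
    base <- .baseMatrix(scheme)
    syms <- names(.IUPAC)
    m <- matrix(NA_real_, 15L, 15L, dimnames = list(syms, syms))
    for (x in syms) for (y in syms)
        m[x, y] <- mean(base[.IUPAC[[x]], .IUPAC[[y]]])
    m
}

#' Pairwise alignment score of two gapped sequences
#'
#' Residue-residue columns contribute their ambiguity-averaged matrix entry;
#' columns where both sequences have a gap (or missing '?') contribute
#' nothing; each maximal residue-versus-gap run is penalized affinely
#' (\code{gapOpen} for its first penalized column, \code{gapExtend} for each
#' further one). Runs are maximal per gap-bearing sequence, and shared-gap
#' columns inside a run are not penalized and do not re-open it.
#'
#' @param s1,s2 equal-length gapped sequence strings.
#' @param scheme a \linkS4class{ScoreScheme}.
#' @param matrix optional precomputed \code{\link{expandScoreMatrix}} result.
#' @return numeric score.
#' @examples
#' pairScore("CTC", "TTG")   # -2
#' pairScore("CTN", "TTY")   # -1
#' @export
pairScore <- function(s1, s2, scheme = scoreScheme(),
                      matrix = expandScoreMatrix(scheme)) {
    s1 <- .normalizeSeq(s1, "DNA"); s2 <- .normalizeSeq(s2, "DNA")
    if (nchar(s1) != nchar(s2))
        stop(sprintf("sequences differ in length (%d vs %d)",
            nchar(s1), nchar(s2)))
    a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
    ok <- c(names(.IUPAC), .GAP_CHARS)
    badA <- which(!a %in% ok); badB <- which(!b %in% ok)
    if (length(badA))
        stop(sprintf("non-IUPAC symbol '%s' at position %d of first sequence",
            a[badA[1L]], badA[1L]))
    if (length(badB))
        stop(sprintf("non-IUPAC symbol '%s' at position %d of second sequence",
            b[badB[1L]], badB[1L]))
    gapA <- a %in% .GAP_CHARS; gapB <- b %in% .GAP_CHARS
    res <- !gapA & !gapB
    score <- if (any(res)) sum(matrix[cbind(a[res], b[res])]) else 0
    gapRunPenalty <- function(gapSelf, gapOther) {
        if (!any(gapSelf)) return(0)
        r <- rle(gapSelf)
        ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
        tot <- 0
        for (i in which(r$values)) {
            k <- sum(!gapOther[starts[i]:ends[i]])
            if (k > 0L) tot <- tot + scheme@gapOpen + (k - 1L) * scheme@gapExtend
        }
        tot
    }
    score + gapRunPenalty(gapA, gapB) + gapRunPenalty(gapB, gapA)
}

#' Sum-of-pairs (SP) score of an alignment
#'
#' The sum of \code{\link{pairScore}} over all unordered sequence pairs; a
#' larger SP score indicates a better alignment of the same content. Shared
#' gaps are never penalized, so an all-gap column leaves the score unchanged.
#'
#' @param msa a nucleotide \linkS4class{Msa} with at least two sequences.
#' @param scheme a \linkS4class{ScoreScheme}.
#' @return numeric SP score.
#' @examples
#' spScore(Msa(c(s1 = "CTC", s2 = "TTG", s3 = "TTC")))   # -1
#' @export
spScore <- function(msa, scheme = scoreScheme()) {
    stopifnot(is(msa, "Msa"))
    n <- length(msa)
    if (n < 2L) stop("SP score requires at least 2 sequences")
    m <- expandScoreMatrix(scheme)
    tot <- 0
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n))
        tot <- tot + pairScore(msa@seqs[i], msa@seqs[j], scheme, m)
    tot
}

#' Select the best-scoring alignment among candidates
#'
#' All candidates must align the same sequences (same identifiers, same
#' ungapped content per identifier); the one with the highest SP score wins.
#' Exact ties go to the earliest candidate, with the tie noted in the report.
#'
#' @param candidates list of \linkS4class{Msa} candidates for the same data.
#' @param scheme a \linkS4class{ScoreScheme}.
#' @return list with \code{best} (the chosen Msa), \code{bestIndex},
#'   \code{report} (data.frame of candidate scores), and \code{tie}.
#' @export
selectBestAlignment <- function(candidates, scheme = scoreScheme()) {
    stopifnot(is.list(candidates), length(candidates) >= 1L)
    ref <- candidates[[1L]]
    refContent <- setNames(.degap(ref@seqs), ref@ids)
    for (k in seq_along(candidates)[-1L]) {
        cand <- candidates[[k]]
        if (!setequal(cand@ids, ref@ids))
            stop(sprintf("candidate %d has different identifiers", k))
        cont <- setNames(.degap(cand@seqs), cand@ids)
        bad <- names(refContent)[cont[names(refContent)] != refContent]
        if (length(bad))
            stop(sprintf(
                "candidate %d disagrees on ungapped content for '%s'", k, bad[1L]))
    }
    scores <- vapply(candidates, spScore, numeric(1), scheme = scheme)
    best <- which.max(scores)   # first maximum on ties
    report <- data.frame(candidate = seq_along(candidates), sp = scores)
    list(best = candidates[[best]], bestIndex = best, report = report,
        tie = sum(scores == scores[best]) > 1L)
}
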