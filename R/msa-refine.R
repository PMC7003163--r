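#' Build a position weight matrix over a nucleotide alignment
#'
#' Per-site counts of A, C, G, T (gaps, missing '?' and ambiguity codes are
#' excluded) are pseudocount-smoothed, converted to frequencies, divided by
#' the background frequencies over all non-gap residues of the alignment
#' (smoothed with the same pseudocount), and log-transformed. A value of zero
#' means the nucleotide is neither preferred nor avoided at the site;
#' positive preferred, negative avoided. All-gap columns yield a row of zeros
#' with a warning.
#'
#' @param msa a nucleotide \linkS4class{Msa} with at least two sequences.
#' @param pseudocount smoothing constant added to each count (default 1).
#' @param logBase base of the logarithm (default 2).
#' @return a \linkS4class{Pwm}.
#' @examples
#' p <- buildPwm(Msa(c(a = "ACGT", b = "ACGT")), pseudocount = 0)
#' pwmValues(p)[1, "A"]   # 2: log2 of 1 over the uniform background 0.25
#' @export
buildPwm <- function(msa, pseudocount = 1, logBase = 2) {
    stopifnot(is(msa, "Msa"), pseudocount >= 0, logBase > 1)
    if (msa@alphabet != "DNA") stop("PWM refinement is nucleotide-only")
    if (length(msa) < 2L) stop("PWM requires at least 2 sequences")
    bases <- c("A", "C", "G", "T")
    ch <- .charMatrix(msa@seqs)          # sequences x sites
    counts <- vapply(bases, function(b) colSums(ch == b),
        numeric(ncol(ch)))               # sites x 4
    counts <- matrix(counts, ncol = 4L, dimnames = list(NULL, bases))
    siteTot <- rowSums(counts)
    bgCounts <- colSums(counts)
    if (sum(bgCounts) == 0L) stop("alignment contains no unambiguous residues")
    bg <- (bgCounts + pseudocount) / (sum(bgCounts) + 4 * pseudocount)
    vals <- matrix(0, nrow(counts), 4L, dimnames = list(NULL, bases))
    nonEmpty <- siteTot > 0L
    if (any(!nonEmpty))
        warning(sprintf("%d all-gap column(s); PWM rows set to zero",
            sum(!nonEmpty)))
    if (any(nonEmpty)) {
        f <- (counts[nonEmpty, , drop = FALSE] + pseudocount) /
            (siteTot[nonEmpty] + 4 * pseudocount)
        vals[nonEmpty, ] <- log(sweep(f, 2L, bg, "/"), base = logBase)
        # a symbol absent from the whole alignment (unsmoothed background 0)
        # is neither preferred nor avoided anywhere
        vals[is.nan(vals)] <- 0
    }
    new("Pwm", values = vals, background = bg, pseudocount = pseudocount,
        logBase = logBase)
}

#' @describeIn buildPwm the sites-by-symbol matrix of log ratios.
#' @param x a \code{Pwm}.
#' @export
pwmValues <- function(x) x@values

#' @describeIn buildPwm the smoothed background frequencies.
#' @export
pwmBackground <- function(x) x@background

#' @export
setMethod("show", "Pwm", function(object) {
    cat(sprintf("Pwm: %d site(s) x %d symbols (pseudocount %g, log base %g)\n",
        nrow(object@values), ncol(object@values), object@pseudocount,
        object@logBase))
    cat("  background:",
        paste(sprintf("%s=%.3f", names(object@background), object@background),
            collapse = " "), "\n")
})

# PWM-sum objective: sum over all residues of their site value; residues
# outside A,C,G,T contribute 0.
.pwmObjective <- function(ch, vals) {
    tot <- 0
    for (b in colnames(vals)) {
        hit <- which(ch == b, arr.ind = TRUE)
        if (nrow(hit)) tot <- tot + sum(vals[hit[, 2L], b])
    }
    tot
}

#' Greedy PWM refinement of an alignment
#'
#' The only move permitted is sliding a residue that immediately borders a
#' gap run in its own sequence to the opposite end of that run (the gap run
#' shifts by one column; ungapped content and alignment width are unchanged).
#' A move is accepted only if it strictly increases the PWM-sum objective
#' (the sum, over all residues, of their site PWM value). The PWM is rebuilt
#' once per pass; passes repeat until a fixpoint or \code{maxIter}.
#'
#' Scan order is deterministic: sequences in input order, gap runs left to
#' right, the run's left border tried before its right border; the first
#' strictly improving move is taken. Equal-objective moves are never made.
#'
#' @param msa an aligned nucleotide \linkS4class{Msa}.
#' @param maxIter maximum number of passes (default 10).
#' @param pseudocount,logBase forwarded to \code{\link{buildPwm}}.
#' @return list with \code{msa} (refined alignment), \code{moves} (accepted
#'   move count), and \code{passes}.
#' @examples
#' r <- refineMsa(Msa(c(a = "AG--T", b = "A--GT", c = "A--GT", d = "A--GT")))
#' msaSeqs(r$msa)[["a"]]   # "A--GT"
#' r$moves                 # 1
#' @export
refineMsa <- function(msa, maxIter = 10L, pseudocount = 1, logBase = 2) {
    stopifnot(is(msa, "Msa"))
    if (msa@alphabet != "DNA") stop("PWM refinement is nucleotide-only")
    ch <- .charMatrix(msa@seqs)
    moves <- 0L; passes <- 0L
    if (ncol(ch) == 0L || !any(ch == "-"))
        return(list(msa = msa, moves = 0L, passes = 0L))
    repeat {
        passes <- passes + 1L
        cur <- Msa(apply(ch, 1L, paste, collapse = ""), ids = msa@ids,
            alphabet = "DNA")
        vals <- suppressWarnings(buildPwm(cur, pseudocount, logBase))@values
        movedThisPass <- 0L
        for (si in seq_len(nrow(ch))) {
            repeat {
                row <- ch[si, ]
                isGap <- row == "-"
                if (!any(isGap)) break
                r <- rle(isGap)
                ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
                applied <- FALSE
                for (g in which(r$values)) {
                    g1 <- starts[g]; g2 <- ends[g]
                    # left-border residue slides right to the run's far end
                    if (g1 > 1L && !row[g1 - 1L] %in% .GAP_CHARS) {
                        sym <- row[g1 - 1L]
                        d <- if (sym %in% colnames(vals))
                            vals[g2, sym] - vals[g1 - 1L, sym] else 0
                        if (d > 0) {
                            ch[si, (g1 - 1L):(g2 - 1L)] <- "-"
                            ch[si, g2] <- sym
                            applied <- TRUE
                        }
                    }
                    # right-border residue slides left to the run's near end
                    if (!applied && g2 < ncol(ch) && !row[g2 + 1L] %in% .GAP_CHARS) {
                        sym <- row[g2 + 1L]
                        d <- if (sym %in% colnames(vals))
                            vals[g1, sym] - vals[g2 + 1L, sym] else 0
                        if (d > 0) {
                            ch[si, (g1 + 1L):(g2 + 1L)] <- "-"
                            ch[si, g1] <- sym
                            applied <- TRUE
                        }
                    }
                    if (applied) break
                }
                if (!applied) break
                moves <- moves + 1L
                movedThisPass <- movedThisPass + 1L
            }
        }
        if (movedThisPass == 0L || passes >= maxIter) break
    }
    out <- Msa(apply(ch, 1L, paste, collapse = ""), ids = msa@ids,
        alphabet = "DNA")
    list(msa = out, moves = moves, passes = passes)
}
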