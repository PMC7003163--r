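# Independent re-derivations used as oracles. These deliberately share no
# code with the package internals.

oracleIupac <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

oracleBaseScore <- function(x, y, match = 1, ts = -1, tv = -2) {
    if (x == y) return(match)
    purines <- c("A", "G")
    if ((x %in% purines) == (y %in% purines)) ts else tv
}

# mean of base scores over all resolved pairs of two IUPAC symbols
oracleEntry <- function(X, Y, match = 1, ts = -1, tv = -2) {
    tot <- 0; n <- 0L
    for (x in oracleIupac[[X]]) for (y in oracleIupac[[Y]]) {
        tot <- tot + oracleBaseScore(x, y, match, ts, tv)
        n <- n + 1L
    }
    tot / n
}

# minimum number of state changes over all internal-node assignments
oracleMinChanges <- function(tree, states, alphabet) {
    nTip <- length(tree$tip.label)
    nNode <- tree$Nnode
    edges <- tree$edge
    tipState <- unname(states[tree$tip.label])
    grid <- expand.grid(rep(list(alphabet), nNode), stringsAsFactors = FALSE)
    best <- Inf
    for (r in seq_len(nrow(grid))) {
        assign <- c(tipState, as.character(unlist(grid[r, ], use.names = FALSE)))
        changes <- sum(assign[edges[, 1L]] != assign[edges[, 2L]])
        if (changes < best) best <- changes
    }
    best
}

# random ungapped codon alignment over all sense codons of the standard code
randomCodonMsa <- function(nSeq, nCodons, seed) {
    set.seed(seed)
    gcode <- Biostrings::getGeneticCode("1")
    sense <- names(gcode)[gcode != "*"]
    seqs <- vapply(seq_len(nSeq), function(i)
        paste(sample(sense, nCodons, replace = TRUE), collapse = ""),
        character(1))
    Msa(seqs, ids = sprintf("r%02d", seq_len(nSeq)), alphabet = "DNA")
}

cliRun <- function(args) {
    script <- system.file("scripts", "degenphy.R", package = "codonDegen")
    rbin <- file.path(R.home("bin"), "Rscript")
    out <- suppressWarnings(system2(rbin, c(shQuote(script), args),
        stdout = TRUE, stderr = TRUE,
        env = paste0("R_LIBS=", shQuote(paste(.libPaths(), collapse = ":")))))
    status <- attr(out, "status")
    list(status = if (is.null(status)) 0L else status, out = out)
}
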