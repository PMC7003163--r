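# run expr with a local, restored RNG state seeded from `seed`
.withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (had) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

#' Generate deterministic multi-gene codon-alignment fixtures
#'
#' Builds a small collection of codon alignments with known ground truth, for
#' exercising concatenation, serine-site filtering, GC3 and degeneration.
#' Background codons avoid AG- and TC- prefixes and stop codons, so the only
#' AGN/UCN co-occurrence sites are the injected ones; third positions are
#' drawn G/C with per-taxon probability \code{gc3Target}. Genes after the
#' first drop a fraction of taxa to emulate partial supermatrix overlap, and
#' whole-codon gap triples can be injected.
#'
#' @param nTaxa,nCodons,nGenes fixture dimensions.
#' @param seed integer seed; identical seeds give identical fixtures.
#' @param gc3Target per-taxon probability that a third position is G/C
#'   (recycled; default drawn uniformly from 0.35-0.80, the compositional
#'   range typical of deep arthropod supermatrices).
#' @param serinePerGene number of AGN/UCN co-occurrence codon sites injected
#'   per gene.
#' @param gapCodonsPerGene number of whole-codon gaps injected per gene.
#' @param dropout fraction of taxa omitted from each gene after the first.
#' @return list with \code{genes} (named list of \linkS4class{Msa}) and
#'   \code{truth} (per-gene injected serine-site indices, per-gene taxa,
#'   and the \code{gc3Target} vector).
#' @examples
#' fx <- makeFixture(nTaxa = 4, nCodons = 20, nGenes = 2, seed = 1)
#' serineSiteFilter(fx$genes[[1]])$removedCount ==
#'     length(fx$truth$serineSites[[1]])
#' @export
makeFixture <- function(nTaxa = 8L, nCodons = 60L, nGenes = 3L, seed = 1L,
                        gc3Target = NULL, serinePerGene = 2L,
                        gapCodonsPerGene = 0L, dropout = 0.25) {
    stopifnot(nTaxa >= 2L, nCodons >= 4L, nGenes >= 1L)
    .withSeed(seed, {
        taxa <- sprintf("t%02d", seq_len(nTaxa))
        if (is.null(gc3Target)) gc3Target <- stats::runif(nTaxa, 0.35, 0.80)
        gc3Target <- setNames(rep_len(gc3Target, nTaxa), taxa)
        # prefixes whose four codons are all sense in the standard code and
        # never AG-/TC-: keeps background free of filterable sites
        prefixes <- c("TT", "CT", "AT", "GT", "CC", "AC", "GC", "CA", "AA",
            "GA", "CG", "GG")
        genes <- list(); truthSer <- list(); truthTaxa <- list()
        for (g in seq_len(nGenes)) {
            present <- taxa
            if (g > 1L && dropout > 0) {
                nDrop <- min(nTaxa - 2L, round(dropout * nTaxa))
                if (nDrop > 0L) present <- sort(sample(taxa, nTaxa - nDrop))
            }
            ancPref <- sample(prefixes, nCodons, replace = TRUE)
            rows <- vapply(present, function(tx) {
                pref <- ancPref
                swap <- stats::runif(nCodons) < 0.1
                pref[swap] <- sample(prefixes, sum(swap), replace = TRUE)
                third <- ifelse(stats::runif(nCodons) < gc3Target[[tx]],
                    sample(c("G", "C"), nCodons, replace = TRUE),
                    sample(c("A", "T"), nCodons, replace = TRUE))
                paste(paste0(pref, third), collapse = "")
            }, character(1))
            msa <- Msa(rows, ids = present, alphabet = "DNA")
            ch <- as.matrix(msa)
            nSer <- min(serinePerGene, nCodons)
            serSites <- sort(sample(seq_len(nCodons), nSer))
            for (s in serSites) {
                pair <- sample(seq_along(present), 2L)
                cols <- (3L * s - 2L):(3L * s)
                ch[pair[1L], cols] <- c("A", "G", sample(c("T", "C"), 1L))
                ch[pair[2L], cols] <- c("T", "C", sample(c("T", "C", "A", "G"), 1L))
            }
            if (gapCodonsPerGene > 0L) {
                open <- setdiff(seq_len(nCodons), serSites)
                nGap <- min(gapCodonsPerGene, length(open))
                for (s in sample(open, nGap))
                    ch[sample(seq_along(present), 1L), (3L * s - 2L):(3L * s)] <-
                        "-"
            }
            genes[[sprintf("gene%02d", g)]] <-
                Msa(apply(ch, 1L, paste, collapse = ""), ids = present,
                    alphabet = "DNA")
            truthSer[[sprintf("gene%02d", g)]] <- serSites
            truthTaxa[[sprintf("gene%02d", g)]] <- present
        }
        list(genes = genes,
            truth = list(serineSites = truthSer, taxa = truthTaxa,
                gc3Target = gc3Target))
    })
}

#' Generate an alignment with deliberately misplaced gap-border residues
#'
#' Builds a well-conserved gapped nucleotide alignment and then, in
#' \code{nMisplaced} sequences, slides one residue bordering the shared gap
#' run to the wrong end -- the configuration PWM refinement is designed to
#' repair.
#'
#' @param nSeq,nSites alignment dimensions (\code{nSites} total columns).
#' @param seed integer seed.
#' @param nMisplaced how many sequences get a misplaced residue.
#' @return list with \code{msa}, \code{clean} (the alignment before
#'   misplacement) and \code{nMisplaced}.
#' @export
makeRefineFixture <- function(nSeq = 8L, nSites = 30L, seed = 1L,
                              nMisplaced = 1L) {
    stopifnot(nSeq >= 4L, nSites >= 12L, nMisplaced < nSeq)
    .withSeed(seed, {
        cons <- sample(c("A", "C", "G", "T"), nSites, replace = TRUE)
        ch <- matrix(rep(cons, each = nSeq), nSeq, nSites)
        mut <- which(matrix(stats::runif(nSeq * nSites) < 0.05, nSeq, nSites))
        ch[mut] <- sample(c("A", "C", "G", "T"), length(mut), replace = TRUE)
        g1 <- floor(nSites / 3); g2 <- g1 + 3L      # shared 4-column gap run
        # keep the run's border columns conserved so the propensity signal
        # for the misplaced residue is unambiguous
        ch[, c(g1 - 1L, g2 + 1L)] <- rep(cons[c(g1 - 1L, g2 + 1L)], each = nSeq)
        ch[, g1:g2] <- "-"
        ids <- sprintf("s%02d", seq_len(nSeq))
        clean <- Msa(apply(ch, 1L, paste, collapse = ""), ids = ids,
            alphabet = "DNA")
        bad <- sample(nSeq, nMisplaced)
        for (i in bad) {   # residue left of the run moves to its right end
            ch[i, g2] <- ch[i, g1 - 1L]
            ch[i, g1 - 1L] <- "-"
        }
        list(msa = Msa(apply(ch, 1L, paste, collapse = ""), ids = ids,
            alphabet = "DNA"), clean = clean, nMisplaced = nMisplaced)
    })
}
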