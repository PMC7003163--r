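test_that("concatenation fills missing taxa and records partitions", {
    g1 <- Msa(c(A = "ATGATG", B = "ATGCTG"))
    g2 <- Msa(c(B = "AAATTTGGG", C = "AAATTTGGC"))
    sm <- concatenateGenes(list(G1 = g1, G2 = g2), separator = "NNNNNN")
    expect_identical(length(sm$msa), 3L)
    expect_identical(msaWidth(sm$msa), 21L)
    s <- msaSeqs(sm$msa)
    expect_identical(s[["A"]], paste0("ATGATG", "NNNNNN", strrep("?", 9)))
    expect_identical(s[["B"]], paste0("ATGCTG", "NNNNNN", "AAATTTGGG"))
    expect_identical(s[["C"]], paste0(strrep("?", 6), "NNNNNN", "AAATTTGGC"))
    expect_identical(sm$partitions$start, c(1L, 13L))
    expect_identical(sm$partitions$end, c(6L, 21L))

    # single gene, no separator: identity
    one <- concatenateGenes(list(g1))
    expect_identical(msaSeqs(one$msa), msaSeqs(g1))
    expect_identical(one$partitions$end, 6L)

    # '-' fill on request
    dash <- concatenateGenes(list(G1 = g1, G2 = g2), fill = "-")
    expect_identical(substr(msaSeqs(dash$msa)[["C"]], 1, 6), "------")
})

test_that("concatenation conserves every residue at its partition coordinate", {
    fx <- makeFixture(nTaxa = 6, nCodons = 15, nGenes = 3, seed = 21,
        dropout = 0.3)
    sm <- concatenateGenes(fx$genes, separator = "NNNNNN")
    for (g in seq_along(fx$genes)) {
        gene <- fx$genes[[g]]
        block <- substr(msaSeqs(sm$msa)[msaIds(gene)],
            sm$partitions$start[g], sm$partitions$end[g])
        expect_identical(unname(block), unname(msaSeqs(gene)))
    }
    # absent taxa are pure fill inside the gene's partition
    for (g in seq_along(fx$genes)) {
        absent <- setdiff(msaIds(sm$msa), msaIds(fx$genes[[g]]))
        for (tx in absent) {
            block <- substr(msaSeqs(sm$msa)[[tx]],
                sm$partitions$start[g], sm$partitions$end[g])
            expect_identical(block, strrep("?", nchar(block)))
        }
    }
})

test_that("serine-site filter removes AGN/UCN co-occurrence sites and only those", {
    r <- serineSiteFilter(Msa(c(a = "AGC", b = "TCA", c = "TTT")))
    expect_identical(r$removedCount, 1L)
    expect_identical(r$removedSites, 1L)
    expect_identical(msaWidth(r$msa), 0L)

    keep <- serineSiteFilter(Msa(c(a = "TCA", b = "TCC", c = "TCG")))
    expect_identical(keep$removedCount, 0L)
    expect_identical(msaSeqs(keep$msa), msaSeqs(Msa(c(a = "TCA", b = "TCC", c = "TCG"))))

    # mixed matrix: only the co-occurrence site goes
    m <- Msa(c(a = "ATGAGCTTT", b = "ATGTCGTTT", c = "ATGGGGTTT"))
    r2 <- serineSiteFilter(m)
    expect_identical(r2$removedSites, 2L)
    expect_identical(msaWidth(r2$msa), 6L)
    expect_identical(msaWidth(r2$msa), msaWidth(m) - 3L * r2$removedCount)
    # idempotent: refiltering removes nothing
    expect_identical(serineSiteFilter(r2$msa)$removedCount, 0L)
})

test_that("strict serine filtering requires actual serine codons", {
    # AGG is arginine in the standard code: literal rule flags it, strict keeps
    m <- Msa(c(a = "AGG", b = "TCA"))
    expect_identical(serineSiteFilter(m)$removedCount, 1L)
    expect_identical(serineSiteFilter(m, strict = TRUE)$removedCount, 0L)
    ser <- Msa(c(a = "AGC", b = "TCA"))
    expect_identical(serineSiteFilter(ser, strict = TRUE)$removedCount, 1L)
})

test_that("filter removes exactly the fixture's injected sites", {
    for (seed in c(2, 17)) {
        fx <- makeFixture(nTaxa = 8, nCodons = 50, nGenes = 2, seed = seed,
            serinePerGene = 4)
        for (g in names(fx$genes)) {
            r <- serineSiteFilter(fx$genes[[g]])
            expect_identical(r$removedSites, fx$truth$serineSites[[g]])
            expect_identical(msaWidth(r$msa),
                msaWidth(fx$genes[[g]]) - 3L * r$removedCount)
        }
    }
})

test_that("gc3 counts G+C at third positions over countable sites", {
    expect_identical(unname(gc3("GGG")), 100)
    expect_identical(unname(gc3("ATA")), 0)
    expect_identical(unname(gc3("ATGGCA")), 50)
    # invariant under whole-codon gap insertion and N at the third position
    expect_identical(unname(gc3("ATG---GCA")), 50)
    expect_identical(unname(gc3("ATGGCAGGN")), 50)
    expect_warning(v <- gc3("---"), "no countable")
    expect_true(is.na(v))
    expect_error(gc3("AT"), "not divisible by 3")
    # fixture taxon with target GC3 of 1 reports exactly 100
    fx <- makeFixture(nTaxa = 3, nCodons = 40, nGenes = 1, seed = 5,
        gc3Target = c(1, 0.5, 0), serinePerGene = 0)
    v <- gc3(fx$genes[[1]])
    expect_identical(unname(v[["t01"]]), 100)
    expect_identical(unname(v[["t03"]]), 0)
})
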