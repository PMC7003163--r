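gc1 <- geneticCode(1)

test_that("resolveCodon expands IUPAC triplets and iupacSymbol inverts it", {
    expect_setequal(resolveCodon("YTR"), c("CTA", "CTG", "TTA", "TTG"))
    expect_identical(resolveCodon("ATG"), "ATG")
    expect_identical(iupacSymbol(c("A", "G")), "R")
    expect_identical(iupacSymbol(c("T", "C", "A", "G")), "N")
    for (sym in c("A", "R", "B", "N"))
        expect_identical(iupacSymbol(resolveCodon(sym)), sym)
    expect_error(resolveCodon("QTR"), "non-IUPAC")
})

test_that("principled map reproduces the printed degenerations", {
    p <- principledMap(gc1)
    mp <- degenMapping(p)
    expect_identical(unname(mp[c("CTT", "CTC", "CTA", "CTG")]),
        rep("CTN", 4L))
    expect_identical(unname(mp[c("TTA", "TTG")]), rep("YTR", 2L))
    expect_identical(unname(mp[c("TCA", "AGT")]), c("TCN", "AGY"))
    expect_identical(unname(mp[["ATG"]]), "ATG")
    expect_true("S" %in% incompatibleFamilies(p))
    expect_false("L" %in% incompatibleFamilies(p))

    p24 <- principledMap(geneticCode(24))
    expect_identical(unname(degenMapping(p24)[c("AAA", "AAG", "AGG")]),
        c("AAR", "AAR", "ARG"))
})

test_that("degen1 map reproduces the Regier-style degenerations", {
    d <- degen1Map(gc1)
    mp <- degenMapping(d)
    expect_identical(unname(mp[c("TTA", "CTT", "TTT")]),
        c("YTN", "YTN", "TTY"))
    expect_identical(unname(mp[["CGA"]]), "MGN")
    # serine subfamilies differ at both of positions 1-2: no cross merge
    expect_identical(unname(mp[c("TCA", "AGT")]), c("TCN", "AGY"))
})

test_that("Degen1 lumps nonsynonymous codons where the principled map does not", {
    d1 <- degenMapping(degen1Map(gc1))[["TTA"]]
    pr <- degenMapping(principledMap(gc1))[["TTA"]]
    expect_identical(d1, "YTN")
    expect_identical(pr, "YTR")
    expect_true("TTT" %in% resolveCodon(d1))     # Phe codon inside YTN
    expect_false("TTT" %in% resolveCodon(pr))    # but not inside YTR
})

test_that("codon compatibility follows shared resolved codons", {
    expect_true(codonsCompatible("CTN", "YTR"))
    expect_true(codonsCompatible("AAR", "ARG"))
    expect_false(codonsCompatible("ARG", "AGA"))
    expect_false(codonsCompatible("YTR", "TTY"))
    expect_false(codonsCompatible("TTY", "CTN"))
})

test_that("principled purity and compatibility hold exhaustively in all tables", {
    for (id in supportedGeneticCodes()$id) {
        code <- geneticCode(id)
        ct <- codonTable(code)
        p <- principledMap(code)
        mp <- degenMapping(p)
        for (cod in names(ct)[ct != "*"]) {
            resolved <- resolveCodon(mp[[cod]])
            expect_true(cod %in% resolved)
            expect_true(all(ct[resolved] == ct[[cod]]),
                label = sprintf("purity of %s -> %s in table %d",
                    cod, mp[[cod]], id))
        }
        for (aa in setdiff(unique(ct[ct != "*"]), incompatibleFamilies(p))) {
            images <- unique(mp[names(ct)[ct == aa]])
            if (length(images) > 1L) {
                prs <- combn(images, 2L)
                for (k in seq_len(ncol(prs)))
                    expect_true(codonsCompatible(prs[1L, k], prs[2L, k]),
                        label = sprintf("compatibility of %s/%s (aa %s, table %d)",
                            prs[1L, k], prs[2L, k], aa, id))
            }
        }
        # degen1: every codon contained in its image in every table
        d <- degenMapping(degen1Map(code))
        for (cod in names(ct)[ct != "*"])
            expect_true(cod %in% resolveCodon(d[[cod]]))
    }
})

test_that("degenerateMsa replaces codons, passes gaps through, is idempotent", {
    p <- principledMap(gc1)
    msa <- Msa(c(a = "CTC---AGT", b = "TTGNNNAGC", c = "TTCTAA???"))
    out <- suppressWarnings(degenerateMsa(msa, p))
    expect_identical(unname(msaSeqs(out)),
        c("CTN---AGY", "YTRNNNAGY", "TTYTAA???"))
    expect_identical(msaIds(out), msaIds(msa))
    expect_identical(msaWidth(out), msaWidth(msa))
    # idempotence: degenerate images pass through unchanged
    expect_identical(msaSeqs(degenerateMsa(out, p)), msaSeqs(out))
    # gap positions preserved on random fixtures
    fx <- makeFixture(nTaxa = 5, nCodons = 30, nGenes = 1, seed = 7,
        gapCodonsPerGene = 4)
    g <- fx$genes[[1]]
    dg <- degenerateMsa(g, p)
    expect_identical(gregexpr("-", msaSeqs(dg)[[1]]),
        gregexpr("-", msaSeqs(g)[[1]]))
})

test_that("degenerateMsa rejects frame violations", {
    p <- principledMap(gc1)
    expect_error(degenerateMsa(Msa(c(a = "CTCA", b = "TTGA")), p),
        "not divisible by 3")
    expect_error(degenerateMsa(Msa(c(a = "CT-CTA", b = "CTACTA")), p),
        "breaks a codon")
})
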