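test_that("ambiguity matrix reproduces printed entries under the default scheme", {
    m <- expandScoreMatrix(scoreScheme())
    expect_identical(m["A", "A"], 1)
    expect_identical(m["A", "R"], 0)     # (1 - 1) / 2
    expect_identical(m["A", "Y"], -2)    # always a transversion
    expect_identical(m["N", "N"], -1)    # mean over all 16 base pairs
})

test_that("ambiguity matrix equals the brute-force averaging oracle", {
    set.seed(42)
    schemes <- rbind(c(1, -1, -2), c(2, 0, -3), c(5, -0.5, -1.5),
        matrix(c(runif(3, 1, 4), runif(3, -2, 0), runif(3, -4, -2)),
            ncol = 3))
    for (r in seq_len(nrow(schemes))) {
        sch <- scoreScheme(schemes[r, 1], schemes[r, 2], schemes[r, 3])
        m <- expandScoreMatrix(sch)
        expect_identical(rownames(m), names(oracleIupac))
        for (x in rownames(m)) for (y in colnames(m))
            expect_equal(m[x, y],
                oracleEntry(x, y, schemes[r, 1], schemes[r, 2], schemes[r, 3]),
                tolerance = 1e-12)
        # symmetry and base-scheme restriction
        expect_equal(m, t(m))
        expect_equal(unname(diag(m[c("A", "C", "G", "T"), c("A", "C", "G", "T")])),
            rep(schemes[r, 1], 4))
    }
})

test_that("pairScore reproduces the one-codon walkthrough and basic identities", {
    expect_identical(pairScore("CTC", "TTG"), -2)   # ts + match + tv
    expect_identical(pairScore("CTC", "TTC"), 1)
    expect_identical(pairScore("TTG", "TTC"), 0)
    expect_identical(pairScore("CTN", "TTY"), -1)
    x <- "ACGTACGT"
    expect_identical(pairScore(x, x), nchar(x) * 1)
    expect_error(pairScore("ACG", "ACGT"), "differ in length")
    expect_error(pairScore("AXG", "ACG"), "non-IUPAC symbol 'X' at position 2")
})

test_that("pairScore is symmetric and monotone in the match score", {
    set.seed(11)
    for (i in 1:20) {
        a <- paste(sample(names(oracleIupac), 12, replace = TRUE), collapse = "")
        b <- paste(sample(names(oracleIupac), 12, replace = TRUE), collapse = "")
        expect_equal(pairScore(a, b), pairScore(b, a))
        lo <- scoreScheme(match = 1)
        hi <- suppressWarnings(scoreScheme(match = 3))
        expect_gte(pairScore(a, b, hi), pairScore(a, b, lo))
    }
})

test_that("gap runs are penalized affinely and shared gaps are free", {
    sch <- scoreScheme()    # gap open -5, extend -1
    expect_identical(pairScore("AAAA", "A--A", sch), 2 - 5 - 1)
    expect_identical(pairScore("AAAA", "A-AA", sch), 3 - 5)
    # two separate runs each open
    expect_identical(pairScore("AAAAA", "A-A-A", sch), 3 - 5 - 5)
    # shared-gap column contributes nothing and does not re-open the run
    expect_identical(pairScore("AA-AA", "A---A", sch), 2 - 5 - 1)
    # column gapped in both sequences is free
    expect_identical(pairScore("A-A", "A-A", sch), 2)
})

test_that("spScore sums all pairs, matches a naive double loop, ignores all-gap columns", {
    msa <- Msa(c(s1 = "CTC", s2 = "TTG", s3 = "TTC"))
    expect_identical(spScore(msa), -2 + 1 + 0)
    two <- Msa(c(a = "ACGT-A", b = "ACG--A"))
    expect_identical(spScore(two), pairScore("ACGT-A", "ACG--A"))
    expect_error(spScore(Msa(c(a = "ACG"))), "at least 2")

    set.seed(3)
    for (rep in 1:5) {
        msa <- randomCodonMsa(5, 8, seed = rep)
        naive <- 0
        s <- msaSeqs(msa)
        for (i in 1:4) for (j in (i + 1):5)
            naive <- naive + pairScore(s[[i]], s[[j]])
        expect_equal(spScore(msa), naive)
        # appending an all-gap column changes nothing
        padded <- Msa(paste0(s, "-"), ids = msaIds(msa))
        expect_equal(spScore(padded), spScore(msa))
    }
})

test_that("selectBestAlignment picks the highest SP score with first-wins ties", {
    good <- Msa(c(a = "ACGTAC", b = "ACGTAC"))
    bad <- Msa(c(a = "ACGTAC--", b = "--ACGTAC"))
    sel <- selectBestAlignment(list(bad, good))
    expect_identical(sel$bestIndex, 2L)
    expect_false(sel$tie)
    expect_identical(nrow(sel$report), 2L)
    expect_true(sel$report$sp[2] > sel$report$sp[1])

    one <- selectBestAlignment(list(good))
    expect_identical(one$bestIndex, 1L)

    tie <- selectBestAlignment(list(good, good))
    expect_identical(tie$bestIndex, 1L)
    expect_true(tie$tie)

    other <- Msa(c(a = "ACGTAT", b = "ACGTAC"))
    expect_error(selectBestAlignment(list(good, other)),
        "disagrees on ungapped content for 'a'")
})
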