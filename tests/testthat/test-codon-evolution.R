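test_that("per-codon site counts match single-mutation enumeration", {
    expect_equal(countSites("TTT"), c(S = 1/3, N = 8/3))
    expect_equal(countSites("GGG"), c(S = 1, N = 2))
    expect_equal(countSites("ATG"), c(S = 0, N = 3))
    expect_error(countSites("TAA"), "stop")
    ## S + N = 3 exactly for every sense codon
    for (codon in senseCodons(gcStd)) {
        sc <- countSites(codon)
        expect_equal(unname(sc["S"] + sc["N"]), 3)
        expect_gte(sc[["S"]], 0)
    }
})

test_that("pathway-averaged differences match the stated examples", {
    expect_equal(countPathwayDifferences("TTT", "TTA"),
                 c(Sd = 0, Nd = 1), ignore_attr = TRUE)
    expect_equal(countPathwayDifferences("TTT", "GTA"),
                 c(Sd = 0.5, Nd = 1.5), ignore_attr = TRUE)
    expect_equal(countPathwayDifferences("AAA", "AAA"),
                 c(Sd = 0, Nd = 0), ignore_attr = TRUE)
})

test_that("pathway counting equals the brute-force ordering oracle on all codon pairs", {
    sense <- senseCodons(gcStd)
    for (a in sense) for (b in sense) {
        expected <- oraclePathwayCounts(a, b)
        if (is.null(expected)) next  # fully blocked; fallback tested below
        got <- countPathwayDifferences(a, b)
        expect_equal(unname(got), unname(expected), tolerance = 1e-12,
                     ignore_attr = TRUE,
                     label = paste("pair", a, b))
        k <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
        expect_equal(unname(got["Sd"] + got["Nd"]), k)
    }
})

test_that("fully stop-blocked pathways fall back and are flagged", {
    ## toy code in which both intermediates of TAT <-> TGC are stops
    toy <- toyCodeWithStops(c("TGT", "TAC"))
    res <- countPathwayDifferences("TAT", "TGC", code = toy)
    expect_true(attr(res, "degenerate"))
    expect_equal(unname(res["Sd"] + res["Nd"]), 2)
})

test_that("Jukes-Cantor correction matches the closed form and saturates", {
    expect_equal(jukesCantor(0.1), 0.10732, tolerance = 1e-4)
    expect_equal(jukesCantor(0), 0)
    expect_error(jukesCantor(0.75), "saturated")
})

test_that("ng86Distance is zero on identical sequences and symmetric", {
    aln <- codonAlignment(c(a = "ATGAAACCCGGGTTTACT", b = "ATGAAACCCGGGTTTACT",
                            c = "ATGAAGCCAGGGTTTACT"))
    d0 <- ng86Distance(aln, "a", "b")
    expect_equal(d0$dS, 0)
    expect_equal(d0$dN, 0)
    dab <- ng86Distance(aln, "a", "c")
    dba <- ng86Distance(aln, "c", "a")
    expect_equal(dab$dS, dba$dS)
    expect_equal(dab$dN, dba$dN)
    ## a-c differs by two synonymous third positions: Sd = 2, Nd = 0
    expect_equal(dab$Sd, 2)
    expect_equal(dab$Nd, 0)
    expect_equal(dab$dS, jukesCantor(2 / dab$S))
    ## S + N = 3 * n_codons
    expect_equal(dab$S + dab$N, 3 * nCodons(aln))
})

test_that("dS grows when synonymous-differing columns are appended", {
    base <- c(a = "ATGAAACCC", b = "ATGAAACCC")
    more <- c(a = paste0(base["a"], "GGG"), b = paste0(base["b"], "GGA"))
    aln1 <- codonAlignment(base)
    aln2 <- codonAlignment(more)
    expect_gt(ng86Distance(aln2, "a", "b")$dS,
              ng86Distance(aln1, "a", "b")$dS)
})

test_that("distanceSummary reports sample statistics over all pairs", {
    aln <- codonAlignment(c(a = "ATGAAACCCGGG", b = "ATGAAACCCGGG",
                            c = "ATGAAACCCGGG"))
    ds <- distanceSummary(aln)
    expect_equal(ds$summary$n_pairs, 3)
    expect_equal(ds$summary$mean_dS, 0)
    expect_equal(ds$summary$sd_dS, 0)
    ## summary is consistent with the pairs table
    aln2 <- codonAlignment(c(a = "ATGAAACCCGGGTTTACTGCT",
                             b = "ATGAAGCCAGGGTTTACTGCT",
                             c = "ATGAAACCAGGCTTCACTGCT"))
    ds2 <- distanceSummary(aln2)
    expect_equal(ds2$summary$mean_dS, mean(ds2$pairs$dS))
    expect_equal(ds2$summary$sd_dS, sd(ds2$pairs$dS))
    expect_equal(ds2$summary$mean_dN, mean(ds2$pairs$dN))
    ## sample SD oracle on {0, 0.1, 0.2}
    expect_equal(sd(c(0, 0.1, 0.2)), 0.1)
})

test_that("divergence time follows T = dS / 2K", {
    expect_equal(divergenceTime(0)$T_years, 0)
    ct <- divergenceTime(0.0876, K = 4.38e-9)
    expect_equal(ct$T_years, 1.0e7)
    expect_equal(ct$T_MY, 10)
    ## linear in dS
    expect_equal(divergenceTime(2 * 0.0876)$T_MY, 2 * ct$T_MY)
    expect_error(divergenceTime(0.1, K = 0), "positive")
    expect_error(divergenceTime(-0.1), "non-negative")
})

test_that("Nc attains its closed-form extremes", {
    sense <- senseCodons(gcStd)
    uniform <- paste(rep(sense, each = 10), collapse = "")
    expect_equal(effectiveNumberOfCodons(uniform)$Nc, 61)
    ## one codon per amino acid: maximal bias, Nc = 20 by Wright's formula
    aaOf <- gcStd@codonToAa[sense]
    oneEach <- sense[!duplicated(aaOf)]
    biased <- paste(rep(oneEach, each = 5), collapse = "")
    expect_equal(effectiveNumberOfCodons(biased)$Nc, 20)
})

test_that("Nc class fallback fills unobserved degeneracy classes", {
    ## only lysine observed, both codons equal: F2 = 0.5, other classes
    ## fall back to 1/k, giving 2 + 18 + 3 + 20 + 18 = 61
    cds <- paste(rep(c("AAA", "AAG"), 10), collapse = "")
    res <- effectiveNumberOfCodons(cds)
    expect_equal(res$Nc, 61)
    expect_equal(unname(res$familyHomozygosity["2"]), 0.5)
    expect_equal(unname(res$familyHomozygosity["4"]), 0.25)
    expect_equal(unname(res$familiesUsed["4"]), 0L)
})

test_that("Nc is invariant to codon order and bounded", {
    set.seed(11)
    sense <- senseCodons(gcStd)
    codons <- sample(sense, 300, replace = TRUE)
    nc1 <- effectiveNumberOfCodons(paste(codons, collapse = ""))$Nc
    nc2 <- effectiveNumberOfCodons(paste(sample(codons), collapse = ""))$Nc
    expect_equal(nc1, nc2)
    expect_lte(nc1, 61)
    expect_gte(nc1, 20)
    expect_error(effectiveNumberOfCodons("TAA"), "no sense codons")
})

test_that("simulated synonymous divergence is recovered by NG86 dS", {
    ## 2 taxa separated by total branch length 0.12 under pure purifying
    ## selection; observed dS should sit within 3 SE of the generator's
    ## synonymous expectation
    tree <- readNewick("(x:0.06,y:0.06);")
    sim <- simulateCodonAlignment(tree = tree, nCodons = 1200, kappa = 2,
                                  omegaClasses = data.frame(omega = 0.3,
                                                            prop = 1),
                                  seed = 21)
    d <- ng86Distance(sim$alignment, "x", "y")
    ## generator-side expectation: synonymous substitutions per codon per
    ## unit branch length over NG86 synonymous sites per codon
    gc <- gcStd
    info <- paralogEvol:::codonPairInfo(gc)
    pi <- rep(1 / info$n, info$n)
    Q <- paralogEvol:::makeQ(2, 0.3, pi, info)
    Q <- Q / paralogEvol:::meanRate(Q, pi)
    synRate <- sum(pi[info$ii] * Q[cbind(info$ii, info$jj)] *
                   info$isSynonymous)
    Sbar <- mean(vapply(senseCodons(gc),
                        function(cc) countSites(cc)[["S"]], numeric(1)))
    expdS <- 0.12 * synRate / Sbar
    se <- sqrt(d$pS * (1 - d$pS) / d$S) / (1 - 4 * d$pS / 3)
    expect_lt(abs(d$dS - expdS), 3 * se)
})
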