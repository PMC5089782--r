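test_that("F3x4 frequencies are normalized and uniform under uniform input", {
    ## alignment whose codon columns realize all 4 bases equally at each
    ## position: frequencies collapse to 1/61 per sense codon
    quads <- c("AAA", "CCC", "GGG", "TTT")
    seqs <- c(a = paste(quads, collapse = ""),
              b = paste(quads[c(2, 3, 4, 1)], collapse = ""),
              c = paste(quads[c(3, 4, 1, 2)], collapse = ""),
              d = paste(quads[c(4, 1, 2, 3)], collapse = ""))
    aln <- codonAlignment(seqs)
    pi <- f3x4Frequencies(aln)
    expect_equal(sum(pi), 1)
    expect_equal(unname(pi), rep(1 / 61, 61), tolerance = 1e-12)
    ## degenerate single-codon alignment: observed codon dominates
    alnA <- codonAlignment(c(a = "AAAAAA", b = "AAAAAA"))
    piA <- f3x4Frequencies(alnA)
    expect_gt(piA[["AAA"]], 0.999)
    expect_equal(sum(piA), 1)
})

test_that("the codon rate matrix is a scaled reversible generator", {
    aln <- codonAlignment(c(a = "ATGAAACCCGGGTTT", b = "ATGAAGCCAGGCTTC"))
    pi <- f3x4Frequencies(aln)
    Q <- codonRateMatrix(kappa = 2.5, omega = 0.4, pi = pi)
    expect_lt(max(abs(rowSums(Q))), 1e-12)
    ## detailed balance pi_i q_ij = pi_j q_ji
    bal <- pi * Q
    expect_lt(max(abs(bal - t(bal))), 1e-12)
    ## scaled to one expected substitution per unit branch length
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
    ## omega = 0 removes all non-synonymous rates
    Q0 <- codonRateMatrix(kappa = 2.5, omega = 0, pi = pi)
    info <- paralogEvol:::codonPairInfo(gcStd)
    nonsyn <- cbind(info$ii, info$jj)[!info$isSynonymous, ]
    expect_true(all(Q0[nonsyn] == 0))
})

test_that("zero branch lengths on identical sequences give the closed-form lnl", {
    aln <- codonAlignment(c(a = "ATGAAACCC", b = "ATGAAACCC",
                            c = "ATGAAACCC"))
    pi <- f3x4Frequencies(aln)
    params <- list(kappa = 2, pi = pi, branchLengths = rep(1e-9, 3),
                   omega = 0.5, prop = 1)
    lnl <- codonLogLikelihood(aln, NULL, params)
    expected <- sum(log(pi[c("ATG", "AAA", "CCC")]))
    expect_equal(lnl, expected, tolerance = 1e-6)
})

test_that("pruning equals brute-force root-state enumeration via expm", {
    skip_if_not_installed("Matrix")
    sim <- simulateCodonAlignment(nCodons = 10, kappa = 2,
                                  omegaClasses = data.frame(
                                      omega = c(0.3, 1), prop = c(0.7, 0.3)),
                                  seed = 3, branchLength = 0.1)
    aln <- sim$alignment
    pi <- f3x4Frequencies(aln)
    bl <- c(0.08, 0.15, 0.05)
    tree <- readNewick("(sp1:0.08,sp2:0.15,sp3:0.05);")
    params <- list(kappa = 2.4, pi = pi, branchLengths = bl,
                   omega = c(0.3, 1), prop = c(0.7, 0.3))
    lnl <- codonLogLikelihood(aln, tree, params)

    sense <- senseCodons(gcStd)
    info <- paralogEvol:::codonPairInfo(gcStd)
    Qs <- lapply(c(0.3, 1), function(w)
        paralogEvol:::makeQ(2.4, w, pi[sense], info))
    mr <- vapply(Qs, paralogEvol:::meanRate, numeric(1), pi = pi[sense])
    s <- sum(c(0.7, 0.3) * mr)
    cm <- paralogEvol:::codonMatrix(aln)
    tips <- c("sp1", "sp2", "sp3")
    Ps <- lapply(Qs, function(Q) Map(function(t)
        as.matrix(Matrix::expm(Q * t / s)), setNames(bl, tips)))
    brute <- 0
    for (j in seq_len(ncol(cm))) {
        Lc <- vapply(1:2, function(cl)
            sum(vapply(seq_along(sense), function(x)
                pi[sense][x] * prod(vapply(tips, function(tp)
                    Ps[[cl]][[tp]][x, match(cm[tp, j], sense)],
                    numeric(1))), numeric(1))), numeric(1))
        brute <- brute + log(0.7 * Lc[1] + 0.3 * Lc[2])
    }
    expect_equal(lnl, brute, tolerance = 1e-8)
})

test_that("site independence: duplicating every column doubles the lnl", {
    aln <- codonAlignment(c(a = "ATGAAACCCGGG", b = "ATGAAGCCAGGC",
                            c = "ATGAAACCAGGG"))
    dup <- codonAlignment(vapply(as.character(alignedSeqs(aln)),
                                 function(s) paste0(s, s), character(1)))
    pi <- f3x4Frequencies(aln)
    params <- list(kappa = 2, pi = pi, branchLengths = c(0.1, 0.1, 0.1),
                   omega = 0.4, prop = 1)
    expect_equal(codonLogLikelihood(dup, NULL, params),
                 2 * codonLogLikelihood(aln, NULL, params),
                 tolerance = 1e-10)
})

test_that("likelihood is invariant to re-rooting the unrooted tree", {
    tree1 <- readNewick("((A:0.08,B:0.12):0.05,C:0.1,D:0.15);")
    sim <- simulateCodonAlignment(tree = tree1, nCodons = 60, kappa = 2,
                                  seed = 9)
    aln <- sim$alignment
    pi <- f3x4Frequencies(aln)
    tree2 <- readNewick("((C:0.1,D:0.15):0.05,A:0.08,B:0.12);")
    p1 <- list(kappa = 2, pi = pi, branchLengths = tree1$edge.length,
               omega = 0.4, prop = 1)
    p2 <- list(kappa = 2, pi = pi, branchLengths = tree2$edge.length,
               omega = 0.4, prop = 1)
    expect_equal(codonLogLikelihood(aln, tree1, p1),
                 codonLogLikelihood(aln, tree2, p2), tolerance = 1e-9)
})

test_that("M0 recovers the generating omega on simulated data", {
    sim <- simulateCodonAlignment(nCodons = 500, kappa = 2,
                                  omegaClasses = data.frame(omega = 0.3,
                                                            prop = 1),
                                  seed = 7, branchLength = 0.05)
    fit <- fitSiteModel(sim$alignment, model = "M0", nRestarts = 2)
    expect_true(fit@converged)
    expect_gt(fit@omega, 0.2)
    expect_lt(fit@omega, 0.4)
})

test_that("nested site models respect constraints and lnl ordering", {
    sim <- simulateCodonAlignment(nCodons = 300, kappa = 2,
                                  omegaClasses = data.frame(
                                      omega = c(0.2, 1), prop = c(0.8, 0.2)),
                                  seed = 15, branchLength = 0.08)
    m0 <- fitSiteModel(sim$alignment, model = "M0", nRestarts = 1)
    m1a <- fitSiteModel(sim$alignment, model = "M1a", nRestarts = 1,
                        init = m0)
    m2a <- fitSiteModel(sim$alignment, model = "M2a", nRestarts = 1,
                        init = m1a)
    expect_gte(m1a@lnl, m0@lnl - 1e-6)
    expect_gte(m2a@lnl, m1a@lnl - 1e-6)
    expect_identical(m1a@omega[2], 1)       # fixed, not estimated
    expect_identical(m2a@omega[2], 1)
    expect_gte(m2a@omega[3], 1)
    expect_lt(m1a@omega[1], 1)
    expect_equal(sum(m2a@prop), 1)
    expect_equal(m0@nFreeParams + 1L, m1a@nFreeParams)
    expect_equal(m1a@nFreeParams + 2L, m2a@nFreeParams)
})

test_that("chi-squared upper tail matches closed forms", {
    expect_equal(chisqUpperTail(9.72, 2), exp(-4.86), tolerance = 1e-12)
    expect_equal(chisqUpperTail(0, 1), 1)
    expect_equal(chisqUpperTail(0, 2), 1)
    expect_equal(chisqUpperTail(18.15, 1), 2.0e-5, tolerance = 2e-2)
})

test_that("likelihoodRatioTest computes 2-delta-lnl with clamping", {
    lrt <- likelihoodRatioTest(-3471.89, -3469.56, df = 1)
    expect_equal(lrt$delta, 4.66, tolerance = 1e-9)
    lrt2 <- likelihoodRatioTest(-2318.59, -2313.73, df = 2)
    expect_equal(lrt2$delta, 9.72, tolerance = 1e-9)
    same <- likelihoodRatioTest(-100, -100, df = 1)
    expect_equal(same$delta, 0)
    expect_equal(same$p_value, 1)
    ## worse alternative clamps (and warns when beyond tolerance)
    expect_warning(out <- likelihoodRatioTest(-100, -100.2, df = 1),
                   "clamped")
    expect_equal(out$delta, 0)
    expect_error(likelihoodRatioTest(-100, -99, df = 0), "df")
})

test_that("BEB posteriors are proper and silent without signal", {
    ## alignment with only synonymous variation: nothing should be flagged
    aln <- codonAlignment(c(a = "ATGAAACCCGGGACT", b = "ATGAAGCCAGGAACC",
                            c = "ATGAAACCGGGCACA"))
    m1 <- fitSiteModel(aln, model = "M1a", nRestarts = 1)
    m2 <- fitSiteModel(aln, model = "M2a", nRestarts = 1, init = m1)
    beb <- bebSitePosteriors(aln, NULL, m2, referenceId = "a")
    expect_true(all(beb$posteriorPositive >= 0 & beb$posteriorPositive <= 1))
    expect_false(any(beb$flagged))
    expect_equal(nrow(beb), nCodons(aln))
    expect_equal(beb$referenceResidue,
                 strsplit("MKPGT", "")[[1]])
    expect_error(bebSitePosteriors(aln, NULL, m2, referenceId = "zz"),
                 "reference")
    expect_error(bebSitePosteriors(aln, NULL, m1, referenceId = "a"),
                 "M2a")
})

test_that("BEB concentrates posterior mass on truly positive sites", {
    sim <- simulateCodonAlignment(nCodons = 800, kappa = 2,
                                  omegaClasses = data.frame(
                                      omega = c(0.2, 1, 8),
                                      prop = c(0.6, 0.3, 0.1)),
                                  seed = 42, branchLength = 0.1)
    aln <- sim$alignment
    m1 <- fitSiteModel(aln, model = "M1a", nRestarts = 1)
    m2 <- fitSiteModel(aln, model = "M2a", nRestarts = 1, init = m1)
    beb <- bebSitePosteriors(aln, NULL, m2, referenceId = "sp1")
    expect_true(all(beb$posteriorPositive >= 0 & beb$posteriorPositive <= 1))
    ## strongly signalled true positives (>= 2 non-synonymous changes,
    ## i.e. three distinct residues across the star) mostly reach the top
    ## posterior decile
    aa <- do.call(rbind, strsplit(as.character(translateAlignment(aln)), ""))
    distinct <- apply(aa, 2, function(col) length(unique(col)))
    strong <- which(sim$siteClasses == 3 & distinct == 3)
    topDecile <- order(beb$posteriorPositive, decreasing = TRUE)[
        seq_len(ceiling(0.1 * nCodons(aln)))]
    expect_gte(mean(strong %in% topDecile), 0.5)
})
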