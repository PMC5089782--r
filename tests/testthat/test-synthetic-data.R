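test_that("generators are deterministic under a fixed seed", {
    s1 <- simulateCodonAlignment(nCodons = 50, seed = 5)
    s2 <- simulateCodonAlignment(nCodons = 50, seed = 5)
    expect_identical(as.character(alignedSeqs(s1$alignment)),
                     as.character(alignedSeqs(s2$alignment)))
    expect_identical(s1$siteClasses, s2$siteClasses)
    s3 <- simulateCodonAlignment(nCodons = 50, seed = 6)
    expect_false(identical(as.character(alignedSeqs(s1$alignment)),
                           as.character(alignedSeqs(s3$alignment))))

    q1 <- simulateQpcrExperiment(seed = 2)
    q2 <- simulateQpcrExperiment(seed = 2)
    expect_identical(q1$data, q2$data)

    p1 <- simulatePromoters(seed = 9)
    p2 <- simulatePromoters(seed = 9)
    expect_identical(p1$sequences, p2$sequences)
})

test_that("zero branch lengths copy the root to every tip", {
    tree <- readNewick("(a:0,b:0,c:0);")
    sim <- simulateCodonAlignment(tree = tree, nCodons = 30, seed = 3)
    seqs <- as.character(alignedSeqs(sim$alignment))
    expect_equal(seqs[["a"]], seqs[["b"]])
    expect_equal(seqs[["a"]], seqs[["c"]])
})

test_that("simulated tip codon frequencies converge to pi", {
    ## marginal distribution at a tip is stationary: chi-squared GOF
    ## against the uniform pi must not reject at n = 50,000 sites
    tree <- readNewick("(x:0.3,y:0.3);")
    sim <- simulateCodonAlignment(tree = tree, nCodons = 50000, seed = 12)
    cm <- paralogEvol:::codonMatrix(sim$alignment)
    counts <- table(factor(cm["x", ], levels = senseCodons(gcStd)))
    gof <- stats::chisq.test(as.numeric(counts),
                             p = rep(1 / 61, 61))
    expect_gt(gof$p.value, 0.01)
})

test_that("site classes are emitted as truth and follow the proportions", {
    sim <- simulateCodonAlignment(nCodons = 2000,
                                  omegaClasses = data.frame(
                                      omega = c(0.1, 1, 5),
                                      prop = c(0.6, 0.3, 0.1)),
                                  seed = 8)
    expect_length(sim$siteClasses, 2000)
    frac <- tabulate(sim$siteClasses, 3) / 2000
    expect_equal(frac, c(0.6, 0.3, 0.1), tolerance = 0.15)
})

test_that("qPCR simulator plants exact fold changes when noiseless", {
    fc <- matrix(c(1, 4), 1, 2, dimnames = list("g", c("c0", "c1")))
    sim <- simulateQpcrExperiment(genes = "g", samples = c("c0", "c1"),
                                  foldChanges = fc, efficiency = 2,
                                  ctNoiseSd = 0, seed = 1)
    ct <- sim$data
    dCt <- mean(ct$Ct[ct$gene == "g" & ct$sample == "c1"]) -
           mean(ct$Ct[ct$gene == "g" & ct$sample == "c0"])
    expect_equal(dCt, -2)       # log2(4)
    ## references constant across conditions
    refCt <- ct[ct$gene == "ref1", ]
    expect_equal(length(unique(round(refCt$Ct, 10))), 1L)
    ## noiseless normalized values are all equal within a condition
    em <- normalizeExpression(quantsFromCt(ct), "g", sim$references,
                              baseline = "c0")
    v <- exprValues(em)[1, sampleInfo(em)$sample == "c1"]
    expect_equal(unname(diff(range(v))), 0)
})

test_that("qPCR curve mode embeds the planted Ct values", {
    sim <- simulateQpcrExperiment(genes = "g", samples = "c0",
                                  nReplicates = 2, ctNoiseSd = 0,
                                  seed = 4, curves = TRUE)
    q <- quantifyCurves(sim$data)
    expect_equal(q$efficiency, rep(2, nrow(q)), tolerance = 0.02)
    expect_equal(q$Ct, sim$ct$Ct[match(q$well, sim$ct$well)],
                 tolerance = 0.2)
})

test_that("promoter simulator plants motifs the scanner closes the loop on", {
    planted <- data.frame(seq = 1L, motif = "PBE-box", position = 100L,
                          strand = "+", stringsAsFactors = FALSE)
    sim <- simulatePromoters(nSequences = 1, planted = planted, seed = 2)
    expect_equal(nchar(sim$sequences[[1]]), 2000L)
    hits <- scanMotifs(sim$sequences[[1]],
                       defaultMotifSet()[defaultMotifSet()$name == "PBE-box", ])
    expect_true(any(hits$start == 100 & hits$end == 106))
    ## background without the consensus letters yields zero hits
    bg <- simulatePromoters(nSequences = 1, length = 500,
                            background = c(A = 0.5, C = 0, G = 0, T = 0.5),
                            seed = 3)
    h0 <- scanMotifs(bg$sequences[[1]],
                     data.frame(name = "G-box", consensus = "CACGTG"))
    expect_equal(nrow(h0), 0L)
    ## out-of-bounds plant errors
    expect_error(simulatePromoters(nSequences = 1, length = 100,
                                   planted = data.frame(seq = 1,
                                                        motif = "CArG",
                                                        position = 95,
                                                        strand = "+")),
                 "out of bounds")
})
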