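## Bayes empirical Bayes identification of positively selected sites
## under the M2a site model (discrete prior grid over the mixture
## parameters, branch lengths and kappa fixed at their MLEs).

#' Bayes empirical Bayes posteriors for positively selected sites
#'
#' For an M2a fit, computes the per-site posterior probability of
#' membership in the positive-selection class (omega2 > 1), integrating
#' over parameter uncertainty with a discrete uniform prior grid: (p0, p1)
#' on the probability triangle, omega0 binned on (0, 1) and omega2 binned
#' on (1, omegaMax), each dimension with `nBins` bin midpoints. Branch
#' lengths, kappa and the codon frequencies are held at their maximum
#' likelihood estimates. Sites whose posterior reaches `threshold` are
#' flagged and reported with the corresponding residue of a named
#' reference sequence.
#'
#' @param aln the [CodonAlignment-class] the model was fitted to
#' @param tree the guide tree used for the fit (`NULL` for the 3-taxon
#'   star)
#' @param m2aFit a [SiteModelFit-class] with `model == "M2a"`
#' @param referenceId id of the sequence whose residues are reported
#' @param threshold posterior probability needed to flag a site
#'   (default 0.95)
#' @param nBins grid bins per prior dimension (default 10)
#' @param omegaMax upper end of the omega2 prior bins (default 11)
#' @param code a [GeneticCode-class]
#' @return data.frame with `siteIndex` (1-based codon position in the
#'   gap-deleted alignment), `referenceResidue`, `posteriorPositive`,
#'   `flagged`
#' @export
bebSitePosteriors <- function(aln, tree = NULL, m2aFit, referenceId,
                              threshold = 0.95, nBins = 10L,
                              omegaMax = 11,
                              code = standardGeneticCode()) {
    stopifnot(is(m2aFit, "SiteModelFit"))
    if (m2aFit@model != "M2a") stop("BEB requires an M2a fit")
    if (!referenceId %in% seqIds(aln))
        stop("reference id not in alignment: ", referenceId)
    if (is.null(tree)) tree <- starTree(seqIds(aln))
    info <- codonPairInfo(code)
    pat <- sitePatterns(aln, code)
    pi <- m2aFit@pi[info$sense]
    bl <- m2aFit@branchLengths
    kappa <- m2aFit@kappa

    ## generator scale fixed at the MLE mixture (branch lengths keep
    ## their fitted meaning across the prior grid)
    QsMLE <- lapply(m2aFit@omega, function(w) makeQ(kappa, w, pi, info))
    scale <- sum(m2aFit@prop *
                 vapply(QsMLE, meanRate, numeric(1), pi = pi))

    td <- treePruneData(tree, rownames(pat$states))
    patLik <- function(w) {
        eig <- eigQ(makeQ(kappa, w, pi, info) / scale, pi)
        prunePatternLikelihood(td, bl, eig, pi, pat$states)
    }
    mids <- (seq_len(nBins) - 0.5) / nBins
    w0Grid <- mids                       # (0, 1)
    w2Grid <- 1 + mids * (omegaMax - 1)  # (1, omegaMax)
    L0 <- vapply(w0Grid, patLik, numeric(ncol(pat$states)))
    L1 <- patLik(1)
    L2 <- vapply(w2Grid, patLik, numeric(ncol(pat$states)))
    L0 <- matrix(L0, ncol = nBins); L2 <- matrix(L2, ncol = nBins)

    ## uniform prior over the (p0, p1) triangle, sampled at grid midpoints
    pGrid <- expand.grid(p0 = mids, p1 = mids)
    pGrid <- pGrid[pGrid$p0 + pGrid$p1 <= 1, ]

    npat <- ncol(pat$states)
    logJoint <- numeric(0)
    postNum <- list()
    k <- 0L
    for (g in seq_len(nrow(pGrid))) {
        p0 <- pGrid$p0[g]; p1 <- pGrid$p1[g]; p2 <- 1 - p0 - p1
        for (i0 in seq_len(nBins)) for (i2 in seq_len(nBins)) {
            mix <- p0 * L0[, i0] + p1 * L1 + p2 * L2[, i2]
            mix <- pmax(mix, 1e-300)
            k <- k + 1L
            logJoint[k] <- sum(pat$weights * log(mix))
            postNum[[k]] <- p2 * L2[, i2] / mix
        }
    }
    wts <- exp(logJoint - max(logJoint))
    wts <- wts / sum(wts)
    postPat <- Reduce(`+`, Map(`*`, postNum, wts))
    post <- postPat[pat$siteToPattern]

    refAA <- strsplit(as.character(
        translateAlignment(aln, code)[[referenceId]]), "")[[1]]
    data.frame(siteIndex = seq_len(aln@nCodons),
               referenceResidue = refAA,
               posteriorPositive = post,
               flagged = post >= threshold)
}
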