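## Goldman-Yang codon substitution model, Felsenstein pruning likelihood,
## and ML fitting of the site models M0 / M1a / M2a.

.pairCache <- new.env(parent = emptyenv())

## directed single-nucleotide-change structure among sense codons,
## cached per genetic code
codonPairInfo <- function(code) {
    key <- code@name
    if (!is.null(.pairCache[[key]])) return(.pairCache[[key]])
    sense <- code@senseCodons
    n <- length(sense)
    chars <- do.call(rbind, strsplit(sense, ""))
    aa <- code@codonToAa[sense]
    ii <- integer(0); jj <- integer(0)
    ts <- logical(0); syn <- logical(0)
    transitions <- c(A = "G", G = "A", C = "T", T = "C")
    for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        d <- which(chars[i, ] != chars[j, ])
        if (length(d) != 1L) next
        ii <- c(ii, i); jj <- c(jj, j)
        ts <- c(ts, transitions[chars[i, d]] == chars[j, d])
        syn <- c(syn, aa[i] == aa[j])
    }
    info <- list(sense = sense, n = n, ii = ii, jj = jj,
                 isTransition = unname(ts), isSynonymous = syn)
    .pairCache[[key]] <- info
    info
}

#' F3x4 codon equilibrium frequencies
#'
#' Estimates equilibrium codon frequencies from the alignment's
#' position-specific nucleotide frequencies: the frequency of a codon is
#' the product of its three nucleotides' frequencies at codon positions
#' 1-3, with stop codons removed and the rest renormalized over the sense
#' codons. Zero frequencies for observed codons are floored at 1e-10 (with
#' a warning) so the likelihood stays finite.
#'
#' @param aln a [CodonAlignment-class]
#' @param code a [GeneticCode-class]
#' @return named numeric vector over the sense codons, summing to 1
#' @export
f3x4Frequencies <- function(aln, code = standardGeneticCode()) {
    chars <- as.character(aln@seqs)
    n <- nchar(chars[1])
    posFreq <- matrix(0, nrow = 4, ncol = 3, dimnames = list(NUC, NULL))
    for (p in 1:3) {
        sub <- unlist(lapply(chars, function(s)
            substring(s, seq(p, n, 3L), seq(p, n, 3L))))
        tab <- table(factor(sub, levels = NUC))
        posFreq[, p] <- as.numeric(tab) / sum(tab)
    }
    sense <- code@senseCodons
    sc <- do.call(rbind, strsplit(sense, ""))
    pi <- posFreq[sc[, 1], 1] * posFreq[sc[, 2], 2] * posFreq[sc[, 3], 3]
    names(pi) <- sense
    observed <- unique(as.vector(codonMatrix(aln)))
    zeroObs <- intersect(observed, sense[pi <= 0])
    if (length(zeroObs))
        warning("observed codon(s) with zero F3x4 frequency floored: ",
                paste(zeroObs, collapse = ", "))
    ## all frequencies floored: the reversible-generator machinery needs
    ## strictly positive equilibrium frequencies
    pi <- pmax(pi, 1e-10)
    pi / sum(pi)
}

## unscaled GY94 generator; meanRate = expected substitutions per codon
## per unit time under pi
makeQ <- function(kappa, omega, pi, info) {
    n <- info$n
    Q <- matrix(0, n, n, dimnames = list(info$sense, info$sense))
    rate <- pi[info$jj] *
        ifelse(info$isTransition, kappa, 1) *
        ifelse(info$isSynonymous, 1, omega)
    Q[cbind(info$ii, info$jj)] <- rate
    diag(Q) <- -rowSums(Q)
    Q
}

meanRate <- function(Q, pi) -sum(pi * diag(Q))

#' Goldman-Yang codon rate matrix
#'
#' Builds the 61 x 61 (for the standard code) reversible generator with
#' entries proportional to pi_j for synonymous transversions, kappa pi_j
#' for synonymous transitions, omega pi_j / omega kappa pi_j for the
#' non-synonymous counterparts, and zero for multi-nucleotide changes.
#' The matrix is scaled so the expected number of substitutions per unit
#' branch length equals 1.
#'
#' @param kappa transition/transversion rate ratio (> 0)
#' @param omega dN/dS ratio (>= 0)
#' @param pi equilibrium frequencies over the sense codons
#' @param code a [GeneticCode-class]
#' @return scaled generator matrix (rows sum to 0)
#' @export
codonRateMatrix <- function(kappa, omega, pi,
                            code = standardGeneticCode()) {
    stopifnot(kappa > 0, omega >= 0, abs(sum(pi) - 1) < 1e-6)
    info <- codonPairInfo(code)
    Q <- makeQ(kappa, omega, pi[info$sense], info)
    Q / meanRate(Q, pi[info$sense])
}

## eigendecomposition of a reversible Q in the pi-symmetrized basis;
## stable transition matrices for the 61-state chain
eigQ <- function(Q, pi) {
    sq <- sqrt(pi)
    B <- (sq * Q) %*% diag(1 / sq)           # rows scaled by sqrt(pi)
    B <- (B + t(B)) / 2                      # symmetrize roundoff
    e <- eigen(B, symmetric = TRUE)
    list(values = e$values, vectors = e$vectors, sq = sq)
}

probMatrix <- function(eig, t) {
    n <- length(eig$sq)
    W <- eig$vectors * rep(exp(eig$values * t), each = n)
    P <- W %*% t(eig$vectors)
    P <- (1 / eig$sq) * P * rep(eig$sq, each = n)
    P[P < 0] <- 0
    P / rowSums(P)
}

## collapse an alignment to unique codon site patterns
sitePatterns <- function(aln, code) {
    info <- codonPairInfo(code)
    idx <- match(codonMatrix(aln), info$sense)
    dim(idx) <- c(length(aln@seqs), aln@nCodons)
    rownames(idx) <- seqIds(aln)
    key <- apply(idx, 2L, paste, collapse = ",")
    u <- !duplicated(key)
    list(states = idx[, u, drop = FALSE],
         weights = as.numeric(table(key)[key[u]]),
         siteToPattern = match(key, key[u]))
}

## star tree over the given tip labels (the unrooted guide for 3 taxa)
starTree <- function(ids, branchLength = 0.1) {
    txt <- paste0("(", paste0(ids, ":", branchLength, collapse = ","), ");")
    ape::read.tree(text = txt)
}

## postorder traversal data computed once per (tree, alignment) pairing
treePruneData <- function(tree, tipNames) {
    edges <- ape::reorder.phylo(tree, "postorder")$edge
    list(tree = tree,
         ntip = length(tree$tip.label),
         edges = edges,
         blIndex = match(paste(edges[, 1], edges[, 2]),
                         paste(tree$edge[, 1], tree$edge[, 2])),
         tipOrder = match(tree$tip.label, tipNames))
}

## per-pattern likelihood under a single omega class, by pruning.
## states: tips x patterns matrix of codon state indices
prunePatternLikelihood <- function(td, bl, eig, pi, states) {
    ntip <- td$ntip
    edges <- td$edges
    blOrd <- bl[td$blIndex]
    partial <- vector("list", ntip + td$tree$Nnode)
    for (e in seq_len(nrow(edges))) {
        parent <- edges[e, 1]; child <- edges[e, 2]
        P <- probMatrix(eig, blOrd[e])
        contrib <- if (child <= ntip)
            P[, states[td$tipOrder[child], ], drop = FALSE]
        else P %*% partial[[child]]
        partial[[parent]] <- if (is.null(partial[[parent]])) contrib
                             else partial[[parent]] * contrib
    }
    as.numeric(pi %*% partial[[ntip + 1L]])
}

## per-class per-pattern likelihoods for a mixture model; Q of each class
## is divided by the common mixture scale so branch lengths are expected
## substitutions per codon averaged over classes
classPatternLikelihoods <- function(td, bl, kappa, pi, omegas, props,
                                    states, info, scale = NULL) {
    Qs <- lapply(omegas, function(w) makeQ(kappa, w, pi, info))
    if (is.null(scale))
        scale <- sum(props * vapply(Qs, meanRate, numeric(1), pi = pi))
    if (scale <= 0) scale <- 1e-12
    L <- vapply(Qs, function(Q) {
        eig <- eigQ(Q / scale, pi)
        prunePatternLikelihood(td, bl, eig, pi, states)
    }, numeric(ncol(states)))
    list(L = matrix(L, ncol = length(omegas)), scale = scale)
}

#' Log-likelihood of a codon alignment under a site model
#'
#' Per-site mixture likelihood over the omega classes, computed by
#' Felsenstein pruning with transition matrices exp(Q t) obtained by
#' eigendecomposition of the pi-symmetrized generator. Branch lengths are
#' expected substitutions per codon, with the class generators jointly
#' scaled by the mixture's mean rate.
#'
#' @param aln a [CodonAlignment-class]
#' @param tree an ape `phylo` whose tip labels match the alignment ids;
#'   `NULL` uses the unrooted star tree (the natural guide for 3 taxa)
#' @param params list with `kappa`, `pi` (named over sense codons),
#'   `branchLengths` (per edge of `tree`), `omega` (per class), `prop`
#'   (per class, summing to 1)
#' @param code a [GeneticCode-class]
#' @return the log-likelihood (numeric scalar)
#' @export
codonLogLikelihood <- function(aln, tree = NULL, params,
                               code = standardGeneticCode()) {
    if (is.null(tree)) tree <- starTree(seqIds(aln))
    if (!setequal(tree$tip.label, seqIds(aln)))
        stop("tree tip labels do not match alignment ids")
    info <- codonPairInfo(code)
    pat <- sitePatterns(aln, code)
    pi <- params$pi[info$sense]
    bl <- params$branchLengths
    if (length(bl) != nrow(tree$edge))
        stop("need one branch length per tree edge")
    td <- treePruneData(tree, rownames(pat$states))
    cl <- classPatternLikelihoods(td, bl, params$kappa, pi,
                                  params$omega, params$prop,
                                  pat$states, info)
    mix <- as.numeric(cl$L %*% params$prop)
    sum(pat$weights * log(pmax(mix, 1e-300)))
}

modelFreeParams <- function(model, nEdges) {
    # kappa + branch lengths + model-specific
    nEdges + 1L + c(M0 = 1L, M1a = 2L, M2a = 4L)[[model]]
}

## encode/decode optimizer vectors per model
modelParamSpec <- function(model, nEdges, blStart = rep(0.1, nEdges)) {
    blLower <- rep(1e-6, nEdges); blUpper <- rep(10, nEdges)
    base <- list(lower = c(0.1, blLower), upper = c(30, blUpper))
    blStart <- pmin(pmax(blStart, blLower), blUpper)
    spec <- switch(model,
        M0 = list(lower = c(base$lower, 1e-4),
                  upper = c(base$upper, 99),
                  start = c(2, blStart, 0.4)),
        M1a = list(lower = c(base$lower, 1e-6, 1e-4),
                   upper = c(base$upper, 1 - 1e-6, 1 - 1e-6),
                   start = c(2, blStart, 0.7, 0.2)),
        M2a = list(lower = c(base$lower, 1e-6, 1e-6, 1e-4, 1),
                   upper = c(base$upper, 1 - 1e-6, 1 - 1e-6, 1 - 1e-6, 99),
                   start = c(2, blStart, 0.7, 0.5, 0.2, 2)))
    spec$decode <- function(theta) {
        kappa <- theta[1]
        bl <- theta[2:(nEdges + 1)]
        rest <- theta[-seq_len(nEdges + 1)]
        switch(model,
            M0 = list(kappa = kappa, bl = bl,
                      omega = rest[1], prop = 1),
            M1a = list(kappa = kappa, bl = bl,
                       omega = c(rest[2], 1),
                       prop = c(rest[1], 1 - rest[1])),
            M2a = {
                p0 <- rest[1]; p1 <- (1 - p0) * rest[2]
                list(kappa = kappa, bl = bl,
                     omega = c(rest[3], 1, rest[4]),
                     prop = c(p0, p1, 1 - p0 - p1))
            })
    }
    spec
}

## map a previous fit onto a start vector for `model` (warm starts keep
## the nested-model lnl ordering in practice)
warmStart <- function(init, model, nEdges, spec) {
    if (is.null(init)) return(NULL)
    bl <- init@branchLengths
    if (length(bl) != nEdges) return(NULL)
    om <- init@omega; pr <- init@prop
    theta <- switch(model,
        M0 = c(init@kappa, bl, max(min(sum(pr * om), 99), 1e-4)),
        M1a = {
            w0 <- if (init@model == "M0") min(om[1], 0.9) else om[1]
            p0 <- if (init@model == "M0") 0.95 else pr[1]
            c(init@kappa, bl, p0, min(max(w0, 1e-4), 1 - 1e-6))
        },
        M2a = {
            if (init@model == "M1a") {
                p0 <- pr[1] * (1 - 1e-3)
                p1 <- pr[2] * (1 - 1e-3)
                c(init@kappa, bl, p0, p1 / max(1 - p0, 1e-6),
                  min(max(om[1], 1e-4), 1 - 1e-6), 1)
            } else c(init@kappa, bl, 0.7, 0.5,
                     min(max(om[1], 1e-4), 1 - 1e-6), 2)
        })
    pmin(pmax(theta, spec$lower), spec$upper)
}

#' Fit a codon site model by maximum likelihood
#'
#' Fits M0, M1a or M2a by bounded quasi-Newton (L-BFGS-B) optimization of
#' kappa, the branch lengths and the model's omega-class parameters, with
#' multiple random restarts. Equilibrium frequencies are F3x4 estimates
#' from the data (fixed during optimization, the usual empirical-frequency
#' convention). A previous fit of a nested model can be supplied as a warm
#' start, which both speeds convergence and preserves the nested
#' log-likelihood ordering M0 <= M1a <= M2a.
#'
#' @param aln a [CodonAlignment-class]
#' @param tree ape `phylo` guide tree; `NULL` uses the 3-taxon star
#' @param model `"M0"`, `"M1a"` or `"M2a"`
#' @param code a [GeneticCode-class]
#' @param nRestarts number of optimizer starts (first from the default or
#'   warm start, the rest randomly jittered under `seed`)
#' @param seed seed for the restart jitter (deterministic fits)
#' @param init optional `SiteModelFit` of a nested model used as warm start
#' @param factr L-BFGS-B convergence tolerance (relative lnl tolerance is
#'   roughly `factr * 1e-16`); loosen for large simulation studies where
#'   sub-1e-3 lnl precision is immaterial
#' @return a [SiteModelFit-class]
#' @export
fitSiteModel <- function(aln, tree = NULL,
                         model = c("M0", "M1a", "M2a"),
                         code = standardGeneticCode(),
                         nRestarts = 5L, seed = 1L, init = NULL,
                         factr = 5e7) {
    model <- match.arg(model)
    if (is.null(tree)) tree <- starTree(seqIds(aln))
    if (!setequal(tree$tip.label, seqIds(aln)))
        stop("tree tip labels do not match alignment ids")
    info <- codonPairInfo(code)
    pat <- sitePatterns(aln, code)
    pi <- f3x4Frequencies(aln, code)[info$sense]
    nEdges <- nrow(tree$edge)
    td <- treePruneData(tree, rownames(pat$states))
    ## data-driven starting branch lengths: mean pairwise nucleotide
    ## JC distance, split over two branches, in per-codon units
    blStart <- rep(0.1, nEdges)
    bl0 <- tryCatch({
        dm <- pairwiseDistanceMatrix(as.character(alignedSeqs(aln)),
                                     "jukes_cantor")
        max(3 * mean(dm[upper.tri(dm)]) / 2, 1e-3)
    }, error = function(e) 0.1)
    blStart <- rep(bl0, nEdges)
    spec <- modelParamSpec(model, nEdges, blStart)

    negLnl <- function(theta) {
        p <- spec$decode(theta)
        cl <- classPatternLikelihoods(td, p$bl, p$kappa, pi,
                                      p$omega, p$prop, pat$states, info)
        mix <- as.numeric(cl$L %*% p$prop)
        -sum(pat$weights * log(pmax(mix, 1e-300)))
    }

    starts <- list()
    ws <- warmStart(init, model, nEdges, spec)
    starts[[1]] <- if (!is.null(ws)) ws else spec$start
    if (nRestarts > 1L) {
        set.seed(seed)
        for (r in 2:nRestarts) {
            jit <- spec$start * exp(runif(length(spec$start), -0.7, 0.7))
            starts[[r]] <- pmin(pmax(jit, spec$lower), spec$upper)
        }
    }
    best <- NULL
    for (theta0 in starts) {
        fit <- tryCatch(
            optim(theta0, negLnl, method = "L-BFGS-B",
                  lower = spec$lower, upper = spec$upper,
                  control = list(factr = factr, maxit = 500,
                                 parscale = pmax(abs(theta0), 0.05))),
            error = function(e) NULL)
        if (is.null(fit)) next
        if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) stop("all optimizer starts failed")
    conv <- best$convergence == 0L
    if (!conv) warning("site-model optimizer did not converge (", model, ")")
    p <- spec$decode(best$par)
    new("SiteModelFit",
        model = model, kappa = p$kappa, pi = pi,
        branchLengths = p$bl, omega = p$omega, prop = p$prop,
        lnl = -best$value,
        nFreeParams = modelFreeParams(model, nEdges),
        converged = conv, nRestartsUsed = length(starts),
        tree = tree)
}

#' Chi-squared upper-tail probability
#'
#' Survival function of the chi-squared distribution, used to judge the
#' likelihood-ratio statistic 2 delta-lnl of nested site-model comparisons
#' (df 1 for M1a vs M0, df 2 for M2a vs M1a).
#'
#' @param x statistic value (>= 0)
#' @param df degrees of freedom
#' @return upper-tail probability
#' @export
chisqUpperTail <- function(x, df) {
    stopifnot(all(x >= 0), all(df >= 1))
    pchisq(x, df = df, lower.tail = FALSE)
}

#' Likelihood-ratio test of nested site models
#'
#' Computes 2 (lnl_alt - lnl_null) and its chi-squared upper-tail p-value.
#' Small negative statistics (optimizer noise on boundary fits) are
#' clamped to 0 with a warning.
#'
#' @param fitNull,fitAlt [SiteModelFit-class] objects, or bare numeric
#'   log-likelihoods
#' @param df degrees of freedom; inferred from the models' free-parameter
#'   counts when both arguments are fits
#' @return list with `delta`, `df`, `p_value`, `null_model`, `alt_model`
#' @examples
#' likelihoodRatioTest(-3471.89, -3469.56, df = 1)$delta  # 4.66
#' @export
likelihoodRatioTest <- function(fitNull, fitAlt, df = NULL) {
    lab <- function(f) if (is(f, "SiteModelFit")) f@model else "lnl"
    lnl <- function(f) if (is(f, "SiteModelFit")) f@lnl else as.numeric(f)
    if (is.null(df)) {
        if (!is(fitNull, "SiteModelFit") || !is(fitAlt, "SiteModelFit"))
            stop("df must be given when bare log-likelihoods are supplied")
        df <- fitAlt@nFreeParams - fitNull@nFreeParams
    }
    if (df < 1) stop("df must be >= 1")
    delta <- 2 * (lnl(fitAlt) - lnl(fitNull))
    if (delta < 0) {
        if (delta < -1e-2)
            warning("alternative model fit worse than null (2dl = ",
                    sprintf("%.4g", delta), "); clamped to 0")
        delta <- 0
    }
    list(delta = delta, df = df,
         p_value = chisqUpperTail(delta, df),
         null_model = lab(fitNull), alt_model = lab(fitAlt))
}
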