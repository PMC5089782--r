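## qPCR analysis: window-of-linearity efficiency and Ct from absolute
## fluorescence, two-reference normalization, fold changes versus a
## baseline, and a distribution-free permutation test.

#' Window-of-linearity quantification of one amplification curve
#'
#' Re-implementation of the window-of-linearity approach to absolute
#' fluorescence data: the baseline (mean of cycles 1-5) is subtracted, the
#' log10 of the positive corrected readings is taken, and the contiguous
#' 4-6-cycle window maximizing the r-squared of a linear fit is selected.
#' The amplification efficiency is E = 10^slope; the threshold is the
#' geometric midpoint of the window's fluorescence span; Ct is the
#' fractional cycle where the fitted line crosses the threshold; the
#' starting quantity is threshold / E^Ct. Efficiencies outside (1, 2.5]
#' are flagged, not errors. Ties between windows are broken toward higher
#' r-squared, then longer, then earlier windows.
#'
#' @param fluorescence per-cycle readings (cycle 1..C, C >= 10)
#' @param baselineCycles cycles averaged for the baseline (default 1:5)
#' @param windowSizes candidate window lengths (default 4:6)
#' @return list with `efficiency`, `Ct`, `threshold`, `quantity`,
#'   `window` (first and last cycle), `r_squared`, `flagged`
#' @export
windowOfLinearity <- function(fluorescence, baselineCycles = 1:5,
                              windowSizes = 4:6) {
    f <- as.numeric(fluorescence)
    if (length(f) < 10L) stop("curve needs at least 10 cycles")
    if (any(!is.finite(f))) stop("non-finite fluorescence readings")
    corrected <- f - mean(f[baselineCycles])
    pos <- which(corrected > 0)
    if (length(pos) < min(windowSizes)) stop("flat curve: no exponential phase")
    logf <- rep(NA_real_, length(f))
    logf[pos] <- log10(corrected[pos])
    best <- NULL
    for (len in sort(windowSizes, decreasing = TRUE)) {
        for (startCycle in seq_len(length(f) - len + 1L)) {
            win <- startCycle:(startCycle + len - 1L)
            if (!all(win %in% pos)) next
            fit <- lm(logf[win] ~ win)
            r2 <- summary(fit)$r.squared
            slope <- coef(fit)[2]
            if (!is.finite(slope) || slope <= 0) next
            if (is.null(best) || r2 > best$r2 + 1e-12) {
                best <- list(win = win, r2 = r2,
                             slope = slope, intercept = coef(fit)[1])
            }
        }
    }
    if (is.null(best)) stop("flat curve: no log-linear window found")
    E <- unname(10^best$slope)
    thr <- sqrt(corrected[best$win[1]] * corrected[best$win[length(best$win)]])
    Ct <- unname((log10(thr) - best$intercept) / best$slope)
    list(efficiency = E, Ct = Ct, threshold = thr,
         quantity = thr / E^Ct,
         window = c(first_cycle = best$win[1],
                    last_cycle = best$win[length(best$win)]),
         r_squared = best$r2,
         flagged = !(E > 1 && E <= 2.5))
}

#' Quantify a table of amplification curves
#'
#' Applies [windowOfLinearity()] per well of a long-format curve table.
#'
#' @param curves data.frame with columns `well`, `gene`, `sample`,
#'   `replicate`, `cycle`, `fluorescence`
#' @return data.frame with one row per well: `well`, `gene`, `sample`,
#'   `replicate`, `efficiency`, `Ct`, `quantity`, `flagged`
#' @export
quantifyCurves <- function(curves) {
    need <- c("well", "gene", "sample", "replicate", "cycle", "fluorescence")
    stopifnot(all(need %in% colnames(curves)))
    out <- lapply(split(curves, curves$well), function(w) {
        w <- w[order(w$cycle), ]
        q <- windowOfLinearity(w$fluorescence)
        data.frame(well = w$well[1], gene = w$gene[1], sample = w$sample[1],
                   replicate = w$replicate[1],
                   efficiency = q$efficiency, Ct = q$Ct,
                   quantity = q$quantity, flagged = q$flagged,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Quantities from a precomputed Ct table
#'
#' Converts (Ct, E) rows into starting quantities `threshold / E^Ct`
#' under a shared threshold (the normalization cancels the threshold when
#' all wells share one).
#'
#' @param ct data.frame with `gene`, `sample`, `replicate`, `Ct` and
#'   optionally `E` (default 2) and `well`
#' @param threshold common fluorescence threshold (default 1)
#' @return data.frame as from [quantifyCurves()]
#' @export
quantsFromCt <- function(ct, threshold = 1) {
    stopifnot(all(c("gene", "sample", "replicate", "Ct") %in% colnames(ct)))
    E <- if ("E" %in% colnames(ct)) ct$E else rep(2, nrow(ct))
    data.frame(well = if ("well" %in% colnames(ct)) ct$well
               else seq_len(nrow(ct)),
               gene = ct$gene, sample = ct$sample,
               replicate = ct$replicate,
               efficiency = E, Ct = ct$Ct,
               quantity = threshold / E^ct$Ct,
               flagged = !(E > 1 & E <= 2.5),
               stringsAsFactors = FALSE)
}

#' Normalize target quantities to two reference genes
#'
#' Per biological replicate of each sample, each target gene's quantity is
#' divided by the mean of the two constitutively expressed reference
#' genes' quantities (arithmetic mean by default, geometric optionally).
#' Technical replicates of a well (duplicate rows for the same gene,
#' sample and replicate) are first collapsed by geometric mean.
#'
#' @param quants data.frame from [quantifyCurves()] or [quantsFromCt()]
#' @param targets character vector of target gene names
#' @param references exactly two reference gene names
#' @param refMean `"arithmetic"` (default) or `"geometric"`
#' @param baseline optional sample label stored as the fold-change
#'   reference
#' @return an [ExpressionMatrix-class]
#' @export
normalizeExpression <- function(quants, targets, references,
                                refMean = c("arithmetic", "geometric"),
                                baseline = character()) {
    refMean <- match.arg(refMean)
    if (length(references) != 2L)
        stop("exactly two reference genes are required")
    ## collapse technical replicates: geometric mean of quantities
    key <- interaction(quants$gene, quants$sample, quants$replicate,
                       drop = TRUE)
    agg <- do.call(rbind, lapply(split(quants, key), function(d)
        data.frame(gene = d$gene[1], sample = d$sample[1],
                   replicate = d$replicate[1],
                   quantity = exp(mean(log(d$quantity))),
                   stringsAsFactors = FALSE)))
    wells <- unique(agg[, c("sample", "replicate")])
    wells <- wells[order(wells$sample, wells$replicate), ]
    cols <- paste(wells$sample, wells$replicate, sep = "_")
    vals <- matrix(NA_real_, nrow = length(targets), ncol = nrow(wells),
                   dimnames = list(targets, cols))
    for (k in seq_len(nrow(wells))) {
        sel <- agg$sample == wells$sample[k] &
               agg$replicate == wells$replicate[k]
        slice <- agg[sel, ]
        refQ <- slice$quantity[match(references, slice$gene)]
        if (any(is.na(refQ)))
            stop("missing reference gene '",
                 references[which(is.na(refQ))[1]],
                 "' in sample ", wells$sample[k],
                 " replicate ", wells$replicate[k])
        denom <- if (refMean == "arithmetic") mean(refQ)
                 else exp(mean(log(refQ)))
        tq <- slice$quantity[match(targets, slice$gene)]
        if (any(is.na(tq)))
            stop("missing target gene '", targets[which(is.na(tq))[1]],
                 "' in sample ", wells$sample[k],
                 " replicate ", wells$replicate[k])
        vals[, k] <- tq / denom
    }
    new("ExpressionMatrix", values = vals,
        sampleInfo = data.frame(column = cols, sample = wells$sample,
                                replicate = wells$replicate,
                                stringsAsFactors = FALSE),
        baseline = as.character(baseline))
}

#' Fold-change matrix relative to a baseline sample
#'
#' Collapses replicates to per-sample means and divides each gene's
#' values by its baseline mean, so the baseline column is identically 1.
#'
#' @param em an [ExpressionMatrix-class]
#' @param baseline sample label of the reference condition (defaults to
#'   the one stored in `em`)
#' @return matrix genes x samples of fold changes
#' @export
foldChangeMatrix <- function(em, baseline = NULL) {
    if (is.null(baseline)) {
        if (!length(em@baseline)) stop("no baseline sample given")
        baseline <- em@baseline
    }
    groups <- unique(em@sampleInfo$sample)
    if (!baseline %in% groups)
        stop("baseline sample not present: ", baseline)
    means <- vapply(groups, function(g)
        rowMeans(em@values[, em@sampleInfo$sample == g, drop = FALSE]),
        numeric(nrow(em@values)))
    means <- matrix(means, nrow = nrow(em@values),
                    dimnames = list(rownames(em@values), groups))
    base <- means[, baseline]
    if (any(base == 0)) stop("zero baseline expression")
    means / base
}

#' Distribution-free permutation test on two groups
#'
#' Two-sided test of a difference in group means with the statistic
#' |mean(a) - mean(b)|. When the number of distinct label reassignments
#' choose(nA + nB, nA) is at most `maxExhaustive`, all are enumerated and
#' the p-value is deterministic; otherwise `nPermutations` Monte Carlo
#' reassignments are drawn under `seed`. The add-one correction
#' p = (#\{stat* >= stat\} + 1) / (m + 1) keeps the test valid.
#'
#' @param groupA,groupB numeric vectors (>= 2 values each)
#' @param nPermutations Monte Carlo sample size (default 10000)
#' @param seed RNG seed for the Monte Carlo branch
#' @param maxExhaustive enumeration cutoff (default 20000)
#' @return list with `statistic`, `p_value`, `n_permutations`,
#'   `exhaustive`, `seed`
#' @export
permutationTest <- function(groupA, groupB, nPermutations = 10000L,
                            seed = 1L, maxExhaustive = 20000L) {
    a <- as.numeric(groupA); b <- as.numeric(groupB)
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 values")
    pooled <- c(a, b)
    nA <- length(a); n <- length(pooled)
    obs <- abs(mean(a) - mean(b))
    nTotal <- choose(n, nA)
    if (nTotal <= maxExhaustive) {
        idx <- combn(n, nA)
        sumAll <- sum(pooled)
        statAt <- function(ix) {
            ma <- sum(pooled[ix]) / nA
            mb <- (sumAll - sum(pooled[ix])) / (n - nA)
            abs(ma - mb)
        }
        stats <- apply(idx, 2L, statAt)
        m <- length(stats)
        count <- sum(stats >= obs - 1e-12)
        exhaustive <- TRUE
    } else {
        set.seed(seed)
        stats <- replicate(nPermutations, {
            ix <- sample.int(n, nA)
            abs(mean(pooled[ix]) - mean(pooled[-ix]))
        })
        m <- nPermutations
        count <- sum(stats >= obs - 1e-12)
        exhaustive <- FALSE
    }
    list(statistic = obs, p_value = (count + 1) / (m + 1),
         n_permutations = m, exhaustive = exhaustive, seed = seed)
}
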