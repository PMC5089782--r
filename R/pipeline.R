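## Orchestration: the full selection analysis (distances -> clock -> Nc ->
## site models -> LRT -> BEB) and the expression analysis (quantify ->
## normalize -> fold change -> permutation tests), with JSON reports.

configHash <- function(cfg) {
    # stable content hash without extra dependencies
    tf <- tempfile()
    on.exit(unlink(tf))
    saveRDS(cfg[order(names(cfg))], tf)
    unname(tools::md5sum(tf))
}

#' Run the selection analysis pipeline on one or more codon alignments
#'
#' For each input alignment: pairwise NG86 distances and their summary,
#' molecular-clock divergence times per pair, Nc per sequence, ML fits of
#' M0, M1a and M2a (warm-started along the nesting chain), the LRTs M1a vs
#' M0 (df 1) and M2a vs M1a (df 2), and - when M2a rejects M1a at the
#' configured level - BEB site posteriors. Per-gene failures are isolated
#' and reported; the run is deterministic given the seeds in the config.
#'
#' @param config list (or path to a YAML file) with elements:
#'   `alignments` (named list of CDS FASTA paths, or of `CodonAlignment`
#'   objects), optional `tree` (newick path), `rateK` (default 4.38e-9),
#'   `bebThreshold` (default 0.95), `alpha` (LRT level for triggering BEB,
#'   default 0.05), `seed` (default 1), `nRestarts` (default 5),
#'   `referenceId` (default the first sequence of each alignment),
#'   `outDir` (optional; JSON report written there)
#' @return the report, an (invisibly JSON-serializable) named list
#' @export
runSelectionPipeline <- function(config) {
    cfg <- normalizeConfig(config)
    rateK <- cfg$rateK %||% 4.38e-9
    seed <- cfg$seed %||% 1L
    nRestarts <- cfg$nRestarts %||% 5L
    alpha <- cfg$alpha %||% 0.05
    bebThreshold <- cfg$bebThreshold %||% 0.95
    tree <- if (!is.null(cfg$tree)) readNewick(cfg$tree) else NULL
    report <- list(tool = "paralogEvol",
                   version = as.character(utils::packageVersion("paralogEvol")),
                   seed = seed, rateK = rateK,
                   configHash = configHash(cfg), genes = list())
    failures <- 0L
    for (gene in names(cfg$alignments)) {
        res <- tryCatch({
            aln <- cfg$alignments[[gene]]
            if (is.character(aln))
                aln <- codonAlignment(readFasta(aln))
            ds <- distanceSummary(aln)
            clock <- lapply(seq_len(nrow(ds$pairs)), function(i) {
                ct <- divergenceTime(ds$pairs$dS[i], rateK)
                list(pair = c(ds$pairs$idA[i], ds$pairs$idB[i]),
                     dS = ds$pairs$dS[i], T_MY = ct$T_MY)
            })
            nc <- lapply(seqIds(aln), function(id)
                effectiveNumberOfCodons(
                    alignedSeqs(aln)[[id]])$Nc)
            names(nc) <- seqIds(aln)
            m0 <- fitSiteModel(aln, tree, "M0",
                               nRestarts = nRestarts, seed = seed)
            m1a <- fitSiteModel(aln, tree, "M1a",
                                nRestarts = nRestarts, seed = seed,
                                init = m0)
            m2a <- fitSiteModel(aln, tree, "M2a",
                                nRestarts = nRestarts, seed = seed,
                                init = m1a)
            lrt10 <- likelihoodRatioTest(m0, m1a)
            lrt21 <- likelihoodRatioTest(m1a, m2a)
            beb <- NULL
            if (lrt21$p_value < alpha) {
                refId <- cfg$referenceId %||% seqIds(aln)[1]
                bb <- bebSitePosteriors(aln, tree, m2a, refId,
                                        threshold = bebThreshold)
                beb <- bb[bb$flagged, , drop = FALSE]
            }
            fitOut <- function(f) list(
                omega = f@omega, prop = f@prop, kappa = f@kappa,
                lnl = f@lnl, converged = f@converged)
            list(n_codons = nCodons(aln),
                 distance_summary = as.list(ds$summary),
                 clock = clock, Nc = nc,
                 fits = list(M0 = fitOut(m0), M1a = fitOut(m1a),
                             M2a = fitOut(m2a)),
                 LRT = list(M1a_vs_M0 = lrt10, M2a_vs_M1a = lrt21),
                 positive_selection = lrt21$p_value < alpha,
                 beb_flagged = beb)
        }, error = function(e) {
            failures <<- failures + 1L
            list(error = conditionMessage(e))
        })
        report$genes[[gene]] <- res
    }
    report$n_failures <- failures
    report$all_failed <- failures == length(cfg$alignments)
    maybeWriteReport(report, cfg, "selection_report.json")
    report
}

#' Run the expression analysis pipeline
#'
#' Quantifies curves (or converts a Ct table), normalizes targets to the
#' two reference genes, computes fold changes against the baseline sample,
#' and permutation-tests each gene in each non-baseline sample against the
#' baseline. Raw p-values are reported (matching per-comparison testing at
#' P < 0.05); Benjamini-Hochberg adjusted values are added alongside.
#'
#' @param config list (or YAML path) with: `curves` (curve data.frame or
#'   TSV path) or `ct` (Ct table or TSV path), `targets`, `references`
#'   (two genes), `baseline` sample label, optional `refMean`, `alpha`
#'   (default 0.05), `seed`, `nPermutations`, `outDir`
#' @return report list with the normalized matrix, fold changes and test
#'   results
#' @export
runExpressionPipeline <- function(config) {
    cfg <- normalizeConfig(config)
    seed <- cfg$seed %||% 1L
    alpha <- cfg$alpha %||% 0.05
    nPerm <- cfg$nPermutations %||% 10000L
    readTab <- function(x) if (is.character(x))
        utils::read.table(x, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE) else x
    quants <- if (!is.null(cfg$curves)) quantifyCurves(readTab(cfg$curves))
              else if (!is.null(cfg$ct)) quantsFromCt(readTab(cfg$ct))
              else stop("config needs 'curves' or 'ct'")
    em <- normalizeExpression(quants, cfg$targets, cfg$references,
                              refMean = cfg$refMean %||% "arithmetic",
                              baseline = cfg$baseline)
    fc <- foldChangeMatrix(em)
    groups <- setdiff(unique(em@sampleInfo$sample), cfg$baseline)
    tests <- list()
    for (g in rownames(em@values)) for (s in groups) {
        a <- em@values[g, em@sampleInfo$sample == cfg$baseline]
        b <- em@values[g, em@sampleInfo$sample == s]
        pt <- permutationTest(a, b, nPermutations = nPerm, seed = seed)
        tests[[length(tests) + 1L]] <- data.frame(
            gene = g, sample = s, baseline = cfg$baseline,
            fold_change = fc[g, s], statistic = pt$statistic,
            p_value = pt$p_value, exhaustive = pt$exhaustive,
            stringsAsFactors = FALSE)
    }
    tests <- do.call(rbind, tests)
    tests$p_adj_BH <- stats::p.adjust(tests$p_value, method = "BH")
    tests$significant <- tests$p_value < alpha
    report <- list(tool = "paralogEvol",
                   version = as.character(utils::packageVersion("paralogEvol")),
                   seed = seed, configHash = configHash(cfg),
                   normalized = em@values, sample_info = em@sampleInfo,
                   fold_change = fc, tests = tests)
    maybeWriteReport(report, cfg, "expression_report.json")
    report
}

normalizeConfig <- function(config) {
    if (is.character(config) && length(config) == 1L &&
        file.exists(config))
        config <- yaml::read_yaml(config)
    if (!is.list(config)) stop("config must be a list or a YAML file path")
    config
}

maybeWriteReport <- function(report, cfg, fileName) {
    if (is.null(cfg$outDir)) return(invisible(NULL))
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(report, file.path(cfg$outDir, fileName),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
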