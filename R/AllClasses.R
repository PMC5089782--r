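#' @import methods
#' @importFrom stats optim pchisq rnorm runif sd setNames lm coef rbinom
#' @importFrom utils combn write.table head
#' @importClassesFrom Biostrings DNAStringSet
NULL

setOldClass("phylo")

#' Genetic code table
#'
#' Holds the 64-codon to amino-acid map, the ordered list of sense codons,
#' and the synonymous-family (degeneracy) structure used by the
#' Nei-Gojobori site counts and the effective-number-of-codons statistic.
#' Under the standard code there are 61 sense codons and 3 stops, and the
#' degenerate families partition into 2 one-fold, 9 two-fold, 1 three-fold,
#' 5 four-fold and 3 six-fold amino acids.
#'
#' @slot name code name, e.g. "standard"
#' @slot codonToAa named character of length 64, codon -> one-letter amino
#'   acid, with `"*"` marking stops
#' @slot senseCodons the 61 (for the standard code) non-stop codons, in a
#'   fixed order used for codon model state indexing
#' @slot degeneracyFamilies named integer, amino acid -> number of
#'   synonymous codons
#' @exportClass GeneticCode
setClass("GeneticCode", slots = c(
    name = "character",
    codonToAa = "character",
    senseCodons = "character",
    degeneracyFamilies = "integer"
))

setValidity("GeneticCode", function(object) {
    msg <- character()
    if (length(object@codonToAa) != 64L)
        msg <- c(msg, "codonToAa must map exactly 64 codons")
    if (any(nchar(names(object@codonToAa)) != 3L))
        msg <- c(msg, "codon names must be trinucleotides")
    stops <- names(object@codonToAa)[object@codonToAa == "*"]
    if (!setequal(object@senseCodons,
                  setdiff(names(object@codonToAa), stops)))
        msg <- c(msg, "senseCodons must be the non-stop codons")
    fam <- table(object@codonToAa[object@senseCodons])
    if (!all(object@degeneracyFamilies[names(fam)] == as.integer(fam)))
        msg <- c(msg, "degeneracyFamilies inconsistent with codonToAa")
    if (length(msg)) msg else TRUE
})

#' The standard genetic code
#'
#' Builds a [GeneticCode-class] object from the standard nuclear code.
#' The code table is injectable throughout the package so that toy codes
#' can be used in tests.
#'
#' @return a `GeneticCode` object
#' @examples
#' gc <- standardGeneticCode()
#' length(senseCodons(gc))  # 61
#' @export
standardGeneticCode <- function() {
    tab <- Biostrings::GENETIC_CODE
    sense <- names(tab)[tab != "*"]
    fam <- table(tab[sense])
    new("GeneticCode",
        name = "standard",
        codonToAa = setNames(as.character(tab), names(tab)),
        senseCodons = sense,
        degeneracyFamilies = setNames(as.integer(fam), names(fam)))
}

#' @rdname GeneticCode-class
#' @param x a `GeneticCode`
#' @export
senseCodons <- function(x) x@senseCodons

#' Translate a single codon
#' @param codon trinucleotide string
#' @param code a [GeneticCode-class]
#' @return one-letter amino acid, `"*"` for stops
#' @export
codonToAa <- function(codon, code = standardGeneticCode()) {
    aa <- code@codonToAa[codon]
    if (any(is.na(aa)))
        stop("unknown codon(s): ", paste(codon[is.na(aa)], collapse = ", "))
    unname(aa)
}

setMethod("show", "GeneticCode", function(object) {
    cat("GeneticCode '", object@name, "': ",
        length(object@senseCodons), " sense codons, ",
        sum(object@codonToAa == "*"), " stops\n", sep = "")
})

#' In-frame codon alignment
#'
#' An alignment of coding sequences restricted to codon columns that are
#' fully resolved in every sequence: codon columns containing a gap, an
#' ambiguous base, or a stop codon in any sequence are deleted whole
#' (complete deletion at codon granularity), so downstream site counting
#' operates on a clean in-frame matrix. This mirrors deleting alignment
#' gaps before estimating dN and dS while preserving the reading frame.
#'
#' @slot seqs a [Biostrings::DNAStringSet] of equal-width gap-free
#'   sequences whose width is a multiple of 3
#' @slot nCodons number of retained codon columns
#' @slot gapPolicy always `"complete_deletion"`
#' @seealso [codonAlignment()]
#' @exportClass CodonAlignment
setClass("CodonAlignment", slots = c(
    seqs = "DNAStringSet",
    nCodons = "integer",
    gapPolicy = "character"
))

setValidity("CodonAlignment", function(object) {
    msg <- character()
    w <- Biostrings::width(object@seqs)
    if (length(object@seqs) < 2L)
        msg <- c(msg, "alignment needs at least 2 sequences")
    if (length(unique(w)) > 1L)
        msg <- c(msg, "sequences must have equal length")
    if (w[1] %% 3L != 0L)
        msg <- c(msg, "alignment length must be a multiple of 3")
    if (w[1] != 3L * object@nCodons)
        msg <- c(msg, "nCodons inconsistent with sequence width")
    if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
        msg <- c(msg, "sequences must carry unique ids")
    freq <- Biostrings::alphabetFrequency(object@seqs, collapse = TRUE)
    bad <- sum(freq[setdiff(names(freq), c("A", "C", "G", "T"))])
    if (bad > 0)
        msg <- c(msg, "alignment must contain only A/C/G/T after construction")
    if (length(msg)) msg else TRUE
})

#' @describeIn CodonAlignment-class number of retained codon columns
#' @param x,object a `CodonAlignment`
#' @export
nCodons <- function(x) x@nCodons

#' @describeIn CodonAlignment-class sequence identifiers
#' @export
seqIds <- function(x) names(x@seqs)

#' @describeIn CodonAlignment-class the aligned sequences as a
#'   `DNAStringSet`
#' @export
alignedSeqs <- function(x) x@seqs

setMethod("show", "CodonAlignment", function(object) {
    cat("CodonAlignment: ", length(object@seqs), " sequences x ",
        object@nCodons, " codons (", object@gapPolicy, ")\n", sep = "")
    cat("  ids: ", paste(head(seqIds(object), 6), collapse = ", "),
        if (length(object@seqs) > 6) ", ..." else "", "\n", sep = "")
})

#' Maximum-likelihood fit of a codon site model
#'
#' The result of fitting one of the site models M0 (single dN/dS ratio),
#' M1a (nearly neutral: a purifying class with 0 <= omega0 < 1 plus a
#' neutral class with omega1 = 1) or M2a (positive selection: M1a plus a
#' third class with omega2 >= 1) by maximum likelihood under the
#' Goldman-Yang codon substitution model.
#'
#' @slot model `"M0"`, `"M1a"` or `"M2a"`
#' @slot kappa estimated transition/transversion rate ratio
#' @slot pi equilibrium frequencies over the sense codons (F3x4 by default)
#' @slot branchLengths expected substitutions per codon per branch, ordered
#'   as the edges of `tree`
#' @slot omega per-class dN/dS values
#' @slot prop per-class proportions (sum to 1)
#' @slot lnl maximised log-likelihood
#' @slot nFreeParams number of free parameters
#' @slot converged optimizer convergence flag
#' @slot nRestartsUsed number of optimizer starts actually run
#' @slot tree the guide tree (ape `phylo`)
#' @seealso [fitSiteModel()]
#' @exportClass SiteModelFit
setClass("SiteModelFit", slots = c(
    model = "character",
    kappa = "numeric",
    pi = "numeric",
    branchLengths = "numeric",
    omega = "numeric",
    prop = "numeric",
    lnl = "numeric",
    nFreeParams = "integer",
    converged = "logical",
    nRestartsUsed = "integer",
    tree = "ANY"
))

setValidity("SiteModelFit", function(object) {
    msg <- character()
    if (!object@model %in% c("M0", "M1a", "M2a"))
        msg <- c(msg, "model must be M0, M1a or M2a")
    if (abs(sum(object@prop) - 1) > 1e-8)
        msg <- c(msg, "class proportions must sum to 1")
    if (length(object@omega) != length(object@prop))
        msg <- c(msg, "omega and prop must have the same length")
    nclass <- c(M0 = 1L, M1a = 2L, M2a = 3L)[object@model]
    if (length(object@omega) != nclass)
        msg <- c(msg, sprintf("%s must have %d omega class(es)",
                              object@model, nclass))
    if (object@model %in% c("M1a", "M2a") &&
        abs(object@omega[2] - 1) > 1e-12)
        msg <- c(msg, "omega1 must be fixed at 1")
    if (object@model == "M2a" && object@omega[3] < 1)
        msg <- c(msg, "omega2 must be >= 1")
    if (!is.finite(object@lnl))
        msg <- c(msg, "lnl must be finite")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SiteModelFit", function(object) {
    cat("SiteModelFit [", object@model, "]  lnl = ",
        sprintf("%.4f", object@lnl),
        if (!object@converged) "  (NOT converged)" else "", "\n", sep = "")
    cat("  kappa = ", sprintf("%.3f", object@kappa), "\n", sep = "")
    for (k in seq_along(object@omega))
        cat(sprintf("  class %d: omega = %.4f, p = %.4f\n",
                    k, object@omega[k], object@prop[k]))
})

#' Normalized expression matrix
#'
#' Genes x (sample, replicate) matrix of reference-normalized expression
#' values, carrying the sample grouping needed for fold-change and
#' permutation statistics.
#'
#' @slot values numeric matrix, rows = genes, columns = individual
#'   biological replicates
#' @slot sampleInfo data.frame with one row per column of `values`:
#'   `column`, `sample` (condition/time-point label), `replicate`
#' @slot baseline optional sample label used as fold-change reference
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", slots = c(
    values = "matrix",
    sampleInfo = "data.frame",
    baseline = "character"
))

setValidity("ExpressionMatrix", function(object) {
    msg <- character()
    if (ncol(object@values) != nrow(object@sampleInfo))
        msg <- c(msg, "sampleInfo must describe every column")
    if (any(object@values <= 0))
        msg <- c(msg, "normalized expression values must be positive")
    if (length(object@baseline) == 1L &&
        !object@baseline %in% object@sampleInfo$sample)
        msg <- c(msg, "baseline sample not present")
    if (length(msg)) msg else TRUE
})

#' @describeIn ExpressionMatrix-class the numeric matrix of values
#' @param x a `ExpressionMatrix`
#' @export
exprValues <- function(x) x@values

#' @describeIn ExpressionMatrix-class per-column sample metadata
#' @export
sampleInfo <- function(x) x@sampleInfo

setMethod("show", "ExpressionMatrix", function(object) {
    cat("ExpressionMatrix: ", nrow(object@values), " genes x ",
        ncol(object@values), " wells (",
        length(unique(object@sampleInfo$sample)), " samples)\n", sep = "")
    if (length(object@baseline))
        cat("  baseline: ", object@baseline, "\n", sep = "")
})
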