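## Distance-based trees: p-distance / Jukes-Cantor matrices with pairwise
## deletion, neighbor-joining (Saitou-Nei, via ape), bootstrap support
## and newick I/O.

#' Pairwise nucleotide distance matrix
#'
#' p-distance or Jukes-Cantor distances between aligned sequences, with
#' pairwise deletion of positions where either sequence has a gap or an
#' ambiguous base. (Promoter alignments are gappy, so pairwise deletion is
#' used here; the codon module keeps complete deletion.)
#'
#' @param seqs aligned sequences: `DNAStringSet` or named character vector
#'   of equal lengths
#' @param model `"p_distance"` or `"jukes_cantor"`
#' @return symmetric matrix with zero diagonal, dimnames = sequence ids
#' @export
pairwiseDistanceMatrix <- function(seqs,
                                   model = c("p_distance", "jukes_cantor")) {
    model <- match.arg(model)
    chars <- if (is.character(seqs)) toupper(seqs)
             else toupper(setNames(as.character(seqs), names(seqs)))
    if (is.null(names(chars)) || anyDuplicated(names(chars)))
        stop("sequences must carry unique ids")
    if (length(unique(nchar(chars))) > 1L)
        stop("aligned sequences must have equal length")
    n <- length(chars)
    mat <- do.call(rbind, strsplit(chars, ""))
    ok <- matrix(mat %in% c("A", "C", "G", "T"), nrow = n)
    d <- matrix(0, n, n, dimnames = list(names(chars), names(chars)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        comp <- ok[i, ] & ok[j, ]
        if (!any(comp))
            stop("no comparable sites for pair ",
                 names(chars)[i], "-", names(chars)[j])
        p <- sum(mat[i, comp] != mat[j, comp]) / sum(comp)
        v <- if (model == "p_distance") p else {
            if (p >= 0.75)
                stop("Jukes-Cantor distance saturated for pair ",
                     names(chars)[i], "-", names(chars)[j])
            jukesCantor(p)
        }
        d[i, j] <- d[j, i] <- v
    }
    d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix (via [ape::nj()]);
#' negative branch-length estimates are clamped to 0 (recorded in the
#' `clamped` attribute).
#'
#' @param dm symmetric distance matrix with labeled rows/columns
#' @return an unrooted ape `phylo`
#' @export
njTree <- function(dm) {
    if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 taxa")
    if (any(abs(dm - t(dm)) > 1e-12) || any(diag(dm) != 0))
        stop("distance matrix must be symmetric with zero diagonal")
    tree <- ape::nj(as.dist(dm))
    clamped <- sum(tree$edge.length < 0)
    tree$edge.length[tree$edge.length < 0] <- 0
    attr(tree, "clamped") <- clamped
    tree
}

#' Bootstrap support for the neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and annotates each internal edge of the full-data tree with
#' the percentage of replicates containing the same bipartition.
#'
#' @param seqs aligned sequences (as for [pairwiseDistanceMatrix()])
#' @param model distance model
#' @param nReplicates number of bootstrap replicates (default 100)
#' @param seed RNG seed (results are reproducible under a fixed seed)
#' @return the full-data `phylo` with `node.label` set to supports in
#'   \[0, 100\]
#' @export
bootstrapSupport <- function(seqs, model = c("p_distance", "jukes_cantor"),
                             nReplicates = 100L, seed = 1L) {
    model <- match.arg(model)
    stopifnot(nReplicates >= 1L)
    chars <- if (is.character(seqs)) toupper(seqs)
             else toupper(setNames(as.character(seqs), names(seqs)))
    len <- nchar(chars[1])
    full <- njTree(pairwiseDistanceMatrix(chars, model))
    set.seed(seed)
    reps <- vector("list", nReplicates)
    for (r in seq_len(nReplicates)) {
        cols <- sample.int(len, len, replace = TRUE)
        resampled <- vapply(strsplit(chars, ""), function(v)
            paste(v[cols], collapse = ""), character(1))
        names(resampled) <- names(chars)
        reps[[r]] <- tryCatch(
            njTree(pairwiseDistanceMatrix(resampled, model)),
            error = function(e) NULL)
    }
    reps <- Filter(Negate(is.null), reps)
    counts <- ape::prop.clades(full, reps, rooted = FALSE)
    counts[is.na(counts)] <- 0
    support <- round(100 * counts / nReplicates)
    full$node.label <- as.character(support)
    full
}

#' Newick I/O
#'
#' Round-trip-safe wrappers over [ape::read.tree()] / [ape::write.tree()];
#' bootstrap supports travel as internal node labels.
#'
#' @param x newick text or a file path for `readNewick`; a `phylo` for
#'   `writeNewick`
#' @param path optional output file for `writeNewick` (otherwise the
#'   newick string is returned)
#' @return `readNewick`: a `phylo`; `writeNewick`: newick text (invisibly
#'   if written to a file)
#' @export
readNewick <- function(x) {
    tree <- tryCatch(suppressWarnings(
        if (file.exists(x) && !grepl("\\(", x)) ape::read.tree(x)
        else ape::read.tree(text = x)),
        error = function(e) NULL)
    if (is.null(tree)) stop("malformed newick: ", substr(x, 1, 60))
    tree
}

#' @rdname readNewick
#' @export
writeNewick <- function(x, path = NULL) {
    txt <- ape::write.tree(x)
    if (!is.null(path)) {
        writeLines(txt, path)
        return(invisible(txt))
    }
    txt
}
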