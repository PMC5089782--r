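## Ground-truth generators: codon alignments evolved under omega-class
## mixtures of the Goldman-Yang model, qPCR experiments with planted fold
## changes, and promoter sequences with planted IUPAC motifs. All
## generators are deterministic under a fixed seed and always emit the
## truth alongside the data.

#' Simulate a codon alignment under a site-class omega mixture
#'
#' Each codon site is assigned an omega class by the mixture proportions;
#' the root codon is drawn from pi and evolved along the tree's branches
#' by sampling from the exact transition matrices exp(Q(omega_class) t),
#' with the class generators jointly scaled by the mixture mean rate (the
#' same convention the likelihood uses, so branch lengths are expected
#' substitutions per codon). The hidden per-site class labels are returned
#' for recovery tests.
#'
#' @param tree ape `phylo` with branch lengths, or `NULL` with `tipIds`
#'   and `branchLength` for a star tree
#' @param nCodons number of codon sites
#' @param kappa transition/transversion rate ratio
#' @param omegaClasses data.frame with `omega` and `prop` columns (one row
#'   per site class, proportions summing to 1)
#' @param pi equilibrium codon frequencies; `NULL` for uniform over the
#'   sense codons
#' @param seed RNG seed
#' @param tipIds tip labels for the default star tree
#' @param branchLength branch length of the default star tree
#' @param code a [GeneticCode-class]
#' @return list with `alignment` (a [CodonAlignment-class]) and
#'   `siteClasses` (integer class index per codon site)
#' @export
simulateCodonAlignment <- function(tree = NULL, nCodons = 500L, kappa = 2,
                                   omegaClasses = data.frame(omega = 0.3,
                                                             prop = 1),
                                   pi = NULL, seed = 1L,
                                   tipIds = c("sp1", "sp2", "sp3"),
                                   branchLength = 0.05,
                                   code = standardGeneticCode()) {
    stopifnot(nCodons >= 1L,
              abs(sum(omegaClasses$prop) - 1) < 1e-8)
    if (is.null(tree)) tree <- starTree(tipIds, branchLength)
    info <- codonPairInfo(code)
    if (is.null(pi)) pi <- rep(1 / info$n, info$n)
    pi <- pi / sum(pi)
    set.seed(seed)
    classes <- sample.int(nrow(omegaClasses), nCodons, replace = TRUE,
                          prob = omegaClasses$prop)
    Qs <- lapply(omegaClasses$omega, function(w) makeQ(kappa, w, pi, info))
    scale <- sum(omegaClasses$prop *
                 vapply(Qs, meanRate, numeric(1), pi = pi))
    if (scale <= 0) scale <- 1e-12
    eigs <- lapply(Qs, function(Q) eigQ(Q / scale, pi))
    ntip <- length(tree$tip.label)
    edges <- tree$edge
    ord <- rev(ape::postorder(tree))          # root-to-tip edge order
    states <- matrix(NA_integer_, nrow = ntip + tree$Nnode, ncol = nCodons)
    states[ntip + 1L, ] <- sample.int(info$n, nCodons, replace = TRUE,
                                      prob = pi)
    for (e in ord) {
        parent <- edges[e, 1]; child <- edges[e, 2]
        t <- tree$edge.length[e]
        for (cl in unique(classes)) {
            sites <- which(classes == cl)
            P <- probMatrix(eigs[[cl]], t)
            par <- states[parent, sites]
            states[child, sites] <- vapply(par, function(x)
                sample.int(info$n, 1L, prob = P[x, ]), integer(1))
        }
    }
    seqs <- vapply(seq_len(ntip), function(i)
        paste(info$sense[states[i, ]], collapse = ""), character(1))
    names(seqs) <- tree$tip.label
    list(alignment = codonAlignment(seqs, code), siteClasses = classes)
}

#' Simulate a qPCR experiment with known fold changes
#'
#' Reference genes are held constant across conditions; each target gene's
#' Ct in a sample is base Ct minus log_E of the planted fold change, plus
#' Gaussian noise. Either a Ct table or full synthetic amplification
#' curves (exponential phase embedded in baseline noise with a plateau)
#' can be produced.
#'
#' @param genes target gene names
#' @param samples condition/time-point labels; the first is the baseline
#'   (fold change 1)
#' @param references two reference gene names
#' @param nReplicates biological replicates per sample (default 3)
#' @param foldChanges matrix genes x samples of true fold changes
#'   (baseline column should be 1); default all 1
#' @param efficiency amplification efficiency E (default 2)
#' @param baseCt baseline-condition Ct of every gene (default 20)
#' @param ctNoiseSd Gaussian Ct noise (default 0.15)
#' @param seed RNG seed
#' @param curves if `TRUE`, emit per-cycle fluorescence curves instead of
#'   a Ct table
#' @param nCycles cycles per curve (default 35)
#' @return list with `data` (Ct table or curve table), `truth` (the fold
#'   change matrix) and `references`
#' @export
simulateQpcrExperiment <- function(genes = c("target1", "target2"),
                                   samples = c("day0", "day1"),
                                   references = c("ref1", "ref2"),
                                   nReplicates = 3L,
                                   foldChanges = NULL,
                                   efficiency = 2, baseCt = 20,
                                   ctNoiseSd = 0.15, seed = 1L,
                                   curves = FALSE, nCycles = 35L) {
    stopifnot(efficiency > 1, efficiency <= 2.5, ctNoiseSd >= 0,
              length(references) == 2L)
    if (is.null(foldChanges))
        foldChanges <- matrix(1, length(genes), length(samples),
                              dimnames = list(genes, samples))
    set.seed(seed)
    rows <- list()
    well <- 0L
    for (g in c(genes, references)) for (s in samples)
        for (r in seq_len(nReplicates)) {
            fc <- if (g %in% references) 1 else foldChanges[g, s]
            ct <- baseCt - log(fc, base = efficiency) +
                  rnorm(1, 0, ctNoiseSd)
            well <- well + 1L
            rows[[well]] <- data.frame(
                well = sprintf("w%03d", well), gene = g, sample = s,
                replicate = r, Ct = ct, E = efficiency,
                stringsAsFactors = FALSE)
        }
    ctTab <- do.call(rbind, rows)
    if (!curves) {
        return(list(data = ctTab, truth = foldChanges,
                    references = references))
    }
    curveRows <- lapply(seq_len(nrow(ctTab)), function(i) {
        ct <- ctTab$Ct[i]
        thr <- 1
        f0 <- thr / efficiency^ct
        cyc <- seq_len(nCycles)
        expo <- f0 * efficiency^cyc
        plateau <- thr * 1e3
        signal <- plateau * expo / (expo + plateau)
        baseline <- abs(rnorm(nCycles, 0.02 * thr, 0.002 * thr))
        data.frame(well = ctTab$well[i], gene = ctTab$gene[i],
                   sample = ctTab$sample[i], replicate = ctTab$replicate[i],
                   cycle = cyc, fluorescence = signal + baseline,
                   stringsAsFactors = FALSE)
    })
    list(data = do.call(rbind, curveRows), ct = ctTab,
         truth = foldChanges, references = references)
}

#' Simulate promoter sequences with planted IUPAC motifs
#'
#' Draws i.i.d. background sequence from the given nucleotide frequencies
#' and plants motif instances (each IUPAC position realized uniformly over
#' its allowed bases; minus-strand plants are inserted as the reverse
#' complement). Overlapping plants whose realized bases contradict a later
#' motif's consensus are an error. Truth records exact coordinates.
#'
#' @param nSequences number of promoters
#' @param length promoter length (default 2000, a 2-kb fragment upstream
#'   of the translation start)
#' @param background nucleotide frequencies (A, C, G, T)
#' @param planted data.frame with `seq` (1-based sequence index), `motif`
#'   (name from `motifs`), `position` (0-based start), `strand`
#' @param motifs motif set (data.frame name/consensus), default
#'   [defaultMotifSet()]
#' @param seed RNG seed
#' @return list with `sequences` (named character vector) and `truth`
#'   (BED-like data.frame of planted positions)
#' @export
simulatePromoters <- function(nSequences = 2L, length = 2000L,
                              background = c(A = 0.3, C = 0.2,
                                             G = 0.2, T = 0.3),
                              planted = NULL,
                              motifs = defaultMotifSet(), seed = 1L) {
    set.seed(seed)
    compiled <- Map(compileMotif, motifs$name, motifs$consensus)
    names(compiled) <- motifs$name
    seqsChar <- replicate(nSequences, sample(NUC, length, replace = TRUE,
                                             prob = background[NUC]),
                          simplify = FALSE)
    truth <- data.frame(sequence_id = character(), motif_name = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
    if (!is.null(planted)) {
        for (i in seq_len(nrow(planted))) {
            m <- compiled[[planted$motif[i]]]
            if (is.null(m)) stop("unknown motif: ", planted$motif[i])
            pos <- planted$position[i]
            if (pos < 0 || pos + m$length > length)
                stop("planted motif out of bounds at position ", pos)
            codes <- strsplit(m$consensus, "")[[1]]
            realized <- vapply(codes, function(code) {
                opts <- strsplit(IUPAC_CODES[[code]], "")[[1]]
                opts[sample.int(base::length(opts), 1L)]
            }, character(1))
            if (planted$strand[i] == "-")
                realized <- rev(c(A = "T", C = "G", G = "C",
                                  T = "A")[realized])
            target <- seqsChar[[planted$seq[i]]]
            idx <- (pos + 1L):(pos + m$length)
            pl <- attr(target, "planted")
            if (is.null(pl)) pl <- logical(base::length(target))
            conflict <- pl[idx] & target[idx] != realized
            if (any(conflict)) {
                fwd <- if (planted$strand[i] == "+") m$consensus
                       else revcompIupac(m$consensus)
                allowed <- strsplit(fwd, "")[[1]]
                compat <- mapply(function(b, code)
                    grepl(b, IUPAC_CODES[[code]]),
                    target[idx][conflict], allowed[conflict])
                if (!all(compat))
                    stop("overlapping planted motifs with contradictory ",
                         "bases at position ", pos)
                realized[conflict] <- target[idx][conflict]
            }
            target[idx] <- realized
            pl[idx] <- TRUE
            attr(target, "planted") <- pl
            seqsChar[[planted$seq[i]]] <- target
            truth <- rbind(truth, data.frame(
                sequence_id = paste0("promoter", planted$seq[i]),
                motif_name = planted$motif[i],
                start = pos, end = pos + m$length,
                strand = planted$strand[i], stringsAsFactors = FALSE))
        }
    }
    seqs <- vapply(seqsChar, paste, character(1), collapse = "")
    names(seqs) <- paste0("promoter", seq_len(nSequences))
    list(sequences = seqs, truth = truth)
}
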