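## Nei-Gojobori (1986) dN/dS with Jukes-Cantor correction, molecular-clock
## dating, and the effective number of codons (Wright 1990).

NUC <- c("A", "C", "G", "T")

#' Synonymous and non-synonymous site counts for one codon
#'
#' Classic NG86 counting: at each of the three positions, the synonymous
#' fraction is the number of the three possible single-base changes that
#' leave the amino acid unchanged, divided by the number of changes
#' counted; changes to stop codons are excluded from the denominator so
#' that S + N = 3 holds exactly per codon.
#'
#' @param codon a sense trinucleotide
#' @param code a [GeneticCode-class]
#' @return named numeric `c(S = , N = )` with `S + N == 3`
#' @examples
#' countSites("TTT")  # S = 1/3: only TTT->TTC is synonymous
#' @export
countSites <- function(codon, code = standardGeneticCode()) {
    aa <- code@codonToAa[codon]
    if (is.na(aa)) stop("unknown codon: ", codon)
    if (aa == "*") stop("stop codon has no site counts: ", codon)
    bases <- strsplit(codon, "")[[1]]
    S <- 0
    for (pos in 1:3) {
        syn <- 0L; counted <- 0L
        for (b in setdiff(NUC, bases[pos])) {
            mut <- bases
            mut[pos] <- b
            maa <- code@codonToAa[paste(mut, collapse = "")]
            if (maa == "*") next           # excluded from denominator
            counted <- counted + 1L
            if (maa == aa) syn <- syn + 1L
        }
        if (counted > 0L) S <- S + syn / counted
    }
    c(S = S, N = 3 - S)
}

#' Pathway-averaged synonymous/non-synonymous differences between codons
#'
#' For codons differing at k positions, all k! orderings of the single-base
#' steps are enumerated; each step is scored synonymous or non-synonymous
#' and counts are averaged over pathways. Pathways passing through a stop
#' codon are excluded before averaging; if every pathway hits a stop the
#' average is taken over all pathways with stop steps scored
#' non-synonymous and the result is flagged degenerate.
#'
#' @param codonA,codonB sense trinucleotides
#' @param code a [GeneticCode-class]
#' @return named numeric `c(Sd = , Nd = )` with `Sd + Nd` equal to the
#'   number of differing positions; attribute `degenerate` marks the
#'   all-pathways-blocked fallback
#' @examples
#' countPathwayDifferences("TTT", "GTA")  # Sd 0.5, Nd 1.5 over 2 pathways
#' @export
countPathwayDifferences <- function(codonA, codonB,
                                    code = standardGeneticCode()) {
    a <- strsplit(codonA, "")[[1]]
    b <- strsplit(codonB, "")[[1]]
    if (any(code@codonToAa[c(codonA, codonB)] == "*"))
        stop("pathway counting requires sense codons")
    diffPos <- which(a != b)
    k <- length(diffPos)
    if (k == 0L) {
        out <- c(Sd = 0, Nd = 0)
        attr(out, "degenerate") <- FALSE
        return(out)
    }
    perms <- permutations(diffPos)
    score <- function(order, countStops) {
        cur <- a
        syn <- 0; non <- 0
        for (pos in order) {
            nxt <- cur
            nxt[pos] <- b[pos]
            aa1 <- code@codonToAa[paste(cur, collapse = "")]
            aa2 <- code@codonToAa[paste(nxt, collapse = "")]
            if (aa2 == "*" && !countStops) return(NULL)
            if (aa1 == aa2 && aa1 != "*") syn <- syn + 1
            else non <- non + 1
            cur <- nxt
        }
        c(syn, non)
    }
    counts <- Filter(Negate(is.null), lapply(perms, score, countStops = FALSE))
    degenerate <- length(counts) == 0L
    if (degenerate)
        counts <- lapply(perms, score, countStops = TRUE)
    m <- do.call(rbind, counts)
    out <- c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
    attr(out, "degenerate") <- degenerate
    out
}

## all orderings of a small index vector (k <= 3 in practice)
permutations <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
        for (rest in permutations(v[-i]))
            out <- c(out, list(c(v[i], rest)))
    out
}

#' Jukes-Cantor multiple-hit correction
#'
#' @param p observed proportion of differences (per site)
#' @return corrected distance `-(3/4) log(1 - 4p/3)`
#' @export
jukesCantor <- function(p) {
    if (any(p >= 0.75))
        stop("distance saturated/undefined (p >= 3/4)")
    -0.75 * log(1 - 4 * p / 3)
}

#' NG86 pairwise dN/dS distance with Jukes-Cantor correction
#'
#' Synonymous (S) and non-synonymous (N) site totals are averaged over the
#' two sequences; observed synonymous/non-synonymous differences are
#' pathway-averaged per codon and summed; the proportions pS = Sd/S and
#' pN = Nd/N are Jukes-Cantor corrected into dS and dN.
#'
#' @param aln a [CodonAlignment-class]
#' @param idA,idB sequence ids present in the alignment
#' @param code a [GeneticCode-class]
#' @return one-row data.frame: `idA`, `idB`, `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `dS`, `dN`
#' @export
ng86Distance <- function(aln, idA, idB, code = standardGeneticCode()) {
    mat <- codonMatrix(aln)
    for (id in c(idA, idB))
        if (!id %in% rownames(mat)) stop("id not in alignment: ", id)
    ca <- mat[idA, ]; cb <- mat[idB, ]
    sitesA <- vapply(ca, countSites, numeric(2), code = code)
    sitesB <- vapply(cb, countSites, numeric(2), code = code)
    S <- (sum(sitesA["S", ]) + sum(sitesB["S", ])) / 2
    N <- (sum(sitesA["N", ]) + sum(sitesB["N", ])) / 2
    Sd <- 0; Nd <- 0
    for (j in which(ca != cb)) {
        d <- countPathwayDifferences(ca[j], cb[j], code = code)
        Sd <- Sd + d["Sd"]; Nd <- Nd + d["Nd"]
    }
    pS <- unname(Sd) / S
    pN <- unname(Nd) / N
    if (pS >= 0.75 || pN >= 0.75)
        stop("distance saturated/undefined for pair ", idA, "-", idB)
    data.frame(idA = idA, idB = idB, S = S, N = N,
               Sd = unname(Sd), Nd = unname(Nd), pS = pS, pN = pN,
               dS = jukesCantor(pS), dN = jukesCantor(pN),
               stringsAsFactors = FALSE)
}

#' All pairwise NG86 distances and their summary
#'
#' Mean and sample standard deviation of dN and dS over all sequence
#' pairs of the alignment.
#'
#' @param aln a [CodonAlignment-class]
#' @param code a [GeneticCode-class]
#' @return list with `pairs` (data.frame of all pairwise distances) and
#'   `summary` (`mean_dN`, `sd_dN`, `mean_dS`, `sd_dS`, `n_pairs`)
#' @export
distanceSummary <- function(aln, code = standardGeneticCode()) {
    ids <- seqIds(aln)
    combos <- combn(ids, 2L)
    pairs <- do.call(rbind, lapply(seq_len(ncol(combos)), function(k)
        ng86Distance(aln, combos[1, k], combos[2, k], code = code)))
    sdOr0 <- function(x) if (length(x) > 1L) sd(x) else 0
    list(pairs = pairs,
         summary = data.frame(
             mean_dN = mean(pairs$dN), sd_dN = sdOr0(pairs$dN),
             mean_dS = mean(pairs$dS), sd_dS = sdOr0(pairs$dS),
             n_pairs = nrow(pairs)))
}

#' Molecular-clock divergence time
#'
#' T = dS / (2 K), where K is the per-lineage synonymous substitution
#' rate. The default K of 4.38e-9 substitutions/site/year is a rate
#' estimated across multiple Solanum loci and is appropriate for tomato
#' and its wild relatives; override it for other taxa.
#'
#' @param dS synonymous distance (substitutions per synonymous site)
#' @param K substitution rate (substitutions/site/year)
#' @return list with `dS`, `K`, `T_years` and `T_MY`
#' @examples
#' divergenceTime(0.0876)$T_MY  # 10 MY at the default rate
#' @export
divergenceTime <- function(dS, K = 4.38e-9) {
    if (any(dS < 0)) stop("dS must be non-negative")
    if (K <= 0) stop("substitution rate K must be positive")
    Ty <- dS / (2 * K)
    list(dS = dS, K = K, T_years = Ty, T_MY = Ty / 1e6)
}

#' Effective number of codons (Nc)
#'
#' Wright's Nc statistic of codon usage bias. For each amino acid with
#' synonymous family size k, the codon homozygosity F is computed from the
#' observed codon frequencies (`raw`: sum of squared proportions;
#' `bias_corrected`: (n * sum p^2 - 1)/(n - 1)); Nc is then
#' 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6 with Fk the mean F over the observed
#' families of each degeneracy class. Families with fewer than 2 codons
#' observed are imputed with the mean F of the observed families in their
#' class; a wholly unobserved class falls back to its uniform-usage
#' expectation F = 1/k. Nc ranges from 20 (one codon per amino acid) to 61
#' (uniform synonymous usage); estimates above 61 are clamped with a
#' warning.
#'
#' @param cds in-frame coding sequence (character string, `DNAString`, or
#'   single-element `DNAStringSet`); stop codons are excluded from counting
#' @param code a [GeneticCode-class]
#' @param estimator `"raw"` (default) or `"bias_corrected"`
#' @return list with `Nc`, `familyHomozygosity` (mean F per class),
#'   `familiesUsed` (observed families per class) and `estimator`
#' @export
effectiveNumberOfCodons <- function(cds, code = standardGeneticCode(),
                                    estimator = c("raw", "bias_corrected")) {
    estimator <- match.arg(estimator)
    s <- toupper(as.character(cds))
    if (length(s) != 1L) stop("cds must be a single sequence")
    if (nchar(s) %% 3L != 0L) stop("cds length must be a multiple of 3")
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    codons <- codons[grepl("^[ACGT]{3}$", codons)]
    codons <- codons[code@codonToAa[codons] != "*"]
    if (length(codons) == 0L) stop("no sense codons in cds")
    aaOf <- code@codonToAa[codons]
    fam <- code@degeneracyFamilies
    Fvals <- list()          # per amino acid: list(k = family size, F = ..)
    for (aa in names(fam)) {
        k <- fam[[aa]]
        if (k < 2L) next
        n <- sum(aaOf == aa)
        if (n < 2L) { Fvals[[aa]] <- list(k = k, F = NA_real_); next }
        cnt <- table(codons[aaOf == aa])
        p <- as.numeric(cnt) / n
        Fhat <- if (estimator == "raw") sum(p^2)
                else (n * sum(p^2) - 1) / (n - 1)
        Fvals[[aa]] <- list(k = k, F = Fhat)
    }
    classes <- c(2L, 3L, 4L, 6L)
    Fbar <- numeric(0); used <- integer(0)
    for (k in classes) {
        fk <- vapply(Fvals, function(v) if (v$k == k) v$F else NA_real_,
                     numeric(1))
        fk <- fk[!is.na(fk)]
        used[as.character(k)] <- length(fk)
        Fbar[as.character(k)] <- if (length(fk)) mean(fk) else 1 / k
    }
    # bias-corrected F can hit 0 or go negative on near-uniform short
    # families; floor so the class contribution stays finite
    Fbar <- pmax(Fbar, 1e-6)
    Nc <- 2 + 9 / Fbar["2"] + 1 / Fbar["3"] + 5 / Fbar["4"] + 3 / Fbar["6"]
    Nc <- unname(Nc)
    if (Nc > 61) {
        warning("Nc estimate ", sprintf("%.2f", Nc), " clamped to 61")
        Nc <- 61
    }
    list(Nc = Nc, familyHomozygosity = Fbar, familiesUsed = used,
         estimator = estimator)
}
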