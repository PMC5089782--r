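## shared fixtures and independent oracles used across test files

gcStd <- standardGeneticCode()

writeTempFasta <- function(lines) {
    tf <- tempfile(fileext = ".fasta")
    writeLines(lines, tf)
    tf
}

## independent brute-force oracle for NG86 pathway counting: walks every
## ordering of the differing positions iteratively (explicit stack, no
## recursion, no shared code with the implementation)
oraclePathwayCounts <- function(codonA, codonB, code = gcStd) {
    a <- strsplit(codonA, "")[[1]]
    b <- strsplit(codonB, "")[[1]]
    diffPos <- which(a != b)
    k <- length(diffPos)
    if (k == 0) return(c(Sd = 0, Nd = 0))
    ords <- switch(as.character(k),
        "1" = matrix(diffPos, 1),
        "2" = rbind(diffPos, rev(diffPos)),
        "3" = {
            g <- expand.grid(diffPos, diffPos, diffPos)
            as.matrix(g[apply(g, 1, function(r)
                length(unique(r)) == 3), ])
        })
    syn <- c(); non <- c()
    for (r in seq_len(nrow(ords))) {
        cur <- a; s <- 0; n <- 0; blocked <- FALSE
        for (pos in ords[r, ]) {
            nxt <- cur; nxt[pos] <- b[pos]
            aa1 <- code@codonToAa[paste(cur, collapse = "")]
            aa2 <- code@codonToAa[paste(nxt, collapse = "")]
            if (aa2 == "*") { blocked <- TRUE; break }
            if (aa1 == aa2) s <- s + 1 else n <- n + 1
            cur <- nxt
        }
        if (!blocked) { syn <- c(syn, s); non <- c(non, n) }
    }
    if (!length(syn)) return(NULL)   # fully blocked: fallback not mirrored
    c(Sd = mean(syn), Nd = mean(non))
}

## independent brute-force motif scanner: consensus -> regex, sliding
## gregexpr on both strands with positions mapped to forward coordinates
oracleScanMotif <- function(seq, name, consensus) {
    expandRepeats <- function(x) {
        while (grepl("\\{", x)) {
            ch <- sub(".*?(.)\\{(\\d+)\\}.*", "\\1", x)
            n <- as.integer(sub(".*?.\\{(\\d+)\\}.*", "\\1", x))
            x <- sub("(.)\\{(\\d+)\\}", strrep(ch, n), x)
        }
        x
    }
    codes <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
               S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
               D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
    cons <- expandRepeats(consensus)
    rx <- paste(codes[strsplit(cons, "")[[1]]], collapse = "")
    L <- nchar(seq)
    w <- nchar(cons)
    revcomp <- function(s) chartr("ACGT", "TGCA",
                                  paste(rev(strsplit(s, "")[[1]]),
                                        collapse = ""))
    hits <- data.frame(motif_name = character(), start = integer(),
                       end = integer(), strand = character())
    for (i in seq_len(L - w + 1)) {
        win <- substr(seq, i, i + w - 1)
        plus <- grepl(paste0("^", rx, "$"), win)
        minus <- grepl(paste0("^", rx, "$"), revcomp(win))
        if (plus)
            hits <- rbind(hits, data.frame(motif_name = name, start = i - 1L,
                                           end = i + w - 1L, strand = "+"))
        if (minus && !plus)
            hits <- rbind(hits, data.frame(motif_name = name, start = i - 1L,
                                           end = i + w - 1L, strand = "-"))
    }
    hits
}

## toy genetic code with extra stops, for exercising blocked-pathway
## handling with the injectable code table
toyCodeWithStops <- function(extraStops) {
    tab <- Biostrings::GENETIC_CODE
    tab[extraStops] <- "*"
    sense <- names(tab)[tab != "*"]
    fam <- table(tab[sense])
    new("GeneticCode", name = paste0("toy-", paste(extraStops, collapse = "")),
        codonToAa = setNames(as.character(tab), names(tab)),
        senseCodons = sense,
        degeneracyFamilies = setNames(as.integer(fam), names(fam)))
}
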