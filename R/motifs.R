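## IUPAC consensus scanning of promoter fragments and paralog motif
## comparison. Matching is delegated to Biostrings fixed=FALSE pattern
## matching; this module adds repeat-notation expansion, double-strand
## scanning in forward coordinates, palindrome deduplication and the
## sharing/exclusivity comparison.

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT",
                 K = "GT", M = "AC", B = "CGT", D = "AGT",
                 H = "ACT", V = "ACG", N = "ACGT")

#' Compile an IUPAC consensus motif
#'
#' Expands fixed-length repeat notation (e.g. `W{6}`) and validates the
#' alphabet against the IUPAC nucleotide codes.
#'
#' @param name motif name
#' @param consensus IUPAC consensus, optionally with `X{n}` repeats
#' @return list with `name`, `consensus` (expanded) and `length`
#' @examples
#' compileMotif("CArG", "CCW{6}GG")$consensus  # "CCWWWWWWGG"
#' @export
compileMotif <- function(name, consensus) {
    if (is.null(consensus) || !nzchar(consensus))
        stop("empty consensus for motif ", name)
    expanded <- consensus
    while (grepl("\\{", expanded)) {
        m <- regmatches(expanded, regexpr("(.)\\{(\\d+)\\}", expanded))[1]
        ch <- substr(m, 1, 1)
        n <- as.integer(sub(".*\\{(\\d+)\\}", "\\1", m))
        expanded <- sub("(.)\\{(\\d+)\\}",
                        paste(rep(ch, n), collapse = ""),
                        expanded)
    }
    expanded <- toupper(expanded)
    bad <- setdiff(strsplit(expanded, "")[[1]], names(IUPAC_CODES))
    if (length(bad))
        stop("illegal IUPAC code(s) in motif ", name, ": ",
             paste(unique(bad), collapse = ", "))
    list(name = name, consensus = expanded, length = nchar(expanded))
}

#' The package's default promoter motif set
#'
#' Reads the shipped motif configuration (name + IUPAC consensus per
#' line). The set covers cis-elements bound by MADS (CArG), PIF (PBE-box,
#' G-box, E-box) and HY5 (ACE, CA-hybrid, CG-hybrid) transcription
#' factors; the hybrid/ACE consensi come from the light-signalling
#' literature and are shipped as configuration, not code, so they can be
#' revalidated or replaced.
#'
#' @param path motif config file (two whitespace-separated columns:
#'   name, consensus); default the packaged set
#' @return data.frame with `name` and `consensus`
#' @export
defaultMotifSet <- function(path = system.file("extdata", "motifs.tsv",
                                               package = "paralogEvol")) {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, comment.char = "#")
    stopifnot(all(c("name", "consensus") %in% colnames(df)))
    df
}

revcompIupac <- function(consensus) {
    comp <- c(A = "T", C = "G", G = "C", T = "A",
              R = "Y", Y = "R", S = "S", W = "W",
              K = "M", M = "K", B = "V", D = "H",
              H = "D", V = "B", N = "N")
    paste(rev(comp[strsplit(consensus, "")[[1]]]), collapse = "")
}

#' Scan a sequence for IUPAC consensus motifs on both strands
#'
#' Every match of every motif is reported (no masking of overlaps), on
#' both strands, in forward-strand 0-based half-open coordinates; a
#' palindromic motif matching the same span on both strands is reported
#' once. Hits are sorted by (start, motif name, strand).
#'
#' @param seq a nucleotide sequence (character, `DNAString`, or a
#'   single-element named `DNAStringSet`)
#' @param motifs data.frame with `name` and `consensus` columns (e.g.
#'   [defaultMotifSet()]), or a list of [compileMotif()] results
#' @param seqId id used in the output (defaults to the sequence's name)
#' @return data.frame with `sequence_id`, `motif_name`, `start`, `end`,
#'   `strand`, `matched_text`
#' @export
scanMotifs <- function(seq, motifs, seqId = NULL) {
    if (is(seq, "DNAStringSet")) {
        if (is.null(seqId)) seqId <- names(seq)[1]
        seq <- seq[[1]]
    }
    s <- Biostrings::DNAString(toupper(as.character(seq)))
    if (is.null(seqId)) seqId <- "seq"
    if (is.data.frame(motifs))
        motifs <- Map(compileMotif, motifs$name, motifs$consensus)
    hits <- list()
    for (m in motifs) {
        for (strand in c("+", "-")) {
            pat <- if (strand == "+") m$consensus
                   else revcompIupac(m$consensus)
            mt <- Biostrings::matchPattern(Biostrings::DNAString(pat), s,
                                           fixed = FALSE)
            if (length(mt) == 0) next
            hits[[length(hits) + 1L]] <- data.frame(
                sequence_id = seqId, motif_name = m$name,
                start = Biostrings::start(mt) - 1L,
                end = Biostrings::end(mt),
                strand = strand,
                matched_text = as.character(mt),
                stringsAsFactors = FALSE)
        }
    }
    if (!length(hits))
        return(data.frame(sequence_id = character(), motif_name = character(),
                          start = integer(), end = integer(),
                          strand = character(), matched_text = character(),
                          stringsAsFactors = FALSE))
    out <- do.call(rbind, hits)
    ## palindrome dedup: identical (span, motif) on both strands -> one hit
    key <- paste(out$motif_name, out$start, out$end)
    out <- out[!duplicated(key), ]
    out <- out[order(out$start, out$motif_name, out$strand), ]
    rownames(out) <- NULL
    out
}

#' Compare motif content of two paralog promoters
#'
#' Partitions the motif names observed in either promoter into shared and
#' exclusive sets and tabulates per-motif hit counts.
#'
#' @param hitsA,hitsB hit data.frames from [scanMotifs()]
#' @return list with `counts` (data.frame motif_name, count_a, count_b),
#'   `shared`, `exclusive_to_a`, `exclusive_to_b`
#' @export
comparePromoterMotifs <- function(hitsA, hitsB) {
    all <- sort(unique(c(hitsA$motif_name, hitsB$motif_name)))
    ca <- vapply(all, function(m) sum(hitsA$motif_name == m), integer(1))
    cb <- vapply(all, function(m) sum(hitsB$motif_name == m), integer(1))
    list(counts = data.frame(motif_name = all, count_a = unname(ca),
                             count_b = unname(cb),
                             stringsAsFactors = FALSE),
         shared = all[ca > 0 & cb > 0],
         exclusive_to_a = all[ca > 0 & cb == 0],
         exclusive_to_b = all[ca == 0 & cb > 0])
}

#' Write motif hits as BED6
#'
#' @param hits data.frame from [scanMotifs()]
#' @param path output file
#' @return `path`, invisibly
#' @export
writeHitsBed <- function(hits, path) {
    bed <- data.frame(chrom = hits$sequence_id, start = hits$start,
                      end = hits$end, name = hits$motif_name,
                      score = 0L, strand = hits$strand)
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
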