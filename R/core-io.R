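#' Read a FASTA file of sequence records
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' package's record conventions: ids are the first whitespace-delimited
#' token of the header (the remainder becomes the description), residues
#' are uppercased, and duplicate ids are an error because ids are the join
#' key across coding sequences, promoters and expression tables.
#'
#' @param path FASTA file
#' @param type `"DNA"` returns a [Biostrings::DNAStringSet] (gaps `-` and
#'   `N` allowed), `"AA"` an `AAStringSet`
#' @return an `XStringSet` with `names()` set to ids and a
#'   `description` element in `S4Vectors::mcols()`
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a first", "acgt"), tf)
#' readFasta(tf)
#' @export
readFasta <- function(path, type = c("DNA", "AA")) {
    type <- match.arg(type)
    if (!file.exists(path)) stop("file not found: ", path)
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L) stop("no sequences in ", path)
    headers <- names(set)
    ids <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    if (any(ids == "")) stop("empty sequence id in ", path)
    dup <- ids[duplicated(ids)]
    if (length(dup))
        stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
    res <- toupper(as.character(set))
    out <- if (type == "DNA") Biostrings::DNAStringSet(res)
           else Biostrings::AAStringSet(res)
    names(out) <- ids
    S4Vectors::mcols(out) <- S4Vectors::DataFrame(description = desc)
    out
}

#' Write sequences to FASTA
#'
#' Writes 60-column wrapped FASTA; descriptions stored in `mcols()` are
#' appended to the header after the id.
#'
#' @param seqs an `XStringSet` (or named character vector)
#' @param path output file
#' @return `path`, invisibly
#' @export
writeFasta <- function(seqs, path) {
    if (is.character(seqs)) {
        if (is.null(names(seqs))) stop("sequences must be named")
        seqs <- Biostrings::BStringSet(seqs)
    }
    headers <- names(seqs)
    mc <- S4Vectors::mcols(seqs)
    if (!is.null(mc) && "description" %in% colnames(mc)) {
        d <- mc$description
        headers <- ifelse(is.na(d) | d == "", headers,
                          paste(headers, d))
    }
    con <- file(path, "w")
    on.exit(close(con))
    txt <- as.character(seqs)
    for (i in seq_along(txt)) {
        writeLines(paste0(">", headers[i]), con)
        s <- txt[i]
        starts <- seq(1L, nchar(s), by = 60L)
        writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
    }
    invisible(path)
}

#' Build an in-frame codon alignment with complete deletion
#'
#' Takes equal-length aligned coding sequences and removes, as whole
#' three-base columns, every codon column in which any sequence has a gap
#' (`-`) or ambiguous base (`N`, or any non-ACGT letter), and every column
#' in which any sequence carries a stop codon. Deleting at codon
#' granularity is the only gap treatment that preserves the reading frame;
#' ambiguous codons are removed because Nei-Gojobori site counting is
#' undefined for them.
#'
#' @param seqs a `DNAStringSet` (aligned, equal widths, width divisible
#'   by 3) or named character vector
#' @param code a [GeneticCode-class]
#' @return a [CodonAlignment-class]
#' @examples
#' codonAlignment(c(a = "ATG---AAA", b = "ATGCCCAAA"))  # 2 codons kept
#' @export
codonAlignment <- function(seqs, code = standardGeneticCode()) {
    if (is.character(seqs)) {
        if (is.null(names(seqs))) stop("sequences must be named")
        chars <- toupper(seqs)
    } else {
        chars <- as.character(seqs)
    }
    if (length(chars) < 2L) stop("alignment needs at least 2 sequences")
    if (is.null(names(chars)) || anyDuplicated(names(chars)))
        stop("sequences must carry unique ids")
    w <- nchar(chars)
    if (length(unique(w)) > 1L)
        stop("aligned sequences must have equal length")
    if (w[1] %% 3L != 0L)
        stop("alignment length (", w[1], ") is not divisible by 3")
    nc <- w[1] %/% 3L
    mat <- do.call(rbind, lapply(chars, function(s)
        substring(s, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))))
    clean <- grepl("^[ACGT]{3}$", mat)
    dim(clean) <- dim(mat)
    keep <- apply(clean, 2L, all)
    if (any(keep)) {
        isStop <- matrix(code@codonToAa[mat[, keep, drop = FALSE]] == "*",
                         nrow = nrow(mat))
        keep[keep] <- !apply(isStop, 2L, any)
    }
    if (!any(keep))
        stop("no codon columns retained after complete deletion")
    res <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
    out <- Biostrings::DNAStringSet(res)
    names(out) <- names(chars)
    new("CodonAlignment", seqs = out, nCodons = sum(keep),
        gapPolicy = "complete_deletion")
}

#' Translate a codon alignment
#'
#' @param aln a [CodonAlignment-class]
#' @param code a [GeneticCode-class]
#' @return an `AAStringSet`, one residue per retained codon column
#' @export
translateAlignment <- function(aln, code = standardGeneticCode()) {
    mat <- codonMatrix(aln)
    aa <- matrix(code@codonToAa[mat], nrow = nrow(mat))
    out <- Biostrings::AAStringSet(apply(aa, 1L, paste, collapse = ""))
    names(out) <- seqIds(aln)
    out
}

## sequences x codon-columns character matrix of trinucleotides
codonMatrix <- function(aln) {
    chars <- as.character(aln@seqs)
    nc <- aln@nCodons
    m <- do.call(rbind, lapply(chars, function(s)
        substring(s, 3L * seq_len(nc) - 2L, 3L * seq_len(nc))))
    rownames(m) <- seqIds(aln)
    m
}
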