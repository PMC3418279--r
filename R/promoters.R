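#' Fixed-length promoter sets
#'
#' A `promoter_set` holds an ordered collection of gene promoter sequences,
#' all of one fixed window length (canonically 1000 bp, 5' to 3', with the
#' last base immediately adjacent to the TSS or translation start). Sequences
#' are stored uppercase over A, C, G, T, N; gene ids are unique. Position 1
#' of a window is the most upstream base (-window_length relative to the
#' TSS); an L-mer occurrence's position is its 1-based start, so the maximum
#' start is `window_length - L + 1` (993 for 8-mers in 1000-bp windows).
#'
#' @param sequences named character vector (names are gene ids).
#' @param window_length required length of every sequence, >= 20.
#' @param species free-text species label.
#' @return A `promoter_set` object.
#' @export
promoter_set <- function(sequences, window_length, species = "unspecified") {
    stopifnot(is.character(sequences), window_length >= 20)
    ids <- names(sequences)
    if (is.null(ids) || any(ids == "" | is.na(ids)))
        stop("every sequence must carry a gene id")
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
        stop("duplicate gene ids: ", paste(head(dup, 5), collapse = ", "))
    sequences <- toupper(sequences)
    len <- nchar(sequences)
    if (any(len != window_length)) {
        off <- ids[len != window_length]
        stop("sequences not of length ", window_length, " (no trimming is ",
             "done): ", paste(head(off, 5), collapse = ", "),
             if (length(off) > 5) ", ...")
    }
    bad <- grepl("[^ACGTN]", sequences)
    if (any(bad))
        stop("characters outside A/C/G/T/N in: ",
             paste(head(ids[bad], 5), collapse = ", "))
    structure(list(sequences = sequences,
                   window_length = as.integer(window_length),
                   species = species),
              class = "promoter_set")
}

#' @export
print.promoter_set <- function(x, ...) {
    cat("<promoter_set> ", length(x$sequences), " promoters x ",
        x$window_length, " bp (", x$species, ")\n", sep = "")
    invisible(x)
}

#' @export
length.promoter_set <- function(x) length(x$sequences)

#' @rdname promoter_set
#' @export
gene_ids <- function(promoters) {
    stopifnot(inherits(promoters, "promoter_set"))
    names(promoters$sequences)
}

#' Read a fixed-length promoter FASTA
#'
#' Reads a promoter FASTA and validates it into a [promoter_set()]. Records
#' whose length differs from `window_length` are rejected with an error
#' naming the offending ids; there is no silent trimming or padding.
#' Lowercase input is normalized to uppercase. FASTA description lines are
#' truncated at the first whitespace to obtain gene ids.
#'
#' @param path FASTA file path.
#' @inheritParams promoter_set
#' @return A `promoter_set`.
#' @export
read_promoters <- function(path, window_length = 1000L,
                           species = "unspecified") {
    seqs <- Biostrings::readDNAStringSet(path)
    x <- as.character(seqs)
    names(x) <- sub("\\s.*$", "", names(seqs))
    promoter_set(x, window_length, species)
}

#' @param promoters a `promoter_set`.
#' @rdname read_promoters
#' @export
write_promoters <- function(promoters, path) {
    stopifnot(inherits(promoters, "promoter_set"))
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(promoters$sequences), path, width = 80L)
    invisible(path)
}

#' Select a cluster of promoters from a universe
#'
#' Returns the promoters whose gene ids are in `ids`, preserving the order of
#' the universe. Ids absent from the universe trigger a warning listing them;
#' an empty intersection is an error.
#'
#' @param universe a [promoter_set()].
#' @param ids character vector of gene ids.
#' @return A `promoter_set` restricted to the requested genes.
#' @export
subset_by_ids <- function(universe, ids) {
    stopifnot(inherits(universe, "promoter_set"), length(ids) > 0)
    ids <- unique(ids)
    missing <- setdiff(ids, gene_ids(universe))
    if (length(missing) == length(ids))
        stop("none of the requested ids are in the universe")
    if (length(missing))
        warning("ids not in the universe: ",
                paste(head(missing, 10), collapse = ", "),
                if (length(missing) > 10) ", ...")
    keep <- gene_ids(universe) %in% ids
    promoter_set(universe$sequences[keep], universe$window_length,
                 universe$species)
}

#' Read a gene-cluster membership list
#'
#' Plain text, one gene id per line; blank lines and `#` comments ignored.
#'
#' @param path file path.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
    x <- trimws(readLines(path, warn = FALSE))
    x <- sub("#.*$", "", x)
    x <- trimws(x)
    x[nzchar(x)]
}
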