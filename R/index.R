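#' Catalog promoter presence of every degenerate oligo
#'
#' For every word of length `L` over the degenerate alphabet, counts the
#' number of promoters harboring at least one matching window. Each promoter
#' contributes at most 1 to any oligo's count regardless of how many times
#' the oligo occurs in it; windows overlapping an `N` are skipped entirely.
#' This is the cataloging loop behind every enrichment statistic: the counts
#' over a genome-wide universe give `k` (and `K = n_promoters`), the counts
#' over a cluster give `m` (and `M`).
#'
#' The counter array is dense, of length `|alphabet|^L` (214,358,881 for
#' 8-mers over the 11-letter alphabet, ~0.9 GB of integer storage), indexed
#' by the positional-notation code of each word (see [encode_oligo()]).
#'
#' @param promoters a [promoter_set()].
#' @param alphabet a [motif_alphabet][alphabet11].
#' @param L word length (8 for the 11-letter alphabet, 12 for the 5-letter
#'   one, by convention; any length with `|alphabet|^L < 2^31` works).
#' @return An `oligo_count_index`: list with `counts` (integer vector of
#'   length `|alphabet|^L`, element `code + 1` is the presence count of the
#'   word with that code), `n_promoters`, `alphabet_name`, `L`,
#'   `window_length`.
#' @export
index_promoters <- function(promoters, alphabet = alphabet11(), L = 8L) {
    stopifnot(inherits(promoters, "promoter_set"),
              inherits(alphabet, "motif_alphabet"),
              L >= 1, promoters$window_length >= L)
    if (n_oligos(alphabet, L) >= 2^31)
        stop("|alphabet|^L exceeds the dense-array design limit")
    counts <- count_index_cpp(unname(promoters$sequences), as.integer(L),
                              .letter_match_idx(alphabet))
    structure(list(counts = counts,
                   n_promoters = length(promoters),
                   alphabet_name = alphabet$name,
                   L = as.integer(L),
                   window_length = promoters$window_length),
              class = "oligo_count_index")
}

#' @export
print.oligo_count_index <- function(x, ...) {
    cat("<oligo_count_index> ", x$alphabet_name, " L=", x$L, ", ",
        format(length(x$counts), big.mark = ","), " oligos over ",
        x$n_promoters, " promoters\n", sep = "")
    invisible(x)
}

#' Occurrence positions of one oligo across promoters
#'
#' Scans each promoter for windows matched by the degenerate word and
#' returns all 1-based start positions, per gene. Genes without any
#' occurrence are dropped.
#'
#' @param promoters a [promoter_set()].
#' @param oligo a single degenerate word.
#' @inheritParams index_promoters
#' @return Named list of integer position vectors, one per gene harboring
#'   the oligo.
#' @export
collect_positions <- function(promoters, oligo, alphabet = alphabet11()) {
    stopifnot(inherits(promoters, "promoter_set"))
    oligo <- as_oligo(oligo, alphabet)
    chars <- strsplit(oligo, "", fixed = TRUE)[[1]]
    allow <- t(vapply(chars, function(l)
        c("A", "C", "G", "T") %in% alphabet$match[[l]], logical(4)))
    hits <- collect_positions_cpp(promoters$sequences, allow)
    hits[vapply(hits, length, integer(1)) > 0]
}

#' Persist and reload a count index
#'
#' The counter array is written as raw little-endian 32-bit integers with a
#' JSON sidecar (`<prefix>.json`) recording the alphabet, word length,
#' promoter count, window length and a checksum, so genome-wide indexes are
#' computed once and reused across cluster analyses.
#'
#' @param index an `oligo_count_index`.
#' @param prefix output path prefix; writes `<prefix>.counts` and
#'   `<prefix>.json`.
#' @return `write_count_index`: the prefix, invisibly. `read_count_index`:
#'   the restored `oligo_count_index`.
#' @export
write_count_index <- function(index, prefix) {
    stopifnot(inherits(index, "oligo_count_index"))
    con <- file(paste0(prefix, ".counts"), "wb")
    on.exit(close(con))
    writeBin(index$counts, con, size = 4L, endian = "little")
    meta <- list(alphabet = index$alphabet_name, L = index$L,
                 n_promoters = index$n_promoters,
                 window_length = index$window_length,
                 n_oligos = length(index$counts),
                 checksum = sum(as.numeric(index$counts)))
    jsonlite::write_json(meta, paste0(prefix, ".json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(prefix)
}

#' @rdname write_count_index
#' @export
read_count_index <- function(prefix) {
    meta <- jsonlite::read_json(paste0(prefix, ".json"))
    con <- file(paste0(prefix, ".counts"), "rb")
    on.exit(close(con))
    counts <- readBin(con, "integer", n = meta$n_oligos, size = 4L,
                      endian = "little")
    if (length(counts) != meta$n_oligos ||
        sum(as.numeric(counts)) != meta$checksum)
        stop("count index is corrupt or truncated: ", prefix)
    structure(list(counts = counts,
                   n_promoters = as.integer(meta$n_promoters),
                   alphabet_name = meta$alphabet,
                   L = as.integer(meta$L),
                   window_length = as.integer(meta$window_length)),
              class = "oligo_count_index")
}

.alphabet_by_name <- function(name) {
    switch(name, alpha11 = alphabet11(), alpha5 = alphabet5(),
           stop("unknown alphabet: ", name))
}
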