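#' Fraction of an oligo's positions already claimed
#'
#' Positions are `(gene_id, start)` pairs; the fraction is relative to the
#' candidate oligo's own position count (asymmetric), so two oligos
#' overlapping the same genomic window at shifted starts do not share a
#' position.
#'
#' @param oligo_positions character vector of position keys
#'   (`"gene_id:start"`), non-empty.
#' @param claimed character vector of already-claimed position keys.
#' @return The overlap fraction in `[0, 1]`.
#' @export
position_overlap <- function(oligo_positions, claimed) {
    if (length(oligo_positions) == 0)
        stop("overlap undefined for an oligo with no positions")
    sum(oligo_positions %in% claimed) / length(oligo_positions)
}

#' Flatten a position map into `"gene_id:start"` keys
#'
#' Converts a [collect_positions()] result into the flat character keys the
#' overlap filter operates on.
#'
#' @param positions named list of integer start vectors, by gene id.
#' @return Character vector of `"gene_id:start"` keys.
#' @export
position_keys <- function(positions) {
    if (length(positions) == 0) return(character(0))
    unlist(lapply(names(positions), function(g)
        paste0(g, ":", positions[[g]])), use.names = FALSE)
}

#' Extract non-redundant major motifs by the position-overlap filter
#'
#' Highly ranked oligos are mostly degenerate variants of a few distinct
#' motifs occupying the same binding sites. The filter walks the ranked list
#' iteratively: the best-ranked remaining oligo becomes a major motif, its
#' occurrence positions are added to the claimed set, and every remaining
#' oligo sharing at least `overlap_fraction` of its *own* positions with the
#' claimed set is removed as a variant. Iteration halts when fewer than
#' `stop_below` oligos remain. Ties in p-value are broken by lower word code
#' for determinism.
#'
#' @param ranked data frame of candidate oligos with at least `motif`,
#'   `code` and `pvalue` columns, reverse-complement deduplicated.
#' @param positions named list (by motif string) of position-key character
#'   vectors (see [position_keys()]) or of named start-position lists as
#'   returned by [collect_positions()].
#' @param overlap_fraction removal threshold (default 0.10: sharing 10% or
#'   more of one's positions with a major's sites marks a variant).
#' @param stop_below halt when fewer than this many oligos remain.
#' @return A `major_motif_report`: list with `majors` (the selected rows of
#'   `ranked`, in selection order), `claimed_positions`,
#'   `survivors_at_stop`, and the filter parameters.
#' @export
select_major_motifs <- function(ranked, positions, overlap_fraction = 0.10,
                                stop_below = 10L) {
    stopifnot(is.data.frame(ranked),
              all(c("motif", "pvalue", "code") %in% names(ranked)),
              overlap_fraction >= 0, overlap_fraction <= 1)
    ranked <- ranked[order(ranked$pvalue, ranked$code), , drop = FALSE]
    keys <- lapply(ranked$motif, function(mo) {
        p <- positions[[mo]]
        if (is.list(p)) position_keys(p) else as.character(p)
    })
    missing <- vapply(keys, length, integer(1)) == 0
    if (any(missing))
        stop("no positions supplied for: ",
             paste(head(ranked$motif[missing], 5), collapse = ", "))

    claimed <- character(0)
    majors <- integer(0)
    remaining <- seq_len(nrow(ranked))
    while (length(remaining) > 0 && length(remaining) >= stop_below) {
        top <- remaining[1]
        majors <- c(majors, top)
        claimed <- unique(c(claimed, keys[[top]]))
        remaining <- remaining[-1]
        if (length(remaining)) {
            ov <- vapply(remaining, function(i)
                position_overlap(keys[[i]], claimed), numeric(1))
            remaining <- remaining[ov < overlap_fraction]
        }
    }
    structure(list(majors = ranked[majors, , drop = FALSE],
                   claimed_positions = claimed,
                   survivors_at_stop = length(remaining),
                   overlap_fraction = overlap_fraction,
                   stop_below = as.integer(stop_below)),
              class = "major_motif_report")
}

#' @export
print.major_motif_report <- function(x, ...) {
    cat("<major_motif_report> ", nrow(x$majors), " major motifs (overlap < ",
        x$overlap_fraction, ", stopped with ", x$survivors_at_stop,
        " oligos left)\n", sep = "")
    if (nrow(x$majors)) print(x$majors, row.names = FALSE)
    invisible(x)
}
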