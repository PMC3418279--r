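#' End-to-end motif discovery for a gene cluster
#'
#' Runs the full single-species pipeline: index the cluster promoters, score
#' every oligo against the genome-wide index, collapse reverse-complement
#' pairs, scan the cluster for occurrence positions of the top candidates,
#' compute TSS position-bias z-scores, apply the p-value / z-score
#' qualification, and extract non-redundant major motifs with the
#' position-overlap filter.
#'
#' Position scanning is limited to the `max_candidates` best-ranked oligos
#' at or below `p_relaxed`; the overlap filter then operates on the
#' qualified subset of those. Majors are therefore always drawn from the
#' strongest candidates, and only the absorption of very low-ranked variants
#' is affected by the cap.
#'
#' @param genome a [promoter_set()] universe.
#' @param cluster_ids gene ids of the co-expressed cluster.
#' @param alphabet a [motif_alphabet][alphabet11].
#' @param L word length.
#' @param genome_index optional precomputed [index_promoters()] result for
#'   `genome` (computed on the fly when `NULL`).
#' @param p_strict,p_relaxed,z_min qualification cutoffs, see
#'   [qualify_motif()].
#' @param overlap_fraction,stop_below position-filter parameters, see
#'   [select_major_motifs()].
#' @param max_candidates cap on position-scanned candidates.
#' @return A `motif_discovery` list: `majors` (data frame: rank, motif, m,
#'   k, M, K, pvalue, qvalue, fold, n, mean_position, zscore),
#'   `candidates` (the scanned candidate table with the same columns plus
#'   `qualified`), `report` (the raw [select_major_motifs()] output),
#'   `positions` (per-candidate occurrence maps), `enrichment`.
#' @export
discover_motifs <- function(genome, cluster_ids, alphabet = alphabet11(),
                            L = 8L, genome_index = NULL,
                            p_strict = 1e-7, p_relaxed = 1e-5, z_min = 3,
                            overlap_fraction = 0.10, stop_below = 10L,
                            max_candidates = 2000L) {
    stopifnot(inherits(genome, "promoter_set"))
    cluster <- subset_by_ids(genome, cluster_ids)
    if (is.null(genome_index))
        genome_index <- index_promoters(genome, alphabet, L)
    cluster_index <- index_promoters(cluster, alphabet, L)
    enr <- oligo_enrichment(cluster_index, genome_index, p_keep = p_relaxed)
    cand <- enrichment_table(enr, p_cutoff = p_relaxed, n_max = max_candidates)

    pos_maps <- list(); stats <- vector("list", nrow(cand))
    for (i in seq_len(nrow(cand))) {
        pm <- collect_positions(cluster, cand$motif[i], alphabet)
        pos_maps[[cand$motif[i]]] <- pm
        stats[[i]] <- position_zscore(unlist(pm, use.names = FALSE),
                                      genome$window_length, L)
    }
    cand$n <- vapply(stats, `[[`, numeric(1), "n")
    cand$mean_position <- vapply(stats, `[[`, numeric(1), "mean_position")
    cand$zscore <- vapply(stats, `[[`, numeric(1), "z")
    cand$qualified <- qualify_motif(cand$pvalue, cand$zscore,
                                    p_strict, p_relaxed, z_min)

    qualified <- cand[cand$qualified, , drop = FALSE]
    report <- select_major_motifs(qualified, pos_maps, overlap_fraction,
                                  stop_below)
    majors <- report$majors
    if (nrow(majors)) majors$rank <- seq_len(nrow(majors))
    structure(list(majors = majors, candidates = cand, report = report,
                   positions = pos_maps, enrichment = enr,
                   params = list(L = L, alphabet = alphabet$name,
                                 p_strict = p_strict, p_relaxed = p_relaxed,
                                 z_min = z_min,
                                 overlap_fraction = overlap_fraction,
                                 stop_below = stop_below,
                                 max_candidates = max_candidates)),
              class = "motif_discovery")
}

#' @export
print.motif_discovery <- function(x, ...) {
    cat("<motif_discovery> ", nrow(x$candidates), " candidates scanned, ",
        sum(x$candidates$qualified), " qualified, ", nrow(x$majors),
        " major motifs\n", sep = "")
    if (nrow(x$majors))
        print(x$majors[, c("rank", "motif", "m", "k", "pvalue",
                           "mean_position", "zscore")], row.names = FALSE)
    invisible(x)
}

#' Write a discovery report as TSV
#'
#' Tab-separated table of the major motifs (rank, motif, in-cluster and
#' in-genome presence counts, p-value, q-value, fold, instance count, mean
#' position, z-score), with `#`-prefixed header comments recording the run
#' parameters.
#'
#' @param discovery a [discover_motifs()] result.
#' @param path output file.
#' @export
write_discovery_tsv <- function(discovery, path) {
    stopifnot(inherits(discovery, "motif_discovery"))
    con <- file(path, "w")
    on.exit(close(con))
    p <- discovery$params
    writeLines(c(
        paste0("# promotif ", as.character(utils::packageVersion("promotif"))),
        paste0("# alphabet=", p$alphabet, " L=", p$L,
               " p_strict=", p$p_strict, " p_relaxed=", p$p_relaxed,
               " z_min=", p$z_min, " overlap=", p$overlap_fraction,
               " stop_below=", p$stop_below)), con)
    cols <- c("rank", "motif", "m", "k", "M", "K", "pvalue", "qvalue",
              "fold", "n", "mean_position", "zscore")
    utils::write.table(discovery$majors[, cols], con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
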