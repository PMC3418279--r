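#' Random-group false-discovery calibration
#'
#' Replicates the null experiment behind the qualification cutoffs: sample
#' groups of promoters uniformly at random from the universe (no shared
#' regulation, so every sub-cutoff oligo is a false positive), run the full
#' enrichment pass for each group against the genome-wide index, and count
#' RC-deduplicated oligos at or below each p-value cutoff. The means are
#' compared with the analytic expectation
#' [expected_false_positives()] (`n_restricted * p / 4`). Optionally, TSS
#' z-scores are computed for every tested oligo, giving the null z
#' distribution (flat around 0 with unit spread) and the count of
#' sub-cutoff oligos with `z > z_min`.
#'
#' Sampling is without replacement within a group and independent across
#' groups; one master seed derives the per-group seeds, so results are fully
#' reproducible.
#'
#' @param universe a [promoter_set()].
#' @param genome_index [index_promoters()] result for `universe`.
#' @param group_size promoters per random group (must be < universe size).
#' @param n_groups number of groups.
#' @param cutoffs p-value cutoffs.
#' @param seed master RNG seed.
#' @param collect_z compute per-oligo z-scores (set `FALSE` to skip the
#'   position scans).
#' @param z_min z cutoff used for the `mean_z_gt3`-style count.
#' @return A `calibration_result`: list with `group_size`, `n_groups`,
#'   `cutoffs`, `mean_counts` (mean sub-cutoff oligos per cutoff),
#'   `expected` (analytic expectation per cutoff), `counts` (n_groups x
#'   n_cutoffs matrix), `mean_z_gt` (mean count of sub-max(cutoff) oligos
#'   with z > z_min), `z_values` (all tested-oligo z-scores pooled over
#'   groups, when `collect_z`), `n_restricted`, `seed`.
#' @export
calibrate_fdr <- function(universe, genome_index, group_size = 20L,
                          n_groups = 20L, cutoffs = c(0.01, 0.05, 0.2),
                          seed = 1L, collect_z = TRUE, z_min = 3) {
    stopifnot(inherits(universe, "promoter_set"),
              inherits(genome_index, "oligo_count_index"),
              group_size < length(universe), n_groups >= 1)
    alphabet <- .alphabet_by_name(genome_index$alphabet_name)
    L <- genome_index$L
    cutoffs <- sort(cutoffs)
    p_max <- max(cutoffs)

    set.seed(seed)
    group_seeds <- sample.int(.Machine$integer.max, n_groups)

    counts <- matrix(0L, n_groups, length(cutoffs))
    z_gt <- numeric(n_groups)
    z_all <- list()
    n_restricted <- NA_real_
    for (g in seq_len(n_groups)) {
        set.seed(group_seeds[g])
        ids <- sample(gene_ids(universe), group_size)
        group <- subset_by_ids(universe, ids)
        enr <- oligo_enrichment(index_promoters(group, alphabet, L),
                                genome_index)
        n_restricted <- enr$n_restricted
        p_kept <- enr$pvalue[enr$keep]
        counts[g, ] <- vapply(cutoffs, function(ct) sum(p_kept <= ct),
                              numeric(1))
        if (collect_z && length(enr$code)) {
            words <- decode_oligo(enr$code, alphabet, L)
            z <- vapply(seq_along(words), function(i) {
                pos <- collect_positions(group, words[i], alphabet)
                position_zscore(unlist(pos, use.names = FALSE),
                                universe$window_length, L)$z
            }, numeric(1))
            z_all[[g]] <- z
            z_gt[g] <- sum(enr$keep & enr$pvalue <= p_max & z > z_min)
        }
    }
    mean_counts <- colMeans(counts)
    structure(list(group_size = as.integer(group_size),
                   n_groups = as.integer(n_groups),
                   cutoffs = cutoffs, mean_counts = mean_counts,
                   expected = expected_false_positives(n_restricted, cutoffs),
                   counts = counts, mean_z_gt = mean(z_gt),
                   z_values = unlist(z_all, use.names = FALSE),
                   n_restricted = n_restricted, z_min = z_min,
                   seed = as.integer(seed)),
              class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
    cat("<calibration_result> ", x$n_groups, " random groups of ",
        x$group_size, " promoters; restricted family ", x$n_restricted,
        "\n", sep = "")
    print(data.frame(cutoff = x$cutoffs, mean_count = x$mean_counts,
                     expected = x$expected), row.names = FALSE)
    if (length(x$z_values))
        cat("tested-oligo z: mean ", round(mean(x$z_values), 3), ", sd ",
            round(sd(x$z_values), 3), "; mean count with z > ", x$z_min,
            " at loosest cutoff: ", round(x$mean_z_gt, 2), "\n", sep = "")
    invisible(x)
}
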