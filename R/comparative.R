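#' Conserved p-value of an oligo tested in two species
#'
#' The larger (worse) of the two per-species enrichment p-values. A motif
#' must be over-represented in the orthologous promoter sets of both species
#' to score well, which removes ~99% of single-species false positives.
#' Symmetric and idempotent.
#'
#' @param p1,p2 per-species p-values (vectorized).
#' @return `pmax(p1, p2)`.
#' @examples
#' conserved_pvalue(1.64e-38, 2.91e-35)  # 2.91e-35
#' @export
conserved_pvalue <- function(p1, p2) {
    stopifnot(all(p1 >= 0 & p1 <= 1), all(p2 >= 0 & p2 <= 1))
    pmax(p1, p2)
}

#' Read a two-column ortholog mapping table
#'
#' TSV with one ortholog pair per line (`gene_id_species1 TAB
#' gene_id_species2`), `#` comments allowed; extra columns (e.g. percent
#' identity) are ignored. The mapping must be one-to-one.
#'
#' @param path file path.
#' @return data frame with columns `id1`, `id2`.
#' @export
read_ortholog_map <- function(path) {
    x <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", stringsAsFactors = FALSE)
    ortholog_map(x[[1]], x[[2]])
}

#' @param id1,id2 parallel gene id vectors for the two species.
#' @rdname read_ortholog_map
#' @export
ortholog_map <- function(id1, id2) {
    stopifnot(length(id1) == length(id2))
    if (anyDuplicated(id1) || anyDuplicated(id2))
        stop("ortholog mapping must be one-to-one (duplicate ids found)")
    data.frame(id1 = as.character(id1), id2 = as.character(id2),
               stringsAsFactors = FALSE)
}

#' Conserved-motif discovery over orthologous promoters
#'
#' Restricts a cluster to genes with orthologs, runs the enrichment pass
#' independently in each species (each cluster against its own genome-wide
#' index), joins the tested oligos on reverse-complement-canonical word
#' identity, assigns each the conserved p-value (the larger of the two), and
#' keeps those at or below `cutoff`. Survivors are reported with per-species
#' presence counts, p-values, mean occurrence positions and TSS z-scores,
#' sorted ascending by conserved p-value.
#'
#' @param cluster_ids species-1 gene ids of the co-expressed cluster.
#' @param orthologs an [ortholog_map()] data frame.
#' @param promoters1,promoters2 per-species [promoter_set()] universes.
#' @param genome_index1,genome_index2 per-species [index_promoters()]
#'   results.
#' @param alphabet a [motif_alphabet][alphabet11].
#' @param L word length.
#' @param cutoff conserved p-value cutoff.
#' @param max_candidates cap on per-species sub-cutoff candidates joined.
#' @return data frame: `motif` (species-1 orientation), `m1`, `p1`,
#'   `mean_position1`, `z1`, `m2`, `p2`, `mean_position2`, `z2`,
#'   `conserved_pvalue`.
#' @export
conserved_motif_analysis <- function(cluster_ids, orthologs,
                                     promoters1, promoters2,
                                     genome_index1, genome_index2,
                                     alphabet = alphabet11(), L = 8L,
                                     cutoff = 1e-5, max_candidates = 20000L) {
    ids1 <- intersect(cluster_ids, orthologs$id1)
    if (length(ids1) == 0)
        stop("no cluster gene has an ortholog")
    ids2 <- orthologs$id2[match(ids1, orthologs$id1)]
    cl1 <- subset_by_ids(promoters1, ids1)
    cl2 <- subset_by_ids(promoters2, ids2)

    enr1 <- oligo_enrichment(index_promoters(cl1, alphabet, L), genome_index1,
                             p_keep = cutoff)
    enr2 <- oligo_enrichment(index_promoters(cl2, alphabet, L), genome_index2,
                             p_keep = cutoff)

    # join per-species records on RC-canonical code; each species' p-value
    # must itself clear the cutoff for the max to clear it
    j1 <- .canon_records(enr1, alphabet, L, cutoff, max_candidates)
    j2 <- .canon_records(enr2, alphabet, L, cutoff, max_candidates)
    shared <- merge(j1, j2, by = "canon", suffixes = c("1", "2"))
    shared$conserved_pvalue <- conserved_pvalue(shared$pvalue1, shared$pvalue2)
    shared <- shared[shared$conserved_pvalue <= cutoff, , drop = FALSE]
    shared <- shared[order(shared$conserved_pvalue, shared$canon), ,
                     drop = FALSE]

    nr <- nrow(shared)
    out <- data.frame(motif = if (nr)
        decode_oligo(shared$code1, alphabet, L) else character(0),
        m1 = shared$m1, p1 = shared$pvalue1,
        mean_position1 = rep(NA_real_, nr), z1 = rep(NA_real_, nr),
        m2 = shared$m2, p2 = shared$pvalue2,
        mean_position2 = rep(NA_real_, nr), z2 = rep(NA_real_, nr),
        conserved_pvalue = shared$conserved_pvalue,
        row.names = NULL)
    for (i in seq_len(nrow(out))) {
        w1 <- out$motif[i]
        s1 <- position_zscore(unlist(collect_positions(cl1, w1, alphabet),
                                     use.names = FALSE),
                              promoters1$window_length, L)
        w2 <- decode_oligo(shared$code2[i], alphabet, L)
        s2 <- position_zscore(unlist(collect_positions(cl2, w2, alphabet),
                                     use.names = FALSE),
                              promoters2$window_length, L)
        out$mean_position1[i] <- s1$mean_position; out$z1[i] <- s1$z
        out$mean_position2[i] <- s2$mean_position; out$z2[i] <- s2$z
    }
    out
}

# kept records of an enrichment at or below cutoff, keyed by RC-canonical
# code, at most n_max best
.canon_records <- function(enr, alphabet, L, cutoff, n_max) {
    sel <- which(enr$keep & enr$pvalue <= cutoff)
    sel <- sel[order(enr$pvalue[sel], enr$code[sel])]
    if (length(sel) > n_max) sel <- sel[seq_len(n_max)]
    data.frame(canon = pmin(enr$code[sel], rc_code(enr$code[sel], alphabet, L)),
               code = enr$code[sel], m = enr$m[sel], pvalue = enr$pvalue[sel])
}

#' Genome-wide scan for TSS position-biased motifs
#'
#' Enumerates every `L`-mer with at most `max_wobbles` degenerate letters
#' drawn from the restricted set (`r`, `y`, `s`, `w`, `n` by default; the
#' asymmetric wobbles m and k are excluded), gathers all occurrence
#' instances across every promoter of a genome, and computes each word's
#' mean position and TSS z-score. Words with `z >= z_min` are reported,
#' reverse-complement deduplicated (keeping the higher-z member), sorted by
#' descending z.
#'
#' @param promoters a [promoter_set()] universe (a whole genome's
#'   promoters).
#' @param L word length.
#' @param z_min z-score cutoff for reporting.
#' @param max_wobbles maximum number of degenerate letters per word.
#' @param wobble_letters allowed degenerate letters.
#' @return data frame `motif`, `code`, `canon`, `n` (occurrence instances),
#'   `mean_position`, `zscore`, sorted by descending z, with attributes
#'   `n_enumerated` (words enumerated) and `params`.
#' @export
genome_bias_scan <- function(promoters, L = 8L, z_min = 3,
                             max_wobbles = 2L,
                             wobble_letters = c("r", "y", "s", "w", "n")) {
    stopifnot(inherits(promoters, "promoter_set"),
              all(wobble_letters %in% c("r", "y", "s", "w", "m", "k", "n")))
    alphabet <- alphabet11()
    tal <- occurrence_tally_cpp(unname(promoters$sequences), as.integer(L))
    S <- last_start(promoters$window_length, L)
    mu <- uniform_position_mean(promoters$window_length, L)
    sigma2 <- (S^2 - 1) / 12

    pow4 <- 4^((L - 1):0)
    pow11 <- 11^((L - 1):0)
    wob_digit <- match(wobble_letters, alphabet$letters) - 1
    wob_bases <- lapply(alphabet$match[wobble_letters],
                        function(b) match(b, c("A", "C", "G", "T")) - 1)

    res_code <- list(); res_n <- list(); res_s <- list()
    piece <- 0L; n_enum <- 0
    for (w in 0:max_wobbles) {
        possets <- if (w == 0) list(integer(0)) else
            apply(utils::combn(L, w), 2, identity, simplify = FALSE)
        lettersets <- if (w == 0) list(integer(0)) else {
            g <- do.call(expand.grid, rep(list(seq_along(wobble_letters)), w))
            lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
        }
        for (ps in possets) {
            corepos <- setdiff(seq_len(L), ps)
            nc <- 4^length(corepos)
            # concrete digits of every core, scattered into full base-4 and
            # base-11 codes (wobble positions left at 0)
            idx <- 0:(nc - 1)
            scat4 <- numeric(nc); scat11 <- numeric(nc)
            x <- idx
            for (p in rev(corepos)) {
                d <- x %% 4
                scat4 <- scat4 + d * pow4[p]
                scat11 <- scat11 + d * pow11[p]
                x <- x %/% 4
            }
            for (ls in lettersets) {
                n_enum <- n_enum + nc
                n_vec <- numeric(nc); s_vec <- numeric(nc)
                combos <- if (w == 0) list(integer(0)) else {
                    g <- do.call(expand.grid, lapply(ls, function(li)
                        wob_bases[[li]]))
                    lapply(seq_len(nrow(g)), function(i) as.integer(g[i, ]))
                }
                for (cb in combos) {
                    off <- if (w == 0) 0 else sum(cb * pow4[ps])
                    n_vec <- n_vec + tal$count[scat4 + off + 1]
                    s_vec <- s_vec + tal$pos_sum[scat4 + off + 1]
                }
                keep <- n_vec > 0
                if (!any(keep)) next
                pbar <- s_vec[keep] / n_vec[keep]
                z <- (pbar - mu) / sqrt(sigma2 / n_vec[keep])
                hit <- z >= z_min
                if (!any(hit)) next
                off11 <- if (w == 0) 0 else sum(wob_digit[ls] * pow11[ps])
                piece <- piece + 1L
                res_code[[piece]] <- scat11[keep][hit] + off11
                res_n[[piece]] <- n_vec[keep][hit]
                res_s[[piece]] <- s_vec[keep][hit]
            }
        }
    }
    code <- as.numeric(unlist(res_code))
    n <- as.numeric(unlist(res_n))
    psum <- as.numeric(unlist(res_s))
    if (length(code)) {
        canon <- pmin(code, rc_code(code, alphabet, L))
        ord <- order(-((psum / n - mu) / sqrt(sigma2 / n)), code)
        code <- code[ord]; n <- n[ord]; psum <- psum[ord]
        canon <- canon[ord]
        dup <- duplicated(canon)
        code <- code[!dup]; n <- n[!dup]; psum <- psum[!dup]
        canon <- canon[!dup]
    } else canon <- numeric(0)
    out <- data.frame(
        motif = if (length(code)) decode_oligo(code, alphabet, L)
                else character(0),
        code = code, canon = canon, n = n,
        mean_position = if (length(code)) psum / n else numeric(0),
        zscore = if (length(code))
            (psum / n - mu) / sqrt(sigma2 / n) else numeric(0),
        row.names = NULL)
    attr(out, "n_enumerated") <- n_enum
    attr(out, "params") <- list(L = as.integer(L), z_min = z_min,
                                max_wobbles = as.integer(max_wobbles),
                                wobble_letters = sort(wobble_letters))
    out
}

#' Cross-genome intersection of position-biased motifs
#'
#' Joins two [genome_bias_scan()] results on reverse-complement-canonical
#' word identity and partitions them into motifs biased in both genomes and
#' motifs exclusive to each. Scan parameters (length, degeneracy
#' restriction) must match.
#'
#' @param scan1,scan2 [genome_bias_scan()] results.
#' @return list with `shared` (data frame with per-genome columns suffixed
#'   `1`/`2`), `only1`, `only2`.
#' @export
intersect_biased <- function(scan1, scan2) {
    p1 <- attr(scan1, "params"); p2 <- attr(scan2, "params")
    if (!identical(p1[c("L", "max_wobbles", "wobble_letters")],
                   p2[c("L", "max_wobbles", "wobble_letters")]))
        stop("bias scans were run with different parameters")
    shared <- merge(scan1, scan2, by = "canon", suffixes = c("1", "2"))
    shared <- shared[order(-pmin(shared$zscore1, shared$zscore2)), ,
                     drop = FALSE]
    rownames(shared) <- NULL
    list(shared = shared,
         only1 = scan1[!(scan1$canon %in% scan2$canon), , drop = FALSE],
         only2 = scan2[!(scan2$canon %in% scan1$canon), , drop = FALSE])
}
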