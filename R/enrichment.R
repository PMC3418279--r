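#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability that a cluster of `M` promoters drawn from a
#' genome of `K` promoters, of which `k` contain the oligo, contains it in
#' `m` or more: `P(X >= m)` with `X ~ Hypergeometric(K, k, M)`. Computed in
#' log space (via the log-gamma machinery underlying [stats::phyper()]), so
#' tails of order 1e-40 are exact to double precision. Only over-represented
#' configurations (`m > k*M/K`) are scored; under-represented input is an
#' error, since the tool tests over-representation only.
#'
#' @param m promoters in the cluster containing the oligo.
#' @param M cluster size.
#' @param k promoters in the genome containing the oligo.
#' @param K genome promoter count.
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' hypergeom_pvalue(3, 5, 4, 10)  # 66/252
#' @export
hypergeom_pvalue <- function(m, M, k, K) {
    if (any(m < 0 | m > M | m > k | k > K | M > K))
        stop("require 0 <= m <= min(M, k) and M, k <= K")
    if (any(m * as.numeric(K) <= as.numeric(k) * M))
        stop("under-represented input (m <= k*M/K): over-representation ",
             "p-values only")
    exp(phyper(m - 1, k, K - k, M, lower.tail = FALSE, log.p = TRUE))
}

#' Fold-change enrichment
#'
#' Cluster frequency over genome frequency: `(m/M) / (k/K)`. Equals 1 when
#' the oligo is at its genome-expected frequency, and exceeds 1 for every
#' tested (over-represented) oligo. A ranking measure only; it is more prone
#' to false discovery than the p-value.
#'
#' @inheritParams hypergeom_pvalue
#' @return Numeric vector of ratios.
#' @examples
#' fold_enrichment(64, 712, 1161, 33518)  # ~2.6
#' @export
fold_enrichment <- function(m, M, k, K) {
    if (any(k <= 0)) stop("fold enrichment undefined for k = 0")
    (m / M) / (k / K)
}

#' Expected false-positive oligo count at a p-value cutoff
#'
#' Of the oligos present in fewer than half of the genome's promoters
#' (`n_restricted`; 75,029,949 for 8-mers on the Arabidopsis universe),
#' about half are over-represented in any given cluster and so get a
#' p-value, and reverse-complement deduplication halves the family again:
#' the expected number of null oligos at or below cutoff `p` is
#' `n_restricted * p / 4`.
#'
#' @param n_restricted size of the restricted oligo family.
#' @param p_cutoff p-value cutoff(s).
#' @return Expected count(s).
#' @export
expected_false_positives <- function(n_restricted, p_cutoff) {
    stopifnot(n_restricted >= 0, all(p_cutoff >= 0))
    n_restricted * p_cutoff / 4
}

#' Keep one member of each reverse-complement pair
#'
#' Single-strand scanning counts an oligo and its reverse complement as two
#' entries with (near-)identical statistics; from a p-value-sorted table,
#' only the first-encountered (better-ranked) member of each pair is
#' retained. Palindromic words (`rc(o) == o`) are kept unconditionally.
#'
#' @param records data frame with a `motif` column, sorted ascending by
#'   p-value.
#' @param alphabet a [motif_alphabet][alphabet11].
#' @return The deduplicated data frame.
#' @export
dedupe_reverse_complements <- function(records, alphabet = alphabet11()) {
    stopifnot(is.data.frame(records), "motif" %in% names(records))
    if (nrow(records) == 0) return(records)
    canon <- pmin(encode_oligo(records$motif, alphabet),
                  encode_oligo(rc_oligo(records$motif, alphabet), alphabet))
    records[!duplicated(canon), , drop = FALSE]
}

#' Benjamini-Hochberg q-values
#'
#' BH-adjusted p-values over a tested, reverse-complement-deduplicated oligo
#' family; monotone non-decreasing in p-value rank.
#'
#' @param p numeric vector of p-values.
#' @param family_size size of the tested family the p-values were drawn
#'   from; defaults to `length(p)`.
#' @return q-values.
#' @export
qvalues <- function(p, family_size = length(p)) {
    stopifnot(family_size >= length(p))
    p.adjust(p, method = "BH", n = family_size)
}

#' Score every oligo of a cluster against a genome index
#'
#' The core enrichment pass. An oligo is *tested* iff it is in the
#' restricted family (present in at least one but fewer than half of the
#' genome's promoters, `1 <= k < K/2`) and over-represented in the cluster
#' (`m > k*M/K`). Tested oligos get a hypergeometric upper-tail p-value;
#' reverse-complement pairs are then collapsed to their better-ranked member
#' and BH q-values computed over the deduplicated family.
#'
#' For 8-mers the counter arrays have 214M entries and tens of millions of
#' oligos can be tested in a single cluster, so the pass streams over the
#' arrays in chunks and materializes only records with
#' `pvalue <= p_keep`. The tested-family size and its reverse-complement
#' pair structure are still accounted exactly, so the BH adjustment uses the
#' true family size; with a truncating `p_keep` the q-values of the
#' retained (best) records are exact unless a later-ranked record would
#' have lowered them, in which case they are conservative upper bounds.
#'
#' @param cluster_index `oligo_count_index` of the cluster promoters.
#' @param genome_index `oligo_count_index` of the genome universe, built
#'   with the same alphabet and word length.
#' @param p_keep retention cutoff: records with larger p-values are counted
#'   in the family but not materialized. The default 1 retains everything.
#' @return An `oligo_enrichment` object: parallel vectors `code` (integer
#'   word codes of retained tested oligos, ascending), `m`, `k`, `pvalue`,
#'   `keep` (FALSE for the worse-ranked member of an RC pair), `qvalue` (NA
#'   where not kept), plus `M`, `K`, `n_restricted`, `n_tested` (tested
#'   oligos before RC dedup), `family_size` (after RC dedup), `p_keep`,
#'   `alphabet_name`, `L`.
#' @export
oligo_enrichment <- function(cluster_index, genome_index, p_keep = 1) {
    stopifnot(inherits(cluster_index, "oligo_count_index"),
              inherits(genome_index, "oligo_count_index"),
              cluster_index$alphabet_name == genome_index$alphabet_name,
              cluster_index$L == genome_index$L,
              length(cluster_index$counts) == length(genome_index$counts),
              p_keep > 0, p_keep <= 1)
    M <- cluster_index$n_promoters
    K <- genome_index$n_promoters
    alphabet <- .alphabet_by_name(genome_index$alphabet_name)
    L <- genome_index$L

    scan <- .tested_scan(cluster_index$counts, genome_index$counts, M, K,
                         alphabet, L, p_keep)
    code <- scan$code; m <- scan$m; k <- scan$k; p <- scan$pvalue
    # both members of any RC pair with p <= p_keep are retained, so pair
    # collapse within the retained set is exact
    canon <- pmin(code, rc_code(code, alphabet, L))
    ord <- order(p, code)
    keep <- logical(length(p))
    keep[ord] <- !duplicated(canon[ord])
    # retained kept records are the best-ranked of the deduplicated family;
    # BH with the true family size, step-up from the worst retained rank
    family_size <- scan$family_size
    q <- rep(NA_real_, length(p))
    kp <- which(keep)
    if (length(kp)) {
        kp <- kp[order(p[kp], code[kp])]
        bh <- pmin(1, p[kp] * family_size / seq_along(kp))
        q[kp] <- rev(cummin(rev(bh)))
    }

    structure(list(code = code, m = m, k = k, pvalue = p, keep = keep,
                   qvalue = q, M = M, K = K,
                   n_restricted = scan$n_restricted,
                   n_tested = scan$n_tested, family_size = family_size,
                   p_keep = p_keep,
                   alphabet_name = genome_index$alphabet_name, L = L),
              class = "oligo_enrichment")
}

#' @export
print.oligo_enrichment <- function(x, ...) {
    cat("<oligo_enrichment> ", x$n_tested, " tested oligos (family ",
        x$family_size, " after RC dedup), ", length(x$code),
        " retained at p <= ", format(x$p_keep), "; cluster M=", x$M,
        " vs genome K=", x$K, ", restricted family ", x$n_restricted,
        "\n", sep = "")
    invisible(x)
}

# Chunked scan of the dense counter arrays: find tested oligos, their
# p-values, the restricted-family size, and the RC-deduplicated family
# size, materializing only records with p <= p_keep (the arrays reach 214M
# entries for 8-mers, and a cluster can test tens of millions of oligos).
.tested_scan <- function(cluster_counts, genome_counts, M, K, alphabet, L,
                         p_keep, chunk = 8000000L) {
    n <- length(genome_counts)
    half <- K / 2
    codes <- list(); ms <- list(); ks <- list(); ps <- list()
    n_restricted <- 0; n_tested <- 0; n_both_nonpal <- 0
    i <- 1L; piece <- 1L
    while (i <= n) {
        j <- min(i + chunk - 1L, n)
        kk <- genome_counts[i:j]
        restricted <- kk >= 1L & kk < half
        n_restricted <- n_restricted + sum(restricted)
        mm <- cluster_counts[i:j]
        sel <- which(restricted & (as.numeric(mm) * K > as.numeric(kk) * M))
        if (length(sel)) {
            code <- (i:j)[sel] - 1   # 0-based word codes
            m <- mm[sel]; k <- kk[sel]
            n_tested <- n_tested + length(sel)
            # is the reverse complement tested too? (array lookup at rc code)
            rc <- rc_code(code, alphabet, L)
            nonpal <- rc != code
            krc <- genome_counts[rc + 1]; mrc <- cluster_counts[rc + 1]
            rc_tested <- krc >= 1L & krc < half &
                (as.numeric(mrc) * K > as.numeric(krc) * M)
            n_both_nonpal <- n_both_nonpal + sum(nonpal & rc_tested)
            p <- exp(phyper(m - 1, k, K - k, M, lower.tail = FALSE,
                            log.p = TRUE))
            retain <- p <= p_keep
            if (any(retain)) {
                codes[[piece]] <- code[retain]
                ms[[piece]] <- m[retain]
                ks[[piece]] <- k[retain]
                ps[[piece]] <- p[retain]
                piece <- piece + 1L
            }
        }
        i <- j + 1L
    }
    list(code = as.numeric(unlist(codes)),
         m = as.integer(unlist(ms)), k = as.integer(unlist(ks)),
         pvalue = as.numeric(unlist(ps)),
         n_restricted = n_restricted, n_tested = n_tested,
         family_size = n_tested - n_both_nonpal / 2)
}

#' Ranked table of enriched oligos
#'
#' Materializes the kept (RC-deduplicated) records of an
#' [oligo_enrichment()] as a data frame sorted ascending by p-value, with
#' decoded motif strings and fold enrichment, optionally truncated.
#'
#' @param enrichment an `oligo_enrichment`.
#' @param p_cutoff keep records with `pvalue <= p_cutoff`.
#' @param n_max keep at most this many top records.
#' @return data frame with columns `code`, `motif`, `m`, `k`, `M`, `K`,
#'   `pvalue`, `qvalue`, `fold`.
#' @export
enrichment_table <- function(enrichment, p_cutoff = 1, n_max = Inf) {
    stopifnot(inherits(enrichment, "oligo_enrichment"))
    alphabet <- .alphabet_by_name(enrichment$alphabet_name)
    sel <- which(enrichment$keep & enrichment$pvalue <= p_cutoff)
    sel <- sel[order(enrichment$pvalue[sel], enrichment$code[sel])]
    if (length(sel) > n_max) sel <- sel[seq_len(n_max)]
    if (length(sel) == 0)
        return(data.frame(code = numeric(0), motif = character(0),
                          m = integer(0), k = integer(0), M = integer(0),
                          K = integer(0), pvalue = numeric(0),
                          qvalue = numeric(0), fold = numeric(0)))
    data.frame(
        code = enrichment$code[sel],
        motif = decode_oligo(enrichment$code[sel], alphabet, enrichment$L),
        m = enrichment$m[sel], k = enrichment$k[sel],
        M = enrichment$M, K = enrichment$K,
        pvalue = enrichment$pvalue[sel], qvalue = enrichment$qvalue[sel],
        fold = fold_enrichment(enrichment$m[sel], enrichment$M,
                               enrichment$k[sel], enrichment$K),
        row.names = NULL)
}
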