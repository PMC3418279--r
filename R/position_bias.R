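#' Uniform-placement constants for the position model
#'
#' For `L`-mers in windows of `window_length` bp there are
#' `S = window_length - L + 1` valid 1-based starts (993 for 8-mers in
#' 1000-bp promoters). Under the null of uniform placement the expected
#' start is `mu = (1 + S) / 2` (497 for the canonical configuration) and the
#' per-instance variance is the discrete-uniform variance
#' `sigma^2 = (S^2 - 1) / 12`.
#'
#' @param window_length promoter window length in bp.
#' @param L word length.
#' @return `uniform_position_mean`: the null mean start `mu`.
#' @export
uniform_position_mean <- function(window_length, L) {
    (1 + last_start(window_length, L)) / 2
}

#' @return `last_start`: the maximum valid start `S`.
#' @rdname uniform_position_mean
#' @export
last_start <- function(window_length, L) {
    stopifnot(window_length >= L)
    window_length - L + 1
}

#' TSS position-bias z-score
#'
#' Occurrence starts of a non-functional oligo should be uniform over the
#' `S` valid positions; an oligo with `n` instances then has mean-position
#' sampling variance `(S^2 - 1) / (12 n)`. The z-score standardizes the
#' observed mean start against this null:
#' `z = (p_bar - mu) / sqrt((S^2 - 1) / (12 n))`. Positive z means the
#' occurrences sit closer to the TSS (position `S` is adjacent to it,
#' position 1 is `-window_length`); z is 0 exactly when the mean start
#' equals `mu`, and grows as `sqrt(n)` at a fixed displacement. `n` counts
#' every occurrence instance (several per promoter allowed), unlike the
#' presence counts `m` and `k`.
#'
#' @param positions integer vector of 1-based occurrence starts, pooled over
#'   the selected promoters.
#' @inheritParams uniform_position_mean
#' @return A `bias_stats` list: `n`, `mean_position`, `z`, `mu`, `sigma2`,
#'   `S`.
#' @examples
#' position_zscore(c(400, 500, 600), 1000, 8)
#' @export
position_zscore <- function(positions, window_length, L) {
    S <- last_start(window_length, L)
    if (length(positions) == 0)
        stop("z-score undefined for an oligo with no occurrences")
    if (any(positions < 1 | positions > S))
        stop("positions must lie in 1..", S)
    mu <- (1 + S) / 2
    sigma2 <- (S^2 - 1) / 12
    n <- length(positions)
    p_bar <- mean(positions)
    structure(list(n = n, mean_position = p_bar,
                   z = (p_bar - mu) / sqrt(sigma2 / n),
                   mu = mu, sigma2 = sigma2, S = S),
              class = "bias_stats")
}

#' Binned positional occurrence profile
#'
#' Occurrence counts per position bin, ordered from the upstream end
#' (position 1, i.e. -window_length) toward the TSS; the density view of the
#' same bias the z-score summarizes. The last bin is truncated when
#' `bin_width` does not divide the start range.
#'
#' @inheritParams position_zscore
#' @param bin_width bin width in bp.
#' @return data frame with `bin_start`, `bin_end`, `count`, `density`
#'   (count per bp of bin); counts sum to `length(positions)`.
#' @export
position_profile <- function(positions, window_length, L, bin_width = 50L) {
    S <- last_start(window_length, L)
    stopifnot(bin_width >= 1, all(positions >= 1 & positions <= S))
    starts <- seq(1L, S, by = bin_width)
    ends <- pmin(starts + bin_width - 1L, S)
    idx <- findInterval(positions, starts)
    count <- tabulate(idx, nbins = length(starts))
    data.frame(bin_start = starts, bin_end = ends, count = count,
               density = count / (ends - starts + 1))
}

#' Motif qualification from p-value and z-score
#'
#' An oligo qualifies as a potential motif when its enrichment p-value is
#' below the strict cutoff, or when it sits in the relaxed p-value band and
#' additionally shows TSS position bias: `p < p_strict`, or
#' `p_strict <= p <= p_relaxed` with `z > z_min`. Defaults follow the
#' calibrated cutoffs 1e-7 / 1e-5 / 3.
#'
#' @param pvalue numeric vector of enrichment p-values.
#' @param z numeric vector of TSS z-scores.
#' @param p_strict strict p-value cutoff (qualifies regardless of z).
#' @param p_relaxed relaxed p-value cutoff (requires z).
#' @param z_min z-score cutoff for the relaxed band.
#' @return Logical vector.
#' @export
qualify_motif <- function(pvalue, z, p_strict = 1e-7, p_relaxed = 1e-5,
                          z_min = 3) {
    stopifnot(p_strict <= p_relaxed)
    pvalue < p_strict | (pvalue <= p_relaxed & z > z_min)
}
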