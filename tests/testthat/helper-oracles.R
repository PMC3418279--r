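# Independent brute-force oracles. These deliberately avoid the package's
# optimized code paths (the C++ indexer, stats::phyper) so that agreement is
# a genuine cross-check.

# presence counts for every code by direct window matching
oracle_presence_counts <- function(promoters, alphabet, L) {
    n_codes <- length(alphabet$letters)^L
    words <- decode_oligo(seq_len(n_codes) - 1, alphabet, L)
    counts <- integer(n_codes)
    for (s in promoters$sequences) {
        wins <- substring(s, seq_len(nchar(s) - L + 1),
                          seq_len(nchar(s) - L + 1) + L - 1)
        for (ci in seq_len(n_codes))
            if (any(oligo_matches(words[ci], wins, alphabet)))
                counts[ci] <- counts[ci] + 1L
    }
    counts
}

# hypergeometric upper tail by exhaustive enumeration of the pmf via choose()
oracle_hyper_tail <- function(m, M, k, K) {
    i <- m:min(M, k)
    sum(choose(k, i) * choose(K - k, M - i)) / choose(K, M)
}

# random degenerate words
random_words <- function(n, alphabet, L) {
    m <- matrix(sample(alphabet$letters, n * L, replace = TRUE), nrow = n)
    do.call(paste0, asplit(m, 2))
}

# random concrete promoter sequences (no N)
random_seqs <- function(n, width, prefix = "g") {
    s <- vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), width, replace = TRUE),
              collapse = ""), character(1))
    names(s) <- paste0(prefix, seq_len(n))
    s
}
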