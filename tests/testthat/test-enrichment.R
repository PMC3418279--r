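test_that("hypergeometric upper tail matches exhaustive enumeration", {
    expect_equal(hypergeom_pvalue(3, 5, 4, 10), 66 / 252, tolerance = 1e-12)
    # fully-contained tail: p = prod (k - i) / (K - i), i = 0..M-1
    expect_equal(hypergeom_pvalue(4, 4, 6, 1000),
                 prod((6 - 0:3) / (1000 - 0:3)), tolerance = 1e-12)
    expect_error(hypergeom_pvalue(1, 10, 5, 10), "under-represented")
    expect_error(hypergeom_pvalue(6, 5, 8, 10), ".")
})

test_that("p-value is monotone in m and within (0, 1]", {
    for (m in 3:8) {
        p <- hypergeom_pvalue(m:8, 8, 8, 40)
        expect_true(all(diff(p) < 0))
        expect_true(all(p > 0 & p <= 1))
    }
})

test_that("log-space evaluation is exact deep in the tail", {
    # m = M = k fully contained, huge universe: closed form ~1e-42
    p <- hypergeom_pvalue(15, 15, 15, 33518)
    expect_equal(p, prod((15 - 0:14) / (33518 - 0:14)), tolerance = 1e-10)
    expect_lt(p, 1e-40)
})

test_that("fold enrichment reproduces printed in-paper ratios", {
    expect_equal(round(fold_enrichment(64, 712, 1161, 33518), 1), 2.6)
    expect_equal(round(fold_enrichment(203, 712, 4185, 33518), 1), 2.3)
    expect_equal(fold_enrichment(10, 100, 50, 500), 1.0)
    expect_error(fold_enrichment(1, 10, 0, 100), "k = 0")
})

test_that("expected false positives follow the linear formula", {
    expect_equal(expected_false_positives(75029949, 1e-7), 1.8757, tolerance = 1e-4)
    expect_equal(expected_false_positives(75029949, 1e-5), 187.57, tolerance = 1e-4)
    expect_equal(expected_false_positives(75029949, 0), 0)
})

test_that("reverse-complement pairs collapse to the better-ranked member", {
    rec <- data.frame(motif = c("AAAAAAAA", "TTTTTTTT", "ACGTACGT"),
                      pvalue = c(1e-9, 1e-8, 1e-7))
    out <- dedupe_reverse_complements(rec)
    # ACGTACGT is palindromic: kept unconditionally
    expect_identical(out$motif, c("AAAAAAAA", "ACGTACGT"))
    # pairing bound: at most half the input can be removed
    set.seed(59)
    w <- unique(random_words(400, alphabet11(), 8L))
    rec2 <- data.frame(motif = w, pvalue = sort(runif(length(w))))
    out2 <- dedupe_reverse_complements(rec2)
    expect_gte(nrow(out2), nrow(rec2) / 2)
})

test_that("q-values are BH over the tested family", {
    expect_equal(qvalues(0.01), 0.01)
    expect_equal(qvalues(rep(0.03, 7)), rep(0.03, 7))
    set.seed(61)
    p <- runif(50)
    q <- qvalues(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_equal(q, p.adjust(p, "BH"))
})

test_that("the enrichment pass finds exactly the over-represented oligos", {
    set.seed(67)
    seqs <- random_seqs(60, 40)
    u <- promoter_set(seqs, 40)
    cl <- subset_by_ids(u, names(seqs)[1:12])
    gidx <- index_promoters(u, alphabet11(), 3L)
    cidx <- index_promoters(cl, alphabet11(), 3L)
    enr <- oligo_enrichment(cidx, gidx)
    K <- 60; M <- 12
    # reconstruct the tested set directly from the two counter arrays
    k <- gidx$counts; m <- cidx$counts
    tested <- which(k >= 1 & k < K / 2 & m * K > k * M) - 1
    expect_identical(enr$code, as.numeric(tested))
    expect_equal(enr$n_tested, length(tested))
    expect_equal(enr$n_restricted, sum(k >= 1 & k < K / 2))
    # p-values agree with the exhaustive-enumeration oracle
    po <- mapply(oracle_hyper_tail, enr$m, M, enr$k, K)
    expect_equal(enr$pvalue, unname(po), tolerance = 1e-10)
    # family size equals a direct RC-dedup of the tested set
    canon <- pmin(tested, promotif:::rc_code(tested, alphabet11(), 3L))
    expect_equal(enr$family_size, length(unique(canon)))
    # keep flags: one member per canonical pair, the smaller p
    expect_equal(sum(enr$keep), length(unique(canon)))
    # q-values on kept records equal p.adjust over the deduped family
    kp <- enr$keep
    expect_equal(sort(enr$qvalue[kp]),
                 sort(p.adjust(enr$pvalue[kp], "BH")), tolerance = 1e-12)
})

test_that("truncated retention keeps counts and best records exact", {
    set.seed(71)
    seqs <- random_seqs(50, 40)
    u <- promoter_set(seqs, 40)
    cl <- subset_by_ids(u, names(seqs)[1:10])
    gidx <- index_promoters(u, alphabet11(), 3L)
    cidx <- index_promoters(cl, alphabet11(), 3L)
    full <- oligo_enrichment(cidx, gidx)
    cut <- stats::quantile(full$pvalue, 0.2)
    trunc <- oligo_enrichment(cidx, gidx, p_keep = cut)
    expect_equal(trunc$n_tested, full$n_tested)
    expect_equal(trunc$family_size, full$family_size)
    sel <- full$pvalue <= cut
    expect_identical(trunc$code, full$code[sel])
    expect_identical(trunc$keep, full$keep[sel])
    tab_f <- enrichment_table(full, p_cutoff = cut)
    tab_t <- enrichment_table(trunc)
    expect_identical(tab_f$motif, tab_t$motif)
    expect_equal(tab_f$pvalue, tab_t$pvalue)
})
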