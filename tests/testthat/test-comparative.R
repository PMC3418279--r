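test_that("conserved p-value is the worse of the two species", {
    # printed per-species pairs from the two-species cluster analysis
    expect_equal(conserved_pvalue(1.64e-38, 2.91e-35), 2.91e-35)
    expect_equal(conserved_pvalue(6.57e-06, 2.61e-06), 6.57e-06)
    # symmetric and idempotent
    expect_equal(conserved_pvalue(2.91e-35, 1.64e-38), 2.91e-35)
    expect_equal(conserved_pvalue(0.3, 0.3), 0.3)
    expect_identical(conserved_pvalue(c(0.1, 0.5), c(0.2, 0.4)), c(0.2, 0.5))
})

test_that("ortholog maps must be one-to-one", {
    expect_error(ortholog_map(c("a", "a"), c("x", "y")), "one-to-one")
    expect_error(ortholog_map(c("a", "b"), c("x", "x")), "one-to-one")
    f <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("# orthologs", "at1\tal1", "at2\tal2"), f)
    om <- read_ortholog_map(f)
    expect_identical(om$id1, c("at1", "at2"))
    expect_identical(om$id2, c("al1", "al2"))
})

# shared reduced-scale two-species fixture: 5-mer planted TSS-proximally in
# 80% of a 30-gene cluster, 15% inter-species divergence (~85% identity)
ortho_fixture <- function(conserved, rate = 0.15) {
    spec <- fixture_spec(n_promoters = 150, window_length = 150,
                         cluster_size = 30,
                         plants = list(plant_motif("rGTCA",
                                                   cluster_fraction = 0.8,
                                                   from = 100, to = 146)),
                         seed = 1, substitution_rate = rate)
    generate_ortholog_fixture(spec, conserved = conserved)
}

test_that("a protected planted motif survives the conserved analysis", {
    ofx <- ortho_fixture(conserved = TRUE)
    fx <- ofx$fixture1
    g1 <- index_promoters(fx$genome, alphabet11(), 5L)
    g2 <- index_promoters(ofx$promoters2, alphabet11(), 5L)
    res <- conserved_motif_analysis(fx$cluster_ids, ofx$orthologs,
                                    fx$genome, ofx$promoters2, g1, g2,
                                    L = 5L, cutoff = 1e-5)
    expect_gt(nrow(res), 0)
    expect_true(all(res$conserved_pvalue == pmax(res$p1, res$p2)))
    expect_true(all(res$conserved_pvalue <= 1e-5))
    expect_true(all(diff(res$conserved_pvalue) >= 0))
    # the top survivor's match set overlaps the planted motif's ("rGTCA"
    # realizes as AGTCA or GGTCA)
    expect_true(oligo_matches(res$motif[1], "AGTCA") ||
                oligo_matches(res$motif[1], "GGTCA"))
    # conserved filtering removes most single-species noise
    enr1 <- oligo_enrichment(
        index_promoters(subset_by_ids(fx$genome, fx$cluster_ids),
                        alphabet11(), 5L), g1, p_keep = 1e-5)
    expect_lt(nrow(res), sum(enr1$keep & enr1$pvalue <= 1e-5))
})

test_that("an unprotected plant at high divergence is dropped by the max rule", {
    ofx <- ortho_fixture(conserved = FALSE, rate = 0.3)
    fx <- ofx$fixture1
    g1 <- index_promoters(fx$genome, alphabet11(), 5L)
    g2 <- index_promoters(ofx$promoters2, alphabet11(), 5L)
    res <- conserved_motif_analysis(fx$cluster_ids, ofx$orthologs,
                                    fx$genome, ofx$promoters2, g1, g2,
                                    L = 5L, cutoff = 1e-5)
    # species 1 alone finds the plant easily...
    enr1 <- oligo_enrichment(
        index_promoters(subset_by_ids(fx$genome, fx$cluster_ids),
                        alphabet11(), 5L), g1, p_keep = 1e-5)
    expect_gt(sum(enr1$keep & enr1$pvalue <= 1e-5), 0)
    # ...but the conserved analysis rejects it
    expect_equal(nrow(res), 0)
})

test_that("restricted-degeneracy enumeration matches the combinatorial count", {
    set.seed(103)
    ps <- promoter_set(random_seqs(30, 60), 60)
    for (L in c(4L, 5L)) {
        scan <- genome_bias_scan(ps, L = L, z_min = -Inf, max_wobbles = 2L)
        expect_equal(attr(scan, "n_enumerated"),
                     4^L + L * 5 * 4^(L - 1) + choose(L, 2) * 25 * 4^(L - 2))
        # no word carries more than 2 degenerate letters, none from {m, k}
        deg <- vapply(strsplit(scan$motif, ""), function(ch)
            sum(ch %in% c("r", "y", "s", "w", "n")), numeric(1))
        expect_true(all(deg <= 2))
        expect_false(any(grepl("[mk]", scan$motif)))
    }
})

test_that("the genome-wide bias scan recovers a planted TSS-proximal element", {
    spec <- fixture_spec(n_promoters = 120, window_length = 300,
                         cluster_size = 10,
                         plants = list(plant_motif("GGCCA",
                                                   cluster_fraction = 0,
                                                   genome_fraction = 0.6,
                                                   from = 250, to = 296)),
                         seed = 8)
    fx <- generate_fixture(spec)
    scan <- genome_bias_scan(fx$genome, L = 5L, z_min = 3)
    expect_gt(nrow(scan), 0)
    # the top word matches the planted element's sites
    expect_true(oligo_matches(scan$motif[1], "GGCCA"))
    expect_gt(scan$zscore[1], 5)
    # z agrees with a direct position scan for the top word
    pos <- unlist(collect_positions(fx$genome, scan$motif[1]),
                  use.names = FALSE)
    direct <- position_zscore(pos, 300, 5L)
    expect_equal(scan$n[1], direct$n)
    expect_equal(scan$zscore[1], direct$z, tolerance = 1e-10)
    # RC-deduplicated output
    expect_false(anyDuplicated(scan$canon) > 0)
})

test_that("a null genome yields few biased survivors", {
    set.seed(107)
    ps <- promoter_set(random_seqs(150, 120), 120)
    scan <- genome_bias_scan(ps, L = 4L, z_min = 3)
    n_enum <- attr(scan, "n_enumerated")
    # Gaussian tail bound: ~0.00135 per word before dedup; allow generous
    # slack for correlated words sharing sites
    expect_lt(nrow(scan), n_enum * 0.00135 * 5)
})

test_that("cross-genome intersection partitions both scans", {
    set.seed(109)
    ps1 <- promoter_set(random_seqs(40, 80), 80)
    ps2 <- promoter_set(random_seqs(40, 80, prefix = "h"), 80)
    s1 <- genome_bias_scan(ps1, L = 4L, z_min = 1)
    s2 <- genome_bias_scan(ps2, L = 4L, z_min = 1)
    both <- intersect_biased(s1, s2)
    expect_equal(nrow(both$shared) + nrow(both$only1), nrow(s1))
    expect_equal(nrow(both$shared) + nrow(both$only2), nrow(s2))
    # identical scans share everything
    self <- intersect_biased(s1, s1)
    expect_equal(nrow(self$shared), nrow(s1))
    expect_equal(nrow(self$only1), 0)
    # parameter mismatch is refused
    s3 <- genome_bias_scan(ps2, L = 5L, z_min = 1)
    expect_error(intersect_biased(s1, s3), "parameters")
})
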