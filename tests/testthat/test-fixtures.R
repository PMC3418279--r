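test_that("fixtures are byte-identical for identical seeds", {
    spec <- fixture_spec(n_promoters = 40, window_length = 60,
                         cluster_size = 10,
                         plants = list(plant_motif("rGTCA", 0.7,
                                                   from = 40, to = 56)),
                         seed = 12)
    a <- generate_fixture(spec)
    b <- generate_fixture(spec)
    expect_identical(a$genome$sequences, b$genome$sequences)
    expect_identical(a$cluster_ids, b$cluster_ids)
    expect_identical(a$truth, b$truth)
    spec2 <- fixture_spec(n_promoters = 40, window_length = 60,
                          cluster_size = 10, seed = 13)
    expect_false(identical(generate_fixture(spec2)$genome$sequences,
                           a$genome$sequences))
})

test_that("planted instances are where the truth table says", {
    spec <- fixture_spec(n_promoters = 60, window_length = 80,
                         cluster_size = 20,
                         plants = list(plant_motif("ksyrw", 0.9,
                                                   genome_fraction = 0.2,
                                                   from = 60, to = 76)),
                         seed = 21)
    fx <- generate_fixture(spec)
    expect_gt(nrow(fx$truth), 0)
    for (i in seq_len(nrow(fx$truth))) {
        s <- fx$genome$sequences[[fx$truth$gene_id[i]]]
        win <- substr(s, fx$truth$start[i], fx$truth$start[i] + 4)
        expect_identical(win, fx$truth$word[i])
        expect_true(oligo_matches(fx$truth$motif[i], win))
        expect_true(fx$truth$start[i] >= 60 && fx$truth$start[i] <= 76)
    }
    # cluster fraction is respected in expectation (loose binomial check)
    n_cl <- sum(fx$truth$in_cluster)
    expect_gt(n_cl, 20 * 0.9 - 3 * sqrt(20 * 0.9 * 0.1))
})

test_that("ortholog fixtures mutate at the requested rate, except plants", {
    spec <- fixture_spec(n_promoters = 30, window_length = 100,
                         cluster_size = 10,
                         plants = list(plant_motif("rGTCAAmn", 1.0,
                                                   from = 50, to = 93)),
                         seed = 33, substitution_rate = 0.15)
    ofx <- generate_ortholog_fixture(spec, conserved = TRUE)
    s1 <- ofx$fixture1$genome$sequences
    s2 <- ofx$promoters2$sequences
    expect_identical(ofx$orthologs$id1, names(s1))
    expect_identical(ofx$orthologs$id2, names(s2))
    diffs <- mapply(function(a, b)
        sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]), s1, s2)
    # protected plant windows are mutation-free, so the realized rate sits a
    # little below the nominal one; allow binomial noise on 3000 bases
    expect_equal(mean(diffs) / 100, 0.15, tolerance = 0.15)
    # protected plants are intact in species 2
    tr <- ofx$fixture1$truth
    id2_of <- setNames(ofx$orthologs$id2, ofx$orthologs$id1)
    for (i in seq_len(nrow(tr))) {
        win2 <- substr(s2[[id2_of[[tr$gene_id[i]]]]], tr$start[i],
                       tr$start[i] + 7)
        expect_identical(win2, tr$word[i])
    }
    # zero divergence: species identical up to renaming
    spec0 <- fixture_spec(n_promoters = 10, window_length = 50,
                          cluster_size = 5, seed = 3,
                          substitution_rate = 0)
    ofx0 <- generate_ortholog_fixture(spec0)
    expect_identical(unname(ofx0$promoters2$sequences),
                     unname(ofx0$fixture1$genome$sequences))
})

test_that("an end-to-end run on a planted fixture ranks the plant first", {
    spec <- fixture_spec(n_promoters = 150, window_length = 150,
                         cluster_size = 30,
                         plants = list(plant_motif("rGTCA", 0.8,
                                                   from = 100, to = 146)),
                         seed = 1)
    fx <- generate_fixture(spec)
    disc <- discover_motifs(fx$genome, fx$cluster_ids, L = 5L,
                            stop_below = 0)
    expect_gt(nrow(disc$majors), 0)
    top <- disc$majors$motif[1]
    expect_true(oligo_matches(top, "AGTCA") || oligo_matches(top, "GGTCA"))
    expect_gt(disc$majors$zscore[1], 3)
    # variants of the plant were candidates but got absorbed: at most one
    # major matches the planted family
    fam <- vapply(disc$majors$motif, function(mo)
        oligo_matches(mo, "AGTCA") || oligo_matches(mo, "GGTCA"), logical(1))
    expect_equal(sum(fam), 1)
    cand_fam <- vapply(disc$candidates$motif, function(mo)
        oligo_matches(mo, "AGTCA") || oligo_matches(mo, "GGTCA"), logical(1))
    expect_gt(sum(cand_fam), 1)
    # TSV report round-trip
    f <- withr::local_tempfile(fileext = ".tsv")
    write_discovery_tsv(disc, f)
    tab <- utils::read.delim(f, comment.char = "#")
    expect_equal(tab$motif, disc$majors$motif)
})
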