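#' Specification of a synthetic promoter fixture
#'
#' Describes a synthetic promoter universe for pipeline testing: an i.i.d.
#' background at a chosen base composition (Arabidopsis-like AT-richness by
#' default), a designated cluster of promoters, and a list of planted
#' degenerate motifs. Each plant names a motif, the fraction of cluster
#' promoters carrying one instance, the fraction of the remaining genome
#' carrying one, and a placement model (uniform over all valid starts, or
#' confined to a TSS-proximal start interval). Planted instances realize a
#' concrete word by sampling each degenerate position uniformly from its
#' match set. The same seed reproduces the fixture byte-identically.
#'
#' @param n_promoters universe size.
#' @param window_length promoter length in bp.
#' @param cluster_size number of cluster promoters.
#' @param base_comp named base probabilities (A, C, G, T).
#' @param plants list of [plant_motif()] entries.
#' @param seed master RNG seed.
#' @param species species label.
#' @param substitution_rate per-base substitution rate applied between the
#'   two species of an ortholog fixture (0.15 emulates ~85% promoter
#'   identity).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_promoters = 200L, window_length = 1000L,
                         cluster_size = 50L,
                         base_comp = c(A = 0.33, C = 0.17, G = 0.17, T = 0.33),
                         plants = list(), seed = 1L,
                         species = "synthetic",
                         substitution_rate = 0.15) {
    stopifnot(n_promoters >= 2, cluster_size >= 1,
              cluster_size <= n_promoters, window_length >= 20,
              identical(sort(names(base_comp)), c("A", "C", "G", "T")),
              abs(sum(base_comp) - 1) < 1e-8,
              substitution_rate >= 0, substitution_rate <= 0.5)
    for (p in plants) stopifnot(inherits(p, "plant_motif"))
    structure(list(n_promoters = as.integer(n_promoters),
                   window_length = as.integer(window_length),
                   cluster_size = as.integer(cluster_size),
                   base_comp = base_comp[c("A", "C", "G", "T")],
                   plants = plants, seed = as.integer(seed),
                   species = species,
                   substitution_rate = substitution_rate),
              class = "fixture_spec")
}

#' @param motif degenerate word to plant.
#' @param cluster_fraction fraction of cluster promoters receiving one
#'   instance.
#' @param genome_fraction fraction of non-cluster promoters receiving one.
#' @param from,to start-position interval for placement (1-based; `NULL`
#'   `to` means the last valid start). `from = 1, to = NULL` is uniform
#'   placement; a TSS-proximal interval such as 800..986 in a 1000-bp window
#'   emulates the position bias of real motifs.
#' @rdname fixture_spec
#' @export
plant_motif <- function(motif, cluster_fraction = 0.7, genome_fraction = 0,
                        from = 1L, to = NULL) {
    stopifnot(cluster_fraction >= 0, cluster_fraction <= 1,
              genome_fraction >= 0, genome_fraction <= 1, from >= 1)
    structure(list(motif = as_oligo(motif),
                   cluster_fraction = cluster_fraction,
                   genome_fraction = genome_fraction,
                   from = as.integer(from), to = to),
              class = "plant_motif")
}

#' Generate a synthetic promoter universe with planted motifs
#'
#' Realizes a [fixture_spec()]: i.i.d. background promoters, a random
#' cluster, planted motif instances spliced in at sampled positions, and a
#' machine-readable truth table for recovery scoring. All randomness derives
#' from the spec's seed through named sub-streams (background, cluster,
#' plants), so identical specs give identical fixtures.
#'
#' @param spec a `fixture_spec`.
#' @return list with `genome` (a [promoter_set()]), `cluster_ids`, `truth`
#'   (data frame: gene_id, motif, start, word, in_cluster), `spec`.
#' @export
generate_fixture <- function(spec) {
    stopifnot(inherits(spec, "fixture_spec"))
    set.seed(spec$seed)
    streams <- sample.int(.Machine$integer.max, 3)

    set.seed(streams[1])
    ids <- sprintf("g%05d", seq_len(spec$n_promoters))
    seqs <- .random_promoters(spec$n_promoters, spec$window_length,
                              spec$base_comp)
    names(seqs) <- ids

    set.seed(streams[2])
    cluster_ids <- sort(sample(ids, spec$cluster_size))

    set.seed(streams[3])
    truth <- list()
    for (p in spec$plants) {
        L <- nchar(p$motif)
        lastpos <- spec$window_length - L + 1
        to <- if (is.null(p$to)) lastpos else min(p$to, lastpos)
        stopifnot(p$from <= to)
        in_cl <- names(seqs) %in% cluster_ids
        take <- (in_cl & stats::runif(length(seqs)) < p$cluster_fraction) |
                (!in_cl & stats::runif(length(seqs)) < p$genome_fraction)
        for (i in which(take)) {
            word <- .realize_word(p$motif)
            start <- if (p$from == to) p$from else
                sample(seq.int(p$from, to), 1)
            substr(seqs[i], start, start + L - 1) <- word
            truth[[length(truth) + 1]] <-
                data.frame(gene_id = names(seqs)[i], motif = p$motif,
                           start = start, word = word,
                           in_cluster = in_cl[i])
        }
    }
    truth <- if (length(truth)) do.call(rbind, truth) else
        data.frame(gene_id = character(0), motif = character(0),
                   start = integer(0), word = character(0),
                   in_cluster = logical(0))
    list(genome = promoter_set(seqs, spec$window_length, spec$species),
         cluster_ids = cluster_ids, truth = truth, spec = spec)
}

#' Generate an orthologous two-species fixture
#'
#' Builds the species-1 fixture with [generate_fixture()], then derives
#' species-2 promoters as mutated copies under the spec's per-base
#' substitution rate. When `conserved = TRUE`, planted motif instances are
#' re-spliced after mutation (the motif is under selection in both
#' species); otherwise they diverge like background. The ortholog map links
#' every gene pair one-to-one.
#'
#' @param spec a [fixture_spec()].
#' @param conserved protect planted instances from inter-species mutation.
#' @return list with `fixture1` (the [generate_fixture()] result),
#'   `promoters2` (species-2 [promoter_set()]), `orthologs` (an
#'   [ortholog_map()]), `cluster_ids2`.
#' @export
generate_ortholog_fixture <- function(spec, conserved = TRUE) {
    fx <- generate_fixture(spec)
    set.seed(spec$seed + 1L)
    seqs1 <- fx$genome$sequences
    seqs2 <- .mutate_promoters(seqs1, spec$substitution_rate)
    if (conserved && nrow(fx$truth)) {
        for (i in seq_len(nrow(fx$truth))) {
            s <- fx$truth$start[i]
            w <- fx$truth$word[i]
            substr(seqs2[fx$truth$gene_id[i]], s, s + nchar(w) - 1) <- w
        }
    }
    ids2 <- paste0("s2_", names(seqs1))
    names(seqs2) <- ids2
    orthologs <- ortholog_map(names(seqs1), ids2)
    list(fixture1 = fx,
         promoters2 = promoter_set(seqs2, spec$window_length,
                                   paste0(spec$species, "_2")),
         orthologs = orthologs,
         cluster_ids2 = orthologs$id2[match(fx$cluster_ids, orthologs$id1)])
}

.random_promoters <- function(n, width, base_comp) {
    chars <- sample(c("A", "C", "G", "T"), n * width, replace = TRUE,
                    prob = base_comp)
    big <- paste(chars, collapse = "")
    starts <- seq.int(1L, by = width, length.out = n)
    substring(big, starts, starts + width - 1L)
}

.realize_word <- function(motif, alphabet = alphabet11()) {
    chars <- strsplit(motif, "", fixed = TRUE)[[1]]
    paste(vapply(chars, function(l) {
        m <- alphabet$match[[l]]
        if (length(m) == 1) m else sample(m, 1)
    }, character(1)), collapse = "")
}

.mutate_promoters <- function(seqs, rate) {
    if (rate == 0) return(seqs)
    bases <- c("A", "C", "G", "T")
    vapply(seqs, function(s) {
        chars <- strsplit(s, "", fixed = TRUE)[[1]]
        hit <- which(stats::runif(length(chars)) < rate & chars %in% bases)
        for (i in hit)
            chars[i] <- sample(setdiff(bases, chars[i]), 1)
        paste(chars, collapse = "")
    }, character(1))
}
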