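test_that("identical dosage columns give r2 = 1 and cross-chromosome pairs are absent", {
    v <- data.table::data.table(snp_id = c("a", "b", "c"),
                                chrom = c("1", "1", "2"),
                                pos = c(100L, 600L, 100L), a1 = "A", a2 = "G")
    dos <- cbind(c(0, 1, 2, 1), c(0, 1, 2, 1), c(2, 0, 1, 1))
    nb <- compute_ld(ref_panel(v, dos))
    expect_equal(nrow(nb$pairs), 1)
    expect_equal(nb$pairs$r2, 1.0)
    expect_equal(nb$pairs$i, 1)
    expect_equal(nb$pairs$j, 2)
})

test_that("windowed sparse LD equals the brute-force all-pairs computation", {
    panel <- random_panel(60, 40, seed = 21, chrom_len = 5e5)
    nb <- compute_ld(panel, window_bp = 2e5, r2_floor = 0.2)
    R2 <- dense_r2(panel, window_bp = 2e5, r2_floor = 0.2)
    sparse <- matrix(0, nb$n_snps, nb$n_snps)
    diag(sparse) <- 1
    for (k in seq_len(nrow(nb$pairs))) {
        i <- nb$pairs$i[k]; j <- nb$pairs$j[k]
        sparse[i, j] <- sparse[j, i] <- nb$pairs$r2[k]
    }
    expect_equal(sparse, R2, tolerance = 1e-12)
})

test_that("the floored weighted sum matches direct summation", {
    # out-of-region SNP 1 with in-region partners at r2 .5/.3 and one below floor
    nb <- manual_nbhd(4, data.table::data.table(i = c(1L, 1L), j = c(2L, 3L),
                                                r2 = c(0.5, 0.3)))
    delta <- c(0, 1, 1, 1)  # SNP 4 in-region but isolated
    sc <- ld_weighted_score(nb, delta)
    expect_equal(sc[1], 0.8)
    expect_equal(sc[4], 1)   # isolated in-region SNP scores exactly 1
    expect_equal(ld_weighted_score(nb, c(0, 0, 0, 0)), rep(0, 4))
})

test_that("total LD sums the whole neighbourhood and bounds every category", {
    nb <- manual_nbhd(3, data.table::data.table(i = c(1L, 1L), j = c(2L, 3L),
                                                r2 = c(0.5, 0.25)))
    expect_equal(total_ld(nb), c(1.75, 1.5, 1.25))
    for (delta in list(c(1, 0, 0), c(0, 1, 1), c(1, 1, 1)))
        expect_true(all(ld_weighted_score(nb, delta) <= total_ld(nb) + 1e-12))
})

test_that("raw indicators use union semantics at interval boundaries", {
    panel <- ref_panel(data.table::data.table(
        snp_id = c("a", "b", "c"), chrom = "1", pos = c(100L, 150L, 250L),
        a1 = "A", a2 = "G"), cbind(c(0, 1), c(1, 2), c(2, 0)))
    tr <- annot_track("t", data.table::data.table(
        chrom = "1", start = c(100L, 120L), end = c(200L, 180L)))
    expect_equal(raw_indicator(panel, tr), c(0L, 1L, 0L))
})

test_that("every score column matches the brute-force oracle on random panels", {
    for (seed in c(5, 17)) {
        panel <- random_panel(120, 40, seed = seed, chrom_len = 8e5)
        tracks <- toy_tracks(panel, seed = seed)
        tab <- build_score_table(panel, tracks, window_bp = 3e5)
        oracle <- brute_scores(panel, tracks, window_bp = 3e5)
        for (cat in attr(tab, "categories")) {
            expect_equal(tab[[paste0("ld_", cat)]], oracle$scores[[cat]],
                         tolerance = 1e-10)
            expect_equal(tab[[paste0("raw_", cat)]],
                         raw_indicator(panel, tracks[[cat]]))
        }
        expect_equal(tab$tot_ld, oracle$tot_ld, tolerance = 1e-10)
        expect_equal(tab$intergenic, oracle$intergenic)
    }
})

test_that("enlarging a track never decreases its scores", {
    panel <- random_panel(80, 30, seed = 9)
    nb <- compute_ld(panel)
    iv <- data.table::data.table(chrom = "1", start = 1000L, end = 200000L)
    small <- raw_indicator(panel, annot_track("t", iv))
    big_iv <- rbind(iv, data.table::data.table(chrom = "2", start = 0L,
                                               end = 1500000L))
    big <- raw_indicator(panel, annot_track("t", big_iv))
    expect_true(all(ld_weighted_score(nb, big) >=
                        ld_weighted_score(nb, small) - 1e-12))
})

test_that("with all pairs floored out, scores collapse to raw indicators", {
    panel <- random_panel(50, 25, seed = 13)
    nb <- compute_ld(panel, r2_floor = 1 - 1e-12)
    nb$pairs <- nb$pairs[r2 < 1]  # only exact duplicates could survive
    tracks <- toy_tracks(panel)
    d <- raw_indicator(panel, tracks$HAR)
    expect_equal(ld_weighted_score(nb, d), as.numeric(d))
    expect_equal(total_ld(nb), rep(1, nb$n_snps))
})

test_that("scores are invariant to panel sample-order permutation", {
    panel <- random_panel(60, 30, seed = 31)
    perm <- sample(nrow(panel$dosages))
    panel2 <- panel
    panel2$dosages <- panel$dosages[perm, ]
    tracks <- toy_tracks(panel)
    t1 <- build_score_table(panel, tracks)
    t2 <- build_score_table(panel2, tracks)
    expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("intergenic flag applies the genic-score and LD-context rules", {
    # 3 SNPs: 1 isolated and far from genes; 2 in an intron; 3 genic-free but
    # in LD with a SNP 50 kb from a gene
    v <- data.table::data.table(snp_id = c("a", "b", "c", "d"), chrom = "1",
                                pos = c(1000000L, 2000000L, 3000000L,
                                        3000500L),
                                a1 = "A", a2 = "G")
    set.seed(2)
    dos <- cbind(rbinom(30, 2, .3), rbinom(30, 2, .4), rbinom(30, 2, .3))
    dos <- cbind(dos, dos[, 3])  # d duplicates c -> r2 = 1
    dos[1, 4] <- 2 - dos[1, 4]   # keep polymorphic, near-perfect LD
    panel <- ref_panel(v, dos)
    nb <- compute_ld(panel)
    empty <- annot_track("e", NULL)
    gene <- annot_track("protein_coding_gene", data.table::data.table(
        chrom = "1", start = 1950000L, end = 1960000L))
    gene2 <- annot_track("protein_coding_gene", data.table::data.table(
        chrom = "1", start = c(1950000L, 3050000L),
        end = c(1960000L, 3060000L)))
    intron <- annot_track("intron", data.table::data.table(
        chrom = "1", start = 1999000L, end = 2001000L))
    genic <- list(exon = rep(0, 4), intron = ld_weighted_score(
        nb, raw_indicator(panel, intron)), utr3 = rep(0, 4),
        utr5 = rep(0, 4))
    ctx <- list(protein_coding_gene = gene2, ncRNA = empty, TFBS = empty,
                miRNA_bs = empty)
    flag <- intergenic_flag(panel, nb, genic, ctx)
    expect_true(flag[1])        # isolated, far from everything
    expect_false(flag[2])       # intron score >= 1
    expect_false(flag[3])       # LD partner d within 100 kb of gene2
    expect_false(flag[4])       # itself within 100 kb of gene2
})
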