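test_that("z magnitudes are derived from p by the two-sided normal relation", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("SNP\tCHR\tBP\tA1\tA2\tP",
                 "rs1\t1\t100\tA\tG\t0.5",
                 "rs2\t1\t200\tA\tG\t0.01",
                 "rs3\t1\t300\tA\tG\t1.0"), f)
    s <- read_summary_stats(f)
    expect_equal(nrow(s), 3)
    # frozen from the inverse-normal quantiles of 0.25, 0.005, 0.5
    expect_equal(abs(s$z), c(0.6745, 2.5758, 0.0), tolerance = 1e-4)
    expect_false(any(s$z_sign_known))
})

test_that("invalid p rows are dropped and counted, not floored", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("SNP\tCHR\tBP\tA1\tA2\tP",
                 "rs1\t1\t100\tA\tG\t0.5",
                 "rs2\t1\t200\tA\tG\t0"), f)
    s <- suppressMessages(read_summary_stats(f))
    expect_equal(nrow(s), 1)
    expect_equal(attr(s, "n_dropped"), 1)
    # opt-in flooring keeps the row instead
    dt <- data.table::data.table(snp_id = c("a", "b"), chrom = "1",
                                 pos = c(1L, 2L), a1 = "A", a2 = "G",
                                 p = c(0.5, 0))
    s2 <- summary_stats(dt, p_floor = 1e-300)
    expect_equal(nrow(s2), 2)
    expect_equal(s2$p[2], 1e-300)
})

test_that("p/z disagreement warns and the configured side wins", {
    dt <- data.table::data.table(snp_id = "rs1", chrom = "1", pos = 100L,
                                 a1 = "A", a2 = "G", p = 0.5, z = 5)
    expect_warning(s <- summary_stats(dt, z_precedence = "z"),
                   "inconsistent")
    expect_equal(s$z, 5)
    expect_equal(s$p, p_from_z(5))
    expect_warning(s2 <- summary_stats(dt, z_precedence = "p"),
                   "inconsistent")
    expect_equal(s2$p, 0.5)
    expect_equal(abs(s2$z), z_from_p(0.5))
})

test_that("missing mandatory columns and empty input raise format errors", {
    f <- tempfile(fileext = ".tsv")
    writeLines(c("SNP\tP", "rs1\t0.5"), f)
    expect_error(read_summary_stats(f), "lacks columns")
    dt <- data.table::data.table(snp_id = "rs1", chrom = "1", pos = 100L,
                                 a1 = "A", a2 = "G", p = 0)
    expect_error(suppressMessages(summary_stats(dt)), "no valid")
})

test_that("summary statistics round-trip through the TSV writer", {
    set.seed(7)
    z <- rnorm(20)
    s <- stats_from_z(z)
    f <- tempfile(fileext = ".tsv")
    write_summary_stats(s, f)
    s2 <- read_summary_stats(f)
    expect_equal(s2$snp_id, s$snp_id)
    expect_equal(s2$pos, s$pos)
    expect_equal(s2$z, s$z, tolerance = 1e-12)
    expect_equal(s2$p, s$p, tolerance = 1e-12)
})

test_that("p <-> z conversion round-trips across ten orders of magnitude", {
    p <- 10^seq(-10, 0, by = 0.5)
    p[length(p)] <- 1
    expect_equal(p_from_z(z_from_p(p)), p, tolerance = 1e-9)
})

test_that("panel construction sorts variants and removes monomorphic sites", {
    v <- data.table::data.table(snp_id = c("b", "a", "c"), chrom = "1",
                                pos = c(300L, 100L, 200L), a1 = "A", a2 = "G")
    dos <- cbind(c(0, 1, 2), c(1, 1, 0), c(0, 0, 0))
    p <- suppressMessages(ref_panel(v, dos))
    expect_equal(p$variants$snp_id, c("a", "b"))  # monomorphic "c" dropped
    expect_equal(p$variants$pos, c(100L, 300L))
    expect_equal(unname(p$dosages[, "a"]), c(1, 1, 0))
    expect_error(ref_panel(v[c(1, 1)], dos[, c(1, 1)]), "duplicate")
})

test_that("dosage-matrix panels round-trip and a missing sidecar errors", {
    panel <- random_panel(30, 20, seed = 11)
    f <- tempfile()
    write_panel_matrix(panel, f)
    p2 <- read_panel(f, format = "matrix")
    expect_equal(p2$variants, panel$variants)
    expect_equal(unname(p2$dosages), unname(panel$dosages))
    file.remove(paste0(f, ".vars"))
    expect_error(read_panel(f, format = "matrix"), "sidecar")
})

test_that("VCF panels load with REF-allele dosages and drop monomorphic sites", {
    skip_if_not_installed("vcfR")
    f <- tempfile(fileext = ".vcf")
    writeLines(c("##fileformat=VCFv4.2",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2\tS3",
                 "1\t100\trs1\tA\tG\t.\t.\t.\tGT\t0/1\t0/1\t0/0",
                 "1\t200\trs2\tT\tC\t.\t.\t.\tGT\t0/0\t0/0\t0/0"), f)
    p <- suppressMessages(read_panel(f, format = "vcf"))
    expect_equal(p$variants$snp_id, "rs1")  # all-0/0 rs2 has no variance
    expect_equal(unname(p$dosages[, 1]), c(1, 1, 2))  # REF-allele counts
})

test_that("BED tracks obey the half-open convention and report bad lines", {
    f <- tempfile(fileext = ".bed")
    writeLines(c("chr1\t100\t200"), f)
    tr <- read_track(f, "t")
    expect_equal(tr$intervals$start, 100L)
    # 1-based positions 101..200 are inside; 100 is not
    panel <- ref_panel(data.table::data.table(
        snp_id = c("x", "y", "z"), chrom = "chr1",
        pos = c(100L, 101L, 200L), a1 = "A", a2 = "G"),
        cbind(c(0, 1), c(1, 0), c(0, 1)))
    expect_equal(raw_indicator(panel, tr), c(0L, 1L, 1L))
    writeLines(character(0), f)
    expect_equal(nrow(read_track(f, "t")$intervals), 0)
    writeLines("chr1\t200\t100", f)
    expect_error(read_track(f, "t"), "line 1")
})

test_that("alignment joins on position, flips z on allele swap, drops mismatches", {
    panel <- ref_panel(data.table::data.table(
        snp_id = c("p1", "p2", "p3"), chrom = "1",
        pos = c(100L, 200L, 300L), a1 = c("G", "A", "A"),
        a2 = c("A", "G", "G")),
        cbind(c(0, 1, 2), c(1, 0, 1), c(2, 1, 0)))
    s <- summary_stats(data.table::data.table(
        snp_id = c("r1", "r2", "r4"), chrom = "1",
        pos = c(100L, 200L, 400L), a1 = "A", a2 = "G",
        z = c(2, -1, 3), p = p_from_z(c(2, -1, 3))))
    idx <- align_stats(s, panel)
    expect_equal(nrow(idx), 2)       # pos 400 absent from panel
    expect_equal(idx$z, c(-2, -1))   # swap at pos 100 flips the sign
    expect_true(idx$swapped[1])
    expect_false(idx$swapped[2])
    expect_false(any(is.na(idx$maf)))
})

test_that("alignment cardinality matches a set-intersection oracle", {
    panel <- random_panel(100, 30, seed = 3)
    v <- panel$variants
    keep <- sort(sample(nrow(v), 80))
    set.seed(4)
    z <- rnorm(80)
    s <- summary_stats(data.table::data.table(
        snp_id = paste0("r", seq_along(keep)), chrom = v$chrom[keep],
        pos = v$pos[keep], a1 = v$a1[keep], a2 = v$a2[keep],
        p = p_from_z(z), z = z))
    idx <- align_stats(s, panel)
    oracle <- length(intersect(paste(v$chrom, v$pos),
                               paste(v$chrom[keep], v$pos[keep])))
    expect_equal(nrow(idx), oracle)
    expect_error(align_stats(stats_from_z(rnorm(5), pos = 1:5 * 10L + 7L),
                             panel), "no variants shared")
})
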