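test_that("design assembly centers and scales and rejects bad covariates", {
    tab <- data.table::data.table(ld_intron = c(1, 2, 3, 4),
                                  ld_exon = c(0, 1, 0, 2),
                                  tot_ld = c(1, 1.5, 3, 2))
    s <- stats_from_z(c(1, -2, 0.5, 1.5))
    d <- build_design(tab, s, covariates = c("intron", "exon", "tot_ld"))
    expect_equal(colSums(d$X), rep(0, 3), tolerance = 1e-12,
                 ignore_attr = TRUE)
    expect_equal(apply(d$X, 2, sd), rep(1, 3), tolerance = 1e-12,
                 ignore_attr = TRUE)
    # de-scaling reproduces the raw columns
    raw <- sweep(sweep(d$X, 2, d$x_scale, "*"), 2, d$x_center, "+")
    expect_equal(unname(raw[, 1]), tab$ld_intron, tolerance = 1e-12)
    expect_error(build_design(tab, s, covariates = c("intron", "absent")),
                 "not found")
    tab2 <- data.table::copy(tab)[, ld_exon := 1]
    expect_error(build_design(tab2, s, covariates = c("intron", "exon")),
                 "constant covariate column: exon")
})

test_that("single-covariate PLSR equals the standardized regression slope", {
    set.seed(5)
    x <- rnorm(200)
    y <- 0.3 * x + rnorm(200)
    d <- manual_design(cbind(x = x), y)
    f <- fit_plsr(d)
    expect_equal(f$n_lv, 1L)
    expect_equal(unname(f$coefficients), cor(x, y), tolerance = 1e-10)
})

test_that("full-rank PLSR reproduces OLS and handles the orthogonal response", {
    set.seed(6)
    n <- 300; p <- 5
    X <- matrix(rnorm(n * p), n, p)
    y <- drop(X %*% runif(p, -1, 1)) + rnorm(n)
    d <- manual_design(X, y)
    f <- fit_plsr(d, n_lv = p)
    ols <- unname(drop(solve(crossprod(d$X), crossprod(d$X, d$y))))
    expect_equal(unname(f$coefficients), ols, tolerance = 1e-8)
    # y orthogonal to every covariate -> all coefficients zero
    Q <- qr.Q(qr(cbind(1, d$X)))
    y_perp <- rnorm(n)
    y_perp <- y_perp - Q %*% crossprod(Q, y_perp)
    d0 <- d
    d0$y <- drop(scale(y_perp))
    f0 <- fit_plsr(d0)
    expect_equal(unname(f0$coefficients), rep(0, p), tolerance = 1e-8)
})

test_that("latent-variable count follows the descriptor-variance rule", {
    set.seed(8)
    n <- 400
    # two independent blocks of correlated covariates
    base1 <- rnorm(n); base2 <- rnorm(n)
    X <- cbind(base1, base1 + 0.01 * rnorm(n), base2, base2 + 0.01 * rnorm(n))
    colnames(X) <- paste0("x", 1:4)
    y <- base1 + 0.5 * base2 + 0.1 * rnorm(n)
    f <- fit_plsr(manual_design(X, y))
    expect_lte(f$n_lv, ncol(X))
    expect_gt(sum(f$x_variance_explained[seq_len(f$n_lv)]), 0.99)
    # an independent PLS implementation agrees on the coefficients
    skip_if_not_installed("mixOmics")
    d <- manual_design(X, y)
    mo <- mixOmics::pls(d$X, matrix(d$y, dimnames = list(NULL, "y")),
                        ncomp = 2, mode = "regression", scale = FALSE)
    nd <- diag(ncol(X))
    colnames(nd) <- colnames(d$X)
    pr <- stats::predict(mo, newdata = nd)
    b_ref <- drop(pr$B.hat[, , 2])
    f2 <- fit_plsr(d, n_lv = 2)
    expect_equal(unname(f2$coefficients), unname(b_ref), tolerance = 1e-6)
})

test_that("fold construction never splits an LD block and balances sizes", {
    nb <- manual_nbhd(12, data.table::data.table(
        i = c(1L, 2L, 5L, 6L), j = c(2L, 3L, 6L, 7L),
        r2 = c(0.9, 0.8, 0.5, 0.4)))
    folds <- ld_folds(nb, k = 4, seed = 2)
    expect_length(folds, 12)
    expect_equal(length(unique(folds[1:3])), 1)  # block {1,2,3}
    expect_equal(length(unique(folds[5:7])), 1)  # block {5,6,7}
    # all-singleton case balances to within one block
    nb0 <- manual_nbhd(10, data.table::data.table(i = integer(),
                                                  j = integer(),
                                                  r2 = numeric()))
    f0 <- ld_folds(nb0, k = 5, seed = 3)
    expect_true(max(table(f0)) - min(table(f0)) <= 1)
    expect_error(ld_folds(nb, k = 11), "blocks")
})

test_that("no pair above the floor crosses folds on synthetic block data", {
    cfg <- generator_config(n_snps = 600, n_samples = 80,
                            chrom_lengths = c("1" = 3e6, "6" = 3e6),
                            track_specs = list(mhc = list(chrom = "6",
                                                          start = 1e6,
                                                          end = 1.5e6),
                                               mhc_extra_genes = 3),
                            seed = 12L)
    panel <- generate_panel(cfg)
    nb <- compute_ld(panel)
    folds <- ld_folds(nb, k = 10, seed = 4)
    crossing <- nb$pairs[folds[i] != folds[j]]
    expect_equal(nrow(crossing), 0)
})

test_that("jackknife inference has the documented sentinel and invariances", {
    set.seed(10)
    n <- 200
    X <- matrix(rnorm(n * 3), n, 3)
    y <- drop(X %*% c(1, 0, 0.5)) + rnorm(n)
    d <- manual_design(X, y)
    f <- fit_plsr(d, n_lv = 3)
    folds <- rep(1:10, each = 20)
    fj <- jackknife_ttest(d, f, folds)
    expect_equal(unname(fj$t_stat),
                 unname(fj$coefficients / fj$jackknife_sd))
    expect_equal(unname(fj$p_value),
                 unname(2 * pt(-abs(fj$t_stat), df = 9)))
    # fold relabeling leaves the jackknife sd unchanged
    relab <- c(5, 3, 9, 1, 10, 2, 8, 6, 4, 7)[folds]
    fj2 <- jackknife_ttest(d, f, relab)
    expect_equal(fj2$jackknife_sd, fj$jackknife_sd, tolerance = 1e-12)
    # duplicated rows make every leave-fold-out fit identical: sd 0 sentinel
    d2 <- d
    d2$X <- d$X[rep(1:20, 10), ]
    d2$y <- d$y[rep(1:20, 10)]
    f2 <- fit_plsr(d2, n_lv = 2)
    fj_s <- jackknife_ttest(d2, f2, rep(1:10, each = 20))
    expect_true(all(is.infinite(fj_s$t_stat) | fj_s$coefficients == 0))
    expect_true(all(fj_s$p_value[is.infinite(fj_s$t_stat)] == 0))
})

test_that("full-fit coefficients are invariant to SNP row permutation", {
    set.seed(14)
    n <- 150
    X <- matrix(rnorm(n * 4), n, 4)
    y <- drop(X %*% c(0.5, -0.2, 0, 0.1)) + rnorm(n)
    d <- manual_design(X, y)
    f1 <- fit_plsr(d)
    perm <- sample(n)
    d2 <- manual_design(X[perm, ], y[perm])
    f2 <- fit_plsr(d2)
    expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
})

test_that("TotLD residual bins reduce to raw means under a zero model", {
    set.seed(16)
    n <- 400
    tab <- data.table::data.table(
        ld_intron = rnorm(n), ld_exon = rnorm(n), ld_utr3 = rnorm(n),
        ld_utr5 = rnorm(n), ld_HAR = rbinom(n, 1, 0.3) * runif(n, 1, 3),
        ld_brain = rnorm(n), tot_ld = runif(n, 1, 10))
    z <- rnorm(n)  # independent of all covariates
    s <- stats_from_z(z)
    rt <- residual_vs_totld(tab, s, "HAR", n_bins = 8)
    expect_equal(sum(rt[stratum == "all"]$n), n)
    expect_equal(sum(rt[stratum == "above"]$n) + sum(rt[stratum == "below"]$n),
                 n)
    # residuals carry the response mean: count-weighted bin means recover it
    all_rows <- rt[stratum == "all"]
    expect_equal(sum(all_rows$mean_resid_z2 * all_rows$n) / sum(all_rows$n),
                 mean(s$z^2), tolerance = 1e-10)
    # a zero-coefficient reduced model leaves raw per-bin y means:
    # feed a response orthogonal to every covariate so all coefficients vanish
    d <- build_design(tab, s, covariates = c("intron", "exon", "utr3",
                                             "utr5", "HAR", "brain"))
    Q <- qr.Q(qr(cbind(1, d$X)))
    y0 <- rnorm(n)
    y0 <- drop(y0 - Q %*% crossprod(Q, y0))
    z2 <- y0 - min(y0) + 0.1          # a valid squared z-score vector
    s0 <- stats_from_z(sqrt(z2))
    rt0 <- residual_vs_totld(tab, s0, "HAR", n_bins = 8)
    edges <- unique(quantile(tab$tot_ld, seq(0, 1, 0.125)))
    bins <- findInterval(tab$tot_ld, edges, rightmost.closed = TRUE,
                         all.inside = TRUE)
    raw_means <- tapply(s0$z^2, bins, mean)
    got <- rt0[stratum == "all"]
    expect_equal(got$mean_resid_z2,
                 as.vector(raw_means[as.character(got$bin)]),
                 tolerance = 1e-6)
})

test_that("MHC subsetting partitions SNPs with inclusive bounds", {
    s <- stats_from_z(rnorm(5), chrom = c("6", "6", "6", "6", "1"),
                      pos = c(25652428L, 25652429L, 30000000L, 33421466L,
                              30000000L))
    ex <- mhc_subset(s, mode = "exclude")
    on <- mhc_subset(s, mode = "only")
    expect_equal(sort(c(ex$rows, on$rows)), 1:5)
    expect_equal(on$rows, c(2, 3, 4))   # both bounds inclusive
    expect_true(1 %in% ex$rows)         # one bp before the region
    expect_error(mhc_subset(s[5], mode = "only"), "empty")
})
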