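# Shared fixtures and independent brute-force oracles.

# Tiny random panel straight from Bernoulli dosages (not the block generator),
# so oracle tests are independent of generate_panel's structure.
random_panel <- function(n_snps, n_samples, seed, chroms = c("1", "2"),
                         chrom_len = 2e6) {
    set.seed(seed)
    chrom <- sort(sample(chroms, n_snps, replace = TRUE))
    pos <- unlist(lapply(unique(chrom), function(ch)
        sort(sample.int(chrom_len, sum(chrom == ch)))))
    maf <- runif(n_snps, 0.1, 0.5)
    dos <- sapply(maf, function(f) rbinom(n_samples, 2, f))
    # inject LD: copy some columns with noise
    for (k in seq_len(floor(n_snps / 4))) {
        i <- sample.int(n_snps - 1, 1)
        flip <- rbinom(n_samples, 1, 0.1)
        dos[, i + 1] <- ifelse(flip == 1, 2 - dos[, i], dos[, i])
    }
    ref_panel(data.table::data.table(
        snp_id = sprintf("s%04d", seq_len(n_snps)), chrom = chrom,
        pos = pos, a1 = "A", a2 = "G"), dos)
}

# Dense all-pairs floored/windowed r^2 matrix (the brute-force reference).
dense_r2 <- function(panel, window_bp = 1e6, r2_floor = 0.2) {
    R2 <- stats::cor(panel$dosages)^2
    dimnames(R2) <- NULL
    v <- panel$variants
    same_chrom <- outer(v$chrom, v$chrom, "==")
    near <- abs(outer(v$pos, v$pos, "-")) <= window_bp
    R2[!(same_chrom & near)] <- 0
    R2[R2 < r2_floor] <- 0
    diag(R2) <- 1
    R2
}

# Brute-force LD-weighted scores, total LD and intergenic flag.
brute_scores <- function(panel, tracks, window_bp = 1e6, r2_floor = 0.2,
                         gene_flank_bp = 1e5) {
    R2 <- dense_r2(panel, window_bp, r2_floor)
    delta <- lapply(tracks, function(tr) raw_indicator(panel, tr))
    scores <- lapply(delta, function(d) as.numeric(R2 %*% d))
    tot <- unname(rowSums(R2))
    genic_zero <- scores$exon == 0 & scores$intron == 0 &
        scores$utr3 == 0 & scores$utr5 == 0
    gene_iv <- data.table::copy(tracks$protein_coding_gene$intervals)
    if (nrow(gene_iv))
        gene_iv[, `:=`(start = pmax(0L, start - as.integer(gene_flank_bp)),
                       end = end + as.integer(gene_flank_bp))]
    context <- raw_indicator(panel, annot_track("gf", gene_iv)) |
        raw_indicator(panel, tracks$ncRNA) |
        raw_indicator(panel, tracks$TFBS) |
        raw_indicator(panel, tracks$miRNA_bs)
    no_context_ld <- as.numeric(R2 %*% as.numeric(context)) == 0
    list(scores = scores, tot_ld = tot,
         intergenic = genic_zero & no_context_ld)
}

# Minimal track set satisfying build_score_table's contract.
toy_tracks <- function(panel, seed = 1) {
    v <- panel$variants
    set.seed(seed)
    pick <- function(n, width) {
        idx <- sample.int(nrow(v), min(n, nrow(v)))
        data.table::data.table(chrom = v$chrom[idx],
                               start = pmax(0L, v$pos[idx] - width %/% 2L),
                               end = v$pos[idx] + width %/% 2L)
    }
    list(HAR = annot_track("HAR", pick(8, 2000)),
         SD = annot_track("SD", pick(3, 20000)),
         Ohno = annot_track("Ohno", pick(4, 10000)),
         exon = annot_track("exon", pick(6, 1500)),
         intron = annot_track("intron", pick(6, 8000)),
         utr5 = annot_track("utr5", pick(3, 400)),
         utr3 = annot_track("utr3", pick(3, 1200)),
         brain = annot_track("brain", pick(5, 10000)),
         protein_coding_gene = annot_track("protein_coding_gene",
                                           pick(6, 30000)),
         ncRNA = annot_track("ncRNA", pick(3, 2000)),
         TFBS = annot_track("TFBS", pick(4, 300)),
         miRNA_bs = annot_track("miRNA_bs", pick(2, 100)))
}

# Hand-built LD neighbourhood from an explicit pair table (i < j).
manual_nbhd <- function(n_snps, pairs, window_bp = 1e6, r2_floor = 0.2,
                        pos = NULL, chrom = NULL) {
    if (is.null(pos)) pos <- seq_len(n_snps) * 1000L
    if (is.null(chrom)) chrom <- rep("1", n_snps)
    structure(list(pairs = data.table::as.data.table(pairs),
                   n_snps = n_snps, chrom = chrom, pos = pos,
                   window_bp = window_bp, r2_floor = r2_floor),
              class = "ld_nbhd")
}

# A design object from raw matrices (bypassing score tables).
manual_design <- function(X, y) {
    if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
    x_center <- colMeans(X)
    x_scale <- apply(X, 2, sd)
    Xs <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
    structure(list(X = Xs, y = (y - mean(y)) / sd(y), x_center = x_center,
                   x_scale = x_scale, y_center = mean(y), y_scale = sd(y),
                   covariates = colnames(X),
                   snp_id = sprintf("s%d", seq_along(y))),
              class = "plsr_design")
}

# Summary stats directly from z-scores at given positions.
stats_from_z <- function(z, chrom = NULL, pos = NULL) {
    n <- length(z)
    summary_stats(data.table::data.table(
        snp_id = sprintf("s%04d", seq_len(n)),
        chrom = if (is.null(chrom)) rep("1", n) else chrom,
        pos = if (is.null(pos)) seq_len(n) * 1000L else pos,
        a1 = "A", a2 = "G", p = p_from_z(z), z = z, n = 10000L))
}
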