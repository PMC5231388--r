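#' Configuration for the synthetic GWAS study generator
#'
#' Defines a block-LD reference panel, annotation tracks (evolutionary
#' regions, gene models with exon/intron/UTR parts, a brain gene subset,
#' intergenic context tracks, one MHC-like gene-dense region) and GWAS
#' summary statistics under a polygenic model with planted per-annotation
#' enrichment. Defaults define the package's reference synthetic study; see
#' the methods vignette for the rationale behind each value.
#'
#' @param n_snps number of panel variants.
#' @param n_samples number of panel samples (diploid).
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param block_size_mean mean LD-block span in bp (block boundaries are
#'   drawn with exponential spacings; LD is block-diagonal).
#' @param within_block_r2 target mean pairwise r^2 inside a block, in [0, 1).
#' @param track_specs list of interval-track parameters; see Details.
#' @param tau named per-category enrichment effects on the z^2 scale: the
#'   causal-effect variance of a SNP adds `tau[c]` for every category c whose
#'   raw indicator it carries.
#' @param base_h2_per_snp baseline per-SNP causal-effect variance.
#' @param n_gwas GWAS sample size entering the summary-statistic model.
#' @param inflation variance multiplier of the noise component (>= 1 emulates
#'   cryptic-relatedness inflation; 1 = none).
#' @param maf_beta shape parameters of the truncated Beta distribution of
#'   block allele frequencies on (0.01, 0.5).
#' @param seed integer master seed; panel, tracks and summary statistics use
#'   sub-seeds derived from it.
#' @details `track_specs` fields: `genic_fraction` (target fraction of the
#'   genome covered by gene bodies), `gene_length`, `n_exons`, `exon_length`,
#'   `utr5_length`, `utr3_length`, `genes_per_cluster` (genes are placed in
#'   clusters separated by gene deserts so that a usable intergenic SNP set
#'   exists), `brain_fraction` and `ohno_fraction` (gene subsets),
#'   `har_n`/`har_width` (many short intervals), `sd_n`/`sd_width` (few wide
#'   ones), `ncrna_n/_width`, `tfbs_n/_width`, `mirna_n/_width`, `mhc`
#'   (chrom/start/end of the MHC-like region) and `mhc_extra_genes` (its
#'   elevated gene density).
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(n_snps = 20000, n_samples = 200,
                             chrom_lengths = c("1" = 4e7, "6" = 4e7),
                             block_size_mean = 2e4, within_block_r2 = 0.5,
                             track_specs = list(), tau = NULL,
                             base_h2_per_snp = 2e-6, n_gwas = 5e4,
                             inflation = 1, maf_beta = c(0.8, 0.8),
                             seed = 42L) {
    ts_default <- list(genic_fraction = 0.08, gene_length = 3e4, n_exons = 5,
                       exon_length = 1000, utr5_length = 300,
                       utr3_length = 1000, genes_per_cluster = 7,
                       brain_fraction = 0.15, ohno_fraction = 0.25,
                       har_n = 400, har_width = 800,
                       sd_n = 40, sd_width = 6e4,
                       ncrna_n = 200, ncrna_width = 2000,
                       tfbs_n = 600, tfbs_width = 300,
                       mirna_n = 200, mirna_width = 100,
                       mhc = list(chrom = "6", start = 1e7, end = 1.4e7),
                       mhc_extra_genes = 15)
    ts <- utils::modifyList(ts_default, track_specs)
    tau_default <- c(HAR = 2e-5, SD = 0, Ohno = 0, exon = 1e-5,
                     intron = 4e-6, utr3 = 1e-5, utr5 = 1e-5, brain = 5e-6)
    if (is.null(tau)) tau <- tau_default
    known <- c("HAR", "SD", "Ohno", "exon", "intron", "utr3", "utr5", "brain")
    bad <- setdiff(names(tau), known)
    if (length(bad)) stop("unknown tau categories: ", paste(bad, collapse = ", "))
    stopifnot(n_snps > 0, n_samples >= 2, all(chrom_lengths > 0),
              block_size_mean > 0, within_block_r2 >= 0, within_block_r2 < 1,
              all(tau >= 0), base_h2_per_snp >= 0, n_gwas > 0, inflation >= 1)
    if (!is.null(ts$mhc)) {
        if (!ts$mhc$chrom %in% names(chrom_lengths) ||
            ts$mhc$end > chrom_lengths[[ts$mhc$chrom]])
            stop("MHC-like region does not fit within chrom_lengths")
    }
    structure(list(n_snps = as.integer(n_snps),
                   n_samples = as.integer(n_samples),
                   chrom_lengths = chrom_lengths,
                   block_size_mean = block_size_mean,
                   within_block_r2 = within_block_r2, track_specs = ts,
                   tau = tau, base_h2_per_snp = base_h2_per_snp,
                   n_gwas = as.integer(n_gwas), inflation = inflation,
                   maf_beta = maf_beta, seed = as.integer(seed)),
              class = "generator_config")
}

# Mutation probability giving a target within-block correlation r for sites
# sharing a Bernoulli(f) clade indicator flipped with probability mu:
# cor = (1-2mu)^2 f(1-f) / (mu(1-mu) + (1-2mu)^2 f(1-f)).
solve_mutation_rate <- function(r_target, f) {
    if (r_target <= 0) return(0.5)
    g <- f * (1 - f)
    h <- function(mu) {
        a <- (1 - 2 * mu)^2
        a * g / (mu * (1 - mu) + a * g) - r_target
    }
    stats::uniroot(h, c(1e-6, 0.5 - 1e-9))$root
}

#' Generate a block-LD reference panel
#'
#' Haplotypes within a block share a latent ancestral clade indicator; each
#' site copies it with a per-site mutation (flip) probability tuned so the
#' realized mean within-block r^2 approximates `within_block_r2`. Blocks are
#' mutually independent. Deterministic given the config seed.
#'
#' @param config a [generator_config].
#' @return A [ref_panel] with attributes `block` (integer LD-block id per
#'   variant) and `block_freq` (clade frequency per block).
#' @export
generate_panel <- function(config) {
    ns <- config$n_samples
    H <- 2L * ns
    with_seed(sub_seed(config$seed, 1L), {
        total <- sum(config$chrom_lengths)
        chroms <- names(config$chrom_lengths)[order(names(config$chrom_lengths))]
        alle <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2,
                       byrow = TRUE)
        all_var <- list(); all_dos <- list(); all_block <- list()
        freqs <- numeric(0)
        block_offset <- 0L
        r_target <- sqrt(config$within_block_r2)
        for (ch in chroms) {
            len <- config$chrom_lengths[[ch]]
            n_c <- max(1L, round(config$n_snps * len / total))
            pos <- sort(sample.int(len, n_c))
            # exponential block spacings
            n_bnd <- ceiling(len / config$block_size_mean * 3) + 2
            bnd <- cumsum(stats::rexp(n_bnd, rate = 1 / config$block_size_mean))
            while (max(bnd) < len)
                bnd <- c(bnd, max(bnd) +
                             cumsum(stats::rexp(n_bnd,
                                                rate = 1 / config$block_size_mean)))
            block <- findInterval(pos, bnd) + 1L
            block <- as.integer(factor(block)) # densify ids
            dos <- matrix(0, ns, n_c)
            mafb <- config$maf_beta
            lo <- stats::pbeta(0.02, mafb[1], mafb[2])
            hi <- stats::pbeta(1, mafb[1], mafb[2])
            for (b in seq_len(max(block))) {
                idx <- which(block == b)
                m <- length(idx)
                f <- 0.5 * stats::qbeta(stats::runif(1, lo, hi),
                                        mafb[1], mafb[2])
                f <- max(f, 0.01)
                freqs <- c(freqs, f)
                mu0 <- solve_mutation_rate(r_target, f)
                mu <- pmin(0.5, pmax(1e-6, mu0 * stats::runif(m, 0.85, 1.2)))
                clade <- stats::rbinom(H, 1, f)
                for (tries in 1:20) {
                    flips <- matrix(stats::rbinom(H * m, 1, rep(mu, each = H)),
                                    H, m)
                    hap <- (matrix(clade, H, m) + flips) %% 2
                    d <- hap[seq(1, H, by = 2), , drop = FALSE] +
                        hap[seq(2, H, by = 2), , drop = FALSE]
                    v <- matrixStats_colVars(d)
                    if (all(v > 0)) break
                }
                dos[, idx] <- d
            }
            v <- matrixStats_colVars(dos)
            keep <- v > 0
            all_var[[ch]] <- data.table::data.table(
                chrom = ch, pos = pos[keep],
                a1 = alle[((seq_len(n_c) - 1L) %% 4L) + 1L, 1][keep],
                a2 = alle[((seq_len(n_c) - 1L) %% 4L) + 1L, 2][keep])
            all_dos[[ch]] <- dos[, keep, drop = FALSE]
            all_block[[ch]] <- block[keep] + block_offset
            block_offset <- block_offset + max(block)
        }
        variants <- data.table::rbindlist(all_var)
        variants[, snp_id := sprintf("snp%06d", .I)]
        panel <- ref_panel(variants, do.call(cbind, all_dos))
        attr(panel, "block") <- unlist(all_block, use.names = FALSE)
        attr(panel, "block_freq") <- freqs
        panel
    })
}

place_uniform <- function(n, width, chrom_lengths) {
    if (n == 0)
        return(data.table::data.table(chrom = character(), start = integer(),
                                      end = integer()))
    ch <- sample(names(chrom_lengths), n, replace = TRUE,
                 prob = chrom_lengths / sum(chrom_lengths))
    start <- vapply(ch, function(c)
        sample.int(max(1L, chrom_lengths[[c]] - width), 1L), integer(1))
    data.table::data.table(chrom = ch, start = as.integer(start),
                           end = as.integer(start + width))
}

granges_to_dt <- function(gr) {
    if (!length(gr))
        return(data.table::data.table(chrom = character(), start = integer(),
                                      end = integer()))
    data.table::data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
                           start = GenomicRanges::start(gr) - 1L,
                           end = GenomicRanges::end(gr))
}

#' Generate annotation tracks for a synthetic genome
#'
#' Gene models are placed in clusters (leaving gene deserts so an intergenic
#' SNP set exists), with exon/5'UTR/3'UTR parts inside each gene body and
#' introns defined as gene minus exon/UTR; brain and ohnolog tracks are gene
#' subsets; HAR-like (many short) and SD-like (few wide) interval tracks plus
#' ncRNA/TFBS/miRNA-binding-site context tracks are scattered uniformly; one
#' contiguous MHC-like region receives extra genes.
#'
#' @param config a [generator_config].
#' @return Named list of [annot_track]s (`HAR`, `SD`, `Ohno`, `exon`,
#'   `intron`, `utr5`, `utr3`, `brain`, `protein_coding_gene`, `ncRNA`,
#'   `TFBS`, `miRNA_bs`, `MHC`) with attribute `genes` (the gene table).
#' @export
generate_tracks <- function(config) {
    ts <- config$track_specs
    cl <- config$chrom_lengths
    with_seed(sub_seed(config$seed, 2L), {
        total <- sum(cl)
        n_genes <- max(2L, round(ts$genic_fraction * total / ts$gene_length))
        n_clusters <- ceiling(n_genes / ts$genes_per_cluster)
        gap <- 5000L
        span <- ts$genes_per_cluster * (ts$gene_length + gap)
        centers <- place_uniform(n_clusters, span, cl)
        genes <- centers[, {
            ng <- min(ts$genes_per_cluster, n_genes)
            s <- start + (seq_len(ng) - 1L) * (ts$gene_length + gap)
            .(gstart = as.integer(s), gend = as.integer(s + ts$gene_length))
        }, by = .(cluster = seq_len(nrow(centers)), chrom)]
        genes <- genes[gend <= cl[chrom]]
        if (!is.null(ts$mhc) && ts$mhc_extra_genes > 0) {
            step <- floor((ts$mhc$end - ts$mhc$start) / ts$mhc_extra_genes)
            if (step <= ts$gene_length)
                stop("MHC-like region too small for mhc_extra_genes")
            s <- as.integer(ts$mhc$start + (seq_len(ts$mhc_extra_genes) - 1L) * step)
            genes <- rbind(genes,
                           data.table::data.table(cluster = 0L,
                                                  chrom = ts$mhc$chrom,
                                                  gstart = s,
                                                  gend = s + as.integer(ts$gene_length)))
        }
        data.table::setorder(genes, chrom, gstart)
        genes[, gene_id := sprintf("gene%04d", .I)]

        u5 <- as.integer(ts$utr5_length); u3 <- as.integer(ts$utr3_length)
        exon_iv <- genes[, {
            s0 <- gstart + u5; e0 <- gend - u3
            starts <- as.integer(round(seq(s0, e0 - ts$exon_length,
                                           length.out = ts$n_exons)))
            .(start = starts, end = starts + as.integer(ts$exon_length))
        }, by = .(gene_id, chrom)][, .(chrom, start, end)]
        utr5_iv <- genes[, .(chrom, start = gstart, end = gstart + u5)]
        utr3_iv <- genes[, .(chrom, start = gend - u3, end = gend)]
        gene_iv <- genes[, .(chrom, start = gstart, end = gend)]

        gene_tr <- annot_track("protein_coding_gene", gene_iv)
        exon_tr <- annot_track("exon", exon_iv)
        utr5_tr <- annot_track("utr5", utr5_iv)
        utr3_tr <- annot_track("utr3", utr3_iv)
        nongenic <- GenomicRanges::setdiff(
            track_granges(gene_tr),
            GenomicRanges::union(track_granges(exon_tr),
                                 GenomicRanges::union(track_granges(utr5_tr),
                                                      track_granges(utr3_tr))))
        intron_tr <- annot_track("intron", granges_to_dt(nongenic))

        pick_genes <- function(frac)
            genes[sort(sample.int(nrow(genes), round(frac * nrow(genes)))),
                  .(chrom, start = gstart, end = gend)]
        tracks <- list(
            HAR = annot_track("HAR", place_uniform(ts$har_n, ts$har_width, cl)),
            SD = annot_track("SD", place_uniform(ts$sd_n, ts$sd_width, cl)),
            Ohno = annot_track("Ohno", pick_genes(ts$ohno_fraction)),
            exon = exon_tr, intron = intron_tr, utr5 = utr5_tr,
            utr3 = utr3_tr,
            brain = annot_track("brain", pick_genes(ts$brain_fraction)),
            protein_coding_gene = gene_tr,
            ncRNA = annot_track("ncRNA",
                                place_uniform(ts$ncrna_n, ts$ncrna_width, cl)),
            TFBS = annot_track("TFBS",
                               place_uniform(ts$tfbs_n, ts$tfbs_width, cl)),
            miRNA_bs = annot_track("miRNA_bs",
                                   place_uniform(ts$mirna_n, ts$mirna_width,
                                                 cl)))
        if (!is.null(ts$mhc))
            tracks$MHC <- annot_track("MHC", data.table::data.table(
                chrom = ts$mhc$chrom, start = as.integer(ts$mhc$start),
                end = as.integer(ts$mhc$end)))
        attr(tracks, "genes") <- genes
        tracks
    })
}

#' Precompute per-block correlation factors for repeated GWAS simulation
#'
#' Stores each LD block's realized dosage correlation matrix and its Cholesky
#' factor on the panel, so repeated calls to [simulate_summary_stats] over a
#' fixed genome (replicate GWAS draws) skip the factorization.
#'
#' @param panel a panel from [generate_panel].
#' @return the panel with a `sim_cache` attribute.
#' @export
precompute_block_factors <- function(panel) {
    block <- attr(panel, "block") %||% seq_len(nrow(panel$variants))
    cache <- lapply(unique(block), function(b) {
        idx <- which(block == b)
        if (length(idx) == 1L) return(list(idx = idx, C = NULL, L = NULL))
        C <- stats::cor(panel$dosages[, idx, drop = FALSE])
        L <- NULL
        for (jit in c(0, 1e-8, 1e-6, 1e-4)) {
            L <- tryCatch(chol(C + diag(jit, nrow(C))),
                          error = function(e) NULL)
            if (!is.null(L)) break
        }
        if (is.null(L))
            stop("block correlation matrix not positive definite (block ", b, ")")
        list(idx = idx, C = C, L = L)
    })
    attr(panel, "sim_cache") <- cache
    panel
}

#' Simulate GWAS summary statistics over a panel with planted enrichment
#'
#' Per-SNP causal effects are drawn as beta_j ~ Normal(0, base_h2_per_snp +
#' sum_c tau_c a_jc), with a_jc the raw indicator of category c. Marginal
#' z-scores follow the summary-statistic model z = sqrt(n_gwas) R beta + eps,
#' eps ~ Normal(0, inflation * R), with R the realized blockwise dosage
#' correlation; p is two-sided normal. Deterministic given the seed.
#'
#' @param panel a panel from [generate_panel] (its `block` attribute defines
#'   the blocks; without one, each variant is its own block).
#' @param tracks tracks from [generate_tracks].
#' @param config a [generator_config] (`tau`, `base_h2_per_snp`, `n_gwas`,
#'   `inflation`).
#' @param seed overrides the config-derived seed (to redraw a GWAS over a
#'   fixed genome).
#' @return A [summary_stats] table with attribute `truth` (list: `tau`,
#'   `base_h2_per_snp`, `inflation`, `n_gwas`, `seed`).
#' @export
simulate_summary_stats <- function(panel, tracks, config, seed = NULL) {
    seed <- seed %||% sub_seed(config$seed, 3L)
    v <- panel$variants
    m <- nrow(v)
    block <- attr(panel, "block") %||% seq_len(m)
    tau <- config$tau
    sigma2 <- rep(config$base_h2_per_snp, m)
    for (cat in names(tau)) {
        if (tau[[cat]] <= 0 || is.null(tracks[[cat]])) next
        sigma2 <- sigma2 + tau[[cat]] * raw_indicator(panel, tracks[[cat]])
    }
    cache <- attr(panel, "sim_cache")
    if (is.null(cache))
        cache <- attr(precompute_block_factors(panel), "sim_cache")
    z <- numeric(m)
    with_seed(seed, {
        beta <- stats::rnorm(m, 0, sqrt(sigma2))
        for (blk in cache) {
            idx <- blk$idx
            if (length(idx) == 1L) {
                z[idx] <- sqrt(config$n_gwas) * beta[idx] +
                    sqrt(config$inflation) * stats::rnorm(1)
                next
            }
            eta <- stats::rnorm(length(idx))
            z[idx] <- sqrt(config$n_gwas) * drop(blk$C %*% beta[idx]) +
                sqrt(config$inflation) * drop(crossprod(blk$L, eta))
        }
    })
    stats <- summary_stats(data.table::data.table(
        snp_id = v$snp_id, chrom = v$chrom, pos = v$pos, a1 = v$a1, a2 = v$a2,
        p = p_from_z(z), z = z, n = config$n_gwas, maf = panel_maf(panel)))
    data.table::setattr(stats, "truth",
                        list(tau = as.list(tau),
                             base_h2_per_snp = config$base_h2_per_snp,
                             inflation = config$inflation,
                             n_gwas = config$n_gwas, seed = seed))
    stats
}

#' Generator preset for genomic-control calibration
#'
#' A gene-sparse genome under the null association model (all tau = 0, no
#' baseline polygenic effect) whose only free knob is the noise inflation:
#' the large intergenic SNP set it yields is what lambda_GC calibration
#' needs.
#'
#' @param n_snps panel size (default 55,000; the gene-sparse layout leaves
#'   well over 50,000 of them intergenic).
#' @param inflation noise variance multiplier (1 = perfectly null).
#' @param seed master seed.
#' @param ... further overrides passed to [generator_config].
#' @return A [generator_config].
#' @export
lambda_null_config <- function(n_snps = 55000, inflation = 1, seed = 42L,
                               ...) {
    generator_config(n_snps = n_snps, n_samples = 200,
                     chrom_lengths = c("1" = 1.1e8, "6" = 1.1e8),
                     track_specs = list(genic_fraction = 0.005,
                                        har_n = 50, sd_n = 5,
                                        ncrna_n = 20, tfbs_n = 50,
                                        mirna_n = 20,
                                        mhc = list(chrom = "6", start = 1e7,
                                                   end = 1.4e7),
                                        mhc_extra_genes = 5),
                     tau = c(HAR = 0, SD = 0, Ohno = 0, exon = 0, intron = 0,
                             utr3 = 0, utr5 = 0, brain = 0),
                     base_h2_per_snp = 0, inflation = inflation, seed = seed,
                     ...)
}

#' Generate a complete synthetic study (panel + tracks + summary statistics)
#'
#' @param config a [generator_config].
#' @return A `synthetic_study` list: `panel`, `tracks`, `stats`, `truth`,
#'   `config`.
#' @export
simulate_study <- function(config = generator_config()) {
    panel <- generate_panel(config)
    tracks <- generate_tracks(config)
    stats <- simulate_summary_stats(panel, tracks, config)
    structure(list(panel = panel, tracks = tracks, stats = stats,
                   truth = attr(stats, "truth"), config = config),
              class = "synthetic_study")
}

#' Write a synthetic study in the on-disk formats the readers consume
#'
#' Summary statistics as TSV, the panel as a dosage matrix with variant
#' sidecar, every track as BED3, and the planted truth as JSON.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_summary_stats(study$stats, file.path(dir, "sumstats.tsv"))
    write_panel_matrix(study$panel, file.path(dir, "panel.dosage"))
    for (nm in names(study$tracks))
        write_track(study$tracks[[nm]], file.path(dir, paste0(nm, ".bed")))
    jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(dir)
}
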