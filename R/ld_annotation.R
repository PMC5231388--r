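#' Compute windowed LD neighbourhoods from a reference panel
#'
#' For every panel SNP, pairwise r^2 (squared Pearson correlation of genotype
#' dosages) is computed against all panel SNPs on the same chromosome within
#' `window_bp` base pairs; values below `r2_floor` are set to 0 (dropped from
#' the sparse representation), and every SNP carries an implicit self pair
#' with r^2 exactly 1.
#'
#' @param panel a [ref_panel].
#' @param window_bp maximum |position difference| for a pair (default 1 Mb,
#'   i.e. a +/- 1 Mb flank).
#' @param r2_floor minimum retained r^2 (default 0.2).
#' @return An `ld_nbhd` object: list with `pairs` (data.table `i`, `j`, `r2`,
#'   i < j, indices into the panel variant order), `n_snps`, `chrom`, `pos`,
#'   `window_bp`, `r2_floor`.
#' @export
compute_ld <- function(panel, window_bp = 1e6, r2_floor = 0.2) {
    stopifnot(window_bp > 0, r2_floor >= 0, r2_floor < 1)
    v <- panel$variants
    Z <- scale(panel$dosages)
    if (any(!is.finite(Z)))
        stop("zero-variance dosage vector in panel (monomorphic variant not filtered?)")
    chrom_code <- as.integer(factor(v$chrom, levels = unique(v$chrom)))
    res <- ld_pairs_cpp(Z, chrom_code, as.numeric(v$pos),
                        as.numeric(window_bp), r2_floor)
    pairs <- data.table::data.table(i = res$i, j = res$j, r2 = res$r2)
    structure(list(pairs = pairs, n_snps = nrow(v), chrom = v$chrom,
                   pos = v$pos, window_bp = window_bp, r2_floor = r2_floor),
              class = "ld_nbhd")
}

#' @export
print.ld_nbhd <- function(x, ...) {
    cat("LD neighbourhoods:", x$n_snps, "SNPs,", nrow(x$pairs),
        "retained pairs (r2 >=", x$r2_floor, ", window", x$window_bp, "bp)\n")
    invisible(x)
}

#' Raw 0/1 annotation indicator for panel SNPs
#'
#' 1 iff the SNP's 1-based position falls inside the union of the track's
#' intervals (BED half-open convention: `[s, e)` covers positions s+1..e).
#'
#' @param panel a [ref_panel] (positions define the SNP set).
#' @param track an [annot_track].
#' @return integer 0/1 vector, one per panel variant.
#' @export
raw_indicator <- function(panel, track) {
    v <- panel$variants
    gr <- track_granges(track)
    if (!length(gr)) return(integer(nrow(v)))
    snps <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos, v$pos))
    as.integer(GenomicRanges::countOverlaps(snps, gr) > 0)
}

#' LD-weighted annotation score
#'
#' For SNP i, `score_i = sum_j delta_j * r2_ij` over i's LD neighbourhood
#' (floored r^2, self pair included), where `delta_j` marks panel SNPs inside
#' the region of interest. An isolated SNP inside the region scores exactly 1.
#'
#' @param nbhd an `ld_nbhd` from [compute_ld].
#' @param delta integer/logical vector over panel SNPs (e.g. from
#'   [raw_indicator]).
#' @return numeric score vector, one per panel SNP.
#' @export
ld_weighted_score <- function(nbhd, delta) {
    stopifnot(length(delta) == nbhd$n_snps)
    delta <- as.numeric(delta)
    score <- delta # self term, r2 = 1
    p <- nbhd$pairs
    if (nrow(p)) {
        idx <- c(p$i, p$j)
        w <- c(p$r2 * delta[p$j], p$r2 * delta[p$i])
        add <- rowsum(w, idx)
        at <- as.integer(rownames(add))
        score[at] <- score[at] + add[, 1]
    }
    score
}

#' Total LD score
#'
#' The same windowed floored-r^2 sum with `delta` identically 1: a per-SNP
#' total LD burden, at least 1 by the self term.
#'
#' @inheritParams ld_weighted_score
#' @return numeric vector >= 1, one per panel SNP.
#' @export
total_ld <- function(nbhd) {
    ld_weighted_score(nbhd, rep(1, nbhd$n_snps))
}

#' Intergenic SNP flag
#'
#' A SNP is intergenic iff its LD-weighted exon, intron, 3'UTR and 5'UTR
#' scores are all exactly zero and no SNP in its LD neighbourhood (self
#' included) lies within 100 kb of a protein-coding gene interval or inside a
#' non-coding RNA, transcription-factor binding-site, or miRNA binding-site
#' interval.
#'
#' @param panel a [ref_panel].
#' @param nbhd an `ld_nbhd` over the same panel.
#' @param genic_scores data.frame/list with numeric elements `exon`, `intron`,
#'   `utr3`, `utr5` (LD-weighted scores per panel SNP).
#' @param context_tracks named list of [annot_track]s with elements
#'   `protein_coding_gene`, `ncRNA`, `TFBS`, `miRNA_bs`.
#' @param gene_flank_bp proximity rule for protein-coding genes (default
#'   100 kb, measured from interval boundaries; 0 if inside).
#' @return logical vector, one per panel SNP.
#' @export
intergenic_flag <- function(panel, nbhd, genic_scores, context_tracks,
                            gene_flank_bp = 1e5) {
    need <- c("protein_coding_gene", "ncRNA", "TFBS", "miRNA_bs")
    miss <- setdiff(need, names(context_tracks))
    if (length(miss))
        stop("intergenic context tracks missing: ", paste(miss, collapse = ", "))
    genic_zero <- genic_scores$exon == 0 & genic_scores$intron == 0 &
        genic_scores$utr3 == 0 & genic_scores$utr5 == 0

    gene <- context_tracks$protein_coding_gene
    flanked <- gene
    if (nrow(gene$intervals)) {
        iv <- data.table::copy(gene$intervals)
        iv[, `:=`(start = pmax(0L, start - as.integer(gene_flank_bp)),
                  end = end + as.integer(gene_flank_bp))]
        flanked <- annot_track("gene_flanked", iv)
    }
    context <- raw_indicator(panel, flanked) |
        raw_indicator(panel, context_tracks$ncRNA) |
        raw_indicator(panel, context_tracks$TFBS) |
        raw_indicator(panel, context_tracks$miRNA_bs)
    # any LD partner (or self) in functional context
    context_ld <- ld_weighted_score(nbhd, as.integer(context))
    genic_zero & context_ld == 0
}

#' Build the per-SNP LD score table
#'
#' Computes raw indicators and LD-weighted scores for every supplied category,
#' total LD, MAF and the intergenic flag for all panel SNPs.
#'
#' @param panel a [ref_panel].
#' @param nbhd an `ld_nbhd` over the panel (computed if `NULL`).
#' @param tracks named list of [annot_track]s; must contain the four genic
#'   part tracks `exon`, `intron`, `utr3`, `utr5` and the intergenic context
#'   tracks (`protein_coding_gene`, `ncRNA`, `TFBS`, `miRNA_bs`); any further
#'   tracks (e.g. `HAR`, `SD`, `Ohno`, `brain`) become score columns too.
#' @param score_categories categories to score (default: every track except
#'   the pure context tracks).
#' @param window_bp,r2_floor passed to [compute_ld] when `nbhd` is `NULL`.
#' @return An `ld_score_table` data.table with one row per panel SNP:
#'   `snp_id`, `chrom`, `pos`, `maf`, `raw_<cat>` and `ld_<cat>` per category,
#'   `tot_ld`, `intergenic`.
#' @export
build_score_table <- function(panel, tracks, nbhd = NULL,
                              score_categories = NULL,
                              window_bp = 1e6, r2_floor = 0.2) {
    context_only <- c("protein_coding_gene", "ncRNA", "TFBS", "miRNA_bs", "MHC")
    need_genic <- c("exon", "intron", "utr3", "utr5")
    miss <- setdiff(c(need_genic, setdiff(context_only, "MHC")), names(tracks))
    if (length(miss))
        stop("build_score_table requires tracks: ", paste(miss, collapse = ", "))
    if (is.null(score_categories))
        score_categories <- setdiff(names(tracks), context_only)
    if (is.null(nbhd)) nbhd <- compute_ld(panel, window_bp, r2_floor)

    v <- panel$variants
    out <- data.table::data.table(snp_id = v$snp_id, chrom = v$chrom,
                                  pos = v$pos, maf = panel_maf(panel))
    for (cat in score_categories) {
        d <- raw_indicator(panel, tracks[[cat]])
        out[, (paste0("raw_", cat)) := d]
        out[, (paste0("ld_", cat)) := ld_weighted_score(nbhd, d)]
    }
    out[, tot_ld := total_ld(nbhd)]
    genic <- lapply(stats::setNames(need_genic, need_genic),
                    function(g) out[[paste0("ld_", g)]])
    out[, intergenic := intergenic_flag(panel, nbhd, genic,
                                        tracks[setdiff(context_only, "MHC")])]
    data.table::setattr(out, "categories", score_categories)
    data.table::setattr(out, "class", c("ld_score_table", class(out)))
    out[]
}

#' Write an LD score table as TSV
#' @param table an `ld_score_table`.
#' @param path output path; values printed with 6 significant digits.
#' @export
write_score_table <- function(table, path) {
    out <- data.table::copy(table)
    num <- names(out)[vapply(out, is.double, logical(1))]
    for (col in num) out[, (col) := signif(get(col), 6)]
    data.table::fwrite(out, path, sep = "\t", quote = FALSE)
    invisible(path)
}
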