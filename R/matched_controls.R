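#' Matching specification for LD/MAF-matched null SNP sets
#'
#' @param table an `ld_score_table` used to place default bin edges: MAF in
#'   `n_maf_bins` equal-width bins on (0, 0.5], TotLD in `n_totld_bins`
#'   quantile bins (deciles by default) of the pooled distribution.
#' @param maf_bin_edges,totld_bin_edges explicit increasing edge vectors
#'   (override the defaults).
#' @param n_maf_bins,n_totld_bins default bin counts (25 and 10).
#' @param n_sets number of matched sets to draw (default 100).
#' @param seed integer seed; set s uses a derived sub-seed.
#' @param allow_reuse sample pool SNPs with replacement when a cell is
#'   undersupplied.
#' @return A `match_spec` list.
#' @export
match_spec <- function(table = NULL, maf_bin_edges = NULL,
                       totld_bin_edges = NULL, n_maf_bins = 25,
                       n_totld_bins = 10, n_sets = 100, seed = 1L,
                       allow_reuse = FALSE) {
    if (is.null(maf_bin_edges))
        maf_bin_edges <- seq(0, 0.5, length.out = n_maf_bins + 1)
    if (is.null(totld_bin_edges)) {
        if (is.null(table))
            stop("totld_bin_edges or a score table must be supplied")
        totld_bin_edges <- unique(stats::quantile(
            table$tot_ld, probs = seq(0, 1, length.out = n_totld_bins + 1)))
    }
    stopifnot(!is.unsorted(maf_bin_edges), !is.unsorted(totld_bin_edges),
              n_sets >= 1)
    structure(list(maf_bin_edges = maf_bin_edges,
                   totld_bin_edges = totld_bin_edges, n_sets = n_sets,
                   seed = seed, allow_reuse = allow_reuse),
              class = "match_spec")
}

match_cells <- function(table, rows, spec) {
    maf_bin <- findInterval(table$maf[rows], spec$maf_bin_edges,
                            rightmost.closed = TRUE, all.inside = TRUE)
    totld_bin <- findInterval(table$tot_ld[rows], spec$totld_bin_edges,
                              rightmost.closed = TRUE, all.inside = TRUE)
    paste(maf_bin, totld_bin, sep = ":")
}

#' Draw SNP sets matched on minor allele frequency and total LD
#'
#' For every 2-D (MAF x TotLD) bin cell, draws from the pool exactly as many
#' SNPs as the source set has in that cell; repeated `n_sets` times with
#' independent sub-seeds. Matched sets are disjoint from the source.
#'
#' @param source integer row indices of the source SNPs (e.g. SNPs physically
#'   inside an annotation, i.e. raw indicator 1).
#' @param table an `ld_score_table` (needs `maf`, `tot_ld`).
#' @param spec a [match_spec]; defaults derived from `table`.
#' @param pool candidate row indices (default: all rows minus `source`).
#' @return list of integer index vectors, one matched set per element.
#' @export
sample_matched <- function(source, table, spec = NULL, pool = NULL) {
    pool <- pool %||% setdiff(seq_len(nrow(table)), source)
    spec <- spec %||% match_spec(table)
    if (!length(source))
        return(replicate(spec$n_sets, integer(0), simplify = FALSE))
    src_cells <- match_cells(table, source, spec)
    pool_cells <- match_cells(table, pool, spec)
    need <- table(src_cells)
    have <- table(pool_cells)
    if (!spec$allow_reuse) {
        deficient <- names(need)[need > ifelse(is.na(have[names(need)]), 0,
                                               have[names(need)])]
        if (length(deficient))
            stop("undersupplied matching cells (maf_bin:totld_bin): ",
                 paste(deficient, collapse = ", "))
    }
    pool_by_cell <- split(pool, pool_cells)
    lapply(seq_len(spec$n_sets), function(s) {
        with_seed(sub_seed(spec$seed, s), {
            picked <- lapply(names(need), function(cell) {
                cand <- pool_by_cell[[cell]]
                k <- as.integer(need[[cell]])
                if (spec$allow_reuse && (is.null(cand) || length(cand) < k))
                    sample(cand %||% pool, k, replace = TRUE)
                else if (length(cand) == 1L && k == 1L) cand
                else sample(cand, k)
            })
            sort(unlist(picked, use.names = FALSE))
        })
    })
}

#' Enrichment curves of matched sets with a pointwise envelope
#'
#' Applies [fold_curve] to every matched set and summarizes the curves by the
#' pointwise median and 2.5/97.5 percentiles.
#'
#' @param matched_sets list of row-index vectors from [sample_matched].
#' @param stats summary statistics defining p-values and the SNP universe.
#' @param grid,pmax_log passed to [fold_curve].
#' @return list with `curves` (per set) and `envelope` (data.table:
#'   `threshold`, `median`, `lo`, `hi`).
#' @export
matched_enrichment <- function(matched_sets, stats, grid = NULL,
                               pmax_log = 7.3) {
    if (!length(matched_sets)) stop("no matched sets supplied")
    curves <- lapply(matched_sets, fold_curve, stats = stats, grid = grid,
                     pmax_log = pmax_log)
    folds <- do.call(cbind, lapply(curves, function(cv) cv$fold_in))
    envelope <- data.table::data.table(
        threshold = curves[[1]]$threshold,
        median = apply(folds, 1, stats::median, na.rm = TRUE),
        lo = apply(folds, 1, stats::quantile, probs = 0.025, na.rm = TRUE),
        hi = apply(folds, 1, stats::quantile, probs = 0.975, na.rm = TRUE))
    list(curves = curves, envelope = envelope)
}
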