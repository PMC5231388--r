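#' Stratify SNPs by an LD-weighted affiliation score
#'
#' Splits SNPs into the stratum with `score >= score_threshold` and its
#' complement. The default threshold of 1 is the score an isolated SNP inside
#' a salient region would have.
#'
#' @param score_table an `ld_score_table` (or any data.table with the score
#'   column).
#' @param category category name; the column `ld_<category>` is used (or the
#'   column itself if present, e.g. `tot_ld`).
#' @param score_threshold stratification threshold (default 1).
#' @return list with integer row indices `in_stratum` and `out_stratum`.
#' @export
stratify <- function(score_table, category, score_threshold = 1) {
    col <- if (paste0("ld_", category) %in% names(score_table))
        paste0("ld_", category)
    else if (category %in% names(score_table)) category
    else stop("unknown category: ", category)
    s <- score_table[[col]]
    in_idx <- which(s >= score_threshold)
    list(in_stratum = in_idx,
         out_stratum = setdiff(seq_along(s), in_idx))
}

#' Conditional fold-enrichment curve
#'
#' SNPs at or beyond genome-wide significance (-log10 p >= `pmax_log`) are
#' removed; at each grid point x the fold enrichment is the ratio of the
#' stratum's -log10(p) exceedance fraction to that of all remaining SNPs:
#' `fold(x) = S_stratum(x) / S_all(x)` with `S(x) = Pr(-log10 p >= x)`
#' (empirical, ties included via >=). At x = 0 both fractions are 1, so the
#' curve starts at 1; values where the overall exceedance count is 0 are
#' recorded as missing.
#'
#' @param stats summary statistics (needs `p`); rows define the SNP universe.
#' @param stratum integer row indices of the stratum of interest.
#' @param grid increasing -log10(p) thresholds in `[0, pmax_log)`; default
#'   200 equally spaced points.
#' @param pmax_log -log10(p) cap (default 7.3, i.e. p > 5e-8).
#' @return An `enrichment_curve` data.table: `threshold`, `fold_in`,
#'   `fold_out`, `n_in`, `n_out`, `n_all` (exceedance counts).
#' @export
fold_curve <- function(stats, stratum, grid = NULL, pmax_log = 7.3) {
    if (is.null(grid)) grid <- seq(0, pmax_log, length.out = 201)[-201]
    stopifnot(all(grid >= 0), all(grid < pmax_log), !is.unsorted(grid))
    x <- -log10(stats$p)
    keep <- x < pmax_log
    x <- x[keep]
    in_mask <- logical(nrow(stats))
    in_mask[stratum] <- TRUE
    in_mask <- in_mask[keep]
    if (!any(in_mask)) stop("stratum empty after the -log10(p) cap")
    x_in <- x[in_mask]; x_out <- x[!in_mask]
    N_in <- length(x_in); N_out <- length(x_out); N <- length(x)
    exceed <- function(v, g) {
        # count of v >= g for each g, via sorted positions
        sv <- sort(v)
        length(v) - findInterval(g, sv, left.open = TRUE)
    }
    n_in <- exceed(x_in, grid)
    n_out <- exceed(x_out, grid)
    n_all <- n_in + n_out
    s_all <- n_all / N
    fold_in <- ifelse(n_all == 0, NA_real_, (n_in / N_in) / s_all)
    fold_out <- if (N_out > 0)
        ifelse(n_all == 0, NA_real_, (n_out / N_out) / s_all)
    else rep(NA_real_, length(grid))
    out <- data.table::data.table(threshold = grid, fold_in = fold_in,
                                  fold_out = fold_out, n_in = n_in,
                                  n_out = n_out, n_all = n_all)
    data.table::setattr(out, "n_stratum", N_in)
    data.table::setattr(out, "n_total", N)
    data.table::setattr(out, "class", c("enrichment_curve", class(out)))
    out[]
}

#' Write an enrichment curve as TSV
#' @param curve an `enrichment_curve`.
#' @param path output path.
#' @export
write_curve <- function(curve, path) {
    data.table::fwrite(curve, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' Plot fold-enrichment curves
#'
#' Thin optional layer over the curve tables (requires ggplot2).
#'
#' @param curves named list of `enrichment_curve` tables.
#' @return a ggplot object.
#' @export
plot_fold_curves <- function(curves) {
    if (!requireNamespace("ggplot2", quietly = TRUE))
        stop("plot_fold_curves requires ggplot2")
    dt <- data.table::rbindlist(
        lapply(names(curves), function(nm)
            data.table::data.table(stratum = nm,
                                   threshold = curves[[nm]]$threshold,
                                   fold = curves[[nm]]$fold_in)))
    ggplot2::ggplot(dt, ggplot2::aes(x = threshold, y = fold,
                                     colour = stratum)) +
        ggplot2::geom_line() +
        ggplot2::geom_hline(yintercept = 1, linetype = 2) +
        ggplot2::labs(x = expression(-log[10](p)), y = "fold enrichment")
}
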