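#' Greedy LD pruning to an approximately independent SNP set
#'
#' Candidates are visited in a seeded random order; a SNP is kept iff its r^2
#' with every already-kept SNP is below `prune_r2` (pairs absent from the
#' floored neighbourhood count as independent). The retained set has no pair
#' with r^2 >= `prune_r2`.
#'
#' @param candidates integer indices into the panel variant order (e.g. the
#'   intergenic SNPs).
#' @param nbhd an `ld_nbhd` from [compute_ld].
#' @param prune_r2 independence threshold (default 0.2).
#' @param seed integer seed for the visiting order.
#' @return integer vector: the retained subset of `candidates`.
#' @export
ld_prune <- function(candidates, nbhd, prune_r2 = 0.2, seed = 1L) {
    if (!length(candidates)) stop("empty candidate set for LD pruning")
    adj <- prune_adjacency(candidates, nbhd, prune_r2)
    ord <- with_seed(seed, sample.int(length(candidates))) - 1L
    keep <- greedy_prune_cpp(ord, adj$ptr, adj$idx)
    sort(candidates[keep])
}

# CSR adjacency among candidates for edges with r2 >= prune_r2; reusable
# across visiting orders.
prune_adjacency <- function(candidates, nbhd, prune_r2) {
    n <- length(candidates)
    local <- integer(nbhd$n_snps)
    local[candidates] <- seq_len(n)
    p <- nbhd$pairs[r2 >= prune_r2]
    li <- local[p$i]; lj <- local[p$j]
    sel <- li > 0L & lj > 0L
    li <- li[sel]; lj <- lj[sel]
    from <- c(li, lj); to <- c(lj, li)
    ord <- order(from)
    list(ptr = c(0L, cumsum(tabulate(from, nbins = n))),
         idx = to[ord] - 1L)
}

#' Genomic-control inflation from intergenic SNPs
#'
#' Estimates the inflation factor lambda_GC as the median squared z-score of
#' independent (LD-pruned) intergenic SNP sets across `n_iter` pruning
#' iterations, divided by the median of the chi-square distribution with one
#' degree of freedom. Each iteration prunes with a fresh sub-seed; the
#' estimate is the median over the per-iteration medians.
#'
#' @param stats an aligned summary-statistics table (needs `z`); row order
#'   must correspond to the panel variant order restricted to aligned SNPs.
#' @param intergenic logical vector over the rows of `stats`.
#' @param nbhd an `ld_nbhd`.
#' @param panel_col integer vector mapping stats rows to panel variant
#'   indices (defaults to `stats$panel_col`, else 1..nrow).
#' @param n_iter number of LD-pruning iterations (default 100).
#' @param prune_r2 pruning threshold (default 0.2).
#' @param seed integer seed; iteration i uses a sub-seed derived from it.
#' @param min_intergenic minimum usable intergenic SNP count (default 30).
#' @param aggregate `"median_of_medians"` (default) takes the median over
#'   per-iteration medians; `"pooled"` takes one median over the pooled
#'   pruned z^2 values of all iterations.
#' @return A `lambda_estimate` list: `lambda_gc`, `per_iteration_medians`,
#'   `n_intergenic`, `n_iter`, `prune_r2`, `seed`.
#' @export
estimate_lambda <- function(stats, intergenic, nbhd, n_iter = 100,
                            prune_r2 = 0.2, seed = 1L, min_intergenic = 30,
                            panel_col = NULL,
                            aggregate = c("median_of_medians", "pooled")) {
    aggregate <- match.arg(aggregate)
    stopifnot(length(intergenic) == nrow(stats))
    panel_col <- panel_col %||% stats$panel_col %||% seq_len(nrow(stats))
    cand_rows <- which(intergenic)
    if (length(cand_rows) < min_intergenic)
        stop("only ", length(cand_rows), " intergenic SNPs; at least ",
             min_intergenic, " required")
    cand_panel <- panel_col[cand_rows]
    z2 <- stats$z[cand_rows]^2
    row_of_panel <- integer(nbhd$n_snps)
    row_of_panel[cand_panel] <- seq_along(cand_rows)

    adj <- prune_adjacency(cand_panel, nbhd, prune_r2)
    chi1_median <- stats::qchisq(0.5, df = 1)
    kept_z2 <- lapply(seq_len(n_iter), function(it) {
        ord <- with_seed(sub_seed(seed, it),
                         sample.int(length(cand_panel))) - 1L
        keep <- greedy_prune_cpp(ord, adj$ptr, adj$idx)
        z2[keep]
    })
    meds <- vapply(kept_z2, stats::median, numeric(1))
    lambda <- if (aggregate == "pooled")
        stats::median(unlist(kept_z2)) / chi1_median
    else stats::median(meds) / chi1_median
    structure(list(lambda_gc = lambda,
                   per_iteration_medians = meds,
                   n_intergenic = length(cand_rows), n_iter = n_iter,
                   prune_r2 = prune_r2, seed = seed),
              class = "lambda_estimate")
}

#' @export
print.lambda_estimate <- function(x, ...) {
    cat(sprintf("lambda_GC = %.4f (%d intergenic SNPs, %d pruning iterations)\n",
                x$lambda_gc, x$n_intergenic, x$n_iter))
    invisible(x)
}

#' Apply genomic-control correction to summary statistics
#'
#' Divides squared z-scores by lambda_GC (preserving the sign) and recomputes
#' two-sided p-values.
#'
#' @param stats a summary-statistics table with `z` and `p`.
#' @param lambda a `lambda_estimate` or a positive number.
#' @param never_inflate if `TRUE`, lambda below 1 is treated as 1 (no-op).
#' @return A corrected copy of `stats`.
#' @export
apply_gc <- function(stats, lambda, never_inflate = FALSE) {
    lg <- if (inherits(lambda, "lambda_estimate")) lambda$lambda_gc else lambda
    stopifnot(is.numeric(lg), lg > 0)
    if (never_inflate) lg <- max(lg, 1)
    out <- data.table::copy(data.table::as.data.table(stats))
    out[, z := z / sqrt(lg)]
    out[, p := p_from_z(z)]
    out[]
}

#' Write a lambda_GC report as JSON
#' @param lambda a `lambda_estimate`.
#' @param path output path.
#' @export
write_lambda_report <- function(lambda, path) {
    jsonlite::write_json(unclass(lambda), path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}
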