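#' Assemble the PLSR design: squared z-scores on LD-weighted covariates
#'
#' Builds the descriptor matrix X from LD-weighted score columns in the
#' declared order and the response y = z^2, then mean-centers and scales both
#' to unit standard deviation (the stored centers/scales allow exact
#' back-transformation).
#'
#' @param score_table an `ld_score_table` whose rows match `stats` rows.
#' @param stats aligned summary statistics (needs `z`).
#' @param evo_category evolutionary category of interest (its `ld_` column
#'   enters the design).
#' @param covariates covariate names in design order; defaults to the
#'   standard set: intron, exon, utr3, utr5, the evolutionary score, brain,
#'   tot_ld. Names are resolved against `ld_<name>` columns first, then plain
#'   columns (`tot_ld`).
#' @return A `plsr_design` list: `X`, `y` (standardized), `x_center`,
#'   `x_scale`, `y_center`, `y_scale`, `covariates`, `snp_id`.
#' @export
build_design <- function(score_table, stats, evo_category = NULL,
                         covariates = NULL) {
    if (is.null(covariates)) {
        if (is.null(evo_category))
            stop("either covariates or evo_category must be given")
        covariates <- c("intron", "exon", "utr3", "utr5", evo_category,
                        "brain", "tot_ld")
    }
    stopifnot(nrow(score_table) == nrow(stats))
    cols <- lapply(covariates, function(cv) {
        nm <- if (paste0("ld_", cv) %in% names(score_table)) paste0("ld_", cv)
        else if (cv %in% names(score_table)) cv
        else stop("covariate not found in score table: ", cv)
        score_table[[nm]]
    })
    X <- do.call(cbind, cols)
    colnames(X) <- covariates
    if (anyDuplicated(covariates)) stop("duplicate covariate names")
    x_center <- colMeans(X)
    x_scale <- apply(X, 2, stats::sd)
    if (any(x_scale == 0))
        stop("constant covariate column: ",
             paste(covariates[x_scale == 0], collapse = ", "))
    X <- sweep(sweep(X, 2, x_center), 2, x_scale, "/")
    y_raw <- stats$z^2
    y_center <- mean(y_raw)
    y_scale <- stats::sd(y_raw)
    if (y_scale == 0) stop("response (squared z-scores) is constant")
    y <- (y_raw - y_center) / y_scale
    structure(list(X = X, y = y, x_center = x_center, x_scale = x_scale,
                   y_center = y_center, y_scale = y_scale,
                   covariates = covariates, snp_id = stats$snp_id),
              class = "plsr_design")
}

# Single-response NIPALS with deflation. X, y already standardized.
# Returns weights W, loadings P, y-loadings q, per-LV X-variance fractions.
nipals_plsr <- function(X, y, max_lv) {
    p <- ncol(X)
    SSX <- sum(X^2)
    W <- matrix(0, p, 0); P <- matrix(0, p, 0)
    q <- numeric(0); xvar <- numeric(0)
    Xd <- X; yd <- y
    for (a in seq_len(max_lv)) {
        w <- crossprod(Xd, yd)
        wn <- sqrt(sum(w^2))
        if (wn < 1e-12) break
        w <- w / wn
        t <- Xd %*% w
        tt <- sum(t^2)
        if (tt < 1e-12) break
        pl <- crossprod(Xd, t) / tt
        qa <- sum(yd * t) / tt
        Xd <- Xd - t %*% t(pl)
        yd <- yd - qa * t
        W <- cbind(W, w); P <- cbind(P, pl)
        q <- c(q, qa); xvar <- c(xvar, tt * sum(pl^2) / SSX)
    }
    list(W = W, P = P, q = q, xvar = xvar)
}

plsr_coef <- function(nip, A) {
    if (A == 0 || ncol(nip$W) == 0) return(NULL)
    W <- nip$W[, seq_len(A), drop = FALSE]
    P <- nip$P[, seq_len(A), drop = FALSE]
    drop(W %*% solve(crossprod(P, W), nip$q[seq_len(A)]))
}

#' Fit a partial least squares regression of squared z-scores
#'
#' Sequential latent-variable (LV) extraction maximizing descriptor-response
#' covariance (single-response NIPALS with deflation). The model order A is
#' the smallest LV count whose cumulative descriptor-block variance explained
#' exceeds `var_threshold` (capped at `max_lv`; if the threshold is never
#' reached, all extracted LVs are kept). Coefficients are reported on the
#' standardized scale, with the raw-scale back-transform alongside.
#'
#' @param design a `plsr_design` from [build_design].
#' @param var_threshold cumulative descriptor-variance cutoff for choosing A
#'   (default 0.99).
#' @param max_lv maximum LV count (default: number of covariates).
#' @param n_lv fix the LV count directly (used by the jackknife refits),
#'   bypassing the variance rule.
#' @return A `plsr_fit` list: `coefficients` (standardized scale, named),
#'   `coefficients_raw`, `intercept_raw`, `n_lv`, `x_variance_explained`
#'   (per-LV), `covariates`.
#' @export
fit_plsr <- function(design, var_threshold = 0.99, max_lv = NULL, n_lv = NULL) {
    X <- design$X; y <- design$y
    p <- ncol(X)
    max_lv <- min(max_lv %||% p, p)
    if (nrow(X) <= p) stop("PLSR needs more rows than covariates")
    stopifnot(var_threshold > 0, var_threshold < 1)
    nip <- nipals_plsr(X, y, max_lv)
    extracted <- length(nip$q)
    if (extracted == 0) {
        # response orthogonal to every covariate: the zero model
        b <- stats::setNames(rep(0, p), design$covariates)
        A <- 1L; xvar <- 0
    } else {
        A <- if (!is.null(n_lv)) min(n_lv, extracted)
        else {
            cum <- cumsum(nip$xvar)
            if (any(cum > var_threshold)) which(cum > var_threshold)[1]
            else extracted
        }
        b <- stats::setNames(plsr_coef(nip, A), design$covariates)
        xvar <- nip$xvar
    }
    b_raw <- b * design$y_scale / design$x_scale
    structure(list(coefficients = b, coefficients_raw = b_raw,
                   intercept_raw = design$y_center -
                       sum(b_raw * design$x_center),
                   n_lv = as.integer(A), x_variance_explained = xvar,
                   var_threshold = var_threshold,
                   covariates = design$covariates),
              class = "plsr_fit")
}

#' @export
print.plsr_fit <- function(x, ...) {
    cat("PLSR fit:", x$n_lv, "latent variable(s),",
        sprintf("%.1f%%", 100 * sum(x$x_variance_explained)),
        "descriptor variance explained\n")
    print(round(x$coefficients, 4))
    if (!is.null(x$t_stat)) {
        cat("jackknife t / p:\n")
        print(data.frame(t = round(x$t_stat, 3),
                         p = signif(x$p_value, 3)))
    }
    invisible(x)
}

#' LD-aware cross-validation folds
#'
#' SNPs are grouped into LD blocks -- connected components of the floored r^2
#' graph, additionally split so no block spans more than the LD window -- and
#' whole blocks are assigned to folds by seeded round-robin over a shuffled
#' block order, so no block is divided across folds.
#'
#' @param nbhd an `ld_nbhd`.
#' @param rows integer panel-variant indices of the design rows (default: all
#'   panel SNPs). Row i of the design corresponds to `rows[i]`.
#' @param k fold count (default 50).
#' @param seed integer seed for the block shuffle.
#' @return integer fold assignment (1..k), one per design row; attribute
#'   `blocks` holds the block id per row.
#' @export
ld_folds <- function(nbhd, rows = NULL, k = 50, seed = 1L) {
    stopifnot(k >= 2)
    rows <- rows %||% seq_len(nbhd$n_snps)
    n <- length(rows)
    local <- integer(nbhd$n_snps)
    local[rows] <- seq_len(n)
    p <- nbhd$pairs
    li <- local[p$i]; lj <- local[p$j]
    sel <- li > 0L & lj > 0L
    g <- igraph::graph_from_edgelist(cbind(li[sel], lj[sel]), directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    # cap block span at the LD window: split long components positionally
    pos <- nbhd$pos[rows]
    block <- comp
    nb <- max(comp)
    for (cid in which(tabulate(comp) > 1)) {
        idx <- which(comp == cid)
        o <- idx[order(pos[idx])]
        anchor <- pos[o[1]]
        cur <- cid
        for (ii in o) {
            if (pos[ii] - anchor > nbhd$window_bp) {
                nb <- nb + 1L; cur <- nb; anchor <- pos[ii]
            }
            block[ii] <- cur
        }
    }
    ids <- unique(block)
    if (length(ids) < k)
        stop("only ", length(ids), " LD blocks; choose k <= that (k = ", k, ")")
    shuffled <- with_seed(seed, sample(ids))
    fold_of_block <- stats::setNames(rep_len(seq_len(k), length(shuffled)),
                                     shuffled)
    folds <- unname(fold_of_block[as.character(block)])
    attr(folds, "blocks") <- block
    folds
}

#' Jackknife approximate t-tests of PLSR coefficients
#'
#' Re-fits the PLSR model (same LV count as the full fit) with each
#' cross-validation fold held out, forms delete-group jackknife variances
#' `(k-1)/k * sum_f (b_(-f) - mean(b_(-f)))^2`, and reports t = b_full / sd
#' with two-sided p-values from the t distribution on k-1 degrees of freedom.
#' When a coefficient's jackknife sd is 0, t is reported as a signed infinity
#' sentinel (0 if the coefficient is also 0) with p = 0 (resp. 1).
#'
#' @param design the `plsr_design` of the full fit.
#' @param fit the full `plsr_fit`.
#' @param folds integer fold assignment per design row (from [ld_folds]).
#' @return The `plsr_fit` augmented with `jackknife_sd`, `t_stat`, `p_value`,
#'   `df`, `k`.
#' @export
jackknife_ttest <- function(design, fit, folds) {
    stopifnot(length(folds) == nrow(design$X))
    ks <- sort(unique(folds))
    k <- length(ks)
    B <- matrix(NA_real_, k, length(fit$coefficients))
    for (f in seq_along(ks)) {
        keep <- folds != ks[f]
        d <- design
        d$X <- design$X[keep, , drop = FALSE]
        d$y <- design$y[keep]
        ft <- tryCatch(fit_plsr(d, var_threshold = fit$var_threshold,
                                n_lv = fit$n_lv),
                       error = function(e)
                           stop("jackknife refit failed for fold ", ks[f],
                                ": ", conditionMessage(e)))
        B[f, ] <- ft$coefficients
    }
    bbar <- colMeans(B)
    jk_var <- (k - 1) / k * colSums(sweep(B, 2, bbar)^2)
    sd <- sqrt(jk_var)
    b <- fit$coefficients
    t <- ifelse(sd > 0, b / sd, ifelse(b == 0, 0, sign(b) * Inf))
    pv <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df = k - 1),
                 ifelse(t == 0, 1, 0))
    fit$jackknife_sd <- stats::setNames(sd, fit$covariates)
    fit$t_stat <- stats::setNames(t, fit$covariates)
    fit$p_value <- stats::setNames(pv, fit$covariates)
    fit$df <- k - 1L
    fit$k <- k
    fit$fold_coefficients <- B
    fit
}

#' Binned residualized squared z-scores against total LD
#'
#' Residualizes y = z^2 in a PLSR model deprived of TotLD (and optionally of
#' the evolutionary score), bins TotLD into equal-count bins, and reports the
#' average residualized z^2 per bin for three strata: category score >=
#' threshold, < threshold, and all SNPs. Residuals are reported on the z^2
#' scale with the response mean re-added, so a zero-coefficient reduced model
#' reproduces the raw per-bin y means. Bins left empty within a stratum are
#' merged into their left neighbour (logged).
#'
#' @param score_table,stats as in [build_design].
#' @param evo_category evolutionary category defining the stratification.
#' @param drop_evo also remove the evolutionary score from the reduced model.
#' @param n_bins number of equal-count TotLD bins (default 20).
#' @param score_threshold stratification threshold (default 1).
#' @param var_threshold passed to [fit_plsr].
#' @return data.table: `stratum`, `bin`, `center` (midpoint of the TotLD bin
#'   edges), `mean_resid_z2`, `n`.
#' @export
residual_vs_totld <- function(score_table, stats, evo_category,
                              drop_evo = FALSE, n_bins = 20,
                              score_threshold = 1, var_threshold = 0.99) {
    stopifnot(n_bins >= 2)
    covs <- c("intron", "exon", "utr3", "utr5",
              if (!drop_evo) evo_category, "brain")
    design <- build_design(score_table, stats, covariates = covs)
    fit <- fit_plsr(design, var_threshold = var_threshold)
    resid_std <- design$y - drop(design$X %*% fit$coefficients)
    resid_z2 <- design$y_center + resid_std * design$y_scale

    totld <- score_table$tot_ld
    edges <- unique(stats::quantile(totld, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(edges) < 3) stop("TotLD has too few distinct values to bin")
    bin <- findInterval(totld, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    centers <- (edges[-length(edges)] + edges[-1]) / 2
    evo_col <- score_table[[paste0("ld_", evo_category)]]
    strata <- list(above = evo_col >= score_threshold,
                   below = evo_col < score_threshold,
                   all = rep(TRUE, length(evo_col)))
    out <- data.table::rbindlist(lapply(names(strata), function(snm) {
        mask <- strata[[snm]]
        tab <- data.table::data.table(bin = bin[mask], r = resid_z2[mask])
        agg <- tab[, .(mean_resid_z2 = mean(r), n = .N), keyby = bin]
        present <- agg$bin
        empty <- setdiff(seq_along(centers), present)
        if (length(empty))
            log_stage("residual_vs_totld", stratum = snm,
                      empty_bins_merged = length(empty))
        data.table::data.table(stratum = snm, bin = agg$bin,
                               center = centers[agg$bin],
                               mean_resid_z2 = agg$mean_resid_z2, n = agg$n)
    }))
    out[]
}

#' Restrict an analysis to, or purge it of, the MHC region
#'
#' @param stats summary statistics.
#' @param score_table optional matching `ld_score_table` (same row order).
#' @param mode `"exclude"` drops SNPs inside the region (bounds inclusive);
#'   `"only"` keeps exactly those.
#' @param region list/vector `(chrom, start, end)`; the default is the
#'   extended MHC on chromosome 6 in hg19 coordinates.
#' @return list with filtered `stats` and (if given) `score_table`, plus the
#'   integer `rows` retained.
#' @export
mhc_subset <- function(stats, score_table = NULL,
                       mode = c("exclude", "only"),
                       region = list(chrom = "6", start = 25652429,
                                     end = 33421466)) {
    mode <- match.arg(mode)
    stopifnot(region$start <= region$end)
    inside <- stats$chrom == as.character(region$chrom) &
        stats$pos >= region$start & stats$pos <= region$end
    rows <- if (mode == "exclude") which(!inside) else which(inside)
    if (!length(rows))
        stop("MHC subset (mode = ", mode, ") is empty")
    list(stats = stats[rows],
         score_table = if (!is.null(score_table)) score_table[rows],
         rows = rows)
}

#' Tabulate PLSR fits in a phenotypes x covariates layout
#'
#' @param fits named list (one per phenotype) of jackknifed `plsr_fit`s.
#' @param digits rounding for the coefficient cells (default 3).
#' @param alpha significance level for the `<cov>_sig` markers (default
#'   0.05): `"*"` nominally significant, `"**"` significant after Bonferroni
#'   correction over `n_tests`.
#' @param n_tests Bonferroni divisor; defaults to covariates x phenotypes in
#'   this table.
#' @return data.table: one row per phenotype, one coefficient column per
#'   covariate, with companion `<cov>_sd`, `<cov>_t`, `<cov>_p`,
#'   `<cov>_sig` columns.
#' @export
plsr_table <- function(fits, digits = 3, alpha = 0.05, n_tests = NULL) {
    n_tests <- n_tests %||%
        (length(fits) * length(fits[[1]]$covariates))
    data.table::rbindlist(lapply(names(fits), function(ph) {
        f <- fits[[ph]]
        row <- data.table::data.table(phenotype = ph)
        has_jk <- !is.null(f$jackknife_sd)
        for (cv in f$covariates) {
            pv <- if (has_jk) f$p_value[[cv]] else NA_real_
            row[, (cv) := round(f$coefficients[[cv]], digits)]
            row[, (paste0(cv, "_sd")) := if (has_jk) f$jackknife_sd[[cv]] else NA_real_]
            row[, (paste0(cv, "_t")) := if (has_jk) f$t_stat[[cv]] else NA_real_]
            row[, (paste0(cv, "_p")) := pv]
            row[, (paste0(cv, "_sig")) :=
                    if (is.na(pv)) "" else if (pv < alpha / n_tests) "**"
                    else if (pv < alpha) "*" else ""]
        }
        row
    }))
}
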