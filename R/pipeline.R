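#' Configuration for a full enrichment analysis run
#'
#' Exactly one of `generator` (a [generator_config] for a synthetic study) or
#' `paths` (named list with `stats`, `panel`, `panel_format`, and `tracks`, a
#' named list of BED paths) must be supplied.
#'
#' @param generator a [generator_config], or `NULL`.
#' @param paths input file paths for a real-data run, or `NULL`.
#' @param categories evolutionary categories to analyse (each needs a track).
#' @param window_bp,r2_floor LD neighbourhood parameters.
#' @param score_threshold stratification threshold for fold curves.
#' @param pmax_log -log10(p) cap for fold curves.
#' @param var_threshold PLSR latent-variable selection cutoff.
#' @param k_folds cross-validation fold count for the jackknife.
#' @param n_iter lambda_GC pruning iterations.
#' @param n_matched_sets matched-control sets per category.
#' @param n_bins TotLD bins for the residual summaries.
#' @param mhc_region list `(chrom, start, end)`; defaults to the generator's
#'   MHC-like region for synthetic runs, else the hg19 MHC.
#' @param apply_gc_correction divide squared z-scores by the estimated
#'   lambda_GC before enrichment and regression (off by default; the raw and
#'   corrected routes are both supported).
#' @param seed master seed for every stochastic stage.
#' @param out_dir output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(generator = NULL, paths = NULL,
                       categories = c("HAR", "SD", "Ohno"),
                       window_bp = 1e6, r2_floor = 0.2, score_threshold = 1,
                       pmax_log = 7.3, var_threshold = 0.99, k_folds = 50,
                       n_iter = 100, n_matched_sets = 100, n_bins = 20,
                       mhc_region = NULL, apply_gc_correction = FALSE,
                       seed = 1L, out_dir = "ldenrich_run") {
    if (is.null(generator) == is.null(paths))
        stop("supply exactly one of generator or paths")
    if (is.null(mhc_region)) {
        mhc_region <- if (!is.null(generator)) generator$track_specs$mhc
        else list(chrom = "6", start = 25652429, end = 33421466)
    }
    structure(list(generator = generator, paths = paths,
                   categories = categories, window_bp = window_bp,
                   r2_floor = r2_floor, score_threshold = score_threshold,
                   pmax_log = pmax_log, var_threshold = var_threshold,
                   k_folds = k_folds, n_iter = n_iter,
                   n_matched_sets = n_matched_sets, n_bins = n_bins,
                   mhc_region = mhc_region,
                   apply_gc_correction = apply_gc_correction,
                   seed = as.integer(seed), out_dir = out_dir),
              class = "run_config")
}

load_run_inputs <- function(config) {
    if (!is.null(config$generator)) {
        study <- simulate_study(config$generator)
        list(panel = study$panel, tracks = study$tracks,
             stats_list = list(synthetic = study$stats), truth = study$truth)
    } else {
        p <- config$paths
        panel <- read_panel(p$panel, format = p$panel_format %||% "vcf")
        tracks <- lapply(stats::setNames(names(p$tracks), names(p$tracks)),
                         function(nm) read_track(p$tracks[[nm]], nm))
        stats_paths <- if (is.list(p$stats)) p$stats else list(gwas = p$stats)
        stats_list <- lapply(stats_paths, read_summary_stats)
        list(panel = panel, tracks = tracks, stats_list = stats_list,
             truth = NULL)
    }
}

#' Fold-enrichment curves for brain-gene strata
#'
#' Three strata per evolutionary category: brain score >= threshold, category
#' score >= threshold, and their intersection (SNPs affiliated to the region
#' of interest and annotated to brain genes). An empty intersection stratum
#' is omitted with a log entry.
#'
#' @param score_table an `ld_score_table`.
#' @param stats matching summary statistics.
#' @param category evolutionary category name.
#' @param score_threshold,grid,pmax_log as in [stratify]/[fold_curve].
#' @return named list of `enrichment_curve`s: `brain`, `<category>`,
#'   `<category>_brain`.
#' @export
brain_stratified_curves <- function(score_table, stats, category,
                                    score_threshold = 1, grid = NULL,
                                    pmax_log = 7.3) {
    br <- stratify(score_table, "brain", score_threshold)$in_stratum
    cat_in <- stratify(score_table, category, score_threshold)$in_stratum
    both <- intersect(br, cat_in)
    out <- list()
    out[["brain"]] <- fold_curve(stats, br, grid, pmax_log)
    out[[category]] <- fold_curve(stats, cat_in, grid, pmax_log)
    if (length(both))
        out[[paste0(category, "_brain")]] <- fold_curve(stats, both, grid,
                                                        pmax_log)
    else log_stage("brain_stratified_curves", category = category,
                   note = "empty intersection stratum omitted")
    out
}

plsr_panel_fits <- function(score_table, stats, category, nbhd, panel_rows,
                            config) {
    run_one <- function(st, tb, rows, label) {
        design <- build_design(tb, st, evo_category = category)
        fit <- fit_plsr(design, var_threshold = config$var_threshold)
        folds <- ld_folds(nbhd, rows = panel_rows[rows],
                          k = config$k_folds,
                          seed = sub_seed(config$seed, 7L))
        jackknife_ttest(design, fit, folds)
    }
    all_rows <- seq_len(nrow(stats))
    excl <- mhc_subset(stats, score_table, "exclude", config$mhc_region)
    only <- tryCatch(mhc_subset(stats, score_table, "only", config$mhc_region),
                     error = function(e) NULL)
    fits <- list(all = run_one(stats, score_table, all_rows, "all"),
                 mhc_excluded = run_one(excl$stats, excl$score_table,
                                        excl$rows, "mhc_excluded"))
    if (!is.null(only))
        fits$mhc_only <- tryCatch(
            run_one(only$stats, only$score_table, only$rows, "mhc_only"),
            error = function(e) {
                log_stage("plsr", panel = "mhc_only",
                          note = conditionMessage(e))
                NULL
            })
    fits[!vapply(fits, is.null, logical(1))]
}

#' Run the full enrichment analysis
#'
#' Orchestrates annotation scoring, lambda_GC estimation, conditional
#' fold-enrichment curves (all SNPs, MHC-excluded, brain-stratified), PLSR
#' with jackknife t-tests in the all / MHC-excluded / MHC-only layouts,
#' TotLD residual summaries and matched-control envelopes, writing one table
#' per artifact plus a manifest with every seed, threshold and content hash.
#'
#' @param config a [run_config].
#' @return (invisibly) a list with the in-memory results: `score_table`,
#'   `lambda`, `curves`, `plsr`, `matched`, `manifest`.
#' @export
run_full <- function(config) {
    out_dir <- config$out_dir
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    t0 <- Sys.time()

    stage <- "load_inputs"
    res <- tryCatch({
        inputs <- load_run_inputs(config)
        panel <- inputs$panel
        tracks <- inputs$tracks
        log_stage(stage, n_variants = nrow(panel$variants),
                  n_phenotypes = length(inputs$stats_list))

        stage <- "ld_annotation"
        nbhd <- compute_ld(panel, config$window_bp, config$r2_floor)
        score_all <- build_score_table(panel, tracks, nbhd = nbhd)
        write_score_table(score_all, file.path(out_dir, "score_table.tsv"))
        log_stage(stage, pairs = nrow(nbhd$pairs))

        curves <- list(); plsr_fits <- list(); matched <- list()
        lambdas <- list()
        for (ph in names(inputs$stats_list)) {
            stage <- paste0("align:", ph)
            stats <- align_stats(inputs$stats_list[[ph]], panel)
            rows <- stats$panel_col
            tb <- score_all[rows]

            stage <- paste0("lambda_gc:", ph)
            lam <- estimate_lambda(stats, tb$intergenic, nbhd,
                                   n_iter = config$n_iter,
                                   seed = sub_seed(config$seed, 5L),
                                   panel_col = rows)
            lambdas[[ph]] <- lam
            write_lambda_report(lam, file.path(out_dir,
                                               paste0("lambda_", ph, ".json")))
            log_stage(stage, lambda = sprintf("%.3f", lam$lambda_gc))
            if (config$apply_gc_correction) stats <- apply_gc(stats, lam)

            for (cat in config$categories) {
                stage <- paste0("enrichment:", ph, ":", cat)
                strat <- stratify(tb, cat, config$score_threshold)
                cv <- fold_curve(stats, strat$in_stratum,
                                 pmax_log = config$pmax_log)
                write_curve(cv, file.path(out_dir,
                                          paste0("enrich_", ph, "_", cat, ".tsv")))
                excl <- mhc_subset(stats, tb, "exclude", config$mhc_region)
                strat_x <- stratify(excl$score_table, cat,
                                    config$score_threshold)
                cv_x <- fold_curve(excl$stats, strat_x$in_stratum,
                                   pmax_log = config$pmax_log)
                write_curve(cv_x, file.path(out_dir,
                                            paste0("enrich_", ph, "_", cat,
                                                   "_noMHC.tsv")))
                bc <- brain_stratified_curves(tb, stats, cat,
                                              config$score_threshold,
                                              pmax_log = config$pmax_log)
                for (nm in names(bc))
                    write_curve(bc[[nm]],
                                file.path(out_dir,
                                          paste0("enrich_", ph, "_brainstrat_",
                                                 nm, ".tsv")))
                curves[[paste(ph, cat, sep = ":")]] <- cv

                stage <- paste0("plsr:", ph, ":", cat)
                fits <- plsr_panel_fits(tb, stats, cat, nbhd, rows, config)
                for (panel_nm in names(fits)) {
                    tab <- plsr_table(stats::setNames(list(fits[[panel_nm]]), ph))
                    data.table::fwrite(tab,
                                       file.path(out_dir,
                                                 paste0("plsr_", ph, "_", cat,
                                                        "_", panel_nm, ".tsv")),
                                       sep = "\t", quote = FALSE)
                }
                plsr_fits[[paste(ph, cat, sep = ":")]] <- fits

                stage <- paste0("residuals:", ph, ":", cat)
                rt <- residual_vs_totld(tb, stats, cat, n_bins = config$n_bins,
                                        score_threshold = config$score_threshold,
                                        var_threshold = config$var_threshold)
                data.table::fwrite(rt,
                                   file.path(out_dir,
                                             paste0("residual_totld_", ph, "_",
                                                    cat, ".tsv")),
                                   sep = "\t", quote = FALSE)

                stage <- paste0("matched:", ph, ":", cat)
                src <- which(tb[[paste0("raw_", cat)]] == 1L)
                if (length(src)) {
                    spec <- match_spec(tb, n_sets = config$n_matched_sets,
                                       seed = sub_seed(config$seed, 9L),
                                       allow_reuse = TRUE)
                    sets <- sample_matched(src, tb, spec)
                    me <- matched_enrichment(sets, stats,
                                             pmax_log = config$pmax_log)
                    data.table::fwrite(me$envelope,
                                       file.path(out_dir,
                                                 paste0("matched_envelope_",
                                                        ph, "_", cat, ".tsv")),
                                       sep = "\t", quote = FALSE)
                    matched[[paste(ph, cat, sep = ":")]] <- me$envelope
                } else {
                    log_stage(stage, note = "no source SNPs; matched controls skipped")
                }
            }
        }

        stage <- "manifest"
        files <- setdiff(list.files(out_dir), "manifest.json")
        manifest <- list(
            seed = config$seed,
            thresholds = config[c("window_bp", "r2_floor", "score_threshold",
                                  "pmax_log", "var_threshold", "k_folds",
                                  "n_iter", "n_matched_sets", "n_bins")],
            mhc_region = config$mhc_region,
            categories = config$categories,
            elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
            files = lapply(stats::setNames(files, files), function(f)
                unname(tools::md5sum(file.path(out_dir, f)))))
        jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                             auto_unbox = TRUE, digits = NA)
        list(score_table = score_all, lambda = lambdas, curves = curves,
             plsr = plsr_fits, matched = matched, manifest = manifest,
             truth = inputs$truth, out_dir = out_dir)
    }, error = function(e) {
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE)
    })
    invisible(res)
}
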