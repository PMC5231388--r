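#' Construct and validate a GWAS summary-statistics table
#'
#' One row per SNP with identifier, position, alleles, association p-value
#' and/or z-score, and sample size. When only p is available the z magnitude is
#' derived from the two-sided normal relation and its (unknown) sign flagged;
#' every downstream statistic in this package uses z^2 or p only, so the sign
#' convention is inconsequential.
#'
#' @param dt data.frame/data.table with columns `snp_id`, `chrom`, `pos`,
#'   `a1`, `a2`, and at least one of `p`, `z`; optionally `n`, `maf`.
#' @param z_precedence when both p and z are present but inconsistent, which
#'   one wins (`"z"` recomputes p from z; `"p"` recomputes z magnitude from p).
#' @param drop_invalid drop rows with invalid p (outside (0, 1]) or
#'   non-positive positions instead of erroring.
#' @param p_floor if set (e.g. 1e-300), p-values of 0 or below are floored at
#'   this value instead of being dropped.
#' @return A `summary_stats` data.table with columns `snp_id`, `chrom`, `pos`,
#'   `a1`, `a2`, `p`, `z`, `n`, `maf`, `z_sign_known`; attribute `n_dropped`
#'   counts discarded rows.
#' @export
summary_stats <- function(dt, z_precedence = c("z", "p"), drop_invalid = TRUE,
                          p_floor = NULL) {
    z_precedence <- match.arg(z_precedence)
    dt <- data.table::as.data.table(dt)
    req <- c("snp_id", "chrom", "pos", "a1", "a2")
    miss <- setdiff(req, names(dt))
    if (length(miss))
        stop("summary statistics missing mandatory columns: ",
             paste(miss, collapse = ", "))
    if (!any(c("p", "z") %in% names(dt)))
        stop("summary statistics need a p or z column")
    dt <- data.table::copy(dt)
    for (col in c("p", "z", "maf")) if (!col %in% names(dt)) dt[, (col) := NA_real_]
    if (!"n" %in% names(dt)) dt[, n := NA_integer_]
    dt[, `:=`(snp_id = as.character(snp_id), chrom = as.character(chrom),
              pos = as.integer(pos), a1 = toupper(as.character(a1)),
              a2 = toupper(as.character(a2)), p = as.numeric(p),
              z = as.numeric(z), n = as.integer(n), maf = as.numeric(maf))]

    if (!is.null(p_floor)) dt[!is.na(p) & p <= 0, p := p_floor]
    bad <- (!is.na(dt$p) & (dt$p <= 0 | dt$p > 1)) |
        (is.na(dt$p) & is.na(dt$z)) |
        is.na(dt$pos) | dt$pos <= 0 | is.na(dt$snp_id)
    n_dropped <- sum(bad)
    if (n_dropped) {
        if (!drop_invalid) stop(n_dropped, " invalid summary-statistic rows")
        log_stage("summary_stats", dropped = n_dropped)
        dt <- dt[!bad]
    }
    if (!nrow(dt)) stop("no valid summary-statistic rows remain")
    if (anyDuplicated(dt$snp_id)) stop("duplicated snp_id in summary statistics")

    sign_known <- !is.na(dt$z)
    both <- !is.na(dt$p) & !is.na(dt$z)
    if (any(both)) {
        pz <- p_from_z(dt$z[both])
        rel <- abs(pz - dt$p[both]) / pmax(dt$p[both], .Machine$double.xmin)
        n_bad <- sum(rel > 1e-6)
        if (n_bad) {
            warning(n_bad, " rows with p/z inconsistent beyond 1e-6 relative; ",
                    "keeping ", z_precedence, " per precedence")
            if (z_precedence == "z") dt[both, p := p_from_z(z)]
            else dt[both, z := sign(z) * z_from_p(p)]
        }
    }
    dt[is.na(z), z := z_from_p(p)]
    dt[is.na(p), p := p_from_z(z)]
    dt[, z_sign_known := sign_known]
    data.table::setattr(dt, "n_dropped", n_dropped)
    data.table::setattr(dt, "class", c("summary_stats", class(dt)))
    dt[]
}

#' Read GWAS summary statistics from a delimited text file
#'
#' @param path tab- or whitespace-delimited file with a header row.
#' @param column_map named character vector mapping internal names
#'   (`snp_id`, `chrom`, `pos`, `a1`, `a2`, `p`, `z`, `n`, `maf`) to the
#'   file's column names. Defaults cover the conventional
#'   SNP/CHR/BP/A1/A2/P/Z/N layout.
#' @inheritParams summary_stats
#' @return A validated [summary_stats] table.
#' @export
read_summary_stats <- function(path,
                               column_map = c(snp_id = "SNP", chrom = "CHR",
                                              pos = "BP", a1 = "A1", a2 = "A2",
                                              p = "P", z = "Z", n = "N",
                                              maf = "MAF"),
                               z_precedence = c("z", "p")) {
    raw <- data.table::fread(path, header = TRUE)
    present <- column_map[column_map %in% names(raw)]
    mandatory <- c("snp_id", "chrom", "pos", "a1", "a2")
    miss <- setdiff(mandatory, names(present))
    if (length(miss))
        stop("file ", path, " lacks columns for: ", paste(miss, collapse = ", "))
    if (!any(c("p", "z") %in% names(present)))
        stop("file ", path, " has neither a p nor a z column")
    dt <- raw[, unname(present), with = FALSE]
    data.table::setnames(dt, names(present))
    summary_stats(dt, z_precedence = z_precedence)
}

#' Write summary statistics in the conventional tabular layout
#'
#' @param stats a [summary_stats] table.
#' @param path output TSV path.
#' @export
write_summary_stats <- function(stats, path) {
    out <- data.table::data.table(SNP = stats$snp_id, CHR = stats$chrom,
                                  BP = stats$pos, A1 = stats$a1, A2 = stats$a2,
                                  P = stats$p, Z = stats$z, N = stats$n,
                                  MAF = stats$maf)
    data.table::fwrite(out, path, sep = "\t", na = "NA", quote = FALSE)
    invisible(path)
}

#' Construct a reference genotype panel
#'
#' @param variants data.frame with columns `snp_id`, `chrom`, `pos`, `a1`,
#'   `a2` (one row per variant).
#' @param dosages samples x variants matrix of a1 allele counts in {0, 1, 2}.
#' @param drop_monomorphic remove zero-variance variants (default) rather than
#'   erroring on them.
#' @return A `ref_panel` object: list with elements `variants` (sorted by
#'   chromosome and position) and `dosages` (columns in the same order).
#' @export
ref_panel <- function(variants, dosages, drop_monomorphic = TRUE) {
    variants <- data.table::as.data.table(variants)
    req <- c("snp_id", "chrom", "pos", "a1", "a2")
    miss <- setdiff(req, names(variants))
    if (length(miss))
        stop("panel variants missing columns: ", paste(miss, collapse = ", "))
    dosages <- as.matrix(dosages)
    if (ncol(dosages) != nrow(variants))
        stop("dosage column count (", ncol(dosages),
             ") does not match variant count (", nrow(variants), ")")
    if (nrow(dosages) < 2) stop("reference panel needs at least 2 samples")
    variants[, `:=`(snp_id = as.character(snp_id), chrom = as.character(chrom),
                    pos = as.integer(pos), a1 = toupper(as.character(a1)),
                    a2 = toupper(as.character(a2)))]
    ord <- order(variants$chrom, variants$pos)
    variants <- variants[ord]
    dosages <- dosages[, ord, drop = FALSE]
    if (anyDuplicated(variants[, .(chrom, pos)]))
        stop("duplicate positions within a chromosome in the panel")
    v <- matrixStats_colVars(dosages)
    mono <- v <= 0
    if (any(mono)) {
        if (!drop_monomorphic) stop(sum(mono), " monomorphic variants in panel")
        log_stage("ref_panel", monomorphic_removed = sum(mono))
        variants <- variants[!mono]
        dosages <- dosages[, !mono, drop = FALSE]
    }
    if (!nrow(variants)) stop("no polymorphic variants remain in panel")
    colnames(dosages) <- variants$snp_id
    structure(list(variants = variants, dosages = dosages), class = "ref_panel")
}

# Column variances without extra dependencies.
matrixStats_colVars <- function(x) {
    mu <- colMeans(x)
    colSums(x * x) / nrow(x) - mu * mu
}

#' @export
print.ref_panel <- function(x, ...) {
    cat("Reference panel:", nrow(x$variants), "variants x",
        nrow(x$dosages), "samples on",
        length(unique(x$variants$chrom)), "chromosome(s)\n")
    invisible(x)
}

#' Minor allele frequency of every panel variant
#' @param panel a [ref_panel].
#' @return numeric vector in (0, 0.5], one per variant.
#' @export
panel_maf <- function(panel) {
    f <- colMeans(panel$dosages) / 2
    pmin(f, 1 - f)
}

#' Read a reference panel from VCF or a dosage-matrix file pair
#'
#' The `matrix` format is a whitespace-delimited dosage table (one row per
#' variant, one column per sample, values 0/1/2, no header) accompanied by a
#' sidecar `<path>.vars` TSV with header columns snp_id, chrom, pos, a1, a2 in
#' the same row order. The VCF route takes biallelic SNP GT records; dosages
#' count the REF (a1) allele.
#'
#' @param path VCF (.vcf or .vcf.gz) or dosage-matrix file.
#' @param format `"vcf"` or `"matrix"`.
#' @return A [ref_panel].
#' @export
read_panel <- function(path, format = c("vcf", "matrix")) {
    format <- match.arg(format)
    if (format == "vcf") {
        if (!requireNamespace("vcfR", quietly = TRUE))
            stop("reading VCF panels requires the vcfR package")
        v <- vcfR::read.vcfR(path, verbose = FALSE)
        fix <- data.table::as.data.table(vcfR::getFIX(v))
        gt <- vcfR::extract.gt(v, element = "GT")
        keep <- nchar(fix$REF) == 1 & nchar(fix$ALT) == 1 & !is.na(fix$ALT)
        fix <- fix[keep]
        gt <- gt[keep, , drop = FALSE]
        # count REF alleles: dosage of a1 = 2 - (# ALT alleles)
        alt_count <- apply(gt, 1:2, function(g) {
            if (is.na(g)) return(NA_real_)
            sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
        })
        dos <- t(2 - alt_count)
        variants <- data.table::data.table(
            snp_id = ifelse(is.na(fix$ID) | fix$ID == ".",
                            paste0(fix$CHROM, ":", fix$POS), fix$ID),
            chrom = fix$CHROM, pos = as.integer(fix$POS),
            a1 = fix$REF, a2 = fix$ALT)
        ref_panel(variants, dos)
    } else {
        sidecar <- paste0(path, ".vars")
        if (!file.exists(sidecar))
            stop("dosage matrix sidecar not found: ", sidecar)
        variants <- data.table::fread(sidecar, header = TRUE)
        dos <- as.matrix(data.table::fread(path, header = FALSE))
        if (nrow(dos) != nrow(variants))
            stop("dosage matrix has ", nrow(dos), " rows but sidecar has ",
                 nrow(variants), " variants")
        ref_panel(variants, t(dos))
    }
}

#' Write a panel in the dosage-matrix format consumed by [read_panel]
#' @param panel a [ref_panel].
#' @param path output path; the variant sidecar goes to `<path>.vars`.
#' @export
write_panel_matrix <- function(panel, path) {
    data.table::fwrite(data.table::as.data.table(t(panel$dosages)), path,
                       sep = "\t", col.names = FALSE, quote = FALSE)
    data.table::fwrite(panel$variants, paste0(path, ".vars"), sep = "\t",
                       quote = FALSE)
    invisible(path)
}

#' Construct an annotation track (a named set of genomic intervals)
#'
#' Intervals are 0-based half-open `[start, end)`, the BED convention; a SNP
#' at 1-based position q lies inside `[s, e)` iff `s < q <= e`.
#'
#' @param name track name (e.g. "HAR", "exon", "brain").
#' @param intervals data.frame with columns `chrom`, `start`, `end`; may be
#'   empty; intervals may overlap (membership is by union).
#' @return An `annot_track` object.
#' @export
annot_track <- function(name, intervals) {
    intervals <- data.table::as.data.table(intervals)
    if (!nrow(intervals)) {
        intervals <- data.table::data.table(chrom = character(),
                                            start = integer(), end = integer())
    } else {
        miss <- setdiff(c("chrom", "start", "end"), names(intervals))
        if (length(miss))
            stop("track intervals missing columns: ", paste(miss, collapse = ", "))
        intervals <- intervals[, .(chrom = as.character(chrom),
                                   start = as.integer(start),
                                   end = as.integer(end))]
        bad <- which(intervals$start >= intervals$end)
        if (length(bad))
            stop("track '", name, "': start >= end at interval ", bad[1])
    }
    structure(list(name = name, intervals = intervals), class = "annot_track")
}

#' Read a BED3 annotation track
#'
#' @param path BED3+ file (first three columns used); coordinates are kept as
#'   written (0-based half-open).
#' @param name track name (taken from this argument, not the BED name column).
#' @return An [annot_track].
#' @export
read_track <- function(path, name) {
    if (file.size(path) == 0) return(annot_track(name, NULL))
    dt <- tryCatch(data.table::fread(path, header = FALSE, select = 1:3),
                   error = function(e) NULL)
    if (is.null(dt) || !nrow(dt))
        return(annot_track(name, NULL))
    data.table::setnames(dt, c("chrom", "start", "end"))
    bad <- which(as.integer(dt$start) >= as.integer(dt$end))
    if (length(bad))
        stop("BED file ", path, ": start >= end at line ", bad[1])
    annot_track(name, dt)
}

#' Write an annotation track as BED3
#' @param track an [annot_track].
#' @param path output path.
#' @export
write_track <- function(track, path) {
    data.table::fwrite(track$intervals, path, sep = "\t", col.names = FALSE,
                       quote = FALSE)
    invisible(path)
}

track_granges <- function(track) {
    iv <- track$intervals
    if (!nrow(iv))
        return(GenomicRanges::GRanges())
    # BED [start, end) covers 1-based positions start+1 .. end
    GenomicRanges::reduce(GenomicRanges::GRanges(
        iv$chrom, IRanges::IRanges(iv$start + 1L, iv$end)))
}

#' Align summary statistics to a reference panel
#'
#' Inner join on (chrom, pos) with the allele pair matched up to swap; a
#' swapped match (stats a1/a2 equal panel a2/a1) flips the z sign. Sites with
#' alleles that match neither way are excluded. Strand-ambiguous pairs (A/T,
#' C/G) are kept as-is by default; no strand flip is attempted.
#'
#' @param stats a [summary_stats] table.
#' @param panel a [ref_panel].
#' @param drop_ambiguous drop A/T and C/G sites before matching.
#' @return An `aligned_index` data.table with one row per matched SNP, in
#'   panel order: `snp_id`, `chrom`, `pos`, `panel_col` (column in the panel
#'   dosage matrix), `swapped`, plus the harmonized `p`, `z` (sign flipped on
#'   swaps), `n`, `maf` (filled from the panel where missing).
#' @export
align_stats <- function(stats, panel, drop_ambiguous = FALSE) {
    s <- data.table::as.data.table(stats)
    if (drop_ambiguous) {
        amb <- (s$a1 == "A" & s$a2 == "T") | (s$a1 == "T" & s$a2 == "A") |
            (s$a1 == "C" & s$a2 == "G") | (s$a1 == "G" & s$a2 == "C")
        s <- s[!amb]
    }
    pv <- data.table::copy(panel$variants)[, panel_col := .I]
    m <- merge(s, pv, by = c("chrom", "pos"), suffixes = c("", ".panel"))
    direct <- m$a1 == m$a1.panel & m$a2 == m$a2.panel
    swapped <- m$a1 == m$a2.panel & m$a2 == m$a1.panel & !direct
    m <- m[direct | swapped]
    if (!nrow(m)) stop("no variants shared between summary statistics and panel")
    m[, swapped := a1 == a2.panel & a2 == a1.panel & !(a1 == a1.panel & a2 == a2.panel)]
    m[, z := ifelse(swapped, -z, z)]
    pmaf <- panel_maf(panel)
    m[is.na(maf), maf := pmaf[panel_col]]
    data.table::setorder(m, panel_col)
    out <- m[, .(snp_id, chrom, pos, panel_col, swapped, p, z, n, maf,
                 z_sign_known)]
    data.table::setattr(out, "class", c("aligned_index", class(out)))
    out[]
}
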