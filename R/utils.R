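#' @useDynLib ldenrich, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
        on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
                add = TRUE)
    }
    set.seed(seed)
    force(code)
}

# Derive a reproducible sub-seed from a base seed; kept within 32-bit range.
sub_seed <- function(seed, k) {
    as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12721L) %% 2147483587)
}

#' Convert two-sided p-values to z-score magnitudes and back
#'
#' The two-sided normal relation \eqn{p = 2\Phi(-|z|)} links GWAS p-values and
#' association z-scores. Signs are not recoverable from p alone.
#'
#' @param p p-values in (0, 1].
#' @param z z-scores (signed or not; only the magnitude matters).
#' @return `z_from_p`: non-negative z magnitudes; `p_from_z`: two-sided
#'   p-values.
#' @examples
#' z_from_p(c(0.5, 0.05))
#' p_from_z(1.96)
#' @export
z_from_p <- function(p) {
    stats::qnorm(p / 2, lower.tail = FALSE)
}

#' @rdname z_from_p
#' @export
p_from_z <- function(z) {
    2 * stats::pnorm(-abs(z))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One structured log line per stage; suppressible via suppressMessages().
log_stage <- function(stage, ...) {
    kv <- list(...)
    msg <- paste0("[", stage, "]",
                  if (length(kv))
                      paste0(" ", paste(names(kv), unlist(kv), sep = "=",
                                        collapse = " ")))
    message(msg)
}
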