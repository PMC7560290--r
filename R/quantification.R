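#' Fit a qPCR standard curve and derive amplification efficiency
#'
#' Ordinary least-squares fit of `Ct = slope * log10(dilution) + intercept`
#' over a serial dilution. The amplification efficiency follows from the
#' slope as `E(%) = (10^(-1/slope) - 1) * 100`: a perfectly doubling reaction
#' has slope `-1/log10(2) = -3.32193` and efficiency 100%. The curve is
#' flagged reliable when the efficiency lies in the conventional 90-115%
#' acceptance window (inclusive).
#'
#' @param log10_dilution numeric vector of log10 relative template amounts
#'   (e.g. `0, -1, -2, ...`), or a 2-column data frame `(log10_dilution, ct)`.
#' @param ct numeric vector of observed Ct values (omit when a data frame is
#'   given).
#' @param reliable_range efficiency acceptance window in percent, default
#'   `c(90, 115)`.
#' @return Object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `efficiency_percent`, `reliable`, `n_points`.
#' @examples
#' fit_standard_curve(c(0, -1, -2, -3), 20 - 1 / log10(2) * c(0, -1, -2, -3))
#' @export
fit_standard_curve <- function(log10_dilution, ct = NULL,
                               reliable_range = c(90, 115)) {
  if (is.data.frame(log10_dilution) || is.matrix(log10_dilution)) {
    pts <- as.data.frame(log10_dilution)
    ct <- pts[[2L]]
    log10_dilution <- pts[[1L]]
  }
  x <- as.numeric(log10_dilution)
  y <- as.numeric(ct)
  if (length(x) != length(y)) stop("dilution and ct lengths differ")
  if (length(unique(x)) < 3L) stop("need at least 3 distinct dilution levels")
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  intercept <- unname(stats::coef(fit)[1L])
  if (!is.finite(slope) || slope >= 0)
    stop("degenerate standard curve: slope is ", signif(slope, 4),
         " (Ct must decrease with template amount)")
  r2 <- stats::cor(x, y)^2
  eff <- efficiency_from_slope(slope)
  tol <- 1e-9  # keep the inclusive window robust to float rounding
  structure(list(slope = slope, intercept = intercept, r_squared = r2,
                 efficiency_percent = eff,
                 reliable = eff >= reliable_range[1] - tol &
                   eff <= reliable_range[2] + tol,
                 reliable_range = reliable_range, n_points = length(x)),
            class = "standard_curve")
}

#' Amplification efficiency (percent) from a standard-curve slope
#'
#' @param slope cycles per log10 dilution (negative for a valid curve).
#' @return `(10^(-1/slope) - 1) * 100`.
#' @export
efficiency_from_slope <- function(slope) (10^(-1 / slope) - 1) * 100

#' Relative expression by the 2^-ddCt method
#'
#' Normalises a target gene against one or more reference genes and expresses
#' each sample relative to a calibrator sample. The reference summary Ct per
#' sample is the arithmetic mean of the reference genes' Ct, which at 100%
#' efficiency equals normalising by the geometric mean of their relative
#' quantities. Then `dCt = Ct_target - Ct_ref`, `ddCt = dCt - dCt(calibrator)`
#' and `fold_change = 2^-ddCt`; the calibrator's fold change is exactly 1.
#'
#' @param m a [ct_matrix()] containing the target and all reference genes.
#' @param target target gene id (must not be among `references`).
#' @param references non-empty character vector of reference gene ids.
#' @param calibrator sample id whose expression defines fold change 1.
#' @return Object of class `ddct_result` with a per-sample data frame
#'   `table` (`sample`, `delta_ct`, `delta_delta_ct`, `fold_change`) plus the
#'   call parameters.
#' @examples
#' m <- ct_matrix(matrix(c(25, 23, 20, 20), nrow = 2, byrow = TRUE,
#'                dimnames = list(c("tgt", "ref"), c("calib", "s2"))))
#' relative_expression_ddct(m, "tgt", "ref", "calib")$table$fold_change
#' @export
relative_expression_ddct <- function(m, target, references, calibrator) {
  stopifnot(inherits(m, "ct_matrix"))
  if (!length(references)) stop("references must be non-empty")
  if (target %in% references) stop("target gene cannot be a reference")
  need <- c(target, references)
  absent <- setdiff(need, rownames(m))
  if (length(absent)) stop("genes absent from Ct matrix: ",
                           paste(absent, collapse = ", "))
  if (!calibrator %in% colnames(m))
    stop("calibrator sample not in Ct matrix: ", calibrator)
  sub <- unclass(m)[need, , drop = FALSE]
  if (anyNA(sub)) stop("missing Ct for target or reference genes")
  ref_ct <- colMeans(sub[references, , drop = FALSE])
  d_ct <- sub[target, ] - ref_ct
  dd_ct <- d_ct - d_ct[calibrator]
  fold <- 2^(-dd_ct)
  structure(list(table = data.frame(sample = colnames(m), delta_ct = d_ct,
                                    delta_delta_ct = dd_ct, fold_change = fold,
                                    row.names = NULL),
                 target = target, references = references,
                 calibrator = calibrator),
            class = "ddct_result")
}

#' Per-replicate fold changes and their dispersion
#'
#' Applies the ddCt computation separately to each biological replicate of a
#' replicate-level Ct table (technical replicates averaged first) and reports,
#' per sample, the mean fold change and its SD across replicates — the usual
#' error bars of relative-expression plots.
#'
#' @param x a [ct_table()] whose `replicate` column labels biological
#'   replicates (average technical replicates beforehand if they are nested).
#' @inheritParams relative_expression_ddct
#' @return Data frame `sample`, `mean_fold_change`, `sd_fold_change`,
#'   `n_replicates`.
#' @export
ddct_replicate_summary <- function(x, target, references, calibrator) {
  stopifnot(inherits(x, "ct_table"))
  reps <- unique(x$replicate)
  per_rep <- lapply(reps, function(r) {
    sub <- x[x$replicate == r, , drop = FALSE]
    m <- aggregate_replicates(ct_table(sub))
    relative_expression_ddct(m, target, references, calibrator)$table
  })
  samples <- unique(x$sample)
  fold <- sapply(per_rep, function(tb) {
    stats::setNames(tb$fold_change, tb$sample)[samples]
  })
  fold <- matrix(fold, nrow = length(samples),
                 dimnames = list(samples, NULL))
  data.frame(sample = samples,
             mean_fold_change = rowMeans(fold),
             sd_fold_change = apply(fold, 1L, stats::sd),
             n_replicates = length(reps), row.names = NULL)
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve: slope %.4f, intercept %.3f, R^2 %.4f\n  efficiency %.1f%% (%sreliable in [%g, %g]%%)\n",
    x$slope, x$intercept, x$r_squared, x$efficiency_percent,
    if (x$reliable) "" else "NOT ", x$reliable_range[1], x$reliable_range[2]))
  invisible(x)
}

#' @export
print.ddct_result <- function(x, ...) {
  cat(sprintf("2^-ddCt: %s vs %s, calibrator %s\n", x$target,
              paste(x$references, collapse = "+"), x$calibrator))
  print(x$table)
  invisible(x)
}
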