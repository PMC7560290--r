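#' Comparative delta-Ct stability
#'
#' For every ordered gene pair (i, j) the per-sample difference
#' `dCt_ij(s) = Ct_i(s) - Ct_j(s)` is formed; its sample standard deviation
#' (n-1 denominator) measures how much the pair co-varies. A gene's stability
#' score is the mean of its pairwise SDs against all other genes; lower is more
#' stable. Per-sample loading shifts cancel in the differences, so the method
#' is invariant to adding any constant to all genes of one sample.
#'
#' @param m a [ct_matrix()] with at least 3 genes and 3 samples.
#' @param subset optional [sample_set()].
#' @return Object of class `delta_ct_result`: `score` (named, cycles), `rank`
#'   (average ranks, 1 = most stable) and `pairwise_sd` (symmetric gene x gene
#'   matrix, zero diagonal).
#' @examples
#' m <- ct_matrix(matrix(c(20, 20, 20, 22, 23, 24, 30, 30, 31), nrow = 3,
#'                byrow = TRUE, dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3"))))
#' delta_ct_method(m)$score
#' @export
delta_ct_method <- function(m, subset = NULL) {
  m <- subset_ct_matrix(m, subset)
  check_stability_input(m, min_genes = 3L, min_samples = 3L)
  genes <- rownames(m)
  k <- length(genes)
  sd_mat <- matrix(0, k, k, dimnames = list(genes, genes))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      s <- sample_sd(m[i, ] - m[j, ])
      sd_mat[i, j] <- sd_mat[j, i] <- s
    }
  }
  score <- rowSums(sd_mat) / (k - 1L)
  structure(list(score = score, rank = rank_ascending(score),
                 pairwise_sd = sd_mat),
            class = c("delta_ct_result", "stability_result"))
}

#' geNorm stability and pairwise-variation series
#'
#' Works on relative quantities `q` (see [to_relative_quantities()]). For a
#' gene pair (j, k), `A_jk(s) = log2(q_j(s) / q_k(s))`; the pairwise variation
#' `V_jk` is the sample SD of `A_jk` and the stability value `M_j` is the mean
#' of `V_jk` over all partners k. In the canonical stepwise mode, the gene with
#' the highest M is excluded and M values are recomputed within the surviving
#' set until two genes remain; the reported rank is the reverse removal order,
#' with the final pair ordered by full-set M, then alphabetically.
#'
#' The V series drives the choice of how many reference genes to combine:
#' `NF_n(s)` is the geometric mean of `q` over the top n ranked genes and
#' `V_n` is the sample SD of `log2(NF_n / NF_(n+1))`, for n = 2..k-1.
#'
#' @param q a `rel_quantities` object, or a [ct_matrix()] which is converted
#'   with fold amplification 2 per cycle.
#' @param subset optional [sample_set()] (applied before conversion when `q`
#'   is a Ct matrix).
#' @param mode `"stepwise"` (canonical, default) or `"full_set"` (rank by M on
#'   the full gene set, no exclusion).
#' @return Object of class `genorm_result` with `full_set_M`, `stepwise_M`
#'   (each gene's M at its exclusion step), `removal_order`, `rank`,
#'   `pairwise_V` and `v_series` (data frame `n`, `V`).
#' @export
genorm <- function(q, subset = NULL, mode = c("stepwise", "full_set")) {
  mode <- match.arg(mode)
  if (inherits(q, "ct_matrix")) q <- to_relative_quantities(q, 2.0, subset)
  stopifnot(inherits(q, "rel_quantities"))
  qm <- q$q
  if (!is.null(subset)) {
    stopifnot(inherits(subset, "sample_set"))
    absent <- setdiff(subset$samples, colnames(qm))
    if (length(absent)) stop("samples absent from quantities: ",
                             paste(absent, collapse = ", "))
    qm <- qm[, subset$samples, drop = FALSE]
  }
  if (any(qm <= 0)) stop("relative quantities must be positive")
  if (nrow(qm) < 3L || ncol(qm) < 3L)
    stop("geNorm requires at least 3 genes and 3 samples")
  a <- log2(qm)
  genes <- rownames(a)
  k <- length(genes)

  m_values <- function(mat) {
    kk <- nrow(mat)
    v <- matrix(0, kk, kk, dimnames = list(rownames(mat), rownames(mat)))
    for (i in seq_len(kk - 1L)) {
      for (j in (i + 1L):kk) {
        s <- sample_sd(mat[i, ] - mat[j, ])
        v[i, j] <- v[j, i] <- s
      }
    }
    list(M = rowSums(v) / (kk - 1L), V = v)
  }

  full <- m_values(a)
  full_set_M <- full$M

  removal_order <- character(0)
  stepwise_M <- stats::setNames(numeric(k), genes)
  if (mode == "stepwise") {
    surviving <- genes
    while (length(surviving) > 2L) {
      M <- m_values(a[surviving, , drop = FALSE])$M
      worst <- names(M)[order(-M, names(M))][1L]  # ties: alphabetically last kept
      stepwise_M[worst] <- M[worst]
      removal_order <- c(removal_order, worst)
      surviving <- setdiff(surviving, worst)
    }
    final_M <- m_values(a[surviving, , drop = FALSE])$M
    stepwise_M[surviving] <- final_M
    # final pair ordered by full-set M, then lexicographically
    pair <- surviving[order(full_set_M[surviving], surviving)]
    ranked <- c(pair, rev(removal_order))
    rank <- stats::setNames(seq_len(k), ranked)[genes]
  } else {
    rank <- rank_ascending(full_set_M)
  }

  # top-n membership for the NF series follows the reported ranking
  top <- genes[order(rank, genes)]
  v_series <- if (k >= 3L) {
    vs <- vapply(2:(k - 1L), function(n) {
      nf_n <- colMeans(a[top[1:n], , drop = FALSE])        # log2 geometric mean
      nf_n1 <- colMeans(a[top[1:(n + 1L)], , drop = FALSE])
      sample_sd(nf_n - nf_n1)
    }, numeric(1))
    data.frame(n = 2:(k - 1L), V = vs)
  } else {
    data.frame(n = integer(0), V = numeric(0))
  }

  structure(list(full_set_M = full_set_M, stepwise_M = stepwise_M,
                 removal_order = removal_order, rank = rank,
                 score = if (mode == "stepwise") stepwise_M else full_set_M,
                 pairwise_V = full$V, v_series = v_series, mode = mode),
            class = c("genorm_result", "stability_result"))
}

#' NormFinder-style stability via variance decomposition
#'
#' Operates on `y = -Ct`, i.e. log2 expression up to a per-gene constant at
#' 100% efficiency. Each sample (column) is first centred across genes, which
#' removes per-sample loading differences. In ungrouped mode the additive model
#' `y_ij = alpha_i + beta_j + eps_ij` with gene-specific error variance
#' `sigma_i^2` is fitted; the per-gene variance is recovered from the two-way
#' residuals by a moment estimator that corrects the bias introduced by joint
#' centering (unbiased for any k >= 3), and the stability value is
#' `sigma_hat_i` (negative variance estimates floored at 0). In grouped mode
#' the stability combines the absolute inter-group deviation `d_ig` of gene i
#' in group g with the within-group error:
#' `(1/G) * sum_g ( |d_ig| + sqrt(sigma2_ig / n_g) )`.
#'
#' @param m a [ct_matrix()].
#' @param subset optional [sample_set()]; its `groups` are used in grouped
#'   mode.
#' @param mode `"auto"` (grouped iff the sample set carries groups, default),
#'   `"grouped"` or `"ungrouped"`.
#' @return Object of class `normfinder_result`: `score` (stability values,
#'   log2 units), `rank`, `mode`, and for grouped mode the matrices
#'   `inter_group_deviation` (`d_ig`, rows = genes) and `intra_group_variance`.
#' @export
normfinder <- function(m, subset = NULL, mode = c("auto", "grouped", "ungrouped")) {
  mode <- match.arg(mode)
  groups <- if (!is.null(subset)) subset$groups else NULL
  m <- subset_ct_matrix(m, subset)
  if (anyNA(m)) stop("Ct matrix contains missing cells")
  if (mode == "auto") mode <- if (is.null(groups)) "ungrouped" else "grouped"
  if (mode == "grouped" && is.null(groups))
    stop("grouped mode requires a sample_set with group labels")
  genes <- rownames(m)
  k <- length(genes)
  n <- ncol(m)
  y <- -unclass(m)
  y <- sweep(y, 2L, colMeans(y))  # per-sample centering across genes

  if (mode == "ungrouped") {
    if (k < 3L || n < 4L)
      stop("ungrouped NormFinder requires >= 3 genes and >= 4 samples")
    r <- y - rowMeans(y)  # two-way residuals (columns already centred)
    u <- rowSums(r^2) / (n - 1L)
    # E[u_i] = ((k-1)/k)^2 sigma_i^2 + (1/k^2) sum_{j != i} sigma_j^2
    total <- sum(u)
    sigma2 <- (u - total / (k * (k - 1L))) * k / (k - 2L)
    sigma2 <- pmax(sigma2, 0)
    score <- sqrt(sigma2)
    names(score) <- genes
    res <- list(score = score, rank = rank_ascending(score), mode = mode,
                sigma2 = stats::setNames(sigma2, genes))
  } else {
    g <- factor(groups[colnames(m)])
    if (nlevels(g) < 2L) stop("grouped mode needs >= 2 groups")
    n_g <- table(g)
    if (any(n_g < 2L))
      stop("every group needs >= 2 samples; offending: ",
           paste(names(n_g)[n_g < 2L], collapse = ", "))
    group_means <- t(apply(y, 1L, function(row) tapply(row, g, mean)))
    overall <- rowMeans(y)
    d <- group_means - overall
    intra <- t(apply(y, 1L, function(row) tapply(row, g, stats::var)))
    se_term <- sweep(sqrt(intra), 2L, sqrt(as.numeric(n_g)), `/`)
    score <- rowMeans(abs(d) + se_term)
    names(score) <- genes
    res <- list(score = score, rank = rank_ascending(score), mode = mode,
                inter_group_deviation = d, intra_group_variance = intra)
  }
  structure(res, class = c("normfinder_result", "stability_result"))
}

#' BestKeeper descriptive stability statistics
#'
#' Per-gene descriptive statistics on the raw Ct scale: arithmetic and
#' geometric mean, extremes, the classical BestKeeper "SD" (mean absolute
#' deviation from the arithmetic mean, `sd_mad`), the n-1 sample SD reported
#' alongside, and `CV% = sd_mad / mean * 100`. Optionally the BestKeeper index
#' (per-sample geometric mean of Ct over all genes) and each gene's Pearson
#' correlation with it. Unlike the ratio-based methods, BestKeeper is
#' sensitive to per-sample loading shifts.
#'
#' @param m a [ct_matrix()] with >= 2 samples; all Ct must be positive.
#' @param subset optional [sample_set()].
#' @param with_index compute the BestKeeper index correlations (default TRUE).
#' @param rank_by ranking key, `"sd"` (mean absolute deviation, default) or
#'   `"cv"`.
#' @return Object of class `bestkeeper_result` with `stats` (data frame),
#'   `score`, `rank`, and optionally `index` and `index_correlation`.
#' @export
bestkeeper <- function(m, subset = NULL, with_index = TRUE,
                       rank_by = c("sd", "cv")) {
  rank_by <- match.arg(rank_by)
  m <- subset_ct_matrix(m, subset)
  if (ncol(m) < 2L) stop("BestKeeper requires at least 2 samples")
  if (any(m <= 0)) stop("non-positive Ct: geometric mean undefined")
  am <- rowMeans(m)
  gm <- apply(unclass(m), 1L, geometric_mean)
  sd_mad <- rowMeans(abs(unclass(m) - am))
  sd_sample <- apply(unclass(m), 1L, sample_sd)
  cv <- sd_mad / am * 100
  stats_df <- data.frame(gene = rownames(m), arithmetic_mean_ct = am,
                         geometric_mean_ct = gm, min_ct = apply(m, 1L, min),
                         max_ct = apply(m, 1L, max), sd_mad = sd_mad,
                         sd_sample = sd_sample, cv_percent = cv,
                         row.names = NULL)
  score <- if (rank_by == "sd") sd_mad else cv
  names(score) <- rownames(m)
  res <- list(stats = stats_df, score = score, rank = rank_ascending(score),
              rank_by = rank_by)
  if (with_index) {
    idx <- apply(unclass(m), 2L, geometric_mean)
    res$index <- idx
    res$index_correlation <- apply(unclass(m), 1L, function(row) {
      if (stats::sd(row) == 0 || stats::sd(idx) == 0) NA_real_
      else stats::cor(row, idx)
    })
  }
  structure(res, class = c("bestkeeper_result", "stability_result"))
}

check_stability_input <- function(m, min_genes, min_samples) {
  if (anyNA(m)) stop("Ct matrix contains missing cells")
  if (nrow(m) < min_genes || ncol(m) < min_samples)
    stop(sprintf("need at least %d genes and %d samples", min_genes, min_samples))
  invisible(m)
}

#' Run all four stability algorithms on one sample set
#'
#' Convenience wrapper returning the per-algorithm results plus a tidy
#' score/rank table, ready for [consensus_rank()].
#'
#' @param m a [ct_matrix()].
#' @param subset optional [sample_set()].
#' @param efficiency fold amplification per cycle for the geNorm transform.
#' @return List with elements `delta_ct`, `genorm`, `normfinder`,
#'   `bestkeeper`, `table` (data frame `method`, `gene`, `score`, `rank`) and
#'   `ranks` (list of rank vectors by method).
#' @export
evaluate_stability <- function(m, subset = NULL, efficiency = 2.0) {
  res <- list(
    delta_ct = delta_ct_method(m, subset),
    genorm = genorm(to_relative_quantities(m, efficiency, subset)),
    normfinder = normfinder(m, subset),
    bestkeeper = bestkeeper(m, subset)
  )
  tab <- do.call(rbind, lapply(names(res), function(meth) {
    r <- res[[meth]]
    data.frame(method = meth, gene = names(r$score),
               score = as.numeric(r$score), rank = as.numeric(r$rank),
               row.names = NULL)
  }))
  res$table <- tab
  res$ranks <- lapply(res[c("delta_ct", "genorm", "normfinder", "bestkeeper")],
                      `[[`, "rank")
  res
}

#' @export
print.stability_result <- function(x, ...) {
  cat(class(x)[1], "- genes ranked by stability (1 = most stable):\n")
  ord <- order(x$rank, names(x$score))
  print(data.frame(gene = names(x$score)[ord],
                   score = signif(x$score[ord], 4),
                   rank = x$rank[ord], row.names = NULL))
  invisible(x)
}
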