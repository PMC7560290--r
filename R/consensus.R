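#' Geometric-mean consensus ranking across stability algorithms
#'
#' Aggregates two or more per-gene rank vectors (e.g. from the comparative
#' delta-Ct method, geNorm, NormFinder and BestKeeper) by the geometric mean
#' of each gene's ranks; the lower the geometric mean, the more stable the
#' gene. Fractional (average) ranks from tied inputs enter the geometric mean
#' unchanged.
#'
#' @param rankings list of >= 2 named numeric vectors, each a ranking of the
#'   identical gene set (1 = most stable).
#' @return Object of class `consensus_ranking`: `geo_mean_rank`, `final_rank`
#'   (average ranks of the geometric means), `most_stable_pair` (the two genes
#'   with lowest geometric-mean rank, in order), `least_stable` and
#'   `contributing_methods`.
#' @examples
#' r <- list(m1 = c(A = 1, B = 2, C = 3), m2 = c(A = 2, B = 1, C = 3))
#' consensus_rank(r)$most_stable_pair
#' @export
consensus_rank <- function(rankings) {
  if (length(rankings) < 2L) stop("need at least two rankings")
  genes <- sort(names(rankings[[1L]]))
  if (is.null(genes) || any(genes == ""))
    stop("rankings must be named by gene")
  for (i in seq_along(rankings)) {
    gi <- sort(names(rankings[[i]]))
    if (!identical(gi, genes)) {
      diff <- c(setdiff(gi, genes), setdiff(genes, gi))
      stop("gene sets differ between rankings; symmetric difference: ",
           paste(diff, collapse = ", "))
    }
  }
  log_sum <- Reduce(`+`, lapply(rankings, function(r) log(r[genes])))
  geo <- exp(log_sum / length(rankings))
  names(geo) <- genes
  final <- rank_ascending(geo)
  ord <- order(geo, genes)
  structure(list(geo_mean_rank = geo, final_rank = final,
                 most_stable_pair = genes[ord[1:2]],
                 least_stable = genes[ord[length(genes)]],
                 contributing_methods = names(rankings) %||%
                   paste0("method", seq_along(rankings))),
            class = "consensus_ranking")
}

#' Optimal number of reference genes from the V series
#'
#' Applies the pairwise-variation rule to the geNorm `V_n` series: the optimal
#' number of reference genes is the smallest n with `V_n` below the threshold
#' (0.15 by convention), meaning the (n+1)-th gene adds no useful information
#' to the normalisation factor. If no `V_n` qualifies, `n_optimal` is the
#' largest n tested plus one and `satisfied` is `FALSE`.
#'
#' @param v_series data frame with columns `n` (consecutive integers from 2)
#'   and `V`, as produced by [genorm()].
#' @param threshold cut-off on `V_n`, default 0.15.
#' @return Object of class `optimal_rg_number`: `n_optimal`, `satisfied`,
#'   `v_series`, `threshold`.
#' @export
optimal_rg_number <- function(v_series, threshold = 0.15) {
  v_series <- as.data.frame(v_series)
  if (!all(c("n", "V") %in% names(v_series)))
    stop("v_series needs columns 'n' and 'V'")
  if (!nrow(v_series)) stop("empty V series")
  n <- as.integer(v_series$n)
  if (anyDuplicated(n) || !identical(n, seq.int(2L, 1L + length(n))))
    stop("V series n values must be consecutive integers starting at 2")
  hit <- which(v_series$V < threshold)
  if (length(hit)) {
    n_opt <- n[hit[1L]]
    satisfied <- TRUE
  } else {
    n_opt <- max(n) + 1L
    satisfied <- FALSE
  }
  structure(list(n_optimal = n_opt, satisfied = satisfied,
                 v_series = v_series, threshold = threshold),
            class = "optimal_rg_number")
}

#' Published per-algorithm rankings of ten oat candidate reference genes
#'
#' Loads the packaged fixture with the per-algorithm stability rank orders of
#' ten candidate reference genes of hexaploid oat (*Avena sativa*) in four
#' experimental sample sets (all samples; shoots and roots of seedlings;
#' developing seeds; developing endosperms), as reported for the comparative
#' delta-Ct method, geNorm, NormFinder and BestKeeper. These published ranks
#' are inputs for the consensus step, allowing the comprehensive ranking to be
#' recomputed without the (unpublished) raw Ct data.
#'
#' @return Data frame with columns `sample_set`, `method`, `gene`, `rank`.
#' @seealso [consensus_rank()]
#' @export
oat_published_rankings <- function() {
  path <- system.file("extdata", "oat_rg_rankings.tsv", package = "refstab",
                      mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# Split a sample_set/method/gene/rank table into per-set lists of rank vectors.
rankings_by_set <- function(tab) {
  lapply(split(tab, tab$sample_set), function(s) {
    lapply(split(s, s$method), function(m) stats::setNames(m$rank, m$gene))
  })
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat("consensus ranking over", length(x$contributing_methods), "methods\n")
  ord <- order(x$final_rank, names(x$geo_mean_rank))
  print(data.frame(gene = names(x$geo_mean_rank)[ord],
                   geo_mean_rank = signif(x$geo_mean_rank[ord], 4),
                   final_rank = x$final_rank[ord], row.names = NULL))
  cat("most stable pair:", paste(x$most_stable_pair, collapse = " + "),
      "| least stable:", x$least_stable, "\n")
  invisible(x)
}

#' @export
print.optimal_rg_number <- function(x, ...) {
  cat(sprintf("optimal number of reference genes: %d (V < %.2f %s)\n",
              x$n_optimal, x$threshold,
              if (x$satisfied) "satisfied" else "not reached"))
  invisible(x)
}
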