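#' Replicate-level Ct tables
#'
#' A `ct_table` is a data frame with one row per technical observation and
#' columns `sample`, `gene`, `replicate` and `ct` (threshold cycles). It is the
#' universal input of the stability pipeline: replicates are aggregated into a
#' [ct_matrix()], which feeds the four stability algorithms.
#'
#' Validation enforces that `(sample, gene, replicate)` triples are unique and
#' that every Ct is finite and inside `ct_bounds` (default `(0, 45]`, the
#' plausible range for a 42-cycle programme plus margin). Out-of-range values
#' are a hard error when `strict = TRUE`, a warning otherwise; they are never
#' silently dropped.
#'
#' @param x data frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @param strict logical; error (`TRUE`, default) or warn on out-of-range Ct.
#' @param ct_bounds numeric length 2, open lower / closed upper Ct bounds.
#' @return A validated data frame of class `ct_table`.
#' @examples
#' df <- data.frame(sample = "s1", gene = "g1",
#'                  replicate = c("r1", "r2", "r3"), ct = c(20.1, 20.2, 20.0))
#' ct_table(df)
#' @export
ct_table <- function(x, strict = TRUE, ct_bounds = c(0, 45)) {
  x <- as.data.frame(x)
  required <- c("sample", "gene", "replicate", "ct")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("ct_table is missing columns: ", paste(missing_cols, collapse = ", "))
  x <- x[required]
  x$sample <- as.character(x$sample)
  x$gene <- as.character(x$gene)
  x$replicate <- as.character(x$replicate)
  if (!is.numeric(x$ct)) {
    ct_num <- suppressWarnings(as.numeric(x$ct))
    bad <- which(is.na(ct_num) & !is.na(x$ct))
    if (length(bad))
      stop("non-numeric ct values at rows: ", paste(utils::head(bad, 5), collapse = ", "))
    x$ct <- ct_num
  }
  if (nrow(x) == 0L) stop("ct_table has no rows")
  key <- paste(x$sample, x$gene, x$replicate, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    d <- x[dup, , drop = FALSE][1L, ]
    stop(sprintf("duplicated (sample, gene, replicate) triple: (%s, %s, %s)",
                 d$sample, d$gene, d$replicate))
  }
  bad <- !is.finite(x$ct) | x$ct <= ct_bounds[1] | x$ct > ct_bounds[2]
  if (any(bad)) {
    msg <- sprintf("%d Ct value(s) outside (%g, %g]", sum(bad), ct_bounds[1], ct_bounds[2])
    if (strict) stop(msg) else warning(msg)
  }
  class(x) <- c("ct_table", "data.frame")
  x
}

#' Read a Ct table from CSV/TSV
#'
#' The long dialect has header `sample,gene,replicate,ct`. The wide dialect has
#' one row per (sample, replicate) with columns `sample`, `replicate` and one
#' column per gene; it is melted into the long form, so both dialects yield
#' identical `ct_table` contents.
#'
#' @param path file path; the delimiter is taken from the extension
#'   (`.tsv`/`.txt` = tab, otherwise comma) unless `sep` is given.
#' @param dialect `"long"` (default) or `"wide"`.
#' @param sep optional field separator override.
#' @inheritParams ct_table
#' @return A `ct_table`.
#' @seealso [write_ct_table()]
#' @export
read_ct_table <- function(path, dialect = c("long", "wide"), sep = NULL,
                          strict = TRUE, ct_bounds = c(0, 45)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- sep %||% if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (dialect == "long") {
    return(ct_table(raw, strict = strict, ct_bounds = ct_bounds))
  }
  id_cols <- c("sample", "replicate")
  if (!all(id_cols %in% names(raw)))
    stop("wide dialect requires columns 'sample' and 'replicate'")
  gene_cols <- setdiff(names(raw), id_cols)
  if (!length(gene_cols)) stop("wide dialect has no gene columns")
  long <- do.call(rbind, lapply(gene_cols, function(g) {
    data.frame(sample = raw$sample, gene = g, replicate = raw$replicate,
               ct = raw[[g]], stringsAsFactors = FALSE)
  }))
  ct_table(long, strict = strict, ct_bounds = ct_bounds)
}

#' Write a Ct table as long CSV/TSV
#'
#' @param x a `ct_table`.
#' @param path output path; extension chooses the delimiter as in
#'   [read_ct_table()].
#' @return `path`, invisibly.
#' @export
write_ct_table <- function(x, path) {
  stopifnot(inherits(x, "ct_table"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(x), path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Named sample sets
#'
#' A `sample_set` is a named, ordered subset of samples, optionally with group
#' labels (e.g. tissues or developmental series). Stability algorithms operate
#' on the samples of one set; NormFinder uses the group labels when present.
#'
#' @param name set name, e.g. `"seedlings"`.
#' @param samples character vector of sample ids (unique, non-empty).
#' @param groups optional named character vector mapping every sample id to a
#'   group label; at least two distinct labels are required when given.
#' @return An object of class `sample_set`.
#' @export
sample_set <- function(name, samples, groups = NULL) {
  samples <- as.character(samples)
  if (!length(samples)) stop("sample_set needs at least one sample")
  if (anyDuplicated(samples)) stop("sample ids must be unique")
  if (!is.null(groups)) {
    groups <- vapply(groups, as.character, character(1))
    missing_g <- setdiff(samples, names(groups))
    if (length(missing_g))
      stop("samples without group label: ", paste(missing_g, collapse = ", "))
    groups <- groups[samples]
    if (length(unique(groups)) < 2L)
      stop("groups must contain at least two distinct labels")
  }
  structure(list(name = as.character(name), samples = samples, groups = groups),
            class = "sample_set")
}

#' Read sample-set definitions from YAML or JSON
#'
#' The file holds a list of sets, each with `name`, `samples` (ordered) and an
#' optional `groups` map from sample id to label.
#'
#' @param path YAML (or JSON, which YAML subsumes) file path.
#' @return Named list of [sample_set()] objects.
#' @export
read_sample_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$name)) raw <- list(raw)  # single set at top level
  sets <- lapply(raw, function(s) {
    groups <- if (!is.null(s$groups)) unlist(s$groups) else NULL
    sample_set(s$name, unlist(s$samples), groups)
  })
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Aggregate technical replicates into a genes-by-samples Ct matrix
#'
#' Collapses the replicate dimension with the chosen policy, producing a
#' `ct_matrix`: a numeric genes x samples matrix with the per-cell replicate
#' counts kept in `attr(, "n_reps")`. Stability statistics require at least
#' 2 genes and 3 samples; that is checked by the algorithms, not here.
#'
#' @param x a [ct_table()].
#' @param policy `"mean"` (default) or `"median"` over each cell's replicates.
#' @param missing `"error"` (default) lists (sample, gene) pairs with no
#'   observation; `"na"` leaves those cells `NA`.
#' @return A `ct_matrix`.
#' @examples
#' df <- expand.grid(sample = c("s1", "s2"), gene = c("gA", "gB"),
#'                   replicate = c("r1", "r2"), stringsAsFactors = FALSE)
#' df$ct <- 20 + seq_len(nrow(df)) / 10
#' aggregate_replicates(ct_table(df))
#' @export
aggregate_replicates <- function(x, policy = c("mean", "median"),
                                 missing = c("error", "na")) {
  stopifnot(inherits(x, "ct_table"))
  policy <- match.arg(policy)
  missing <- match.arg(missing)
  genes <- unique(x$gene)
  samples <- unique(x$sample)
  f <- switch(policy, mean = mean, median = stats::median)
  gi <- factor(x$gene, levels = genes)
  si <- factor(x$sample, levels = samples)
  m <- tapply(x$ct, list(gi, si), f)
  n <- tapply(x$ct, list(gi, si), length)
  n[is.na(n)] <- 0L
  if (any(is.na(m))) {
    if (missing == "error") {
      idx <- which(is.na(m), arr.ind = TRUE)
      pairs <- paste0("(", samples[idx[, 2]], ", ", genes[idx[, 1]], ")")
      stop("missing Ct for (sample, gene) pairs: ",
           paste(utils::head(pairs, 10), collapse = ", "))
    }
  }
  m <- matrix(as.numeric(m), nrow = length(genes),
              dimnames = list(gene = genes, sample = samples))
  ct_matrix(m, n_reps = matrix(as.integer(n), nrow = length(genes),
                               dimnames = dimnames(m)))
}

#' Construct a Ct matrix directly
#'
#' @param m numeric matrix, genes in rows (rownames) and samples in columns
#'   (colnames).
#' @param n_reps optional integer matrix of per-cell replicate counts.
#' @return A `ct_matrix` (a classed numeric matrix).
#' @export
ct_matrix <- function(m, n_reps = NULL) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("ct_matrix needs gene rownames and sample colnames")
  storage.mode(m) <- "double"
  structure(m, n_reps = n_reps, class = c("ct_matrix", class(matrix())))
}

# Restrict a ct_matrix to the samples of a sample_set (keeping its order),
# defaulting to all samples when `subset` is NULL.
subset_ct_matrix <- function(m, subset = NULL) {
  stopifnot(inherits(m, "ct_matrix"))
  if (is.null(subset)) return(m)
  stopifnot(inherits(subset, "sample_set"))
  absent <- setdiff(subset$samples, colnames(m))
  if (length(absent))
    stop("sample_set '", subset$name, "' has samples absent from the Ct matrix: ",
         paste(absent, collapse = ", "))
  ct_matrix(unclass(m)[, subset$samples, drop = FALSE])
}

#' Transform Ct values into gene-wise relative quantities
#'
#' For each gene, `q = E^(Ct_min - Ct)` where `E` is the fold amplification per
#' cycle (2.0 at 100% efficiency) and `Ct_min` is taken within the analysed
#' sample subset, so the per-gene maximum quantity is exactly 1. This is the
#' input convention of geNorm.
#'
#' @param m a [ct_matrix()].
#' @param efficiency scalar or named per-gene vector of fold amplification per
#'   cycle; values outside `[1.6, 2.2]` trigger a warning.
#' @param subset optional [sample_set()] restricting (and ordering) samples;
#'   `Ct_min` is computed within that subset.
#' @return Object of class `rel_quantities`: list with `q` (genes x samples
#'   matrix in `(0, 1]`) and `efficiency` (named per-gene vector).
#' @examples
#' m <- ct_matrix(matrix(c(20, 21, 22, 18, 18, 18), nrow = 2, byrow = TRUE,
#'                       dimnames = list(c("gA", "gB"), c("s1", "s2", "s3"))))
#' to_relative_quantities(m)$q
#' @export
to_relative_quantities <- function(m, efficiency = 2.0, subset = NULL) {
  m <- subset_ct_matrix(m, subset)
  if (!ncol(m)) stop("empty sample subset")
  genes <- rownames(m)
  if (length(efficiency) == 1L && is.null(names(efficiency))) {
    eff <- stats::setNames(rep(as.numeric(efficiency), length(genes)), genes)
  } else {
    absent <- setdiff(genes, names(efficiency))
    if (length(absent))
      stop("no efficiency for genes: ", paste(absent, collapse = ", "))
    eff <- as.numeric(efficiency[genes])
    names(eff) <- genes
  }
  if (any(eff < 1.6 | eff > 2.2))
    warning("amplification efficiencies outside [1.6, 2.2] fold per cycle")
  if (any(eff <= 1)) stop("fold amplification per cycle must exceed 1")
  if (anyNA(m)) stop("Ct matrix contains missing cells")
  ct_min <- apply(unclass(m), 1L, min)
  q <- eff ^ (ct_min - unclass(m))  # recycles eff and ct_min by row
  structure(list(q = q, efficiency = eff), class = "rel_quantities")
}

#' @export
print.ct_table <- function(x, ...) {
  cat(sprintf("ct_table: %d observations, %d genes, %d samples\n",
              nrow(x), length(unique(x$gene)), length(unique(x$sample))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("sample_set '%s': %d samples%s\n", x$name, length(x$samples),
              if (is.null(x$groups)) "" else
                sprintf(", %d groups", length(unique(x$groups)))))
  invisible(x)
}
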