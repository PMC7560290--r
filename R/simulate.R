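#' Configure a synthetic Ct experiment
#'
#' Defines the additive generative model used by [simulate_ct_table()]:
#'
#' `Ct(sample s, bio rep b, gene i, tech rep t) =
#'    mu_i + lambda_(s,b) + delta_(i, group(s)) + eps_(i,s,b) + tau_t`
#'
#' with `lambda ~ N(0, sigma_load)` a shared per-(sample, biological
#' replicate) loading shift, `eps ~ N(0, sigma_bio_i)` gene-specific
#' biological noise and `tau ~ N(0, sigma_tech)` technical noise. Biological
#' replicates enter downstream analysis as separate samples; technical
#' replicates are the `replicate` column of the resulting [ct_table()]. This
#' structure matches the assumptions of the stability algorithms: loading
#' shifts cancel in ratio-based methods, group deltas model condition-specific
#' expression of unstable genes.
#'
#' @param genes data frame with columns `gene`, `mu` (baseline Ct in (0, 45))
#'   and `sigma_bio` (biological SD in cycles, >= 0).
#' @param samples data frame with columns `sample`, optional `group`
#'   (default a single group `"all"`) and optional `n_bio_reps` (default 1).
#' @param group_deltas optional genes x groups matrix of Ct shifts (cycles);
#'   dimnames must match gene ids and sample group labels; defaults to zero.
#' @param sigma_load SD of the per-(sample, bio rep) loading shift, cycles.
#' @param sigma_tech SD of technical replicate noise, cycles.
#' @param n_tech_reps technical replicates per biological replicate (>= 1;
#'   default 3, the usual qPCR layout).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(genes, samples, group_deltas = NULL, sigma_load = 0.15,
                       sigma_tech = 0.1, n_tech_reps = 3L) {
  genes <- as.data.frame(genes)
  samples <- as.data.frame(samples)
  stopifnot(all(c("gene", "mu", "sigma_bio") %in% names(genes)),
            "sample" %in% names(samples))
  if (is.null(samples$group)) samples$group <- "all"
  if (is.null(samples$n_bio_reps)) samples$n_bio_reps <- 1L
  if (anyDuplicated(genes$gene)) stop("duplicate gene ids")
  if (anyDuplicated(samples$sample)) stop("duplicate sample ids")
  if (any(genes$mu <= 0 | genes$mu >= 45)) stop("mu must lie in (0, 45)")
  if (any(genes$sigma_bio < 0) || sigma_load < 0 || sigma_tech < 0)
    stop("all SDs must be >= 0")
  if (n_tech_reps < 1L) stop("n_tech_reps must be >= 1")
  groups <- unique(as.character(samples$group))
  if (is.null(group_deltas)) {
    group_deltas <- matrix(0, nrow(genes), length(groups),
                           dimnames = list(genes$gene, groups))
  } else {
    group_deltas <- as.matrix(group_deltas)
    if (!setequal(rownames(group_deltas), genes$gene))
      stop("group_deltas rows must match gene ids")
    extra <- setdiff(colnames(group_deltas), groups)
    if (length(extra))
      stop("group_deltas columns not among sample groups: ",
           paste(extra, collapse = ", "))
    full <- matrix(0, nrow(genes), length(groups),
                   dimnames = list(genes$gene, groups))
    full[, colnames(group_deltas)] <- group_deltas[genes$gene, , drop = FALSE]
    group_deltas <- full
  }
  structure(list(genes = genes, samples = samples, group_deltas = group_deltas,
                 sigma_load = sigma_load, sigma_tech = sigma_tech,
                 n_tech_reps = as.integer(n_tech_reps)),
            class = "sim_config")
}

#' Simulate a replicate-level Ct table with known ground truth
#'
#' Draws one dataset from the model described in [sim_config()]. With the
#' same seed the result is bit-identical. The returned object keeps the
#' individual noise components so that counterfactuals can be rebuilt
#' deterministically (see [rescale_loading()]).
#'
#' The ground truth defines the planted stability of each gene as
#' `sqrt( Var_groups(delta_ig; weighted by group sizes) + sigma_bio_i^2 )`
#' — the across-sample SD of its expression once loading and technical noise
#' are removed — and ranks genes by it.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return List of class `ct_simulation`: `table` (a [ct_table()] whose
#'   samples are `sample` or `sample.b<r>` units), `truth` (data frame `gene`,
#'   `true_stability`, `true_rank`), `sample_set` (a [sample_set()] of the
#'   simulated units with their group labels) and `components` (per-row model
#'   terms).
#' @export
simulate_ct_table <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- cfg$genes$gene
  k <- length(genes)
  reps <- cfg$samples$n_bio_reps
  unit_sample <- rep(cfg$samples$sample, reps)
  unit_rep <- unlist(lapply(reps, seq_len))
  unit_id <- ifelse(rep(reps, reps) > 1L,
                    paste0(unit_sample, ".b", unit_rep), unit_sample)
  unit_group <- rep(as.character(cfg$samples$group), reps)
  U <- length(unit_id)
  Tt <- cfg$n_tech_reps
  draws <- with_seed(seed, {
    lambda <- stats::rnorm(U, 0, cfg$sigma_load)
    eps <- matrix(stats::rnorm(k * U, 0, rep(cfg$genes$sigma_bio, U)),
                  nrow = k)
    tau <- stats::rnorm(U * k * Tt, 0, cfg$sigma_tech)
    list(lambda = lambda, eps = eps, tau = tau)
  })
  # row order: unit (outer), gene, technical replicate (inner)
  mu_vec <- rep(rep(cfg$genes$mu, each = Tt), times = U)
  lambda_vec <- rep(draws$lambda, each = k * Tt)
  delta_mat <- cfg$group_deltas[, unit_group, drop = FALSE]
  delta_vec <- rep(as.vector(delta_mat), each = Tt)
  eps_vec <- rep(as.vector(draws$eps), each = Tt)
  tau_vec <- draws$tau
  tab <- data.frame(
    sample = rep(unit_id, each = k * Tt),
    gene = rep(rep(genes, each = Tt), times = U),
    replicate = paste0("t", rep(seq_len(Tt), times = U * k)),
    ct = mu_vec + lambda_vec + delta_vec + eps_vec + tau_vec)
  components <- list(mu = mu_vec, lambda = lambda_vec, delta = delta_vec,
                     eps = eps_vec, tau = tau_vec, frame = tab[1:3])
  w <- as.vector(table(factor(unit_group, levels = colnames(cfg$group_deltas))))
  wvar <- apply(cfg$group_deltas, 1L, function(d) {
    wm <- sum(w * d) / sum(w)
    sum(w * (d - wm)^2) / sum(w)
  })
  truth <- data.frame(gene = genes,
                      true_stability = sqrt(wvar + cfg$genes$sigma_bio^2))
  truth$true_rank <- rank(truth$true_stability, ties.method = "average")
  groups <- NULL
  if (length(unique(unit_group)) >= 2L)
    groups <- stats::setNames(unit_group, unit_id)
  structure(list(table = ct_table(tab), truth = truth,
                 sample_set = sample_set("simulated", unit_id, groups),
                 components = components, cfg = cfg),
            class = "ct_simulation")
}

#' Rebuild a simulation with its loading shifts rescaled
#'
#' Multiplies the already-drawn per-unit loading shifts `lambda` by `factor`
#' and reassembles the Ct table, reusing every other noise draw. Because the
#' ratio-based stability methods are invariant to per-sample shifts, their
#' results on the rescaled table are identical to the original — a
#' deterministic assertion the test suite exploits — while Ct-scale methods
#' (BestKeeper) respond.
#'
#' @param sim a `ct_simulation`.
#' @param factor multiplier applied to the loading component.
#' @return A `ct_simulation` with the modified table (same truth and draws).
#' @export
rescale_loading <- function(sim, factor) {
  stopifnot(inherits(sim, "ct_simulation"))
  comp <- sim$components
  tab <- comp$frame
  tab$ct <- comp$mu + factor * comp$lambda + comp$delta + comp$eps + comp$tau
  sim$table <- ct_table(tab)
  sim
}

#' Simulate a qPCR dilution series
#'
#' Generates Ct values on a straight line whose slope corresponds to the
#' requested amplification efficiency
#' (`slope = -1 / log10(1 + E% / 100)`), over `levels` ten-fold dilutions,
#' with optional technical noise. [fit_standard_curve()] on the noise-free
#' output recovers the efficiency exactly.
#'
#' @param efficiency_percent true efficiency in percent, within `[50, 150]`.
#' @param intercept Ct of the undiluted sample.
#' @param levels number of dilution levels (>= 3; default 5).
#' @param sigma_tech SD of Ct noise (cycles).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return Data frame `log10_dilution`, `ct`.
#' @export
simulate_dilution_series <- function(efficiency_percent, intercept = 25,
                                     levels = 5L, sigma_tech = 0,
                                     seed = NULL) {
  if (efficiency_percent < 50 || efficiency_percent > 150)
    stop("efficiency_percent must lie in [50, 150]")
  if (levels < 3L) stop("need at least 3 dilution levels")
  x <- -(seq_len(levels) - 1)
  slope <- -1 / log10(1 + efficiency_percent / 100)
  ct <- intercept + slope * x +
    with_seed(seed, stats::rnorm(levels, 0, sigma_tech))
  data.frame(log10_dilution = x, ct = ct)
}

#' Packaged end-to-end benchmark scenario
#'
#' A ready-made [sim_config()] emulating a small polyploid qPCR study:
#' 10 candidate genes across 4 groups (shoots and roots at two seedling
#' stages, each its own group) with 3 biological x 3 technical replicates.
#' Two genes are planted as stable (biological SD 0.05 cycles, no group
#' effects); the remainder span biological SDs of 0.40-0.80 cycles, three of
#' them with tissue-specific shifts of 0.3-0.7 cycles, covering the range of
#' dispersions typical for candidate reference genes while keeping the
#' planted ordering identifiable at this sample size. Loading SD 0.15 and
#' technical SD 0.1 cycles.
#'
#' @param n_bio_reps biological replicates per sample (default 3).
#' @return A [sim_config()].
#' @export
benchmark_scenario <- function(n_bio_reps = 3L) {
  genes <- data.frame(
    gene = sprintf("g%02d", 1:10),
    mu = c(20, 22, 18, 24, 21, 19, 23, 25, 17, 26),
    sigma_bio = c(0.05, 0.05, 0.40, 0.45, 0.50, 0.55, 0.60, 0.65, 0.70, 0.80))
  grp <- c("shoot2", "root2", "shoot3", "root3")
  samples <- data.frame(sample = grp, group = grp, n_bio_reps = n_bio_reps)
  deltas <- matrix(0, 10, 4, dimnames = list(genes$gene, grp))
  deltas["g06", ] <- c(-0.3, 0.3, -0.3, 0.3)   # tissue-specific expression
  deltas["g08", ] <- c(0.5, -0.5, 0.5, -0.5)
  deltas["g10", ] <- c(-0.7, 0.7, -0.7, 0.7)
  sim_config(genes, samples, group_deltas = deltas,
             sigma_load = 0.15, sigma_tech = 0.1, n_tech_reps = 3L)
}

#' Synthetic homeolog transcripts embedding a primer pair
#'
#' Builds `n_copies` synthetic transcript copies that all carry the given
#' primer pair at an exact spacing producing a product of `amplicon_bp`
#' (forward primer through the reverse-complemented reverse primer,
#' inclusive). Copies diverge from each other by random substitutions outside
#' the primer binding sites, emulating homeologous gene copies whose primers
#' were placed in identical regions. These sequences are synthetic stand-ins
#' for real transcripts and are meant for exercising [in_silico_pcr()] and
#' [identical_windows()].
#'
#' @param primers a [primer_pair()].
#' @param amplicon_bp desired product length (>= forward + reverse length).
#' @param n_copies number of homeolog copies (>= 1).
#' @param flank length of random sequence added on each side of the product.
#' @param divergence per-base substitution probability between copies,
#'   applied outside the primer sites.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A named `DNAStringSet` (`<name>_copy<i>`, or `<name>` if a single
#'   copy).
#' @export
simulate_homeolog_transcripts <- function(primers, amplicon_bp, n_copies = 1L,
                                          flank = 60L, divergence = 0.03,
                                          seed = NULL) {
  stopifnot(inherits(primers, "primer_pair"))
  lf <- nchar(primers$forward)
  lr <- nchar(primers$reverse)
  if (amplicon_bp < lf + lr)
    stop("amplicon_bp shorter than the two primers combined")
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    rand_dna <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(primers$reverse)))
    insert <- rand_dna(amplicon_bp - lf - lr)
    base_seq <- paste0(rand_dna(flank), primers$forward, insert, rc,
                       rand_dna(flank))
    # positions that must stay identical: the two primer sites
    protect <- c(seq(flank + 1L, flank + lf),
                 seq(flank + amplicon_bp - lr + 1L, flank + amplicon_bp))
    copies <- vapply(seq_len(n_copies), function(i) {
      if (i == 1L) return(base_seq)
      chars <- strsplit(base_seq, "")[[1L]]
      mutable <- setdiff(seq_along(chars), protect)
      hit <- mutable[stats::runif(length(mutable)) < divergence]
      chars[hit] <- vapply(chars[hit], function(b)
        sample(setdiff(bases, b), 1L), character(1))
      paste(chars, collapse = "")
    }, character(1))
    names(copies) <- if (n_copies == 1L) primers$name else
      paste0(primers$name, "_copy", seq_len(n_copies))
    Biostrings::DNAStringSet(copies)
  })
}

#' Synthetic transcript set for the packaged oat primer panel
#'
#' For every primer pair in the packaged panel (see
#' `system.file("extdata", "oat_primers.tsv", package = "refstab")`), builds
#' synthetic homeolog transcripts with the published product length and copy
#' number via [simulate_homeolog_transcripts()]. The real transcript
#' sequences are not redistributed; these synthetic templates reproduce only
#' the primer sites, spacings and copy structure, which is what the in-silico
#' PCR machinery needs for verification.
#'
#' @param seed integer seed (default 20201015).
#' @return List with `primers` (list of [primer_pair()]), `info` (the primer
#'   panel data frame) and `transcripts` (a named `DNAStringSet`).
#' @export
synthetic_oat_transcripts <- function(seed = 20201015) {
  path <- system.file("extdata", "oat_primers.tsv", package = "refstab",
                      mustWork = TRUE)
  info <- utils::read.table(path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  primers <- read_primer_table(path)
  sets <- lapply(seq_len(nrow(info)), function(i)
    simulate_homeolog_transcripts(primers[[info$gene[i]]],
                                  amplicon_bp = info$amplicon_bp[i],
                                  n_copies = info$n_copies[i],
                                  seed = seed + i))
  transcripts <- do.call(c, sets)
  list(primers = primers, info = info, transcripts = transcripts)
}
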