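#' Read transcript sequences from FASTA
#'
#' Wraps [Biostrings::readDNAStringSet()], normalises sequences to upper case,
#' trims FASTA descriptions to the first whitespace-delimited token and
#' validates the alphabet (`A`, `C`, `G`, `T`, `N`; anything else is rejected
#' with its position).
#'
#' @param path FASTA file path.
#' @return A named `DNAStringSet`.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  validate_dna(as.character(seqs), names(seqs), allow_n = TRUE)
  Biostrings::DNAStringSet(toupper(as.character(seqs)))
}

validate_dna <- function(seqs, ids = NULL, allow_n = FALSE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  for (i in seq_along(seqs)) {
    s <- toupper(seqs[[i]])
    if (!nzchar(s)) stop("empty sequence: ", ids[i] %||% i)
    bad <- regexpr(sprintf("[^%s]", alphabet), s)
    if (bad > 0)
      stop(sprintf("invalid character '%s' at position %d of %s",
                   substr(s, bad, bad), bad, ids[i] %||% i))
  }
  invisible(TRUE)
}

#' Define a qPCR primer pair
#'
#' Both primers are written 5' to 3': the forward primer matches the sense
#' strand, the reverse primer matches the template as its reverse complement.
#'
#' @param name primer-pair name (usually the gene).
#' @param forward,reverse primer sequences (A/C/G/T, length >= 10).
#' @return Object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  validate_dna(c(forward, reverse), c("forward", "reverse"))
  if (nchar(forward) < 10L || nchar(reverse) < 10L)
    stop("primers must be at least 10 nt long")
  structure(list(name = as.character(name), forward = forward,
                 reverse = reverse), class = "primer_pair")
}

#' Read a primer table (TSV with columns name/gene, forward, reverse)
#'
#' @param path TSV path.
#' @return Named list of [primer_pair()] objects.
#' @export
read_primer_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  id_col <- intersect(c("name", "gene"), names(tab))[1L]
  if (is.na(id_col) || !all(c("forward", "reverse") %in% names(tab)))
    stop("primer table needs columns name (or gene), forward, reverse")
  pairs <- lapply(seq_len(nrow(tab)), function(i)
    primer_pair(tab[[id_col]][i], tab$forward[i], tab$reverse[i]))
  names(pairs) <- tab[[id_col]]
  pairs
}

#' Percent identity of two sequences under global alignment
#'
#' Needleman-Wunsch global alignment with configurable scores (default:
#' match +1, mismatch 0, linear gap penalty 1 per gapped position), computed
#' with [Biostrings::pairwiseAlignment()]. Identity is the number of identical
#' alignment columns divided by the total alignment length (gap columns
#' included), in percent. The scoring parameters are recorded in the result so
#' that reported similarities are reproducible.
#'
#' @param a,b sequences (character or `DNAString`).
#' @param match,mismatch,gap alignment scores; `gap` is the per-position
#'   linear penalty (applied as gap extension with zero opening cost).
#' @return List of class `identity_result`: `percent_identity`,
#'   `identical_columns`, `alignment_length`, `params`.
#' @examples
#' pairwise_identity("ACGT", "ACGA")$percent_identity  # 75
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = 0, gap = 1) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  validate_dna(c(a, b), c("a", "b"), allow_n = TRUE)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = gap)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  n_id <- sum(pa == pb & pa != "-")
  len <- length(pa)
  structure(list(percent_identity = 100 * n_id / len,
                 identical_columns = n_id, alignment_length = len,
                 params = c(match = match, mismatch = mismatch, gap = gap)),
            class = "identity_result")
}

#' Maximal windows identical across all sequences
#'
#' Finds every maximal substring of length at least `min_len` that occurs
#' exactly (no mismatches, no gaps) in every input sequence — the regions in
#' which primers for duplicated gene copies can be placed so that all copies
#' are amplified identically. Windows are reported in order of their position
#' in the first sequence, with 1-based start coordinates in every sequence
#' (first occurrence). Maximality means a window cannot be extended left or
#' right and remain common to all sequences.
#'
#' @param seqs `DNAStringSet`, or character vector (>= 2 sequences).
#' @param min_len minimum window length in bp; values below 15 warn (too
#'   short for a usable primer site).
#' @return Data frame with columns `length`, `sequence` and one
#'   `start_<id>` column per input sequence; zero rows when no common window
#'   exists.
#' @export
identical_windows <- function(seqs, min_len = 20L) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))  # before as.character,
  seqs <- toupper(as.character(seqs))                     # which drops names
  ids[ids == ""] <- paste0("seq", which(ids == ""))
  if (min_len < 15L) warning("min_len below 15 bp is shorter than a usable primer")
  ref <- seqs[[1L]]
  others <- seqs[-1L]
  l1 <- nchar(ref)
  common <- function(sub) all(vapply(others, function(s)
    grepl(sub, s, fixed = TRUE), logical(1)))
  # ext[p]: longest common substring of all sequences starting at p in ref
  ext <- integer(l1)
  for (p in seq_len(l1)) {
    lo <- 0L; hi <- l1 - p + 1L   # invariant: length lo is common, hi+1 is not
    while (lo < hi) {
      mid <- as.integer(ceiling((lo + hi) / 2))
      if (common(substr(ref, p, p + mid - 1L))) lo <- mid else hi <- mid - 1L
    }
    ext[p] <- lo
  }
  keep <- which(ext >= min_len &
                  (seq_len(l1) == 1L | c(0L, ext[-l1]) <= ext))
  if (!length(keep))
    return(stats::setNames(
      data.frame(matrix(nrow = 0, ncol = 2 + length(ids))),
      c("length", "sequence", paste0("start_", ids))))
  rows <- lapply(keep, function(p) {
    win <- substr(ref, p, p + ext[p] - 1L)
    starts <- c(p, vapply(others, function(s)
      as.integer(regexpr(win, s, fixed = TRUE)), integer(1)))
    out <- data.frame(length = ext[p], sequence = win)
    for (i in seq_along(ids)) out[[paste0("start_", ids[i])]] <- starts[i]
    out
  })
  do.call(rbind, rows)
}

#' Exact-match in-silico PCR
#'
#' Predicts PCR products by locating the forward primer on the sense strand
#' and the reverse complement of the reverse primer downstream of it. Every
#' (forward site, downstream reverse site) pairing on every template is
#' reported; templates with several products are flagged via `n_products`.
#' Coordinates are 1-based inclusive on the template's sense strand, and the
#' product length is `end - start + 1` (the convention under which reported
#' amplicon lengths include both primers).
#'
#' @param primers a [primer_pair()].
#' @param templates `DNAStringSet` (or named character vector) of templates.
#' @param max_mismatches allowed mismatches per primer site (default 0, exact
#'   matching; indels are never allowed).
#' @return Data frame `template_id`, `primer`, `start`, `end`, `length_bp`,
#'   `n_products`, `sequence`; zero rows when nothing binds.
#' @export
in_silico_pcr <- function(primers, templates, max_mismatches = 0L) {
  stopifnot(inherits(primers, "primer_pair"))
  if (is.character(templates)) templates <- Biostrings::DNAStringSet(toupper(templates))
  ids <- names(templates) %||% paste0("template", seq_along(templates))
  fwd <- Biostrings::DNAString(primers$forward)
  rev_rc <- Biostrings::reverseComplement(Biostrings::DNAString(primers$reverse))
  out <- list()
  for (i in seq_along(templates)) {
    tmpl <- templates[[i]]
    f_hits <- Biostrings::matchPattern(fwd, tmpl, max.mismatch = max_mismatches)
    r_hits <- Biostrings::matchPattern(rev_rc, tmpl, max.mismatch = max_mismatches)
    if (!length(f_hits) || !length(r_hits)) next
    prods <- list()
    for (fs in seq_along(f_hits)) {
      f_start <- BiocGenerics::start(f_hits)[fs]
      f_end <- BiocGenerics::end(f_hits)[fs]
      for (rs in seq_along(r_hits)) {
        r_start <- BiocGenerics::start(r_hits)[rs]
        r_end <- BiocGenerics::end(r_hits)[rs]
        if (r_start <= f_end) next  # reverse site must lie downstream
        prods[[length(prods) + 1L]] <- data.frame(
          template_id = ids[i], primer = primers$name,
          start = f_start, end = r_end, length_bp = r_end - f_start + 1L,
          sequence = as.character(Biostrings::subseq(tmpl, f_start, r_end)))
      }
    }
    if (length(prods)) {
      prods <- do.call(rbind, prods)
      prods$n_products <- nrow(prods)
      out[[length(out) + 1L]] <- prods
    }
  }
  if (!length(out))
    return(data.frame(template_id = character(0), primer = character(0),
                      start = integer(0), end = integer(0),
                      length_bp = integer(0), sequence = character(0),
                      n_products = integer(0)))
  res <- do.call(rbind, out)
  res[c("template_id", "primer", "start", "end", "length_bp", "n_products",
        "sequence")]
}

#' Check a primer pair against standard qPCR design constraints
#'
#' Evaluates the conventional design windows used for the candidate primers:
#' primer length 20-24 bp, melting temperature 55-65 degrees C, GC content
#' 45-60%, product size 80-200 bp. Tm is computed with nearest-neighbor
#' thermodynamics (see [primer_tm()]); the method tag is recorded in the
#' report. Flags are `TRUE` only when both primers satisfy the window.
#'
#' @param primers a [primer_pair()].
#' @param product_len product length in bp (e.g. from [in_silico_pcr()]).
#' @param conc_nM,na_mM primer concentration and monovalent-cation
#'   concentration passed to [primer_tm()].
#' @return List of class `primer_report`: per-primer `gc_percent` and
#'   `tm_celsius`, the four window flags, and `tm_method`.
#' @export
check_primer_constraints <- function(primers, product_len,
                                     conc_nM = 250, na_mM = 50) {
  stopifnot(inherits(primers, "primer_pair"))
  seqs <- c(forward = primers$forward, reverse = primers$reverse)
  len <- nchar(seqs)
  gc <- vapply(seqs, gc_percent, numeric(1))
  tm <- vapply(seqs, primer_tm, numeric(1), conc_nM = conc_nM, na_mM = na_mM)
  structure(list(
    name = primers$name,
    primer_length = len, gc_percent = gc, tm_celsius = tm,
    product_len = as.integer(product_len),
    length_ok = all(len >= 20 & len <= 24),
    tm_ok = all(tm >= 55 & tm <= 65),
    gc_ok = all(gc >= 45 & gc <= 60),
    product_size_ok = product_len >= 80 && product_len <= 200,
    tm_method = "nearest-neighbor (SantaLucia 1998 unified parameters)"),
    class = "primer_report")
}

gc_percent <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1L]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

#' Oligonucleotide melting temperature (nearest-neighbor)
#'
#' Two-state nearest-neighbor Tm with the unified DNA/DNA parameter set
#' (SantaLucia 1998), entropy salt correction
#' `dS + 0.368 * (N - 1) * ln([Na+])` and
#' `Tm = 1000 * dH / (dS + R * ln(CT / 4)) - 273.15`.
#'
#' @param seq primer sequence, A/C/G/T.
#' @param conc_nM total oligo concentration in nM (default 250).
#' @param na_mM monovalent cation concentration in mM (default 50).
#' @return Tm in degrees Celsius.
#' @export
primer_tm <- function(seq, conc_nM = 250, na_mM = 50) {
  s <- toupper(seq)
  validate_dna(s, "primer")
  chars <- strsplit(s, "")[[1L]]
  n <- length(chars)
  if (n < 8L) stop("nearest-neighbor Tm needs at least 8 nt")
  # unified NN parameters: dH kcal/mol, dS cal/(mol K)
  dh <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
          GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
          CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
  ds <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
          TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
          GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
          CC = -19.9)
  steps <- paste0(chars[-n], chars[-1L])
  H <- sum(dh[steps])
  S <- sum(ds[steps])
  for (terminal in chars[c(1L, n)]) {
    if (terminal %in% c("G", "C")) { H <- H + 0.1; S <- S - 2.8 }
    else { H <- H + 2.3; S <- S + 4.1 }
  }
  S <- S + 0.368 * (n - 1L) * log(na_mM / 1000)
  1000 * H / (S + 1.987 * log(conc_nM * 1e-9 / 4)) - 273.15
}

#' @export
print.primer_report <- function(x, ...) {
  cat(sprintf("primer report '%s' (Tm: %s)\n", x$name, x$tm_method))
  print(data.frame(primer = names(x$primer_length), length = x$primer_length,
                   gc_percent = round(x$gc_percent, 1),
                   tm_celsius = round(x$tm_celsius, 1), row.names = NULL))
  cat(sprintf(
    "product %d bp | length_ok %s, tm_ok %s, gc_ok %s, product_size_ok %s\n",
    x$product_len, x$length_ok, x$tm_ok, x$gc_ok, x$product_size_ok))
  invisible(x)
}
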