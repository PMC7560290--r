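# Independent brute-force oracles, written directly from the defining
# formulas. They deliberately share no code with the package internals.

oracle_pairwise_sd <- function(m) {
  genes <- rownames(m)
  k <- length(genes)
  out <- matrix(0, k, k, dimnames = list(genes, genes))
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j) {
    d <- as.numeric(m[i, ] - m[j, ])
    out[i, j] <- sqrt(sum((d - mean(d))^2) / (length(d) - 1))
  }
  out
}

oracle_delta_ct_scores <- function(m) {
  sd_mat <- oracle_pairwise_sd(m)
  sapply(rownames(m), function(g) mean(sd_mat[g, setdiff(rownames(m), g)]))
}

# geNorm M on relative quantities q = eff^(ctmin - ct)
oracle_genorm_M <- function(m, eff = 2) {
  q <- t(apply(m, 1L, function(ct) eff^(min(ct) - ct)))
  a <- log2(q)
  rownames(a) <- rownames(m)
  oracle_delta_ct_scores(a)  # same mean-of-pairwise-SD formula on log2 q
}

oracle_v_series <- function(m, ranked_genes, eff = 2) {
  q <- t(apply(m, 1L, function(ct) eff^(min(ct) - ct)))
  rownames(q) <- rownames(m)
  k <- length(ranked_genes)
  sapply(2:(k - 1), function(n) {
    nf_n <- apply(q[ranked_genes[1:n], , drop = FALSE], 2, function(col)
      prod(col)^(1 / n))
    nf_n1 <- apply(q[ranked_genes[1:(n + 1)], , drop = FALSE], 2, function(col)
      prod(col)^(1 / (n + 1)))
    r <- log2(nf_n / nf_n1)
    sqrt(sum((r - mean(r))^2) / (length(r) - 1))
  })
}

oracle_bestkeeper <- function(m) {
  t(apply(m, 1L, function(ct) {
    am <- mean(ct)
    mad <- mean(abs(ct - am))
    c(am = am, gm = prod(ct)^(1 / length(ct)), mad = mad,
      cv = mad / am * 100)
  }))
}

# NormFinder ungrouped: solve the full moment system
# E[u_i] = ((k-1)/k)^2 s_i + (1/k^2) sum_{j!=i} s_j for s = sigma^2.
oracle_normfinder_sigma <- function(m) {
  y <- -m
  y <- sweep(y, 2, colMeans(y))
  r <- y - rowMeans(y)
  k <- nrow(m); n <- ncol(m)
  u <- apply(r, 1, function(x) sum(x^2)) / (n - 1)
  A <- matrix(1 / k^2, k, k)
  diag(A) <- ((k - 1) / k)^2
  s <- solve(A, u)
  stats::setNames(sqrt(pmax(s, 0)), rownames(m))
}

# Needleman-Wunsch DP: maximise matches*match + mismatches*mismatch -
# gap_columns*gap; returns score, matches and alignment length of one optimal
# alignment (standard traceback).
oracle_nw <- function(a, b, match = 1, mismatch = 0, gap = 1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  la <- length(a); lb <- length(b)
  S <- matrix(0, la + 1, lb + 1)
  S[, 1] <- -gap * (0:la)
  S[1, ] <- -gap * (0:lb)
  for (i in 1:la) for (j in 1:lb) {
    sub <- S[i, j] + if (a[i] == b[j]) match else mismatch
    S[i + 1, j + 1] <- max(sub, S[i, j + 1] - gap, S[i + 1, j] - gap)
  }
  i <- la; j <- lb; n_match <- 0L; len <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] == S[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      n_match <- n_match + (a[i] == b[j]); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    len <- len + 1L
  }
  list(score = S[la + 1, lb + 1], matches = n_match, length = len,
       identity = 100 * n_match / len)
}

# All maximal common windows of length >= min_len, by exhaustive enumeration.
oracle_common_windows <- function(seqs, min_len) {
  ref <- seqs[[1]]
  others <- seqs[-1]
  l1 <- nchar(ref)
  hits <- list()
  for (p in 1:l1) {
    for (L in (l1 - p + 1):1) {
      if (L < min_len) break
      sub <- substr(ref, p, p + L - 1)
      if (all(vapply(others, function(s) grepl(sub, s, fixed = TRUE),
                     logical(1)))) {
        hits[[length(hits) + 1]] <- c(p = p, L = L)
        break  # longest at this start; shorter ones are not right-maximal
      }
    }
  }
  if (!length(hits)) return(data.frame(p = integer(0), L = integer(0)))
  h <- as.data.frame(do.call(rbind, hits))
  keep <- vapply(seq_len(nrow(h)), function(i) {
    !any(h$p < h$p[i] & h$p + h$L >= h$p[i] + h$L[i])
  }, logical(1))
  h[keep, , drop = FALSE]
}

# REML for the heteroscedastic two-way fixed-effects model, by numerical
# optimisation of the restricted likelihood; rows of y = genes.
oracle_reml_sigma <- function(y) {
  k <- nrow(y); n <- ncol(y)
  X <- stats::model.matrix(~ gf + sf,
                           data.frame(gf = factor(rep(1:k, n)),
                                      sf = factor(rep(1:n, each = k))))
  yv <- as.vector(y)
  nll <- function(ls) {
    s2 <- exp(2 * ls)[rep(1:k, n)]
    W <- 1 / s2
    XtWX <- crossprod(X * W, X)
    beta <- solve(XtWX, crossprod(X * W, yv))
    r <- yv - X %*% beta
    as.numeric(0.5 * (sum(log(s2)) +
                        determinant(XtWX, logarithm = TRUE)$modulus +
                        sum(r^2 * W)))
  }
  o <- stats::optim(rep(log(0.5), k), nll, method = "L-BFGS-B",
                    lower = log(0.02), upper = log(5),
                    control = list(maxit = 1000))
  exp(o$par)
}

# Random genes x samples Ct matrix from a small integer grid.
random_grid_matrix <- function(k = 3, n = 3, grid = 18:23) {
  m <- matrix(sample(grid, k * n, replace = TRUE), k, n,
              dimnames = list(paste0("g", 1:k), paste0("s", 1:n)))
  ct_matrix(m)
}

toy_matrix_abc <- function() {
  ct_matrix(matrix(c(20, 20, 20, 22, 23, 24, 30, 30, 31), nrow = 3,
                   byrow = TRUE,
                   dimnames = list(c("A", "B", "C"), c("s1", "s2", "s3"))))
}
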