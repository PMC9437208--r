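# Independent oracles used to verify the package's statistics and
# algorithms.  Each is a deliberately naive implementation (exhaustive
# enumeration or a literal transcription of the textbook procedure) kept
# separate from the code paths it checks.

random_dna <- function(len, planted = FALSE) {
  s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  if (planted && len >= 27) {
    unit <- sample(c("CTG", "CAG", "CGG", "GAA"), 1)
    k <- sample(3:8, 1)
    run <- rep(strsplit(unit, "")[[1]], k)
    n_mm <- sample(0:3, 1)
    if (n_mm > 0) {
      pos <- sample(length(run), min(n_mm, length(run)))
      for (p in pos) run[p] <- sample(setdiff(c("A","C","G","T"), run[p]), 1)
    }
    at <- sample(max(1, len - length(run) + 1), 1)
    end <- min(len, at + length(run) - 1)
    s[at:end] <- run[seq_len(end - at + 1)]
  }
  paste(s, collapse = "")
}

# Exhaustive window/rotation/Hamming scanner: enumerate every 3k window,
# compare against all 3 cyclic rotations of each paired unit via explicit
# string matrices, assign ties lexicographically, merge overlapping
# windows per assigned unit.
oracle_scan <- function(seq, spec) {
  s <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  k <- spec$min_units; L <- 3L * k; n <- length(s); m <- spec$max_mismatches
  units <- spec$unit
  if (spec$include_complement)
    units <- unique(c(units, tritarget::reverse_complement(spec$unit)))
  units <- sort(units)
  empty <- data.frame(start = integer(), end = integer(),
                      matched_unit = character(), n_units = integer(),
                      n_mismatches = integer(), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  n_win <- n - L + 1L
  idx <- outer(seq_len(n_win) - 1L, seq_len(L), "+")
  W <- matrix(s[idx], ncol = L)
  best <- sapply(units, function(u) {
    uu <- strsplit(u, "")[[1]]
    per_rot <- sapply(0:2, function(a) {
      pat <- rep(uu[((seq_len(3) - 1L + a) %% 3L) + 1L], k)
      rowSums(W != matrix(pat, n_win, L, byrow = TRUE))
    })
    apply(matrix(per_rot, nrow = n_win), 1, min)
  })
  best <- matrix(best, nrow = n_win)
  qual <- which(apply(best, 1, min) <= m)
  if (!length(qual)) return(empty)
  assigned <- apply(best[qual, , drop = FALSE], 1, which.min)
  hits <- empty
  for (ui in seq_along(units)) {
    st <- qual[assigned == ui]
    if (!length(st)) next
    mm <- best[st, ui]
    runs <- list(); cs <- st[1]; ce <- st[1] + L; cm <- mm[1]
    if (length(st) > 1) for (j in 2:length(st)) {
      if (st[j] < ce) { ce <- max(ce, st[j] + L); cm <- min(cm, mm[j]) }
      else { runs[[length(runs) + 1]] <- c(cs, ce, cm)
             cs <- st[j]; ce <- st[j] + L; cm <- mm[j] }
    }
    runs[[length(runs) + 1]] <- c(cs, ce, cm)
    rr <- do.call(rbind, runs)
    hits <- rbind(hits, data.frame(
      start = as.integer(rr[, 1] - 1L), end = as.integer(rr[, 2] - 1L),
      matched_unit = units[ui],
      n_units = as.integer((rr[, 2] - rr[, 1]) %/% 3),
      n_mismatches = as.integer(rr[, 3]),
      stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$start, hits$matched_unit), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Literal BH step-up: sort, multiply, cumulative minimum from the top.
bh_oracle <- function(p) {
  m <- length(p); o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m); out[o] <- q
  out
}

# Hypergeometric p-values from explicit binomial coefficients (lchoose),
# independent of dhyper/phyper.
hyper_pmf_oracle <- function(K, n, N) {
  lo <- max(0L, K + n - N); hi <- min(K, n); xs <- lo:hi
  list(xs = xs,
       pmf = exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}
hyper2_oracle <- function(x, K, n, N) {
  h <- hyper_pmf_oracle(K, n, N)
  obs <- h$pmf[x - h$xs[1] + 1]
  min(1, sum(h$pmf[h$pmf <= obs * (1 + 1e-7)]))
}
hyper_upper_oracle <- function(x, K, n, N) {
  h <- hyper_pmf_oracle(K, n, N)
  sum(h$pmf[h$xs >= x])
}

# Textbook UPGMA agglomerator returning the cophenetic matrix: at each
# step merge the two clusters with the smallest average pairwise original
# distance, recomputed from scratch.
upgma_coph_oracle <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  members <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(members) > 1) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_len(length(members) - 1)) {
      for (j in (i + 1):length(members)) {
        d <- mean(D[members[[i]], members[[j]]])
        if (d < best) { best <- d; bi <- i; bj <- j }
      }
    }
    coph[members[[bi]], members[[bj]]] <- best
    coph[members[[bj]], members[[bi]]] <- best
    members[[bi]] <- c(members[[bi]], members[[bj]])
    members[[bj]] <- NULL
  }
  coph
}

# Exact two-sample KS by full enumeration over all rank assignments.
ks_enum_oracle <- function(x, y, alternative = "greater") {
  stopifnot(!anyDuplicated(c(x, y)))
  m <- length(x); nn <- length(y); N <- m + nn
  z_obs <- c(rep(1, m), rep(0, nn))[order(c(x, y))]
  Dof <- function(z) {
    diff <- cumsum(z) / m - cumsum(1 - z) / nn
    if (alternative == "greater") max(diff) else max(abs(diff))
  }
  d_obs <- Dof(z_obs)
  combs <- utils::combn(N, m)
  Z <- matrix(0, N, ncol(combs))
  Z[cbind(as.vector(combs), rep(seq_len(ncol(combs)), each = m))] <- 1
  diffs <- apply(Z, 2, cumsum) / m - apply(1 - Z, 2, cumsum) / nn
  Ds <- if (alternative == "greater") apply(diffs, 2, max)
        else apply(abs(diffs), 2, max)
  list(D = d_obs, p = mean(Ds >= d_obs - 1e-12))
}

# Mean silhouette for a two-group labelling of points.
silhouette2 <- function(X, grp) {
  d <- as.matrix(stats::dist(X))
  n <- nrow(d)
  mean(sapply(seq_len(n), function(i) {
    a <- mean(d[i, grp == grp[i] & seq_len(n) != i])
    b <- mean(d[i, grp != grp[i]])
    (b - a) / max(a, b)
  }))
}

# Small null cohort helper used by several calibration tests.
null_cohort <- function(seed, n_genes = 2000, n_case = 10, n_control = 10) {
  tr <- sim_truth(seed = seed, n_genes = n_genes, pi0 = 0)
  simulate_counts(tr, simulate_labels(tr), n_case, n_control)
}
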