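# Independent reference implementations used as oracles.  These are
# deliberately written as straight-line / brute-force transcriptions of the
# formulas, separate from the package's vectorized code paths.

# Classic multiplicative-update NMF (Lee-Seung, Frobenius loss) with the
# same denominator stabilizer.  Returns the per-iteration objective
# ||X - W H'||_F^2 computed after each full W,H cycle.
nmf_reference <- function(X, W, H, iters, eps = 1e-9) {
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    W <- W * (X %*% H) / (W %*% (t(H) %*% H) + eps)
    H <- H * (t(X) %*% W) / (H %*% (t(W) %*% W) + eps)
    trace[it] <- sum((X - W %*% t(H))^2)
  }
  list(trace = trace, W = W, H = H)
}

# Element-by-element transcription of the W update rule, including target.
naive_update_w <- function(W, Xs, Hs, Y = NULL, HY = NULL, eps = 1e-9) {
  m <- nrow(W); r <- ncol(W)
  out <- matrix(0, m, r)
  for (a in seq_len(m)) for (b in seq_len(r)) {
    num <- 0; den <- 0
    for (i in seq_along(Xs)) {
      X <- Xs[[i]]; H <- Hs[[i]]
      for (j in seq_len(nrow(H))) num <- num + X[a, j] * H[j, b]
      # (W H' H)[a, b] = sum_c W[a, c] * sum_j H[j, c] H[j, b]
      for (cc in seq_len(r)) {
        hh <- 0
        for (j in seq_len(nrow(H))) hh <- hh + H[j, cc] * H[j, b]
        den <- den + W[a, cc] * hh
      }
    }
    if (!is.null(Y)) {
      num <- num + Y[a] * HY[1, b]
      for (cc in seq_len(r)) den <- den + W[a, cc] * HY[1, cc] * HY[1, b]
    }
    out[a, b] <- W[a, b] * num / (den + eps)
  }
  out
}

# Element-by-element transcription of the H update rule.
naive_update_h <- function(H, X, W, alpha, eps = 1e-9) {
  n <- nrow(H); r <- ncol(H)
  out <- matrix(0, n, r)
  for (a in seq_len(n)) for (b in seq_len(r)) {
    num <- alpha * H[a, b]
    for (s in seq_len(nrow(W))) num <- num + X[s, a] * W[s, b]
    den <- 0
    for (cc in seq_len(r)) {
      ww <- 0
      for (s in seq_len(nrow(W))) ww <- ww + W[s, cc] * W[s, b]
      den <- den + H[a, cc] * ww
      hh <- 0
      for (j in seq_len(n)) hh <- hh + H[j, cc] * H[j, b]
      den <- den + 2 * alpha * H[a, cc] * hh
    }
    out[a, b] <- H[a, b] * num / (den + eps)
  }
  out
}

# Element-by-element transcription of the H_Y update rule.
naive_update_hy <- function(HY, Y, W, eps = 1e-9) {
  r <- ncol(HY)
  out <- matrix(0, 1, r)
  for (b in seq_len(r)) {
    num <- 0
    for (s in seq_len(nrow(W))) num <- num + Y[s] * W[s, b]
    den <- 0
    for (cc in seq_len(r)) {
      ww <- 0
      for (s in seq_len(nrow(W))) ww <- ww + W[s, cc] * W[s, b]
      den <- den + HY[1, cc] * ww
    }
    out[1, b] <- HY[1, b] * num / (den + eps)
  }
  out
}

# Brute-force greedy spacing rule on sites with distinct counts: accept in
# descending count order unless within min_distance of an accepted site on
# the same chrom/strand (O(n^2)).
naive_peak_selection <- function(sites, min_distance) {
  ord <- order(-sites$cdna_count)
  accepted <- integer(0)
  for (s in ord) {
    ok <- TRUE
    for (a in accepted) {
      if (sites$chrom[a] == sites$chrom[s] &&
          sites$strand[a] == sites$strand[s] &&
          abs(sites$position[a] - sites$position[s]) < min_distance) {
        ok <- FALSE
        break
      }
    }
    if (ok) accepted <- c(accepted, s)
  }
  sites[sort(accepted), , drop = FALSE]
}

# Replays the initialization of one ionmf restart (seed + k convention).
replay_init <- function(seed, k, m, ns, r, target = FALSE) {
  set.seed(seed + k)
  W <- matrix(runif(m * r), m, r)
  H <- lapply(ns, function(n) matrix(runif(n * r), n, r))
  HY <- if (target) matrix(runif(r), 1, r) else NULL
  list(W = W, H = H, HY = HY)
}

# Membership-set partition labels (samples grouped by their exact module
# set) for adjusted-Rand comparisons of overlapping assignments.
membership_labels <- function(membership) {
  apply(membership, 1, function(x) paste(which(x), collapse = ","))
}

random_sources <- function(m, ns, seed = 1) {
  set.seed(seed)
  out <- lapply(seq_along(ns), function(i)
    data_source(matrix(runif(m * ns[i]), m, ns[i]), paste0("S", i)))
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
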