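# Independent oracles, deliberately written without reference to the package
# implementation paths they check.

# -- Winding-number point-in-polygon (vs the package's crossing-number code) --
oracle_point_in_polygon <- function(px, py, v) {
  n <- nrow(v)
  wn <- numeric(length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    x1 <- v[i, 1]; y1 <- v[i, 2]; x2 <- v[j, 1]; y2 <- v[j, 2]
    is_left <- (x2 - x1) * (py - y1) - (px - x1) * (y2 - y1)
    wn <- wn + ((y1 <= py) & (y2 > py) & (is_left > 0)) -
               ((y1 > py) & (y2 <= py) & (is_left < 0))
  }
  wn != 0
}

# -- Two-sided Student-t tail probability by numerical quadrature ------------
oracle_t_pvalue <- function(tstat, df) {
  dens <- function(x)
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  2 * stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-12)$value
}

# -- Brute-force soft-margin SVM dual solver (sequential minimal optimisation)
# Operates on a precomputed kernel matrix; y in {-1, +1}.
oracle_smo_train <- function(K, y, C, tol = 1e-3, max_passes = 50) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  passes <- 0
  while (passes < max_passes) {
    changed <- 0L
    for (i in seq_len(n)) {
      Ei <- sum(alpha * y * K[, i]) + b - y[i]
      if ((y[i] * Ei < -tol && alpha[i] < C) || (y[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample(seq_len(n)[-i], 1L)
        Ej <- sum(alpha * y * K[, j]) + b - y[j]
        ai0 <- alpha[i]; aj0 <- alpha[j]
        if (y[i] != y[j]) {
          L <- max(0, aj0 - ai0); H <- min(C, C + aj0 - ai0)
        } else {
          L <- max(0, ai0 + aj0 - C); H <- min(C, ai0 + aj0)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj <- min(max(aj0 - y[j] * (Ei - Ej) / eta, L), H)
        if (abs(aj - aj0) < 1e-7) next
        ai <- ai0 + y[i] * y[j] * (aj0 - aj)
        alpha[i] <- ai; alpha[j] <- aj
        b1 <- b - Ei - y[i] * (ai - ai0) * K[i, i] - y[j] * (aj - aj0) * K[i, j]
        b2 <- b - Ej - y[i] * (ai - ai0) * K[i, j] - y[j] * (aj - aj0) * K[j, j]
        b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  }
  list(alpha = alpha, b = b)
}

oracle_rbf_kernel <- function(A, B, gamma) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

# k-fold CV accuracy (%) using the SMO oracle on given fold assignments.
oracle_cv_accuracy <- function(X, y01, folds, C, gamma) {
  y <- ifelse(y01 == 1L, 1, -1)
  correct <- 0L
  for (k in seq_len(max(folds))) {
    te <- folds == k
    Xtr <- X[!te, , drop = FALSE]
    Ktr <- oracle_rbf_kernel(Xtr, Xtr, gamma)
    fit <- oracle_smo_train(Ktr, y[!te], C)
    f <- oracle_rbf_kernel(X[te, , drop = FALSE], Xtr, gamma) %*%
      (fit$alpha * y[!te]) + fit$b
    correct <- correct + sum((f > 0) == (y01[te] == 1L))
  }
  100 * correct / length(y01)
}

# Exhaustive largest-remainder reference (independent re-derivation).
oracle_largest_remainder <- function(n, w) {
  q <- n * w / sum(w)
  base <- floor(q)
  r <- q - base
  need <- n - sum(base)
  ord <- order(-r, seq_along(r))
  add <- integer(length(w))
  if (need > 0) add[ord[seq_len(need)]] <- 1L
  as.integer(base + add)
}
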