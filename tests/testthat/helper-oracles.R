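# Independent oracles, deliberately brute-force: they share no code with the
# implementation paths they check.

# Maximum of c'x over {A x = b, lb <= x <= ub} by enumerating every basic
# solution: all column subsets of size rank(A), all bound assignments of the
# nonbasic columns. Only viable for tiny LPs.
enum_lp_max <- function(A, b, lb, ub, cc, tol = 1e-7) {
  m <- nrow(A)
  n <- ncol(A)
  best <- -Inf
  for (B in combn(n, m, simplify = FALSE)) {
    AB <- A[, B, drop = FALSE]
    if (abs(det(AB)) < 1e-10) next
    N <- setdiff(seq_len(n), B)
    k <- length(N)
    grid <- if (k > 0) {
      as.matrix(expand.grid(rep(list(c(0, 1)), k)))
    } else {
      matrix(0, 1, 0)
    }
    for (g in seq_len(nrow(grid))) {
      xN <- ifelse(grid[g, ] == 0, lb[N], ub[N])
      if (any(!is.finite(xN))) next
      rhs <- b - if (k > 0) A[, N, drop = FALSE] %*% xN else 0
      xB <- tryCatch(solve(AB, rhs), error = function(e) NULL)
      if (is.null(xB)) next
      if (all(xB >= lb[B] - tol) && all(xB <= ub[B] + tol)) {
        x <- numeric(n)
        x[B] <- xB
        x[N] <- xN
        best <- max(best, sum(cc * x))
      }
    }
  }
  best
}

# random feasible bounded LP in FBA shape (equality rows + finite box)
random_toy_lp <- function(n_rxns, n_mets) {
  A <- matrix(sample(-2:2, n_mets * n_rxns, replace = TRUE), n_mets, n_rxns)
  lb <- round(runif(n_rxns, -5, 0), 1)
  ub <- lb + round(runif(n_rxns, 0.5, 8), 1)
  x0 <- lb + runif(n_rxns) * (ub - lb)
  b <- as.vector(A %*% x0)
  cc <- round(runif(n_rxns, -3, 3), 1)
  list(A = A, b = b, lb = lb, ub = ub, cc = cc)
}

# exact permutation p of the Kruskal-Wallis H (three groups), with H
# recomputed from first principles for every assignment
kw_exact_p <- function(groups_values) {
  y <- unlist(groups_values)
  sizes <- lengths(groups_values)
  h_of <- function(g1, g2, g3) {
    kw_H_oracle(list(y[g1], y[g2], y[g3]))
  }
  n <- length(y)
  h_obs <- h_of(seq_len(sizes[1]),
                sizes[1] + seq_len(sizes[2]),
                sizes[1] + sizes[2] + seq_len(sizes[3]))
  count <- 0
  total <- 0
  for (g1 in combn(n, sizes[1], simplify = FALSE)) {
    rest <- setdiff(seq_len(n), g1)
    for (g2 in combn(rest, sizes[2], simplify = FALSE)) {
      g3 <- setdiff(rest, g2)
      total <- total + 1
      if (h_of(g1, g2, g3) >= h_obs - 1e-9) count <- count + 1
    }
  }
  count / total
}

# exact two-sided Wilcoxon rank-sum p by enumerating all group splits
wilcox_exact_p <- function(a, b) {
  y <- c(a, b)
  n <- length(y)
  ra <- sum(rank(y)[seq_along(a)])
  splits <- combn(n, length(a))
  stats <- apply(splits, 2, function(idx) sum(rank(y)[idx]))
  mu <- mean(stats)
  mean(abs(stats - mu) >= abs(ra - mu) - 1e-9)
}

# classic two-sided 2x2 Fisher p from the hypergeometric distribution
fisher_2x2_p <- function(tb) {
  m <- sum(tb[, 1])
  n <- sum(tb[, 2])
  k <- sum(tb[1, ])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tb[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# tie-corrected Kruskal-Wallis H recomputed from first principles
kw_H_oracle <- function(groups_values) {
  y <- unlist(groups_values)
  N <- length(y)
  r <- rank(y)
  ns <- lengths(groups_values)
  idx <- rep(seq_along(ns), ns)
  H <- 12 / (N * (N + 1)) *
    sum(ns * (tapply(r, idx, mean) - (N + 1) / 2)^2)
  ties <- table(y)
  unname(H / (1 - sum(ties^3 - ties) / (N^3 - N)))
}
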