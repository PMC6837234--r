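# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the edit-distance oracle is a plain recursion on
# the textbook definition, the likelihood oracle enumerates ancestral states
# with matrix-exponential transition probabilities, and clustering is
# cross-checked against stats::hclust.

# Levenshtein distance by direct recursion on the defining identity
# (feasible for strings up to ~8 characters).
lev_recursive <- function(a, b) {
  if (!nchar(a)) return(nchar(b))
  if (!nchar(b)) return(nchar(a))
  a1 <- substr(a, 1, 1); b1 <- substr(b, 1, 1)
  ar <- substr(a, 2, nchar(a)); br <- substr(b, 2, nchar(b))
  min(lev_recursive(ar, b) + 1,
      lev_recursive(a, br) + 1,
      lev_recursive(ar, br) + (a1 != b1))
}

# hand-built rate matrix + Pade matrix exponential (Matrix::expm), kept
# separate from build_q()/transition_matrix()
expm_kernel <- function(pi, mu, t) {
  k <- length(pi)
  q <- mu * matrix(pi, k, k, byrow = TRUE)
  diag(q) <- diag(q) - mu
  as.matrix(Matrix::expm(q * t))
}

# exhaustive ancestral-state enumeration of the tree likelihood; transition
# probabilities from the matrix exponential, root weighted by pi
enum_loglik <- function(tree, states, pi, mu) {
  k <- length(pi)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  internal <- ntip + seq_len(nnode)
  grid <- do.call(expand.grid, rep(list(seq_len(k)), nnode))
  pmat <- lapply(tree$edge.length, function(t) expm_kernel(pi, mu, t))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign_full <- c(states + 1L, as.integer(grid[g, ]))
    lik <- pi[assign_full[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      pa <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      if (ch <= ntip && is.na(assign_full[ch])) next  # missing tip
      lik <- lik * pmat[[e]][assign_full[pa], assign_full[ch]]
    }
    total <- total + lik
  }
  log(total)
}

# random rooted binary tree with exponential branch lengths (years scale)
random_tree <- function(n, mean_len = 5000) {
  tree <- ape::rtree(n, rooted = TRUE)
  tree$edge.length <- stats::rexp(length(tree$edge.length), 1 / mean_len)
  tree$tip.label <- sprintf("t%d", seq_len(n))
  tree
}

# random symmetric distance matrix in [0, 1] with zero diagonal
random_dist <- function(n) {
  d <- matrix(stats::runif(n * n), n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(letters[seq_len(n)], letters[seq_len(n)])
  d
}

# partitions equal up to label permutation
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# flat average-linkage clustering via the independent hclust/cutree route
hclust_flat <- function(d, theta) {
  if (nrow(d) == 1L) return(stats::setNames(1L, rownames(d)))
  stats::cutree(stats::hclust(stats::as.dist(d), method = "average"),
                h = theta)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(sum(tab))
  exp_ix <- sum_a * sum_b / n2
  mx <- (sum_a + sum_b) / 2
  if (mx == exp_ix) return(1)
  (sum_ij - exp_ix) / (mx - exp_ix)
}

# 1-D quadrature of the marginal likelihood on a fixed tree: the rate prior
# is one-dimensional, so the evidence integral is available to high accuracy
# by adaptive quadrature, an absolute reference for the stepping-stone
# sampler.
quad_log_ml <- function(tree, ch, pi, prior = "uniform", upper = 100) {
  ll <- Vectorize(function(mu) pruning_loglik(tree, ch, pi, mu / 1e4))
  grid <- exp(seq(log(1e-3), log(upper), length.out = 200))
  m <- max(ll(grid))
  dens <- if (prior == "uniform") function(mu) 1 / upper else
    function(mu) exp(-mu)
  f <- function(mu) exp(ll(mu) - m) * dens(mu)
  log(stats::integrate(f, 0, upper, rel.tol = 1e-9,
                       subdivisions = 500L)$value) + m
}

# OLS estimates and standard errors straight from the normal equations
ols_oracle <- function(X, y) {
  xtx_inv <- solve(t(X) %*% X)
  beta <- xtx_inv %*% t(X) %*% y
  res <- y - X %*% beta
  s2 <- sum(res^2) / (nrow(X) - ncol(X))
  list(beta = drop(beta), se = sqrt(diag(xtx_inv) * s2))
}
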