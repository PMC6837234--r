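test_that("empirical frequencies are plain tip proportions", {
  ch <- multistate_character(c(a = 0, b = 0, c = 1, d = 1))
  expect_equal(empirical_frequencies(ch), c(0.5, 0.5))
  expect_equal(empirical_frequencies(multistate_character(c(a = 0, b = 0, c = 0))),
               1)
  ch3 <- multistate_character(c(en = 0, sv = 1, pl = 2))
  expect_equal(empirical_frequencies(ch3), rep(1 / 3, 3))
  expect_error(empirical_frequencies(multistate_character(c(a = NA, b = NA))),
               "missing")
})

test_that("the rate matrix is frequency-scaled with zero row sums and pi stationary", {
  q <- build_q(c(0.5, 0.5), 1)
  expect_equal(q, matrix(c(-0.5, 0.5, 0.5, -0.5), 2, byrow = TRUE))
  set.seed(3)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    pi <- as.numeric(stats::rgamma(k, 2)); pi <- pi / sum(pi)
    mu <- stats::rexp(1)
    q <- build_q(pi, mu)
    expect_equal(rowSums(q), rep(0, k), tolerance = 1e-12)
    expect_true(all(q[row(q) != col(q)] >= 0))
    expect_equal(drop(pi %*% q), rep(0, k), tolerance = 1e-12)
  }
  expect_true(isTRUE(attr(build_q(1, 2), "degenerate")))
})

test_that("the global rate is the stationary-weighted flux", {
  pi <- c(0.5, 0.5)
  expect_equal(global_rate(build_q(pi, 1), pi), 0.5)
  for (k in 2:5) {
    piu <- rep(1 / k, k)
    expect_equal(global_rate(build_q(piu, 2), piu), 2 * (1 - 1 / k))
  }
  # a frequency-1 state cannot be observably replaced
  pi_deg <- c(1 - 1e-15, 1e-15)
  expect_equal(global_rate(build_q(pi_deg, 5), pi_deg), 0, tolerance = 1e-12)
})

test_that("closed-form kernel matches the matrix exponential", {
  pi <- c(0.2, 0.3, 0.5)
  expect_equal(transition_matrix(pi, 0.7, 0), diag(3))
  expect_equal(transition_matrix(pi, 0.7, 1e9),
               matrix(pi, 3, 3, byrow = TRUE), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    pi <- as.numeric(stats::rgamma(k, 2)); pi <- pi / sum(pi)
    mu <- stats::rexp(1); t1 <- stats::rexp(1); t2 <- stats::rexp(1)
    p1 <- transition_matrix(pi, mu, t1)
    expect_equal(rowSums(p1), rep(1, k), tolerance = 1e-12)
    expect_equal(p1, expm_kernel(pi, mu, t1), tolerance = 1e-10)
    # Chapman-Kolmogorov
    expect_equal(p1 %*% transition_matrix(pi, mu, t2),
                 transition_matrix(pi, mu, t1 + t2), tolerance = 1e-8)
  }
  expect_error(transition_matrix(pi, 1, -1), "non-negative")
})

test_that("pruning matches hand expansions on one- and two-leaf trees", {
  pi <- c(0.3, 0.7)
  one <- ape::read.tree(text = "(A:1);")
  chA <- multistate_character(c(A = 1L))
  expect_equal(pruning_loglik(one, chA, pi, 0.4), log(0.7))

  two <- ape::read.tree(text = "(A:2,B:3);")
  ch <- multistate_character(c(A = 0L, B = 0L))
  mu <- 0.31
  hand <- sum(pi * transition_matrix(pi, mu, 2)[, 1] *
                transition_matrix(pi, mu, 3)[, 1])
  expect_equal(pruning_loglik(two, ch, pi, mu), log(hand), tolerance = 1e-12)
})

test_that("pruning equals exhaustive ancestral enumeration on small trees", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(3:5, 1)
    k <- sample(2:4, 1)
    tree <- random_tree(n, mean_len = 2)
    pi <- as.numeric(stats::rgamma(k, 2)); pi <- pi / sum(pi)
    mu <- stats::rexp(1, 2)
    states <- sample(0:(k - 1), n, replace = TRUE)
    if (i %% 5 == 0) states[sample(n, 1)] <- NA  # exercise missing tips
    ch <- multistate_character(stats::setNames(states, tree$tip.label))
    expect_equal(pruning_loglik(tree, ch, pi, mu),
                 enum_loglik(tree, states, pi, mu), tolerance = 1e-10)
  }
})

test_that("the likelihood is invariant to state relabelling", {
  set.seed(31)
  tree <- random_tree(6, mean_len = 1.5)
  k <- 3
  pi <- c(0.2, 0.5, 0.3)
  states <- sample(0:(k - 1), 6, replace = TRUE)
  ch <- multistate_character(stats::setNames(states, tree$tip.label))
  perm <- sample(k)
  ch_p <- multistate_character(stats::setNames(perm[states + 1] - 1L,
                                               tree$tip.label))
  expect_equal(pruning_loglik(tree, ch, pi, 0.8),
               pruning_loglik(tree, ch_p, pi[order(perm)], 0.8),
               tolerance = 1e-12)
})

test_that("rates scale exactly between per-year and per-10-kyr units", {
  expect_equal(scale_rate(1e-4), 1)
  expect_identical(scale_rate(0), 0)
  x <- stats::runif(5)
  expect_equal(scale_rate(x) / 1e4, x)
})

test_that("chain schedules enforce their arithmetic invariants", {
  s <- chain_schedule()
  expect_equal(s$n_draws, 10000L)
  expect_equal(scaled_down_schedule()$n_draws, 1000L)
  expect_error(chain_schedule(100, 200, 10), "burn-in")
  expect_error(chain_schedule(1000, 100, 7), "divisible")
  expect_error(chain_schedule(1000, 100, 0), "thinning")
})
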