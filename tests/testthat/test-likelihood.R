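test_that("HKY matrices satisfy their structural invariants", {
  pi <- c(0.31, 0.31, 0.13, 0.25)
  m <- hky_model(8, pi, gamma_shape = 0.5)
  expect_equal(unname(rowSums(m$Q)), rep(0, 4), tolerance = 1e-12)
  # detailed balance
  for (i in 1:4) for (j in 1:4)
    expect_equal(m$base_freqs[i] * m$Q[i, j], m$base_freqs[j] * m$Q[j, i],
                 tolerance = 1e-12)
  # unit mean rate
  expect_equal(-sum(m$base_freqs * diag(m$Q)), 1, tolerance = 1e-12)
  # spectral transition probabilities match a generic matrix exponential
  for (t in c(0.01, 0.3, 2)) {
    P <- transition_prob(m, t)
    expect_equal(rowSums(P), rep(1, 4), tolerance = 1e-10)
    expect_equal(P, as.matrix(Matrix::expm(m$Q * t)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("discrete gamma categories average to one and track the shape", {
  for (a in c(0.2, 0.5, 1, 5)) {
    r <- discrete_gamma_rates(a, 4)
    expect_equal(mean(r), 1, tolerance = 1e-9)
    expect_true(all(diff(r) > 0))
  }
  # a large shape approaches rate homogeneity
  expect_lt(diff(range(discrete_gamma_rates(100, 4))), 0.3)
  skip_if_not_installed("phangorn")
  expect_equal(discrete_gamma_rates(0.4, 4),
               phangorn::discrete.gamma(0.4, 4), tolerance = 1e-6)
})

test_that("pruning equals exhaustive enumeration on small trees", {
  for (seed in 1:6) {
    ntaxa <- 2 + (seed %% 4)
    tr <- random_rooted_tree(ntaxa, seed)
    aln <- random_alignment(tr$tip.label, 1 + (seed %% 4), seed + 50)
    kappa <- c(1, 2, 8)[1 + (seed %% 3)]
    shape <- if (seed %% 2) 0.5 else NULL
    ll <- tree_log_likelihood(aln, tr, kappa = kappa, gamma_shape = shape)
    oracle <- brute_force_loglik(aln, tr, kappa = kappa, gamma_shape = shape)
    expect_equal(ll, oracle, tolerance = 1e-10, label = paste("seed", seed))
  }
})

test_that("ambiguity codes enter as partial observations", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.2):0;")
  base <- matrix(c("C", "C"), 2, dimnames = list(c("a", "b"), NULL))
  y <- matrix(c("Y", "C"), 2, dimnames = list(c("a", "b"), NULL))
  t_ <- matrix(c("T", "C"), 2, dimnames = list(c("a", "b"), NULL))
  f <- c(0.25, 0.25, 0.25, 0.25)
  lY <- tree_log_likelihood(y, tr, kappa = 2, base_freqs = f)
  lC <- tree_log_likelihood(base, tr, kappa = 2, base_freqs = f)
  lT <- tree_log_likelihood(t_, tr, kappa = 2, base_freqs = f)
  expect_equal(exp(lY), exp(lC) + exp(lT), tolerance = 1e-12)
})

test_that("two identical one-site sequences approach log base frequency", {
  tr <- ape::read.tree(text = "(a:1e-9,b:1e-9):0;")
  aln <- matrix(c("G", "G"), 2, dimnames = list(c("a", "b"), NULL))
  f <- c(0.31, 0.31, 0.13, 0.25)
  ll <- tree_log_likelihood(aln, tr, kappa = 2, base_freqs = f)
  expect_equal(ll, log(0.13), tolerance = 1e-6)
})

test_that("kappa = 1 reduces to the equal-rates closed form", {
  # under kappa 1 (F81), P_ij(t) = pi_j + (delta_ij - pi_j) exp(-beta t)
  f <- c(0.31, 0.31, 0.13, 0.25)
  beta <- 1 / (1 - sum(f^2))
  t1 <- 0.07; t2 <- 0.12
  tr <- ape::read.tree(text = sprintf("(a:%f,b:%f):0;", t1, t2))
  aln <- matrix(c("A", "G"), 2, dimnames = list(c("a", "b"), NULL))
  ll <- tree_log_likelihood(aln, tr, kappa = 1, base_freqs = f)
  # reversibility collapses the two branches into one path
  p_ag <- f[3] * (1 - exp(-beta * (t1 + t2)))
  expect_equal(ll, log(f[1] * p_ag), tolerance = 1e-10)
})

test_that("likelihood is invariant to tip order and root sliding", {
  tr <- random_rooted_tree(5, 3)
  aln <- random_alignment(tr$tip.label, 6, 9)
  ll <- tree_log_likelihood(aln, tr, kappa = 3, gamma_shape = 0.7)
  perm <- sample(nrow(aln))
  ll2 <- tree_log_likelihood(aln[perm, , drop = FALSE], tr, kappa = 3,
                             gamma_shape = 0.7)
  expect_equal(ll, ll2, tolerance = 1e-12)
  # slide the root along its edge keeping the total path length fixed
  root_edges <- which(tr$edge[, 1] == ape::Ntip(tr) + 1L)
  tr2 <- tr
  d <- min(tr$edge.length[root_edges]) / 2
  tr2$edge.length[root_edges[1]] <- tr$edge.length[root_edges[1]] - d
  tr2$edge.length[root_edges[2]] <- tr$edge.length[root_edges[2]] + d
  ll3 <- tree_log_likelihood(aln, tr2, kappa = 3, gamma_shape = 0.7)
  expect_equal(ll, ll3, tolerance = 1e-9)
})

test_that("an empty alignment is rejected", {
  tr <- ape::read.tree(text = "(a:0.1,b:0.2):0;")
  aln <- matrix(character(0), 2, 0, dimnames = list(c("a", "b"), NULL))
  expect_error(tree_log_likelihood(aln, tr, kappa = 2), "zero-length")
})

test_that("the six-bin partition covers the genome exactly once", {
  ref <- mt_reference()
  mask <- site_mask()
  parts <- partition_sites(ref, mask)
  expect_equal(length(parts$bins), 6L)
  expect_true(all(parts$bin_sizes > 0))
  expect_equal(sum(parts$bin_sizes) + length(mask$snp_positions), 16569L)
  # positions land in their annotated bins
  expect_equal(parts$bins[parts$site_map[16400]], "HVS")
  expect_equal(parts$bins[parts$site_map[100]], "HVS")    # HVS-II
  expect_equal(parts$bins[parts$site_map[600]], "tRNA")
  expect_equal(parts$bins[parts$site_map[3309]], "codon3")  # third of codon 1 gene start
  expect_true(is.na(parts$site_map[16519]))
  # default relative rates are flat with weighted mean one
  w <- parts$bin_sizes / sum(parts$bin_sizes)
  expect_equal(sum(w * parts$relative_rates), 1, tolerance = 1e-12)
  rr <- set_relative_rates(parts, c(codon1 = 1, codon2 = 0.4, codon3 = 2,
                                    HVS = 6, tRNA = 0.5, other = 0.8))
  expect_equal(sum(w * rr$relative_rates), 1, tolerance = 1e-12)
})

test_that("rate surveys average into a moment-matched lognormal prior", {
  # single component: moment matching returns its own parameters
  one <- average_rate_prior(data.frame(mean = 2e-8, sd = 4e-9))
  expect_equal(one$mean_rate, 2e-8)
  m <- one$meanlog; s <- one$sdlog
  expect_equal(exp(m + s^2 / 2), 2e-8, tolerance = 1e-12)
  expect_equal((exp(s^2) - 1) * exp(2 * m + s^2), (4e-9)^2,
               tolerance = 1e-12)

  # the packaged survey averages to the calibration value
  prior <- average_rate_prior()
  expect_equal(prior$mean_rate, 2.285e-8, tolerance = 1e-15)

  # two-point mixture: closed-form moments
  rates <- data.frame(mean = c(1e-8, 3e-8), sd = c(2e-9, 2e-9))
  p <- average_rate_prior(rates)
  mix_mean <- 2e-8
  mix_var <- mean(rates$sd^2) + mean((rates$mean - mix_mean)^2)
  expect_equal(p$sdlog^2, log(1 + mix_var / mix_mean^2), tolerance = 1e-12)
  expect_equal(p$meanlog, log(mix_mean) - p$sdlog^2 / 2, tolerance = 1e-12)

  expect_error(average_rate_prior(data.frame(mean = -1, sd = 1)),
               "non-positive")
})
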