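# Independent oracles and shared fixtures for the test suite.

NUC4 <- c("A", "C", "G", "T")

# Brute-force tree likelihood: enumerate all internal-state combinations,
# transition probabilities via Matrix::expm (independent of the package's
# spectral decomposition and pruning recursion).
brute_force_loglik <- function(aln, tree, kappa, gamma_shape = NULL,
                               ncat = 4L, base_freqs = NULL) {
  if (is.null(base_freqs)) {
    tab <- table(factor(aln[aln %in% NUC4], levels = NUC4))
    base_freqs <- (as.numeric(tab) + 1) / sum(as.numeric(tab) + 1)
  }
  pi <- base_freqs / sum(base_freqs)
  Q <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ts <- paste(sort(c(NUC4[i], NUC4[j])), collapse = "") %in% c("AG", "CT")
    Q[i, j] <- if (ts) kappa * pi[j] else pi[j]
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(pi * diag(Q)))
  rates <- if (is.null(gamma_shape)) 1 else
    discrete_gamma_rates(gamma_shape, ncat)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  aln <- aln[tree$tip.label, , drop = FALSE]
  allowed <- function(b) {
    codes <- list(A = 1, C = 2, G = 3, T = 4, R = c(1, 3), Y = c(2, 4),
                  S = c(2, 3), W = c(1, 4), K = c(3, 4), M = c(1, 2),
                  N = 1:4, `-` = 1:4, `?` = 1:4)
    codes[[b]]
  }
  total <- 0
  for (s in seq_len(ncol(aln))) {
    sitelik <- 0
    for (r in rates) {
      P <- lapply(tree$edge.length * r, function(t)
        as.matrix(Matrix::expm(Q * t)))
      combos <- as.matrix(expand.grid(rep(list(1:4), nnode)))
      for (ci in seq_len(nrow(combos))) {
        intstates <- combos[ci, ]
        pr <- pi[intstates[1]]  # root = ntip + 1 is the first internal
        state_of <- function(nd) {
          if (nd <= ntip) NA else intstates[nd - ntip]
        }
        for (e in seq_len(nrow(tree$edge))) {
          u <- state_of(tree$edge[e, 1])
          vnd <- tree$edge[e, 2]
          if (vnd <= ntip) {
            pr <- pr * sum(P[[e]][u, allowed(aln[vnd, s])])
          } else {
            pr <- pr * P[[e]][u, state_of(vnd)]
          }
        }
        sitelik <- sitelik + pr / length(rates)
      }
    }
    total <- total + log(sitelik)
  }
  total
}

# Brute-force minimum-change (parsimony) count: enumerate all internal
# labelings over the observed-state alphabet.
brute_force_parsimony <- function(tree, tip_states) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  alpha <- sort(unique(tip_states))
  combos <- as.matrix(expand.grid(rep(list(alpha), nnode)))
  best <- Inf
  for (ci in seq_len(nrow(combos))) {
    st <- c(tip_states[tree$tip.label], combos[ci, ])
    changes <- sum(st[tree$edge[, 1]] != st[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# deterministic random rooted tree with branch lengths
random_rooted_tree <- function(ntip, seed) {
  set.seed(seed)
  tr <- ape::rtree(ntip, rooted = TRUE)
  tr$edge.length <- tr$edge.length * 0.3 + 0.01
  tr
}

random_alignment <- function(tips, nsites, seed, codes = NUC4) {
  set.seed(seed)
  m <- matrix(sample(codes, length(tips) * nsites, replace = TRUE),
              nrow = length(tips), dimnames = list(tips, NULL))
  m
}

# fixture tree + profiles used across annotation/acceptance tests
fixture_bundle <- function() {
  ht <- l5p7_haplotree()
  ref <- mt_reference()
  fx <- plant_haplogroup_fixture(ht, ref)
  tr <- haplotree_as_phylo(ht)
  list(ht = ht, ref = ref, fx = fx, tree = tr)
}

fixture_clade_node <- function(tree, tips) {
  keys <- haplomt:::clade_keys(tree)
  hit <- which(keys == paste(sort(tips), collapse = "|"))
  if (!length(hit)) stop("clade not in tree")
  ape::Ntip(tree) + hit
}

l7_family <- c("L7", "L7a", "L7a*", "L7a1", "L7b", "L7b1", "L7b2")
l5_family <- c("L5", "L5a", "L5a1", "L5a2", "L5b", "L5b1", "L5b*")
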