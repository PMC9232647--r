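simulate_labels <- function(tree, q, levels, seed) {
  set.seed(seed)
  k <- length(levels)
  ntip <- ape::Ntip(tree)
  states <- integer(ntip + tree$Nnode)
  states[ntip + 1L] <- sample.int(k, 1)
  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  el <- tree$edge.length[match(paste(edge[, 1], edge[, 2]),
                               paste(tree$edge[, 1], tree$edge[, 2]))]
  for (e in seq_len(nrow(edge))) {
    P <- haplomt:::er_pmat(k, q, el[e])
    states[edge[e, 2]] <- sample.int(k, 1, prob = P[states[edge[e, 1]], ])
  }
  stats::setNames(levels[states[seq_len(ntip)]], tree$tip.label)
}

test_that("uniform tip labels give certain ancestors", {
  cfg <- sim_config(seed = 1, n_tips = 12, ne = 2000)
  tr <- simulate_coalescent_tree(cfg)
  labs <- stats::setNames(rep("Bantu", 12), tr$tip.label)
  pa <- ancestral_populations(tr, labs)
  expect_equal(unique(as.numeric(pa$node_prob)), 1)
  expect_true(all(pa$informative))
  expect_error(ancestral_populations(tr, stats::setNames(rep(NA, 12),
                                                         tr$tip.label)),
               "all tips unknown")
})

test_that("two distant tips leave the root uninformative", {
  tr <- ape::read.tree(text = "(a:1e7,b:1e7);")
  labs <- c(a = "RFHG", b = "Bantu")
  pa <- ancestral_populations(tr, labs)
  # 2-state closed form: at saturation the root marginal is uniform
  expect_equal(as.numeric(pa$node_prob[1, ]), c(0.5, 0.5), tolerance = 0.02)
  expect_false(pa$informative[1])
})

test_that("probability vectors always sum to one and flag at the cutoff", {
  cfg <- sim_config(seed = 8, n_tips = 25, ne = 2000)
  tr <- simulate_coalescent_tree(cfg)
  labs <- simulate_labels(tr, q = 2e-5, levels = c("A", "B", "C"), seed = 5)
  pa <- ancestral_populations(tr, labs)
  expect_equal(rowSums(pa$node_prob), rep(1, tr$Nnode), tolerance = 1e-9)
  expect_identical(pa$informative,
                   unname(apply(pa$node_prob, 1, max) > 0.9))
})

test_that("the fitted transition rate matches an independent engine", {
  cfg <- sim_config(seed = 9, n_tips = 25, ne = 3000)
  tr <- simulate_coalescent_tree(cfg)
  tr$edge.length <- tr$edge.length / 1000
  labs <- simulate_labels(tr, q = 0.02, levels = c("A", "B", "C"), seed = 2)
  pa <- ancestral_populations(tr, labs)
  a <- ape::ace(factor(labs[tr$tip.label]), tr, type = "discrete",
                model = "ER")
  expect_equal(pa$rate, as.numeric(a$rates), tolerance = 1e-3)
  # identical model, root handled as uniform: logliks differ by log k
  expect_equal(pa$loglik, a$loglik - log(3), tolerance = 1e-4)
  # marginal node vectors agree
  expect_equal(unname(pa$node_prob), unname(a$lik.anc), tolerance = 1e-4)
})

test_that("label-change rates are recovered within a factor of two", {
  q_true <- 1e-5
  fitted <- vapply(1:12, function(i) {
    cfg <- sim_config(seed = 100 + i, n_tips = 30, ne = 3000)
    tr <- simulate_coalescent_tree(cfg)
    labs <- simulate_labels(tr, q = q_true,
                            levels = c("A", "B", "C", "D"), seed = 200 + i)
    if (length(unique(labs)) < 2) return(NA_real_)
    ancestral_populations(tr, labs)$rate
  }, numeric(1))
  fitted <- fitted[is.finite(fitted)]
  ratio <- exp(mean(log(fitted))) / q_true
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("frequency aggregation normalizes within regions", {
  tab <- data.frame(region = rep("A", 4), haplogroup = c("L5", "L5", "L5", "L7"))
  fr <- aggregate_frequencies(tab)
  expect_equal(sort(fr$frequencies$frequency), c(0.25, 0.75))
  expect_equal(sum(fr$frequencies$count), 4)
  expect_error(aggregate_frequencies(tab[0, ]), "empty")
})

test_that("heatmaps normalize per haplogroup and flag the peak region", {
  tab <- data.frame(
    region = c(rep("East", 10), rep("West", 10), rep("South", 5)),
    haplogroup = c(rep("L5", 2), rep("L2", 8),
                   rep("L5", 1), rep("L2", 9),
                   rep("L5", 3), rep("L2", 2)))
  fr <- aggregate_frequencies(tab)
  heat_l5 <- fr$heatmap[fr$heatmap$haplogroup == "L5", ]
  expect_equal(heat_l5$value[heat_l5$region == "South"], 1)
  expect_true(heat_l5$is_peak[heat_l5$region == "South"])
  expect_false(any(heat_l5$is_peak[heat_l5$region != "South"]))
  # regions absent from the data never appear
  expect_false("North" %in% fr$heatmap$region)
  # counts conserved per region
  agg <- tapply(fr$frequencies$count, fr$frequencies$region, sum)
  expect_equal(as.numeric(agg[c("East", "South", "West")]), c(10, 5, 10))
})

test_that("heatmaps are invariant to count rescaling", {
  tab <- data.frame(region = c("A", "A", "B"), haplogroup = c("L5", "L7", "L5"))
  f1 <- aggregate_frequencies(tab)
  f3 <- aggregate_frequencies(tab[rep(seq_len(nrow(tab)), each = 3), ])
  expect_equal(f1$heatmap$value[order(f1$heatmap$region, f1$heatmap$haplogroup)],
               f3$heatmap$value[order(f3$heatmap$region, f3$heatmap$haplogroup)])
})
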