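test_that("support collapsing deletes exactly the weak nodes", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,((c:1,d:1):0.5,e:1.5):0.5):0;")
  tr$node.label <- c("1.0", "0.9", "0.6", "0.95")
  same <- collapse_low_support(tr, 0.5)
  expect_equal(same$Nnode, tr$Nnode)
  expect_equal(ape::Ntip(same), 5L)

  tr$node.label <- c("1.0", "0.9", "0.49", "0.95")
  co <- collapse_low_support(tr, 0.5)
  expect_equal(co$Nnode, 3L)          # one polytomy created
  expect_equal(sort(co$tip.label), sort(tr$tip.label))
  # tip depths preserved
  expect_equal(max(ape::node.depth.edgelength(co)),
               max(ape::node.depth.edgelength(tr)))
  # idempotent
  co2 <- collapse_low_support(co, 0.5)
  expect_equal(ape::write.tree(co2), ape::write.tree(co))
})

test_that("a chain of weak nodes collapses into a single polytomy", {
  tr <- ape::read.tree(
    text = "((((a:1,b:1):1,c:2):1,d:3):1,e:4):0;")
  tr$node.label <- c("1.0", "0.2", "0.3", "0.1")
  co <- collapse_low_support(tr, 0.5)
  expect_equal(co$Nnode, 1L)
  expect_equal(ape::Ntip(co), 5L)
  expect_equal(max(ape::node.depth.edgelength(co)), 4)
})

test_that("identical tips reconstruct to identical ancestors", {
  ref <- mt_reference()
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1):0;")
  prof <- lapply(c(a = "a", b = "b", c = "c", d = "d"), function(id)
    mt_profile(id, c("T3423C", "A6527G")))
  anc <- reconstruct_ancestral(tr, prof, ref, method = "Fitch")
  expect_equal(anc$fitch_changes, 0L)
  syn <- extract_synapomorphies(anc)
  expect_true(all(vapply(syn, nrow, integer(1)) == 0L))
  # under the stationary root prior ML agrees: every ancestor matches the tips
  ancML <- reconstruct_ancestral(tr, prof, ref, method = "ML",
                                 root_prior = "stationary")
  expect_true(all(ancML$node_states[, "3423"] == "C"))
  expect_true(all(ancML$node_states[, "6527"] == "G"))
})

test_that("a single derived pair puts one change on the pair's stem", {
  ref <- mt_reference()
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1):0;")
  prof <- list(a = mt_profile("a", "T3423C"), b = mt_profile("b", "T3423C"),
               c = mt_profile("c"), d = mt_profile("d"))
  for (method in c("Fitch", "ML")) {
    anc <- reconstruct_ancestral(tr, prof, ref, method = method)
    syn <- extract_synapomorphies(anc)
    nz <- names(syn)[vapply(syn, nrow, integer(1)) > 0]
    pair_stem <- paste0("node", fixture_clade_node(tr, c("a", "b")))
    expect_equal(nz, pair_stem, label = method)
    expect_equal(syn[[pair_stem]]$token, "T3423C", label = method)
  }
  ancF <- reconstruct_ancestral(tr, prof, ref, method = "Fitch")
  expect_equal(ancF$fitch_changes, 1L)
})

test_that("Fitch equals the exhaustive minimum-change oracle", {
  ref <- mt_reference()
  positions <- c(1001L, 2002L, 3003L)
  for (seed in 1:5) {
    tr <- random_rooted_tree(6, seed)
    set.seed(seed + 100)
    states <- matrix(sample(c("A", "C", "G", "T"), 18, replace = TRUE,
                            prob = c(0.4, 0.3, 0.2, 0.1)),
                     nrow = 6, dimnames = list(tr$tip.label, positions))
    prof <- lapply(tr$tip.label, function(id) {
      toks <- character(0)
      for (j in seq_along(positions)) {
        b <- states[id, j]
        rb <- ref$bases[positions[j]]
        if (b != rb) {
          alt <- if (haplomt:::is_transition(rb, b)) b else tolower(b)
          toks <- c(toks, paste0(rb, positions[j], alt))
        }
      }
      mt_profile(id, toks)
    })
    names(prof) <- tr$tip.label
    anc <- reconstruct_ancestral(tr, prof, ref, method = "Fitch")
    brute <- sum(vapply(seq_along(positions), function(j)
      brute_force_parsimony(tr, states[, j]), numeric(1)))
    expect_equal(anc$fitch_changes, brute, label = paste("seed", seed))
  }
})

test_that("the planted clade system yields its printed branch variants", {
  b <- fixture_bundle()
  prof <- b$fx$profiles
  anc <- reconstruct_ancestral(b$tree, prof, b$ref, method = "ML")
  syn <- extract_synapomorphies(anc)

  l7_node <- fixture_clade_node(b$tree, l7_family)
  expect_setequal(syn[[paste0("node", l7_node)]]$token,
                  c("A6527G", "T11809C"))
  l57_node <- fixture_clade_node(b$tree, c("L5'7", l7_family, l5_family))
  expect_setequal(syn[[paste0("node", l57_node)]]$token,
                  c("T3423C", "C12432T", "A16166G"))
  l5_node <- fixture_clade_node(b$tree, l5_family)
  expect_setequal(syn[[paste0("node", l5_node)]]$token,
                  c("A7972G", "A12950G", "C16148T", "459.1C"))
  # the singleton branch carries its 27 printed derived variants
  expect_equal(nrow(syn[["L7a*"]]), 27L)
  # outgroup branch clean
  expect_equal(nrow(syn[["outgroup"]]), 0L)
})

test_that("ML and parsimony agree on homoplasy-free data", {
  b <- fixture_bundle()
  ancML <- reconstruct_ancestral(b$tree, b$fx$profiles, b$ref, "ML")
  ancF <- reconstruct_ancestral(b$tree, b$fx$profiles, b$ref, "Fitch")
  sML <- extract_synapomorphies(ancML)
  sF <- extract_synapomorphies(ancF)
  for (nm in names(sML))
    expect_setequal(sML[[nm]]$token, sF[[nm]]$token)
  # total branch changes equal the parsimony minimum on homoplasy-free data
  snp_total <- sum(vapply(sML, function(m)
    sum(m$kind %in% c("transition", "transversion")), numeric(1)))
  expect_equal(snp_total, ancF$fitch_changes)
})

test_that("synapomorphy extraction recovers the simulator's truth", {
  cfg <- sim_config(seed = 31, n_tips = 8, ne = 1500, genome_length = 4000)
  tr <- simulate_coalescent_tree(cfg)
  sim <- simulate_sequences(tr, cfg)
  ref <- mt_reference()
  prof <- lapply(rownames(sim$alignment), function(id)
    call_variants(c(sim$alignment[id, ],
                    ref$bases[(cfg$genome_length + 1L):16569L]), ref, id))
  names(prof) <- rownames(sim$alignment)
  # restrict to sites hit exactly once in the whole genealogy
  hits <- table(unlist(lapply(sim$branch_mutations, function(m) m$position)))
  clean <- as.integer(names(hits)[hits == 1])
  anc <- reconstruct_ancestral(tr, prof, ref, method = "ML")
  syn <- extract_synapomorphies(anc)
  for (nm in names(sim$branch_mutations)) {
    truth <- sim$branch_mutations[[nm]]
    if (is.null(truth)) next  # the root has no subtending branch
    truth <- truth$token[truth$position %in% clean]
    got <- syn[[nm]]
    got <- got$token[got$position %in% clean]
    expect_setequal(got, truth)
  }
})

test_that("clade tables compute stems from parent and clade ages", {
  ages <- l5p7_clade_ages()
  tab <- build_clade_table(ages[, c("clade", "parent", "mean_age",
                                    "hpd_upper", "hpd_lower", "posterior")])
  # worked examples: child under parent
  expect_equal(tab$stem_length[tab$clade == "L7a"], 91476 - 79365)
  expect_equal(tab$stem_length[tab$clade == "L7a1"], 79365 - 16333)
  # a clade at its parent's age has a zero stem
  toy <- data.frame(clade = c("p", "c"), parent = c(NA, "p"),
                    mean_age = c(100, 100))
  ttab <- build_clade_table(toy)
  expect_equal(ttab$stem_length[ttab$clade == "c"], 0)
  # missing parent age stays missing, never zero-filled
  expect_true(is.na(tab$stem_length[tab$clade == "L5'7"]))
  # printed stems agree with recomputed stems within printed rounding
  recomputed <- tab$stem_length[match(ages$clade, tab$clade)]
  off <- abs(recomputed - ages$stem_length)
  expect_true(all(off[!is.na(off)] <= 1))
  # sorted root-ward (oldest first)
  expect_true(all(diff(tab$mean_age) <= 0))
})
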