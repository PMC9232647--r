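test_that("haplotree construction validates its invariants", {
  expect_error(haplotree(data.frame(name = c("r", "a", "a"),
                                    parent = c(NA, "r", "r"),
                                    variants = c(NA, "A1G", "A2G"))),
               "duplicate")
  expect_error(haplotree(data.frame(name = c("r", "a"),
                                    parent = c(NA, "zz"),
                                    variants = c(NA, "A1G"))),
               "unknown parent")
  expect_error(haplotree(data.frame(name = c("r", "a"),
                                    parent = c(NA, "r"),
                                    variants = c(NA, ""))),
               "no defining variants")
  expect_error(haplotree(data.frame(name = c("r", "a"),
                                    parent = c("a", "r"),
                                    variants = c("A1G", "A2G"))),
               "no root|cycle")
})

test_that("cumulative genotypes accumulate along the path", {
  ht <- l5p7_haplotree()
  root_g <- expected_genotype(ht, ht$root)
  expect_equal(nrow(root_g$variants), 0L)
  l7 <- expected_genotype(ht, "L7")
  expect_setequal(l7$variants$token,
                  c("T3423C", "C12432T", "A16166G", "A6527G", "T11809C"))
  expect_error(expected_genotype(ht, "L99"), "unknown haplogroup")
})

test_that("a back-mutation cancels the matching earlier change", {
  toy <- haplotree(data.frame(
    name = c("r", "a", "b"), parent = c(NA, "r", "a"),
    variants = c(NA, "T146C A6527G", "T146C! T3423C")))
  g <- expected_genotype(toy, "b")
  expect_false(146 %in% g$variants$position)
  expect_setequal(g$variants$token, c("A6527G", "T3423C"))
})

test_that("every packaged clade classifies back to itself definitively", {
  ht <- l5p7_haplotree()
  for (clade in setdiff(names(ht$nodes), ht$root)) {
    res <- classify(expected_genotype(ht, clade), ht)
    expect_equal(res$assigned, clade, label = clade)
    expect_true(res$definitive, label = clade)
  }
})

test_that("ancestral-only profiles stop at the parent clade", {
  ht <- l5p7_haplotree()
  # exactly the three deep shared variants, full coverage: a basal sample
  p <- mt_profile("basal", c("T3423C", "C12432T", "A16166G"))
  res <- classify(p, ht)
  expect_equal(res$assigned, "L5'7")
  expect_true(res$definitive)  # every child positively excluded

  # same variants but coding-region-only coverage: children not excludable
  p2 <- mt_profile("coding", c("T3423C", "C12432T"), coverage = "577-16023")
  res2 <- classify(p2, ht)
  expect_equal(res2$assigned, "L5'7")
  expect_false(res2$definitive)
  expect_gt(length(res2$ineligible), 0)
})

test_that("control-region-only coverage leaves two deep SNPs ineligible", {
  ht <- l5p7_haplotree()
  # all callable branch variants positive: descends into the L5 side
  p <- mt_profile("cr", c("A16166G", "C16148T", "459.1C"),
                  coverage = "16024-576")
  res <- classify(p, ht)
  expect_equal(res$assigned, "L5")
  expect_false(res$definitive)   # the coding SNPs were never callable
  # 3423 and 12432 of the deep branch are among the ineligible variants
  expect_length(grep("3423|12432", res$ineligible), 2)

  # missing the callable insertion blocks the descent
  p2 <- mt_profile("cr2", c("A16166G", "C16148T"), coverage = "16024-576")
  res2 <- classify(p2, ht)
  expect_equal(res2$assigned, "L5'7")
  expect_false(res2$definitive)
})

test_that("a profile derived for both sisters stops with a conflict", {
  ht <- l5p7_haplotree()
  both <- c("T3423C", "C12432T", "A16166G",        # deep branch
            "459.1C", "A7972G", "A12950G", "C16148T",  # one sister
            "A6527G", "T11809C")                   # and the other
  res <- classify(mt_profile("conflicted", both), ht)
  expect_equal(res$assigned, "L5'7")
  expect_false(res$definitive)
  expect_gt(length(res$conflicting_sister), 0)
})

root_path_labels <- function(ht, clade) {
  path <- clade
  while (!is.na(ht$nodes[[path[1]]]$parent))
    path <- c(ht$nodes[[path[1]]]$parent, path)
  path
}

test_that("classification never deepens when coverage shrinks", {
  ht <- l5p7_haplotree()
  cr <- "16024-576"
  for (clade in setdiff(names(ht$nodes), ht$root)) {
    g <- expected_genotype(ht, clade)
    full <- classify(g, ht)$assigned
    keep <- g$variants$position >= 16024 | g$variants$span_end <= 576
    trunc <- mt_profile(clade, g$variants[keep, , drop = FALSE],
                        coverage = cr)
    shallow <- classify(trunc, ht)$assigned
    expect_true(shallow %in% root_path_labels(ht, full), label = clade)
  }
})

test_that("heteroplasmy at a defining site blocks a definitive call", {
  ht <- l5p7_haplotree()
  g <- expected_genotype(ht, "L7b2")
  v <- g$variants[g$variants$position != 6527, , drop = FALSE]
  p <- mt_profile("het", v,
                  uncertain = data.frame(position = 6527L, code = "R"))
  res <- classify(p, ht)
  expect_false(res$definitive)
  # never jumps to the wrong sister
  expect_false(any(c("L5", "L5a", "L5b") %in% res$assigned))
})

test_that("monophyly audit finds intruders and trivial cases", {
  tr <- ape::read.tree(
    text = "((b2:1,(x:0.5,(b1a:0.2,b1b:0.2):0.3):0.5):1,out:2);")
  expect_true(check_monophyly(tr, "b2")$is_monophyletic)
  expect_true(check_monophyly(tr, tr$tip.label)$is_monophyletic)
  rep1 <- check_monophyly(tr, c("b1a", "b1b", "b2"), "old grouping")
  expect_false(rep1$is_monophyletic)
  expect_equal(rep1$offending_samples, "x")
  expect_error(check_monophyly(tr, "nope"), "unknown tips")
})

test_that("restructuring relabels without touching branch contents", {
  ht <- l5p7_haplotree()
  idm <- restructure(ht, data.frame(old = character(0), new = character(0)))
  expect_identical(names(idm$nodes), names(ht$nodes))

  map <- data.frame(old = c("L7", "L7a"), new = c("Lx", "Lxa"))
  out <- restructure(ht, map)
  expect_true("Lx" %in% names(out$nodes))
  expect_equal(out$nodes[["Lxa"]]$parent, "Lx")
  expect_identical(out$nodes[["Lx"]]$variants$token,
                   ht$nodes[["L7"]]$variants$token)
  expect_equal(attr(out, "audit")$old, map$old)
  # multiset of (branch, variants) preserved up to relabeling
  olds <- sort(vapply(ht$nodes, function(n) paste(n$variants$token, collapse = " "),
                      character(1)))
  news <- sort(vapply(out$nodes, function(n) paste(n$variants$token, collapse = " "),
                      character(1)))
  expect_identical(unname(olds), unname(news))

  expect_error(restructure(ht, data.frame(old = "L7", new = "L5")),
               "collides")
  expect_error(restructure(ht, data.frame(old = "Lzz", new = "A")),
               "unknown")
  expect_error(restructure(ht, data.frame(old = c("L7", "L7"),
                                          new = c("A", "B"))),
               "injective")
})

test_that("relabeled tip groups regain monophyly after the split", {
  # the historical situation: the subclade sister to everything else was
  # lumped into a group that is therefore not monophyletic
  tr <- ape::read.tree(
    text = "(((a1:1,a2:1):1,(b1:1.2,b2:1.2):0.8):1,(c1:2.4,c2:2.4):0.6);")
  old_b <- c("b1", "b2", "c1", "c2")   # lumped labels
  expect_false(check_monophyly(tr, old_b)$is_monophyletic)
  # reassign the misplaced pair to a new sister group
  map <- data.frame(old = c("c1", "c2"), new = c("n1", "n2"))
  new_b <- setdiff(old_b, map$old)
  expect_true(check_monophyly(tr, new_b)$is_monophyletic)
})

test_that("haplotree files read back identically from JSON and TSV", {
  ht <- l5p7_haplotree()
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(
    name = names(ht$nodes),
    parent = vapply(ht$nodes, function(n) n$parent, character(1)),
    variants = vapply(ht$nodes, function(n)
      paste(n$variants$token, collapse = " "), character(1)))
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_haplotree(tsv)
  expect_setequal(names(back$nodes), names(ht$nodes))
  expect_identical(back$nodes[["L7b2"]]$variants$token,
                   ht$nodes[["L7b2"]]$variants$token)
})
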