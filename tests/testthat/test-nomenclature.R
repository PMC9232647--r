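test_that("representative tokens parse into the right fields", {
  m <- parse_mutation("T3423C")
  expect_equal(m$kind, "transition")
  expect_equal(m$position, 3423L)
  expect_equal(m$ref, "T")
  expect_equal(m$alt, "C")
  expect_equal(m$back, 0L)

  ins <- parse_mutation("459.1C")
  expect_equal(ins$kind, "insertion")
  expect_equal(ins$position, 459L)
  expect_equal(ins$ins_index, 1L)
  expect_equal(ins$alt, "C")

  del <- parse_mutation("8281-8289d")
  expect_equal(del$kind, "deletion")
  expect_equal(del$position, 8281L)
  expect_equal(del$span_end, 8289L)

  back <- parse_mutation("T146C!")
  expect_equal(back$kind, "transition")
  expect_equal(back$back, 1L)

  tv <- parse_mutation("A12021c")
  expect_equal(tv$kind, "transversion")
  expect_equal(tv$alt, "C")
  expect_equal(tv$token, "A12021c")

  unspec <- parse_mutation("(573.XC)")
  expect_true(unspec$ins_unspecified)
  expect_true(unspec$parens)
  expect_equal(unspec$token, "(573.XC)")
})

test_that("malformed tokens raise errors naming the token", {
  expect_error(parse_mutation("Q99Z"), "Q99Z")
  expect_error(parse_mutation("T0C"), "malformed|coordinates")
  expect_error(parse_mutation("A16570G"), "16570")
  expect_error(parse_mutation("A100A"), "identical")
  expect_error(parse_mutation("8289-8281d"), "span")
  expect_error(parse_mutation(""), "malformed")
})

test_that("every token of the packaged clade system round-trips", {
  ht <- l5p7_haplotree()
  for (nm in names(ht$nodes)) {
    toks <- ht$nodes[[nm]]$variants$token
    if (!length(toks)) next
    reparsed <- parse_mutations(toks)
    expect_identical(serialize_mutations(reparsed), toks, label = nm)
  }
  # the longest printed mutation string: the old singleton branch
  expect_equal(nrow(ht$nodes[["L7a*"]]$variants), 27L)
})

test_that("variant calling inverts variant application", {
  ref <- mt_reference()
  # identity
  p0 <- call_variants(ref$bases, ref)
  expect_equal(nrow(p0$variants), 0L)
  expect_equal(nrow(p0$uncertain), 0L)
  # single substitution
  seq <- ref$bases
  seq[3423] <- "C"
  p1 <- call_variants(seq, ref)
  expect_equal(p1$variants$token, "T3423C")
  # IUPAC heteroplasmy becomes an uncertain site, not a variant
  seq2 <- ref$bases
  seq2[16169] <- "Y"
  p2 <- call_variants(seq2, ref)
  expect_equal(nrow(p2$variants), 0L)
  expect_equal(p2$uncertain$position, 16169L)
  expect_equal(p2$uncertain$code, "Y")
  # coordinate mismatch
  expect_error(call_variants(ref$bases[-1], ref), "length")
})

test_that("apply_variants plays paths onto the reference and back", {
  ref <- mt_reference()
  expect_identical(apply_variants(ref, character(0))$bases, ref$bases)
  # a forward change followed by its flagged reversion restores the reference
  sq <- apply_variants(ref, c("T3423C", "T3423C!"))
  expect_identical(sq$bases, ref$bases)
  # the deletion-bearing path loses exactly 9 bases
  ht <- l5p7_haplotree()
  toks <- unlist(lapply(c("L5'7", "L7", "L7b", "L7b2"),
                        function(n) ht$nodes[[n]]$variants$token))
  sq2 <- apply_variants(ref, toks)
  expect_equal(sum(sq2$bases == "-"), 9L)
  expect_equal(sum(sq2$bases != "-"), 16569L - 9L)
  # conflicting set reports the offending token
  expect_error(apply_variants(ref, c("T3423C", "T3423a")),
               "inconsistent.*T3423a")
})

test_that("profiles round-trip through sequence space", {
  ref <- mt_reference()
  ht <- l5p7_haplotree()
  for (clade in c("L7b2", "L5a1", "L7a*")) {
    g <- expected_genotype(ht, clade)
    sq <- apply_variants(ref, g$variants)
    back <- call_variants(sq$bases, ref, insertions = sq$insertions)
    expect_setequal(back$variants$token, g$variants$token)
  }
})

test_that("hotspot masking removes exactly the configured sites", {
  p <- mt_profile("s", c("T152C", "A6527G", "309.1C", "G16519A"))
  m <- apply_mask(p)
  expect_equal(m$variants$token, "A6527G")
  # idempotent
  expect_identical(apply_mask(m)$variants$token, m$variants$token)
  # empty profile passes through
  expect_equal(nrow(apply_mask(mt_profile("e"))$variants), 0L)
  # indel mask does not touch SNPs at 16183 (SNP mask is the four hotspots)
  p2 <- apply_mask(mt_profile("s2", c("A16183c", "16183.1C")))
  expect_equal(p2$variants$token, "A16183c")
})

test_that("masked hotspots never appear in masked planted profiles", {
  ht <- l5p7_haplotree()
  hot <- c(152L, 195L, 310L, 16519L)
  for (nm in setdiff(names(ht$nodes), ht$root)) {
    g <- apply_mask(expected_genotype(ht, nm))
    snp <- g$variants[g$variants$kind %in% c("transition", "transversion"), ]
    expect_length(intersect(snp$position, hot), 0)
  }
})

test_that("profile invariants are enforced", {
  expect_error(mt_profile("x", c("T3423C", "T3423A")), "share position")
  expect_error(mt_profile("x", "T3423C", coverage = "16024-576"),
               "outside covered range")
  p <- mt_profile("x", "C16148T", coverage = "16024-576")
  expect_equal(nrow(p$coverage), 2L)  # wrap-around range splits at origin
})

test_that("HSD and FASTA files round-trip", {
  ht <- l5p7_haplotree()
  profs <- list(expected_genotype(ht, "L7"), expected_genotype(ht, "L5a1"))
  f <- tempfile(fileext = ".hsd")
  write_hsd(profs, f)
  back <- read_hsd(f)
  expect_equal(length(back), 2L)
  expect_setequal(back[[1]]$variants$token, profs[[1]]$variants$token)
  expect_setequal(back[[2]]$variants$token, profs[[2]]$variants$token)

  aln <- matrix(sample(c("A", "C", "G", "T"), 60, replace = TRUE), nrow = 3,
                dimnames = list(c("s1", "s2", "s3"), NULL))
  fa <- tempfile(fileext = ".fasta")
  write_alignment(aln, fa)
  expect_identical(unname(read_alignment(fa)), unname(aln))
})
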