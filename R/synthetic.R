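## Synthetic-data generators: coalescent trees under piecewise-constant Ne,
## sequence evolution under the partitioned strict-clock HKY+Gamma model,
## planted haplogroup fixtures from defining-variant trees, and
## input-degradation artifacts (heteroplasmy, control-region truncation).

#' Simulation configuration
#'
#' Bundles the generative parameters used across the simulators. Defaults
#' reflect the study conditions of the package's worked examples: the
#' calibration mutation rate 2.285e-8 substitutions/site/year, the full
#' 16,569-site genome under the six-bin partition scheme (relative rates
#' elevated in the hypervariable segments and third codon positions,
#' depressed in tRNAs and second positions, site-weighted mean 1), HKY kappa
#' 22 and gamma shape 0.4 (typical mtDNA values), human generation time 25
#' years, and an effective population size of 5,000.
#'
#' @param seed mandatory integer seed.
#' @param n_tips number of samples.
#' @param ne effective population size: a single number or a data frame
#'   `(time, ne)` of piecewise-constant values, `time` in years BP ascending
#'   from 0.
#' @param gen_time generation time in years.
#' @param mu mutation rate, substitutions/site/year.
#' @param genome_length number of reference-coordinate sites simulated.
#' @param kappa,gamma_shape,ncat HKY+Gamma parameters.
#' @param parts `mt_partition`; the default carries no mask (masking is an
#'   analysis step, not a property of the data).
#' @param het_prob per-variant heteroplasmy (IUPAC degradation) probability.
#' @param cr_only_frac fraction of profiles truncated to the control region.
#' @return a list of class `mt_simconfig`.
#' @export
sim_config <- function(seed, n_tips = 20L, ne = 5000, gen_time = 25,
                       mu = 2.285e-8, genome_length = MT_GENOME_LENGTH,
                       kappa = 22, gamma_shape = 0.4, ncat = 4L,
                       parts = NULL, het_prob = 0, cr_only_frac = 0) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.numeric(ne) && length(ne) == 1) ne <- data.frame(time = 0, ne = ne)
  ne <- as.data.frame(ne)
  stopifnot(all(ne$ne > 0), all(diff(ne$time) > 0), ne$time[1] == 0,
            n_tips >= 2, mu >= 0, gen_time > 0, genome_length >= 1)
  if (is.null(parts))
    parts <- partition_sites(
      mt_reference(),
      mask = site_mask(integer(0),
                       data.frame(start = integer(0), end = integer(0))),
      relative_rates = c(codon1 = 0.9, codon2 = 0.4, codon3 = 2.2,
                         HVS = 5, tRNA = 0.5, other = 0.7))
  structure(list(seed = as.integer(seed), n_tips = as.integer(n_tips),
                 ne = ne, gen_time = gen_time, mu = mu,
                 genome_length = as.integer(genome_length),
                 kappa = kappa, gamma_shape = gamma_shape, ncat = ncat,
                 parts = parts, het_prob = het_prob,
                 cr_only_frac = cr_only_frac),
            class = "mt_simconfig")
}

## piecewise-constant exponential waiting time: consume an Exp(1) deviate
## through segments with per-year hazard k(k-1) / (2 ne(t) gen_time)
piecewise_wait <- function(t0, kl, ne, gen_time) {
  E <- rexp(1)
  t <- t0
  repeat {
    seg <- findInterval(t, ne$time)
    lambda <- kl * (kl - 1) / 2 / (ne$ne[seg] * gen_time)
    seg_end <- if (seg < nrow(ne)) ne$time[seg + 1] else Inf
    cap <- lambda * (seg_end - t)
    if (E <= cap || !is.finite(cap)) return(t + E / lambda)
    E <- E - cap
    t <- seg_end
  }
}

#' Simulate a coalescent genealogy under piecewise-constant Ne
#'
#' Standard haploid coalescent: with k active lineages the coalescence
#' hazard is k(k-1)/(2 Ne(t)) per generation, converted to years by the
#' generation time. Returns an ultrametric `phylo` with branch lengths in
#' years and strictly ordered internal node ages (exactly `n_tips - 1` of
#' them).
#'
#' @param cfg an `mt_simconfig` (fields `n_tips`, `ne`, `gen_time`, `seed`).
#' @param seed optional override of `cfg$seed`.
#' @return an ultrametric `phylo`; tip labels `t1..tn`.
#' @export
simulate_coalescent_tree <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "mt_simconfig"))
  set.seed(seed)
  n <- cfg$n_tips
  active <- seq_len(n)
  age <- numeric(2L * n - 1L)
  left <- right <- integer(n - 1L)
  t <- 0
  for (i in seq_len(n - 1L)) {
    k <- length(active)
    t <- piecewise_wait(t, k, cfg$ne, cfg$gen_time)
    pick <- sample(length(active), 2L)
    prov <- n + i
    age[prov] <- t
    left[i] <- active[pick[1]]
    right[i] <- active[pick[2]]
    active <- c(active[-pick], prov)
  }
  # remap provisional internal ids so the root becomes n + 1 (ape numbering)
  remap <- c(seq_len(n), (2L * n - 1L):(n + 1L))
  edge <- matrix(0L, 2L * (n - 1L), 2L)
  elen <- numeric(2L * (n - 1L))
  for (i in seq_len(n - 1L)) {
    p <- remap[n + i]
    for (j in 1:2) {
      child <- if (j == 1) left[i] else right[i]
      r <- 2L * (i - 1L) + j
      edge[r, ] <- c(p, remap[child])
      elen[r] <- age[n + i] - age[child]
    }
  }
  tr <- list(edge = edge, edge.length = elen,
             tip.label = paste0("t", seq_len(n)), Nnode = n - 1L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Evolve sequences down a dated tree
#'
#' Simulates nucleotide evolution under the strict-clock HKY+Gamma model
#' with per-bin partition rates: each site draws a fixed gamma category,
#' its per-year rate is `mu * rel_rate(bin) * cat_rate`, and states evolve
#' branch by branch with exact HKY transition probabilities. Returns both
#' the tip alignment and the true per-branch mutation lists (PhyloTree
#' tokens, back mutations flagged when a branch restores the root state at a
#' previously mutated site), the ground truth for synapomorphy tests.
#'
#' @param tree dated `phylo`, branch lengths in years.
#' @param cfg an `mt_simconfig`.
#' @param seed optional override of `cfg$seed`.
#' @return list with `alignment` (tips x sites character matrix),
#'   `branch_mutations` (named by child: tip label or `node<k>`),
#'   `site_categories`, `tree`, `cfg`.
#' @export
simulate_sequences <- function(tree, cfg, seed = cfg$seed) {
  stopifnot(inherits(tree, "phylo"), inherits(cfg, "mt_simconfig"))
  if (cfg$genome_length < 1) stop("zero-length genome", call. = FALSE)
  set.seed(seed)
  ref <- mt_reference()
  L <- cfg$genome_length
  rootseq <- ref$bases[seq_len(L)]
  map <- cfg$parts$site_map[seq_len(L)]
  map[is.na(map)] <- match("other", cfg$parts$bins)
  rel <- unname(cfg$parts$relative_rates)[map]
  cat_rates <- discrete_gamma_rates(cfg$gamma_shape, cfg$ncat)
  sitecat <- sample.int(cfg$ncat, L, replace = TRUE)
  site_rate <- cfg$mu * rel * cat_rates[sitecat]

  freqs <- empirical_base_freqs(matrix(rootseq, 1))
  model <- hky_model(cfg$kappa, freqs)

  ntip <- ape::Ntip(tree)
  nvert <- ntip + tree$Nnode
  seqs <- matrix(NA_character_, nvert, L)
  seqs[ntip + 1L, ] <- rootseq
  # rate groups: identical per-site rates share a transition matrix
  grp_key <- paste0(map, ":", sitecat)
  grp_ids <- split(seq_len(L), grp_key)

  edge <- ape::reorder.phylo(tree, "cladewise")$edge
  muts <- vector("list", nvert)
  for (e in seq_len(nrow(edge))) {
    u <- edge[e, 1]; v <- edge[e, 2]
    tyr <- tree$edge.length[match(TRUE, tree$edge[, 1] == u & tree$edge[, 2] == v)]
    parent <- seqs[u, ]
    child <- parent
    for (ids in grp_ids) {
      d <- site_rate[ids[1]] * tyr
      if (d == 0) next
      P <- transition_prob(model, d)
      for (s in 1:4) {
        here <- ids[parent[ids] == NUC[s]]
        if (!length(here)) next
        child[here] <- NUC[sample.int(4, length(here), replace = TRUE,
                                      prob = P[s, ])]
      }
    }
    seqs[v, ] <- child
    hit <- which(child != parent)
    if (length(hit)) {
      back <- child[hit] == rootseq[hit] & parent[hit] != rootseq[hit]
      alt <- ifelse(is_transition(parent[hit], child[hit]),
                    child[hit], tolower(child[hit]))
      muts[[v]] <- parse_mutations(paste0(parent[hit], hit, alt,
                                          ifelse(back, "!", "")))
    } else muts[[v]] <- empty_mutations()
  }
  names(muts) <- c(tree$tip.label, paste0("node", ntip + seq_len(tree$Nnode)))
  aln <- seqs[seq_len(ntip), , drop = FALSE]
  rownames(aln) <- tree$tip.label
  list(alignment = aln, branch_mutations = muts,
       site_categories = sitecat, tree = tree, cfg = cfg)
}

#' Plant a haplogroup fixture
#'
#' Builds, for every named clade of a haplogroup tree, one tip profile
#' carrying the clade's cumulative genotype (plus an outgroup tip carrying
#' the root genotype), together with the expected classification of each
#' tip and the corresponding aligned sequences — a complete, download-free
#' test fixture for the classification and annotation stages.
#'
#' @param htree an `mt_haplotree`.
#' @param ref an `mt_reference`.
#' @return list with `profiles` (named list of `mt_profile`), `expected`
#'   (data frame `sample_id`, `clade`), `sequences` (character matrix, `-`
#'   for deletions), `insertions` (per-sample companion list).
#' @export
plant_haplogroup_fixture <- function(htree, ref = mt_reference()) {
  stopifnot(inherits(htree, "mt_haplotree"))
  clades <- setdiff(names(htree$nodes), htree$root)
  if (!length(clades))
    stop("haplogroup tree has no named clades to plant", call. = FALSE)
  ids <- c("outgroup", clades)
  profiles <- vector("list", length(ids))
  names(profiles) <- ids
  seqs <- matrix(NA_character_, length(ids), MT_GENOME_LENGTH,
                 dimnames = list(ids, NULL))
  ins <- vector("list", length(ids))
  names(ins) <- ids
  for (i in seq_along(ids)) {
    clade <- if (ids[i] == "outgroup") htree$root else ids[i]
    sq <- apply_variants(ref, parse_mutations(path_tokens(htree, clade)))
    p <- call_variants(sq$bases, ref, sample_id = ids[i],
                       insertions = sq$insertions)
    profiles[[i]] <- p
    seqs[i, ] <- sq$bases
    ins[[i]] <- sq$insertions
  }
  list(profiles = profiles,
       expected = data.frame(
         sample_id = ids,
         clade = c(htree$root, clades),
         stringsAsFactors = FALSE),
       sequences = seqs, insertions = ins)
}

AMBIGUITY_OF <- c(AG = "R", CT = "Y", AC = "M", GT = "K", AT = "W", CG = "S")

pair_code <- function(a, b) {
  key <- paste(sort(c(a, b)), collapse = "")
  unname(AMBIGUITY_OF[key])
}

#' Degrade profiles with realistic artifacts
#'
#' Injects heteroplasmy (each SNP variant becomes, with probability
#' `het_prob`, an IUPAC uncertain site covering its reference and derived
#' bases) and truncates a fraction `cr_only_frac` of profiles to
#' control-region-only coverage (16024-16569 and 1-576), dropping variants
#' and uncertain sites outside. Deterministic given the seed.
#'
#' @param profiles list of `mt_profile`.
#' @param het_prob per-SNP heteroplasmy probability.
#' @param cr_only_frac fraction of profiles truncated to the control region.
#' @param seed integer seed.
#' @return the degraded list of `mt_profile`.
#' @export
degrade_profiles <- function(profiles, het_prob = 0, cr_only_frac = 0, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(seed)
  truncate <- runif(length(profiles)) < cr_only_frac
  out <- profiles
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    v <- p$variants
    if (het_prob > 0 && nrow(v)) {
      is_snp <- v$kind %in% c("transition", "transversion")
      flip <- is_snp & runif(nrow(v)) < het_prob
      if (any(flip)) {
        unc <- data.frame(position = v$position[flip],
                          code = mapply(pair_code, v$ref[flip], v$alt[flip]),
                          stringsAsFactors = FALSE)
        p$uncertain <- rbind(p$uncertain, unc)
        v <- v[!flip, , drop = FALSE]
        class(v) <- c("mt_mutations", "data.frame")
        p$variants <- v
      }
    }
    if (truncate[i]) {
      cr <- data.frame(start = c(1L, 16024L), end = c(576L, MT_GENOME_LENGTH))
      keep <- vapply(seq_len(nrow(p$variants)), function(j)
        any(p$variants$position[j] >= cr$start &
            p$variants$span_end[j] <= cr$end), logical(1))
      p$variants <- p$variants[keep, , drop = FALSE]
      class(p$variants) <- c("mt_mutations", "data.frame")
      keepu <- vapply(p$uncertain$position, function(x)
        any(x >= cr$start & x <= cr$end), logical(1))
      p$uncertain <- p$uncertain[keepu, , drop = FALSE]
      p$coverage <- cr
    }
    out[[i]] <- validate_profile(p)
  }
  out
}
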