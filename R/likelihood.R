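## Partitioned HKY+Gamma tree likelihood on compressed site patterns.
## The pruning recursion itself lives in src/peel.cpp.

#' Compress alignment columns into site patterns
#'
#' @param aln character matrix, rows = samples, columns = sites (bases,
#'   IUPAC codes, `-`, `N`).
#' @return list with `patterns` (matrix, one column per distinct pattern),
#'   `weights` (pattern multiplicities) and `index` (pattern of each original
#'   column).
#' @export
compress_patterns <- function(aln) {
  if (is.null(dim(aln)) || ncol(aln) == 0) stop("zero-length alignment", call. = FALSE)
  key <- apply(aln, 2, paste, collapse = "")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  list(patterns = aln[, first, drop = FALSE],
       weights = as.numeric(tabulate(idx, nbins = sum(first))),
       index = idx)
}

tip_partial_matrix <- function(states) {
  # 4 x npat partial-observation matrix for one tip
  vapply(states, function(b) {
    allowed <- if (b %in% c("-", "?", "N")) NUC else IUPAC_PARTIAL[[b]]
    if (is.null(allowed))
      stop("unknown base code '", b, "' in alignment", call. = FALSE)
    as.numeric(NUC %in% allowed)
  }, numeric(4))
}

## Precompute everything that does not change between likelihood calls:
## postorder edges, per-partition compressed patterns and tip partials.
likelihood_context <- function(aln, tree, parts = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(dim(aln)) || ncol(aln) == 0)
    stop("zero-length alignment", call. = FALSE)
  if (is.null(rownames(aln)) || !setequal(rownames(aln), tree$tip.label))
    stop("alignment rows must match tree tips", call. = FALSE)
  aln <- toupper(aln[tree$tip.label, , drop = FALSE])
  po <- ape::reorder.phylo(tree, "postorder")
  edge_order <- match(paste(po$edge[, 1], po$edge[, 2]),
                      paste(tree$edge[, 1], tree$edge[, 2]))
  groups <- if (is.null(parts)) {
    list(all = seq_len(ncol(aln)))
  } else {
    map <- parts$site_map[seq_len(ncol(aln))]
    lapply(stats::setNames(seq_along(parts$bins), parts$bins),
           function(b) which(!is.na(map) & map == b))
  }
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  blocks <- lapply(groups, function(cols) {
    cp <- compress_patterns(aln[, cols, drop = FALSE])
    tp <- lapply(seq_len(nrow(cp$patterns)), function(i)
      tip_partial_matrix(cp$patterns[i, ]))
    list(tips = tp, weights = cp$weights, npat = length(cp$weights))
  })
  list(tree = tree, postorder = po$edge, edge_order = edge_order,
       ntip = ape::Ntip(tree), nnode = tree$Nnode,
       blocks = blocks,
       rel_rates = if (is.null(parts)) stats::setNames(1, "all")
                   else parts$relative_rates[names(blocks)],
       base_freqs = empirical_base_freqs(aln))
}

empirical_base_freqs <- function(aln) {
  tab <- table(factor(aln[aln %in% NUC], levels = NUC))
  f <- as.numeric(tab)
  if (sum(f) == 0) f <- rep(1, 4)
  f <- f + 1  # pseudocount keeps all frequencies positive
  f / sum(f)
}

context_loglik <- function(ctx, model, edge_len, rel_rates = NULL) {
  # edge_len: branch lengths in expected substitutions, tree$edge order
  if (is.null(rel_rates)) rel_rates <- ctx$rel_rates
  bl <- edge_len[ctx$edge_order]
  total <- 0
  for (b in names(ctx$blocks)) {
    blk <- ctx$blocks[[b]]
    total <- total + peel_loglik_cpp(
      ctx$postorder, ctx$ntip, ctx$nnode, bl * rel_rates[[b]],
      blk$tips, blk$weights, model$U, model$Uinv, model$eigenvalues,
      model$base_freqs, model$cat_rates)
  }
  total
}

#' Partitioned HKY+Gamma log-likelihood of a tree
#'
#' Computes the log-likelihood of an alignment on a rooted tree under the
#' HKY substitution model with optional discrete-gamma rate heterogeneity
#' and an optional six-bin partition scheme (per-bin relative rates,
#' site-weighted mean 1). Branch lengths are taken from `tree$edge.length`
#' and multiplied by `rate`, so trees in years combine with a clock rate in
#' substitutions/site/year. Heteroplasmic IUPAC codes enter as partial
#' observations over their compatible states. The result is invariant to tip
#' order and traversal order.
#'
#' @param aln character matrix (rows = samples matching `tree$tip.label`).
#' @param tree rooted `phylo` with branch lengths.
#' @param kappa HKY transition/transversion ratio.
#' @param gamma_shape discrete-gamma shape, or `NULL` for a single rate.
#' @param ncat gamma categories (default 4).
#' @param base_freqs equilibrium frequencies; defaults to the empirical
#'   frequencies of the alignment.
#' @param parts optional `mt_partition` (alignment columns must then be
#'   reference positions 1..16,569).
#' @param rate clock rate multiplier applied to branch lengths (default 1:
#'   branch lengths already in expected substitutions).
#' @return the log-likelihood (scalar).
#' @export
tree_log_likelihood <- function(aln, tree, kappa = 2, gamma_shape = NULL,
                                ncat = 4L, base_freqs = NULL, parts = NULL,
                                rate = 1) {
  ctx <- likelihood_context(aln, tree, parts)
  if (is.null(base_freqs)) base_freqs <- ctx$base_freqs
  model <- hky_model(kappa, base_freqs, gamma_shape, ncat)
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  context_loglik(ctx, model, tree$edge.length * rate)
}
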