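## Posterior summarisation: maximum clade credibility tree with mean node
## ages and 95% HPD intervals, HPD computation, effective sample size.

clade_keys <- function(tree) {
  # one key per internal node: sorted tip labels of its clade
  ntip <- ape::Ntip(tree)
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po)))
    desc[[po[i, 1]]] <- c(desc[[po[i, 1]]], desc[[po[i, 2]]])
  vapply((ntip + 1L):(ntip + tree$Nnode),
         function(nd) paste(sort(desc[[nd]]), collapse = "|"), character(1))
}

#' Highest posterior density interval
#'
#' Shortest interval containing a `prob` fraction of the sample (empirical
#' HPD over sorted draws).
#'
#' @param x numeric sample.
#' @param prob mass to cover (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n == 0) return(c(NA_real_, NA_real_))
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m)
  width <- x[starts + m] - x[starts]
  i <- which.min(width)
  c(x[i], x[i + m])
}

#' Effective sample size of an MCMC trace
#'
#' `n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated at the
#' first non-positive pair (Geyer's initial positive sequence). A constant
#' trace reports `n` with a warning; anticorrelated traces may exceed `n`.
#'
#' @param x numeric trace (length >= 10).
#' @return the ESS (scalar).
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10) stop("trace too short for ESS (need >= 10)", call. = FALSE)
  if (var(x) == 0) {
    warning("constant trace; reporting ESS = n", call. = FALSE)
    return(n)
  }
  rho <- acf(x, lag.max = min(n - 1L, 2000L), plot = FALSE,
             demean = TRUE)$acf[-1]
  if (rho[1] < -0.1) {
    # strongly anticorrelated (e.g. alternating) trace: the pair-truncated
    # sum degenerates; report the super-efficient ESS and flag it
    warning("anticorrelated trace; ESS exceeds the sample size", call. = FALSE)
    return(n / (1 + 2 * max(rho[1], -0.5 + 1e-6)))
  }
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2L
  }
  n / (1 + 2 * s)
}

#' Maximum clade credibility tree and posterior summary
#'
#' Scores every sampled topology by the product of its clades' posterior
#' frequencies and returns the best, annotated with per-clade posterior
#' support, mean node ages and 95% HPD age intervals computed over the
#' samples containing each clade.
#'
#' @param run an `mt_mcmc`, or a list of dated `phylo` trees.
#' @param burnin fraction of initial samples to discard (default 0.1).
#' @param prob HPD mass (default 0.95).
#' @return list with `tree` (the MCC `phylo`, node labels = posterior
#'   support), `summary` (data frame: clade key, posterior, mean age, HPD
#'   bounds), and `n_samples`.
#' @export
summarize_mcc <- function(run, burnin = 0.1, prob = 0.95) {
  trees <- if (inherits(run, "mt_mcmc")) run$trees else run
  if (!length(trees)) stop("no posterior samples to summarize", call. = FALSE)
  drop <- floor(length(trees) * burnin)
  trees <- trees[(drop + 1L):length(trees)]
  n <- length(trees)
  keys <- lapply(trees, clade_keys)
  hts <- lapply(trees, function(t) {
    h <- node_heights(t)
    h[(ape::Ntip(t) + 1L):length(h)]
  })
  freq <- table(unlist(keys)) / n
  score <- vapply(keys, function(k) sum(log(as.numeric(freq[k]))), numeric(1))
  best <- which.max(score)
  mcc <- trees[[best]]
  bk <- keys[[best]]

  age_samples <- lapply(bk, function(key) {
    unlist(mapply(function(k, h) h[k == key], keys, hts, SIMPLIFY = FALSE))
  })
  mean_age <- vapply(age_samples, mean, numeric(1))
  hpd <- t(vapply(age_samples, hpd_interval, numeric(2), prob = prob))
  post <- as.numeric(freq[bk])
  mcc$node.label <- formatC(post, format = "g", digits = 6)

  # set the MCC branch times to the summarized mean ages
  ntip <- ape::Ntip(mcc)
  h <- numeric(ntip + mcc$Nnode)
  h[(ntip + 1L):length(h)] <- mean_age
  mcc$edge.length <- h[mcc$edge[, 1]] - h[mcc$edge[, 2]]

  list(tree = mcc,
       summary = data.frame(clade = bk, posterior = post,
                            mean_age = mean_age,
                            hpd_lower = hpd[, 1], hpd_upper = hpd[, 2],
                            stringsAsFactors = FALSE),
       n_samples = n)
}

#' Write posterior summaries to disk
#'
#' `write_mcc` writes the annotated summary tree as NEXUS plus plain newick;
#' `write_trace` writes a tab-delimited posterior trace (first column the
#' state index) readable by common trace viewers.
#'
#' @param mcc result of [summarize_mcc()].
#' @param prefix output path prefix (writes `<prefix>.nex`, `<prefix>.nwk`,
#'   `<prefix>_clades.tsv`).
#' @return the paths written, invisibly.
#' @export
write_mcc <- function(mcc, prefix) {
  nex <- paste0(prefix, ".nex")
  nwk <- paste0(prefix, ".nwk")
  tsv <- paste0(prefix, "_clades.tsv")
  ape::write.nexus(mcc$tree, file = nex)
  ape::write.tree(mcc$tree, file = nwk)
  write.table(mcc$summary, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nex, nwk, tsv))
}

#' @rdname write_mcc
#' @param run an `mt_mcmc`.
#' @param path trace file path.
#' @export
write_trace <- function(run, path) {
  stopifnot(inherits(run, "mt_mcmc"))
  write.table(run$log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
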