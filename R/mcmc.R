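## Strict-clock Bayesian dating MCMC: partitioned HKY+Gamma likelihood,
## lognormal clock prior averaged from a rate survey, Bayesian-skyline
## (piecewise-constant) or constant-size coalescent tree prior, scale and
## node-age kernels, optional NNI topology moves.

node_heights <- function(tree) {
  depth <- ape::node.depth.edgelength(tree)
  h <- max(depth) - depth
  h[seq_len(ape::Ntip(tree))] <- 0
  h
}

## log coalescent density of contemporaneous-tip node heights under a
## piecewise-constant Ne (skyline with grouped intervals)
coalescent_logprior <- function(heights, ntip, ne, group_of) {
  ev <- sort(heights[-seq_len(ntip)])
  n <- ntip
  t0 <- 0
  lp <- 0
  for (i in seq_along(ev)) {
    k <- n - i + 1
    dt <- ev[i] - t0
    nei <- ne[group_of[i]]
    lp <- lp - log(nei) - k * (k - 1) / 2 * dt / nei
    t0 <- ev[i]
  }
  lp
}

## contiguous grouping of the n-1 coalescent events into g blocks
event_groups <- function(nevents, g) {
  g <- max(1L, min(g, nevents))
  sort(rep(seq_len(g), length.out = nevents))
}

#' Strict-clock Bayesian dating by MCMC
#'
#' Samples node ages (and optionally topology), the clock rate, HKY kappa,
#' gamma shape, per-partition relative rates and skyline population sizes
#' from their joint posterior. The tree prior is a piecewise-constant
#' coalescent (classic Bayesian skyline with the coalescent events split
#' into contiguous groups) or a constant-size coalescent. The clock rate is
#' either sampled under the lognormal survey prior or fixed to its mean.
#' Kernels are multiplier (scale) moves on the scalar parameters, uniform
#' node-age slides respecting parent/child order, a whole-tree scale move,
#' and optional age-respecting NNI exchanges. All randomness flows from
#' `seed`; the returned object records settings, seed and per-kernel
#' acceptance rates.
#'
#' @param aln character alignment matrix (rows = tree tips), or `NULL` to
#'   sample from the prior alone.
#' @param tree rooted ultrametric starting tree, branch lengths in years.
#' @param steps number of MCMC steps (> 0).
#' @param seed integer random seed (mandatory).
#' @param parts optional `mt_partition` for the six-bin scheme; alignment
#'   columns are then reference coordinates.
#' @param clock_prior an `mt_clock_prior` (default: the packaged survey
#'   averaging 2.285e-8 substitutions/site/year).
#' @param thin sampling interval (default: `steps/1000` capped below at 1).
#' @param topology `"fixed"` (dating only) or `"nni"`.
#' @param tree_prior `"skyline"` or `"constant"`.
#' @param skyline_groups number of skyline segments (default 5).
#' @param clock_mode `"sample"` (under the lognormal prior) or `"fixed"` (at
#'   the prior mean).
#' @param estimate_rel_rates estimate per-bin relative rates under the
#'   mean-one constraint (default: yes whenever `parts` is given).
#' @param kappa,gamma_shape initial values.
#' @param ncat discrete-gamma categories.
#' @return an object of class `mt_mcmc`: list with `log` (one row per
#'   retained sample: state index first, then posterior/likelihood/prior and
#'   parameters), `ages` (matrix of internal node heights), `trees` (list of
#'   dated `phylo`), `acceptance`, `settings`.
#' @export
mcmc_sample <- function(aln, tree, steps, seed, parts = NULL,
                        clock_prior = average_rate_prior(),
                        thin = NULL,
                        topology = c("fixed", "nni"),
                        tree_prior = c("skyline", "constant"),
                        skyline_groups = 5L,
                        clock_mode = c("sample", "fixed"),
                        estimate_rel_rates = !is.null(parts),
                        kappa = 10, gamma_shape = 0.5, ncat = 4L) {
  topology <- match.arg(topology)
  tree_prior <- match.arg(tree_prior)
  clock_mode <- match.arg(clock_mode)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory", call. = FALSE)
  if (is.null(steps) || steps < 1) stop("settings must be positive: steps", call. = FALSE)
  if (is.null(thin)) thin <- max(1L, floor(steps / 1000))
  set.seed(seed)

  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  stopifnot(ntip >= 2)
  edge <- tree$edge
  h <- node_heights(tree)

  ctx <- if (!is.null(aln)) likelihood_context(aln, tree, parts) else NULL
  freqs <- if (!is.null(ctx)) ctx$base_freqs else rep(0.25, 4)

  ngroups <- if (tree_prior == "skyline") max(1L, skyline_groups) else 1L
  grp <- event_groups(nnode, ngroups)
  ne <- rep(max(h) / 2, ngroups)   # heuristic start near the tree scale
  ne_bounds <- c(1e-3, 1e12)

  rate <- clock_prior$mean_rate
  rel <- if (!is.null(parts)) parts$relative_rates else NULL
  bin_w <- if (!is.null(parts)) parts$bin_sizes / sum(parts$bin_sizes) else NULL

  parent_of <- integer(ntip + nnode)
  parent_of[edge[, 2]] <- edge[, 1]
  children_of <- function(E) split(E[, 2], E[, 1])
  kids <- children_of(edge)

  postorder_of <- function(E) {
    tr <- list(edge = E, tip.label = tree$tip.label, Nnode = nnode)
    class(tr) <- "phylo"
    po <- ape::reorder.phylo(tr, "postorder")$edge
    po
  }
  if (!is.null(ctx)) {
    ctx$postorder <- postorder_of(edge)
    ctx$edge_order <- match(paste(ctx$postorder[, 1], ctx$postorder[, 2]),
                            paste(edge[, 1], edge[, 2]))
  }

  model <- hky_model(kappa, freqs, gamma_shape, ncat)
  loglik_of <- function(E, h, model, rate, rel) {
    if (is.null(ctx)) return(0)
    el <- (h[E[, 1]] - h[E[, 2]]) * rate
    context_loglik(ctx, model, el,
                   rel_rates = if (is.null(rel)) NULL else rel[names(ctx$blocks)])
  }
  logprior_of <- function(h, ne, rate, kappa, alpha) {
    lp <- coalescent_logprior(h, ntip, ne, grp)
    lp <- lp - sum(log(ne))                            # log-uniform Ne
    if (any(ne < ne_bounds[1] | ne > ne_bounds[2])) return(-Inf)
    if (clock_mode == "sample")
      lp <- lp + stats::dlnorm(rate, clock_prior$meanlog, clock_prior$sdlog,
                               log = TRUE)
    lp <- lp + stats::dlnorm(kappa, meanlog = 1, sdlog = 1.25, log = TRUE)
    lp <- lp + stats::dexp(alpha, 1, log = TRUE)
    lp
  }

  alpha <- gamma_shape
  ll <- loglik_of(edge, h, model, rate, rel)
  lp <- logprior_of(h, ne, rate, kappa, alpha)

  kernels <- c("slide", "root", "scale_tree", "kappa", "alpha", "ne",
               if (clock_mode == "sample") "clock",
               if (estimate_rel_rates) "relrates",
               if (topology == "nni") "nni")
  kw <- c(slide = max(1, nnode - 1), root = 1, scale_tree = 1, kappa = 0.6,
          alpha = 0.6, ne = ngroups * 0.5, clock = 1, relrates = 1, nni = nnode / 2)
  kw <- kw[kernels]
  tries <- accepts <- stats::setNames(numeric(length(kernels)), kernels)

  nsamp <- floor(steps / thin)
  log_rows <- vector("list", nsamp)
  ages <- matrix(NA_real_, nsamp, nnode)
  trees <- vector("list", nsamp)
  si <- 0L

  internal <- ntip + seq_len(nnode)
  non_root <- setdiff(internal, ntip + 1L)

  build_phylo <- function(E, h) {
    tr <- list(edge = E, edge.length = h[E[, 1]] - h[E[, 2]],
               tip.label = tree$tip.label, Nnode = nnode)
    class(tr) <- "phylo"
    tr
  }

  for (it in seq_len(steps)) {
    mv <- sample(kernels, 1, prob = kw)
    tries[mv] <- tries[mv] + 1
    h2 <- h; ne2 <- ne; rate2 <- rate; kappa2 <- kappa; alpha2 <- alpha
    rel2 <- rel; edge2 <- edge
    lhast <- 0
    model2 <- model
    ok <- TRUE

    if (mv == "slide") {
      v <- if (length(non_root) == 1L) non_root else sample(non_root, 1)
      lo <- max(h[kids[[as.character(v)]]])
      hi <- h[parent_of[v]]
      h2[v] <- runif(1, lo, hi)
    } else if (mv == "root") {
      r <- ntip + 1L
      m <- exp(0.7 * (runif(1) - 0.5))
      lo <- max(h[kids[[as.character(r)]]])
      h2[r] <- h[r] * m
      lhast <- log(m)
      ok <- h2[r] > lo
    } else if (mv == "scale_tree") {
      m <- exp(0.4 * (runif(1) - 0.5))
      h2[internal] <- h[internal] * m
      lhast <- nnode * log(m)
    } else if (mv == "kappa") {
      m <- exp(0.5 * (runif(1) - 0.5))
      kappa2 <- kappa * m; lhast <- log(m)
      model2 <- hky_model(kappa2, freqs, alpha, ncat)
    } else if (mv == "alpha") {
      m <- exp(0.5 * (runif(1) - 0.5))
      alpha2 <- alpha * m; lhast <- log(m)
      model2 <- hky_model(kappa, freqs, alpha2, ncat)
    } else if (mv == "clock") {
      m <- exp(0.3 * (runif(1) - 0.5))
      rate2 <- rate * m; lhast <- log(m)
    } else if (mv == "ne") {
      g <- sample.int(ngroups, 1)
      m <- exp(1.2 * (runif(1) - 0.5))
      ne2[g] <- ne[g] * m; lhast <- log(m)
    } else if (mv == "relrates") {
      ij <- sample(names(rel)[bin_w > 0], 2)
      d <- runif(1, 0, 0.08)
      rel2[ij[1]] <- rel[ij[1]] + d / bin_w[ij[1]]
      rel2[ij[2]] <- rel[ij[2]] - d / bin_w[ij[2]]
      ok <- all(rel2 > 0)
    } else if (mv == "nni") {
      cand <- non_root[vapply(as.character(non_root),
                              function(v) !is.null(kids[[v]]), logical(1))]
      if (!length(cand)) ok <- FALSE
      else {
        v <- if (length(cand) == 1L) cand else sample(cand, 1)
        u <- parent_of[v]
        vkids <- kids[[as.character(v)]]
        sibs <- setdiff(kids[[as.character(u)]], v)
        cnode <- if (length(vkids) == 1L) vkids else sample(vkids, 1)
        snode <- if (length(sibs) == 1L) sibs else sample(sibs, 1)
        if (h[v] <= h[snode]) ok <- FALSE
        else {
          edge2[edge2[, 1] == v & edge2[, 2] == cnode, ] <- c(u, cnode)
          edge2[edge2[, 1] == u & edge2[, 2] == snode, ] <- c(v, snode)
        }
      }
    }

    if (ok && any(h2[edge2[, 1]] <= h2[edge2[, 2]])) ok <- FALSE
    if (ok) {
      if (mv == "nni" && !is.null(ctx)) {
        ctx$postorder <- postorder_of(edge2)
        ctx$edge_order <- match(paste(ctx$postorder[, 1], ctx$postorder[, 2]),
                                paste(edge2[, 1], edge2[, 2]))
      }
      ll2 <- tryCatch(loglik_of(edge2, h2, model2, rate2, rel2),
                      error = function(e) -Inf)
      lp2 <- logprior_of(h2, ne2, rate2, kappa2, alpha2)
      if (is.finite(ll2 + lp2) &&
          log(runif(1)) < (ll2 + lp2) - (ll + lp) + lhast) {
        h <- h2; ne <- ne2; rate <- rate2; kappa <- kappa2; alpha <- alpha2
        rel <- rel2; model <- model2; ll <- ll2; lp <- lp2
        accepts[mv] <- accepts[mv] + 1
        if (mv == "nni") {
          edge <- edge2
          parent_of[edge[, 2]] <- edge[, 1]
          kids <- children_of(edge)
        }
      } else if (mv == "nni" && !is.null(ctx)) {
        ctx$postorder <- postorder_of(edge)
        ctx$edge_order <- match(paste(ctx$postorder[, 1], ctx$postorder[, 2]),
                                paste(edge[, 1], edge[, 2]))
      }
    }

    if (it %% thin == 0L) {
      si <- si + 1L
      row <- data.frame(state = it, posterior = ll + lp, loglik = ll,
                        logprior = lp, clock_rate = rate, kappa = kappa,
                        gamma_shape = alpha, root_age = h[ntip + 1L])
      for (g in seq_len(ngroups)) row[[paste0("ne", g)]] <- ne[g]
      if (!is.null(rel))
        for (b in names(rel)) row[[paste0("rate_", b)]] <- rel[[b]]
      log_rows[[si]] <- row
      ages[si, ] <- h[internal]
      trees[[si]] <- build_phylo(edge, h)
    }
  }
  acc <- ifelse(tries > 0, accepts / tries, NA)
  if (all(accepts == 0))
    warning("all proposals rejected; check starting state and scales",
            immediate. = TRUE)
  structure(list(
    log = do.call(rbind, log_rows[seq_len(si)]),
    ages = ages[seq_len(si), , drop = FALSE],
    trees = trees[seq_len(si)],
    acceptance = data.frame(kernel = names(acc), tries = as.numeric(tries),
                            rate = as.numeric(acc)),
    settings = list(steps = steps, thin = thin, seed = seed,
                    topology = topology, tree_prior = tree_prior,
                    skyline_groups = ngroups, clock_mode = clock_mode,
                    ncat = ncat),
    tip_label = tree$tip.label
  ), class = "mt_mcmc")
}

#' @export
print.mt_mcmc <- function(x, ...) {
  cat("<mt_mcmc> ", nrow(x$log), " samples (steps ", x$settings$steps,
      ", thin ", x$settings$thin, ", seed ", x$settings$seed, ")\n", sep = "")
  cat("  mean root age ", format(mean(x$log$root_age), digits = 6),
      "; kernel acceptance ",
      paste(sprintf("%s %.2f", x$acceptance$kernel, x$acceptance$rate),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Two-chain agreement check
#'
#' Compares per-parameter posterior means of two independent chains using
#' their combined Monte-Carlo standard errors (autocorrelation-adjusted via
#' [effective_sample_size()]); agreement means every compared parameter's
#' z-score is below the cutoff.
#'
#' @param a,b `mt_mcmc` objects from independent seeds.
#' @param params columns of the trace to compare (default: root age and
#'   clock rate).
#' @param z cutoff on the |z| score (default 3).
#' @param burnin fraction of initial samples to drop.
#' @return list with `agree` (logical) and `table`.
#' @export
chains_agree <- function(a, b, params = c("root_age", "clock_rate"),
                         z = 3, burnin = 0.1) {
  take <- function(x, p) {
    v <- x$log[[p]]
    v[-seq_len(floor(length(v) * burnin))]
  }
  rows <- lapply(params, function(p) {
    va <- take(a, p); vb <- take(b, p)
    se <- sqrt(var(va) / effective_sample_size(va) +
               var(vb) / effective_sample_size(vb))
    zz <- if (se == 0) 0 else abs(mean(va) - mean(vb)) / se
    data.frame(param = p, mean_a = mean(va), mean_b = mean(vb), z = zz)
  })
  tab <- do.call(rbind, rows)
  list(agree = all(tab$z < z), table = tab)
}
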