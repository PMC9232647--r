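## Classic (generalized) skyline estimate of effective population size
## through time from dated ultrametric genealogies, aggregated over a set of
## posterior (or simulated) trees with credibility bounds.

coalescent_intervals <- function(tree) {
  ntip <- ape::Ntip(tree)
  h <- node_heights(tree)
  ev <- sort(h[(ntip + 1L):length(h)])
  bounds <- c(0, ev)
  data.frame(start = bounds[-length(bounds)], end = ev,
             k = ntip:(ntip - length(ev) + 1L))
}

## grouped classic skyline for one tree: per group of consecutive
## coalescent intervals, the constant-rate MLE
## N_hat = sum_j C(k_j,2) * w_j / (#events in group)
skyline_one <- function(tree, groups) {
  ci <- coalescent_intervals(tree)
  m <- nrow(ci)
  g <- event_groups(m, groups)
  pergroup <- vapply(seq_len(max(g)), function(gg) {
    rows <- ci[g == gg, , drop = FALSE]
    sum(rows$k * (rows$k - 1) / 2 * (rows$end - rows$start)) / nrow(rows)
  }, numeric(1))
  ends <- vapply(seq_len(max(g)), function(gg) max(ci$end[g == gg]), numeric(1))
  data.frame(start = c(0, ends[-length(ends)]), end = ends, ne = pergroup)
}

ne_at <- function(sky, times) {
  idx <- findInterval(times, c(0, sky$end), rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx > nrow(sky)] <- nrow(sky)
  sky$ne[idx]
}

#' Skyline estimate of effective population size through time
#'
#' Computes, for each dated tree, the classic skyline: the per-interval
#' coalescent estimator N̂e = k(k-1)·w/2 with consecutive intervals pooled
#' into `groups` segments (the constant-rate maximum-likelihood estimate
#' within each segment), then aggregates the piecewise trajectories over all
#' trees on a common time grid with mean and central 95% bounds. Ne is
#' reported in the same units as the tree's branch lengths (years times
#' generation time); divide by `gen_time` for individuals.
#'
#' @param trees list of ultrametric `phylo` (e.g. `mt_mcmc$trees` after
#'   burn-in), or a single tree.
#' @param groups number of skyline segments per tree (default: events/5,
#'   at least 1).
#' @param gen_time generation time in years used to convert to individuals
#'   (default 1: leave Ne in branch-length units).
#' @param grid_size number of grid points in the reported trajectory.
#' @return an object of class `mt_skyline`: data frame with `time`
#'   (years BP, increasing), `ne_mean`, `ne_lower`, `ne_upper`, plus
#'   attribute `per_tree` (list of stepwise trajectories).
#' @export
skyline_estimate <- function(trees, groups = NULL, gen_time = 1,
                             grid_size = 50L) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "mt_mcmc")) trees <- trees$trees
  if (!length(trees)) stop("no trees supplied", call. = FALSE)
  ntip <- ape::Ntip(trees[[1]])
  if (ntip < 3) stop("skyline needs at least 3 tips", call. = FALSE)
  if (is.null(groups)) groups <- max(1L, floor((ntip - 1L) / 5L))
  per_tree <- lapply(trees, skyline_one, groups = groups)
  tmax <- stats::median(vapply(per_tree, function(s) max(s$end), numeric(1)))
  grid <- seq(0, tmax, length.out = grid_size)
  vals <- vapply(per_tree, function(s) ne_at(s, grid) / gen_time,
                 numeric(length(grid)))
  vals <- matrix(vals, nrow = length(grid))
  out <- data.frame(
    time = grid,
    ne_mean = rowMeans(vals),
    ne_lower = apply(vals, 1, quantile, 0.025),
    ne_upper = apply(vals, 1, quantile, 0.975)
  )
  structure(out, class = c("mt_skyline", "data.frame"),
            per_tree = per_tree, groups = groups, gen_time = gen_time)
}

#' Trend of a skyline trajectory
#'
#' Fits a per-tree least-squares slope of log Ne against time and returns
#' the across-tree mean slope with a 95% t-interval; a constant-size history
#' yields an interval covering zero, while growth toward the present gives a
#' significantly negative slope against years BP.
#'
#' @param trees list of ultrametric `phylo`.
#' @param groups skyline segments per tree (at least 2 needed for a slope).
#' @return list with `slope`, `ci` (length-2), `per_tree_slopes`.
#' @export
skyline_trend <- function(trees, groups = 4L) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  slopes <- vapply(trees, function(t) {
    s <- skyline_one(t, groups)
    if (nrow(s) < 2) return(NA_real_)
    mid <- (s$start + s$end) / 2
    stats::coef(stats::lm(log(s$ne) ~ mid))[2]
  }, numeric(1))
  slopes <- slopes[is.finite(slopes)]
  if (length(slopes) < 2)
    stop("need at least two trees with >= 2 segments", call. = FALSE)
  se <- sd(slopes) / sqrt(length(slopes))
  m <- mean(slopes)
  ci <- m + c(-1, 1) * stats::qt(0.975, length(slopes) - 1) * se
  list(slope = m, ci = ci, per_tree_slopes = slopes)
}

#' @export
print.mt_skyline <- function(x, ...) {
  cat("<mt_skyline> ", nrow(x), " grid points to ",
      format(max(x$time), digits = 6), " years BP; Ne range ",
      format(min(x$ne_mean), digits = 4), " - ",
      format(max(x$ne_mean), digits = 4), "\n", sep = "")
  invisible(x)
}
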