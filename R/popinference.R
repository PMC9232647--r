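## Discrete-ML ancestral reconstruction of population categories on a dated
## tree (equal-rates k-state Markov model) and haplogroup frequency
## aggregation with max-normalised heatmap tables.

POPULATION_GROUPS <- c("Khoisan-speakers", "RFHG", "Bantu",
                       "Niger-Congo (non-Bantu)", "Nilo-Saharan",
                       "Afro-Asiatic", "Arabic")

## ER transition probabilities have the closed form
## P(same) = 1/k + (k-1)/k e^{-kqt}, P(diff) = 1/k - 1/k e^{-kqt}
er_pmat <- function(k, q, t) {
  e <- exp(-k * q * t)
  m <- matrix((1 - e) / k, k, k)
  diag(m) <- 1 / k + (k - 1) / k * e
  m
}

#' Ancestral population reconstruction
#'
#' Fits an equal-rates (ER) k-state Markov model of population-label change
#' along a dated tree by maximum likelihood and returns, for every internal
#' node, the marginal probability vector over categories. Tips with unknown
#' labels enter as uniform partial observations. Nodes whose best category
#' exceeds the `threshold` (default 0.9) are flagged informative; only such
#' nodes should be interpreted.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param labels named character vector (tip label -> category, `NA` for
#'   unknown); categories default to the seven standard groups present in
#'   the data.
#' @param threshold informativeness cutoff on the per-node maximum.
#' @return object of class `mt_popanc`: list with `levels`, `rate` (fitted
#'   transitions per unit branch length), `node_prob` (matrix, one row per
#'   internal node), `informative`, `loglik`.
#' @export
ancestral_populations <- function(tree, labels, threshold = 0.9) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  if (!all(tips %in% names(labels)))
    stop("missing label for tip(s): ",
         paste(setdiff(tips, names(labels)), collapse = ", "), call. = FALSE)
  labels <- labels[tips]
  if (all(is.na(labels))) stop("all tips unknown", call. = FALSE)
  lv <- sort(unique(labels[!is.na(labels)]))
  k <- length(lv)
  ntip <- length(tips)
  nnode <- tree$Nnode
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths", call. = FALSE)
  el <- tree$edge.length
  H <- max(node_heights(tree))

  tipmat <- matrix(1 / k, k, ntip)   # unknown = uniform partial observation
  for (i in seq_len(ntip))
    if (!is.na(labels[i])) tipmat[, i] <- as.numeric(lv == labels[i])

  po <- ape::reorder.phylo(tree, "postorder")$edge
  el_po <- el[match(paste(po[, 1], po[, 2]), paste(tree$edge[, 1], tree$edge[, 2]))]

  down_pass <- function(q) {
    down <- matrix(1, k, ntip + nnode)
    down[, seq_len(ntip)] <- tipmat
    for (i in seq_len(nrow(po))) {
      P <- er_pmat(k, q, el_po[i])
      down[, po[i, 1]] <- down[, po[i, 1]] * (P %*% down[, po[i, 2]])
    }
    down
  }
  loglik_of <- function(q) {
    d <- down_pass(q)
    log(sum(d[, ntip + 1L] / k))
  }
  if (k == 1L) {
    q <- 0
  } else {
    opt <- optimize(function(lq) loglik_of(exp(lq)),
                    c(log(1e-4 / H), log(1e3 / H)), maximum = TRUE)
    q <- exp(opt$maximum)
  }

  down <- down_pass(q)
  up <- matrix(1, k, ntip + nnode)
  up[, ntip + 1L] <- 1 / k
  kids <- split(seq_len(nrow(po)), po[, 1])
  for (i in rev(seq_len(nrow(po)))) {   # root-down
    u <- po[i, 1]; v <- po[i, 2]
    P <- er_pmat(k, q, el_po[i])
    above <- up[, u]
    for (j in setdiff(kids[[as.character(u)]], i)) {
      Pj <- er_pmat(k, q, el_po[j])
      above <- above * (Pj %*% down[, po[j, 2]])
    }
    up[, v] <- crossprod(P, above)
  }
  node_prob <- matrix(NA_real_, nnode, k, dimnames = list(NULL, lv))
  for (nd in ntip + seq_len(nnode)) {
    w <- if (nd == ntip + 1L) down[, nd] / k else up[, nd] * down[, nd]
    node_prob[nd - ntip, ] <- w / sum(w)
  }
  structure(list(levels = lv, rate = q, node_prob = node_prob,
                 informative = apply(node_prob, 1, max) > threshold,
                 threshold = threshold,
                 loglik = loglik_of(q)),
            class = "mt_popanc")
}

#' @export
print.mt_popanc <- function(x, ...) {
  cat("<mt_popanc> ", length(x$levels), " categories, fitted rate ",
      format(x$rate, digits = 4), "; ", sum(x$informative), "/",
      nrow(x$node_prob), " informative nodes (> ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Aggregate haplogroup frequencies by region
#'
#' Tallies per-region haplogroup counts, converts them to within-region
#' frequencies (each region's frequencies sum to 1), and normalises each
#' haplogroup's frequencies to its maximum across regions (the heatmap
#' convention: the peak region scores 1 and is flagged). Regions without
#' data simply do not appear; they are not zero-filled.
#'
#' @param samples data frame with columns `region` and `haplogroup`
#'   (one row per sample; a `population` column, if present, is carried
#'   through grouping when `by = "population"`).
#' @param by grouping column (default `"region"`).
#' @return object of class `mt_freqtable`: list with `frequencies` (region,
#'   haplogroup, count, frequency) and `heatmap` (region, haplogroup,
#'   value in (0,1], `is_peak`).
#' @export
aggregate_frequencies <- function(samples, by = "region") {
  samples <- as.data.frame(samples)
  if (!nrow(samples)) stop("empty sample table", call. = FALSE)
  stopifnot(all(c(by, "haplogroup") %in% names(samples)))
  tab <- as.data.frame(table(region = samples[[by]],
                             haplogroup = samples$haplogroup),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab <- tab[tab$count > 0, , drop = FALSE]
  tot <- tapply(tab$count, tab$region, sum)
  tab$frequency <- tab$count / as.numeric(tot[tab$region])
  mx <- tapply(tab$frequency, tab$haplogroup, max)
  heat <- data.frame(region = tab$region, haplogroup = tab$haplogroup,
                     value = tab$frequency / as.numeric(mx[tab$haplogroup]),
                     stringsAsFactors = FALSE)
  heat$is_peak <- heat$value >= 1 - 1e-12
  rownames(tab) <- rownames(heat) <- NULL
  structure(list(frequencies = tab, heatmap = heat), class = "mt_freqtable")
}

#' @export
print.mt_freqtable <- function(x, ...) {
  cat("<mt_freqtable> ", length(unique(x$frequencies$region)), " regions x ",
      length(unique(x$frequencies$haplogroup)), " haplogroups\n", sep = "")
  invisible(x)
}

#' @rdname aggregate_frequencies
#' @param x an `mt_freqtable`.
#' @param prefix output path prefix (writes `<prefix>_frequencies.csv` and
#'   `<prefix>_heatmap.csv`, plain CSV for any charting layer).
#' @export
write_frequency_tables <- function(x, prefix) {
  stopifnot(inherits(x, "mt_freqtable"))
  f1 <- paste0(prefix, "_frequencies.csv")
  f2 <- paste0(prefix, "_heatmap.csv")
  utils::write.csv(x$frequencies, f1, row.names = FALSE)
  utils::write.csv(x$heatmap, f2, row.names = FALSE)
  invisible(c(f1, f2))
}
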