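## HKY+Gamma substitution model, six-bin partition scheme, and the
## averaged-literature-rate lognormal clock prior.

NUC <- c("A", "C", "G", "T")

#' HKY rate matrix and spectral decomposition
#'
#' Builds the HKY85 instantaneous rate matrix with transition/transversion
#' ratio `kappa` and equilibrium frequencies `base_freqs`, normalised to one
#' expected substitution per site per unit branch length, together with its
#' spectral decomposition (computed on the pi-symmetrised matrix, so it is
#' numerically exact for this reversible model) and, optionally, discrete
#' gamma rate categories.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param base_freqs equilibrium frequencies in A, C, G, T order; normalised
#'   internally.
#' @param gamma_shape shape of the gamma rate-heterogeneity distribution, or
#'   `NULL` for a single rate class.
#' @param ncat number of equiprobable discrete gamma categories (default 4).
#' @return an object of class `mt_submodel` with fields `Q`, `U`, `Uinv`,
#'   `eigenvalues`, `base_freqs`, `kappa`, `gamma_shape`, `cat_rates`.
#' @export
hky_model <- function(kappa, base_freqs = rep(0.25, 4), gamma_shape = NULL,
                      ncat = 4L) {
  stopifnot(kappa > 0, length(base_freqs) == 4, all(base_freqs > 0))
  pi <- base_freqs / sum(base_freqs)
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    ts <- is_transition(NUC[i], NUC[j])
    Q[i, j] <- if (ts) kappa * pi[j] else pi[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  d <- sqrt(pi)
  B <- diag(d) %*% Q %*% diag(1 / d)
  B <- (B + t(B)) / 2
  eig <- eigen(B, symmetric = TRUE)
  U <- diag(1 / d) %*% eig$vectors
  Uinv <- t(eig$vectors) %*% diag(d)
  cr <- if (is.null(gamma_shape)) 1 else discrete_gamma_rates(gamma_shape, ncat)
  structure(list(Q = Q, U = U, Uinv = Uinv, eigenvalues = eig$values,
                 base_freqs = pi, kappa = kappa, gamma_shape = gamma_shape,
                 cat_rates = cr),
            class = "mt_submodel")
}

#' Discrete gamma rate categories
#'
#' Mean rates of `ncat` equiprobable slices of a Gamma(shape, shape)
#' distribution (mean 1), the standard discretisation for among-site rate
#' heterogeneity.
#'
#' @param shape gamma shape parameter alpha (> 0).
#' @param ncat number of categories.
#' @return numeric vector of length `ncat`, averaging 1.
#' @export
discrete_gamma_rates <- function(shape, ncat = 4L) {
  stopifnot(shape > 0, ncat >= 1)
  if (ncat == 1L) return(1)
  b <- stats::qgamma(seq(0, 1, length.out = ncat + 1), shape, rate = shape)
  p <- stats::pgamma(b, shape + 1, rate = shape)
  ncat * diff(p)
}

#' Transition probability matrix
#'
#' @param model an `mt_submodel`.
#' @param t branch length in expected substitutions per site.
#' @return 4x4 row-stochastic matrix in A, C, G, T order.
#' @export
transition_prob <- function(model, t) {
  P <- model$U %*% diag(exp(model$eigenvalues * t)) %*% model$Uinv
  P[P < 0] <- 0
  P
}

## -------------------------------------------------------------- partitions

PARTITION_BINS <- c("codon1", "codon2", "codon3", "HVS", "tRNA", "other")

#' Six-bin partition scheme for mtDNA
#'
#' Maps every unmasked position to one of six rate bins: codon positions 1-3
#' of the protein-coding genes, the combined hypervariable segments
#' (HVS-I/II/III), the conserved tRNA genes, and other non-coding sites
#' (including the rRNAs). Masked SNP positions are left unmapped, so mapped
#' plus masked sites account for the whole genome.
#'
#' @param ref an `mt_reference` carrying the functional annotation.
#' @param mask an `mt_site_mask`; its SNP positions are excluded.
#' @param relative_rates optional named per-bin rate multipliers; rescaled so
#'   that the site-weighted mean rate is exactly 1 (the mean overall rate is
#'   held fixed while relative rates vary).
#' @return an object of class `mt_partition` with fields `site_map` (integer
#'   bin index per position, NA where masked), `bins`, `relative_rates`,
#'   `bin_sizes`.
#' @export
partition_sites <- function(ref = mt_reference(), mask = site_mask(),
                            relative_rates = NULL) {
  ann <- ref$annotation
  if (anyNA(ann)) stop("unannotated position(s) in reference", call. = FALSE)
  cls <- ifelse(ann %in% PARTITION_BINS, ann, "other")
  map <- match(cls, PARTITION_BINS)
  map[mask$snp_positions] <- NA_integer_
  sizes <- tabulate(map, nbins = 6L)
  names(sizes) <- PARTITION_BINS
  parts <- structure(list(site_map = map, bins = PARTITION_BINS,
                          bin_sizes = sizes,
                          relative_rates = stats::setNames(rep(1, 6),
                                                           PARTITION_BINS)),
                     class = "mt_partition")
  if (!is.null(relative_rates)) parts <- set_relative_rates(parts, relative_rates)
  parts
}

#' @rdname partition_sites
#' @param parts an `mt_partition`.
#' @export
set_relative_rates <- function(parts, relative_rates) {
  stopifnot(inherits(parts, "mt_partition"))
  r <- relative_rates[parts$bins]
  stopifnot(all(r > 0), !anyNA(r))
  w <- parts$bin_sizes / sum(parts$bin_sizes)
  r <- r / sum(w * r)  # fix the site-weighted mean rate to 1
  parts$relative_rates <- stats::setNames(as.numeric(r), parts$bins)
  parts
}

#' @export
print.mt_partition <- function(x, ...) {
  cat("<mt_partition> six bins:\n")
  print(data.frame(bin = x$bins, sites = as.integer(x$bin_sizes),
                   rel_rate = round(unname(x$relative_rates), 4)))
  invisible(x)
}

## ------------------------------------------------------------- clock prior

#' Average literature rate distributions into a lognormal clock prior
#'
#' Forms the equal-weight mixture of the supplied rate distributions
#' (each given by its mean and standard deviation) and fits a lognormal by
#' matching the mixture's mean and variance. The fitted prior mean equals the
#' arithmetic mean of the input means, so a survey averaging to
#' 2.285e-8 substitutions/site/year yields a prior centred there while the
#' spread carries the disagreement between studies.
#'
#' @param rates data frame with columns `mean`, `sd` and optionally `family`
#'   (recorded, not used: only the first two moments enter the fit).
#' @return an object of class `mt_clock_prior` with `mean_rate`, `meanlog`,
#'   `sdlog`, `components`.
#' @export
average_rate_prior <- function(rates = default_rate_survey()) {
  rates <- as.data.frame(rates)
  stopifnot(nrow(rates) >= 1, all(c("mean", "sd") %in% names(rates)))
  if (any(rates$mean <= 0))
    stop("non-positive rate mean in survey", call. = FALSE)
  m <- mean(rates$mean)
  v <- mean(rates$sd^2) + mean((rates$mean - m)^2)
  sdlog2 <- log(1 + v / m^2)
  structure(list(mean_rate = m,
                 meanlog = log(m) - sdlog2 / 2,
                 sdlog = sqrt(sdlog2),
                 components = rates),
            class = "mt_clock_prior")
}

#' Default mutation-rate survey
#'
#' A representative synthetic stand-in for a literature survey of human
#' whole-mtDNA mutation rates (the published per-study distributions are not
#' redistributed): three components whose means average exactly
#' 2.285e-8 substitutions/site/year, the calibration value used throughout
#' the package.
#'
#' @return data frame with columns `mean`, `sd`, `family`.
#' @export
default_rate_survey <- function() {
  data.frame(
    mean = c(1.665e-8, 2.530e-8, 2.660e-8),
    sd = c(0.20e-8, 0.30e-8, 0.35e-8),
    family = "lognormal",
    stringsAsFactors = FALSE
  )
}

#' @export
print.mt_clock_prior <- function(x, ...) {
  cat("<mt_clock_prior> mean ", format(x$mean_rate, digits = 6),
      " subs/site/year (meanlog ", format(x$meanlog, digits = 6),
      ", sdlog ", format(x$sdlog, digits = 4), ")\n", sep = "")
  invisible(x)
}
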