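## Clade annotation: collapse weakly supported nodes, reconstruct ancestral
## sequences (Fitch parsimony and single-rate ML), extract per-branch
## synapomorphies in PhyloTree notation, and emit clade report rows.

node_supports <- function(t, support = NULL) {
  if (is.null(support)) {
    support <- suppressWarnings(as.numeric(t$node.label))
    if (is.null(t$node.label)) support <- rep(1, t$Nnode)
  }
  stopifnot(length(support) == t$Nnode)
  root <- ape::Ntip(t) + 1L
  support[1L] <- ifelse(is.na(support[1L]), 1, support[1L])  # root
  support[is.na(support)] <- 1
  if (any(support < 0 | support > 1))
    stop("node supports must lie in [0, 1]", call. = FALSE)
  support
}

#' Collapse weakly supported nodes into polytomies
#'
#' Deletes every internal node whose support (posterior probability or
#' bootstrap proportion) falls below the threshold and grafts its children
#' onto its parent, preserving tip depths. The tip set is unchanged and the
#' operation is idempotent.
#'
#' @param t a rooted `phylo` tree; supports are taken from `support` or
#'   parsed from `t$node.label` (root support is defined as 1).
#' @param threshold nodes with support strictly below this are collapsed
#'   (default 0.5, the conventional posterior cut for polytomy collapsing).
#' @param support optional numeric vector of length `t$Nnode`.
#' @return the collapsed `phylo`, with surviving supports in `node.label`.
#' @export
collapse_low_support <- function(t, threshold = 0.5, support = NULL) {
  stopifnot(inherits(t, "phylo"), threshold >= 0, threshold <= 1)
  ntip <- ape::Ntip(t)
  root <- ntip + 1L
  support <- node_supports(t, support)
  node_ids <- ntip + seq_len(t$Nnode)
  drop <- node_ids[support < threshold & node_ids != root]
  if (!length(drop)) {
    t$node.label <- format_support(support)
    return(t)
  }
  edge <- t$edge
  len <- if (is.null(t$edge.length)) rep(NA_real_, nrow(edge)) else t$edge.length
  parent_of <- integer(max(edge))
  parent_of[edge[, 2]] <- edge[, 1]
  len_of <- numeric(max(edge))
  len_of[edge[, 2]] <- len

  keep_edge <- !(edge[, 2] %in% drop)
  new_edges <- edge[keep_edge, , drop = FALSE]
  new_len <- len[keep_edge]
  for (i in seq_len(nrow(new_edges))) {
    u <- new_edges[i, 1]
    acc <- new_len[i]
    while (u %in% drop) {
      acc <- acc + len_of[u]
      u <- parent_of[u]
    }
    new_edges[i, 1] <- u
    new_len[i] <- acc
  }
  keep_nodes <- setdiff(node_ids, drop)
  new_ids <- integer(max(edge))
  new_ids[seq_len(ntip)] <- seq_len(ntip)
  new_ids[keep_nodes] <- ntip + seq_along(keep_nodes)
  out <- list(
    edge = cbind(new_ids[new_edges[, 1]], new_ids[new_edges[, 2]]),
    tip.label = t$tip.label,
    Nnode = length(keep_nodes),
    node.label = format_support(support[keep_nodes - ntip])
  )
  if (!all(is.na(new_len))) out$edge.length <- new_len
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

format_support <- function(x) formatC(x, format = "g", digits = 6)

## ---------------------------------------------------- ancestral states

profiles_to_site_matrix <- function(tree, tip_profiles, ref) {
  tips <- tree$tip.label
  if (!all(tips %in% names(tip_profiles)))
    stop("unlabeled tip(s): ",
         paste(setdiff(tips, names(tip_profiles)), collapse = ", "),
         call. = FALSE)
  snp_pos <- sort(unique(unlist(lapply(tip_profiles[tips], function(p) {
    v <- p$variants
    v$position[v$kind %in% c("transition", "transversion")]
  }))))
  mat <- matrix(rep(ref$bases[snp_pos], each = length(tips)),
                nrow = length(tips), dimnames = list(tips, snp_pos))
  for (tp in tips) {
    p <- tip_profiles[[tp]]
    v <- p$variants
    snp <- v[v$kind %in% c("transition", "transversion"), , drop = FALSE]
    mat[tp, as.character(intersect(snp$position, snp_pos))] <-
      snp$alt[snp$position %in% snp_pos]
    if (length(snp_pos)) {
      covered <- profile_covers(p, snp_pos)
      mat[tp, !covered] <- "N"
      unc <- intersect(p$uncertain$position, snp_pos)
      if (length(unc))
        mat[tp, as.character(unc)] <-
          p$uncertain$code[match(unc, p$uncertain$position)]
      del <- v[v$kind == "deletion", , drop = FALSE]
      for (i in seq_len(nrow(del))) {
        hit <- snp_pos >= del$position[i] & snp_pos <= del$span_end[i]
        mat[tp, hit] <- "-"
      }
    }
  }
  mat
}

indel_presence_matrix <- function(tree, tip_profiles) {
  tips <- tree$tip.label
  keys <- unique(unlist(lapply(tip_profiles[tips], function(p) {
    v <- p$variants
    v <- v[v$kind %in% c("insertion", "deletion") & !v$ins_unspecified, ,
           drop = FALSE]
    mutation_site_key(v)
  })))
  tokens <- unlist(lapply(unname(tip_profiles[tips]), function(p) {
    v <- p$variants
    v <- v[v$kind %in% c("insertion", "deletion") & !v$ins_unspecified, ,
           drop = FALSE]
    stats::setNames(v$token, mutation_site_key(v))
  }))
  tokens <- tokens[!duplicated(names(tokens))]
  if (!length(keys))
    return(list(mat = matrix(FALSE, length(tips), 0,
                             dimnames = list(tips, NULL)),
                tokens = character(0)))
  mat <- matrix(FALSE, length(tips), length(keys),
                dimnames = list(tips, keys))
  for (tp in tips) {
    v <- tip_profiles[[tp]]$variants
    v <- v[v$kind %in% c("insertion", "deletion") & !v$ins_unspecified, ,
           drop = FALSE]
    mat[tp, mutation_site_key(v)] <- TRUE
  }
  list(mat = mat, tokens = tokens)
}

fitch_sets <- function(tree, tip_sets) {
  # tip_sets: list over tips of character vectors of allowed states
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  sets[seq_len(ntip)] <- tip_sets
  changes <- 0L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  assign_set <- function(nd) {
    if (nd <= ntip) return(sets[[nd]])
    ch <- kids[[as.character(nd)]]
    s <- NULL
    for (c in ch) {
      cs <- assign_set(c)
      s <- if (is.null(s)) cs else {
        inter <- intersect(s, cs)
        if (length(inter)) inter else { changes <<- changes + 1L; union(s, cs) }
      }
    }
    sets[[nd]] <<- s
    s
  }
  assign_set(ntip + 1L)
  list(sets = sets, changes = changes, kids = kids)
}

#' Reconstruct ancestral sequences on a rooted tree
#'
#' Reconstructs per-site ancestral nucleotide states for every internal node,
#' either by Fitch parsimony (minimum-change; set-valued states resolved
#' root-down, preferring the parent state) or by marginal maximum likelihood
#' under a single-rate reversible substitution model with empirical base
#' frequencies. On homoplasy-free data the two methods agree. Heteroplasmic
#' IUPAC codes and uncovered positions enter as partial observations. Indel
#' variants are carried along by presence/absence parsimony and reported as
#' annotation-level events, never entering the nucleotide likelihood.
#'
#' @param tree a rooted `phylo`; tips must be named in `tip_profiles`.
#' @param tip_profiles named list of `mt_profile`, one per tip.
#' @param ref an `mt_reference`.
#' @param method `"ML"` (marginal maximum likelihood) or `"Fitch"`.
#' @param root_prior `"reference"` (default: the root state prior is a point
#'   mass on the reference base, the natural choice for variant data
#'   expressed relative to a known ancestral reference and for trees rooted
#'   by an outgroup carrying the root genotype) or `"stationary"` (the
#'   model's equilibrium frequencies).
#' @return an object of class `mt_ancestral`: list with `tree`, `sites`
#'   (positions analysed), `tip_states`, `node_states` (matrix, rows =
#'   internal nodes in ape numbering), `prob` (ML mode: list of per-site
#'   probability matrices), `fitch_changes` (Fitch mode: minimum change
#'   count), `indels` (per-branch indel gains) and `method`.
#' @export
reconstruct_ancestral <- function(tree, tip_profiles, ref = mt_reference(),
                                  method = c("ML", "Fitch"),
                                  root_prior = c("reference", "stationary")) {
  stopifnot(inherits(tree, "phylo"))
  method <- match.arg(method)
  root_prior <- match.arg(root_prior)
  mat <- profiles_to_site_matrix(tree, tip_profiles, ref)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  nsite <- ncol(mat)
  sites <- as.integer(colnames(mat))
  node_states <- matrix(NA_character_, nnode, nsite,
                        dimnames = list(NULL, colnames(mat)))
  prob <- NULL
  fitch_changes <- NA_integer_

  kids <- split(tree$edge[, 2], tree$edge[, 1])
  parent_of <- integer(ntip + nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]

  if (method == "Fitch" && nsite) {
    total <- 0L
    for (j in seq_len(nsite)) {
      tip_sets <- lapply(mat[, j], function(b) IUPAC_PARTIAL[[b]] %||%
                                               c("A", "C", "G", "T"))
      fs <- fitch_sets(tree, tip_sets)
      total <- total + fs$changes
      # root-down resolution, preferring the parent state, then the
      # reference base, then alphabetical order
      resolve <- function(nd, parent_state) {
        s <- fs$sets[[nd]]
        pick <- if (!is.null(parent_state) && parent_state %in% s)
          parent_state
        else if (ref$bases[sites[j]] %in% s) ref$bases[sites[j]]
        else sort(s)[1]
        if (nd > ntip) node_states[nd - ntip, j] <<- pick
        for (c in kids[[as.character(nd)]] %||% integer(0)) resolve(c, pick)
      }
      resolve(ntip + 1L, NULL)
    }
    fitch_changes <- total
  } else if (nsite) {
    freqs <- empirical_frequencies(ref)
    rootp <- if (root_prior == "reference")
      vapply(ref$bases[sites], function(b) as.numeric(NUC == b), numeric(4))
    else matrix(freqs, 4, nsite)
    prob <- marginal_ml_states(tree, mat, freqs, rootp)
    raw <- prob$states
    # tie-break toward the parent state root-down
    order_nodes <- unique(ape::reorder.phylo(tree, "cladewise")$edge[, 1])
    for (j in seq_len(nsite)) {
      for (nd in order_nodes) {
        pvec <- prob$prob[[j]][nd - ntip, ]
        best <- max(pvec)
        cand <- c("A", "C", "G", "T")[pvec >= best - 1e-9]
        par <- parent_of[nd]
        ps <- if (par > ntip && par != 0) node_states[par - ntip, j] else NA
        node_states[nd - ntip, j] <-
          if (!is.na(ps) && ps %in% cand) ps else cand[1]
      }
    }
  }

  ip <- indel_presence_matrix(tree, tip_profiles)
  indels <- reconstruct_indels(tree, ip, kids)

  structure(list(tree = tree, sites = sites,
                 tip_states = mat, node_states = node_states,
                 prob = prob$prob, loglik = prob$loglik,
                 fitch_changes = fitch_changes,
                 indels = indels, indel_tokens = ip$tokens,
                 ref = ref, method = method),
            class = "mt_ancestral")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empirical_frequencies <- function(ref) {
  tab <- table(factor(ref$bases, levels = c("A", "C", "G", "T")))
  as.numeric(tab / sum(tab))
}

## Marginal ML reconstruction under an F81-type model (empirical equilibrium
## frequencies, single exchangeability), branch scale fitted by ML.
marginal_ml_states <- function(tree, mat, freqs, root_prior) {
  ntip <- nrow(mat)
  nnode <- tree$Nnode
  nsite <- ncol(mat)
  states <- c("A", "C", "G", "T")
  beta <- 1 / (1 - sum(freqs^2))
  edge <- tree$edge
  rel_len <- if (!is.null(tree$edge.length) && all(tree$edge.length >= 0) &&
                 sum(tree$edge.length) > 0) tree$edge.length
             else rep(1, nrow(edge))
  rel_len <- rel_len / mean(rel_len)
  pmat <- function(t) {
    e <- exp(-beta * t)
    m <- matrix(freqs, 4, 4, byrow = TRUE) * (1 - e)
    diag(m) <- diag(m) + e
    m
  }
  tip_partial <- function(b) {
    allowed <- IUPAC_PARTIAL[[b]] %||% states
    if (b == "-") allowed <- states
    as.numeric(states %in% allowed)
  }
  tips_part <- array(0, c(4, nsite, ntip))
  for (i in seq_len(ntip))
    tips_part[, , i] <- vapply(mat[i, ], tip_partial, numeric(4))

  po <- ape::reorder.phylo(tree, "postorder")$edge
  loglik_for <- function(scale) {
    down <- array(1, c(4, nsite, ntip + nnode))
    down[, , seq_len(ntip)] <- tips_part
    for (i in seq_len(nrow(po))) {
      u <- po[i, 1]; v <- po[i, 2]
      Pv <- pmat(rel_len[match(v, edge[, 2])] * scale)
      down[, , u] <- down[, , u] * (Pv %*% down[, , v])
    }
    rootp <- root_prior * down[, , ntip + 1L]
    sum(log(colSums(rootp)))
  }
  opt <- optimize(loglik_for, c(1e-4, 10), maximum = TRUE, tol = 1e-4)
  scale <- opt$maximum

  # recompute partials at the optimum and run the up-down pass
  P <- lapply(rel_len * scale, pmat)
  names(P) <- as.character(edge[, 2])
  down <- array(1, c(4, nsite, ntip + nnode))
  down[, , seq_len(ntip)] <- tips_part
  for (i in seq_len(nrow(po))) {
    u <- po[i, 1]; v <- po[i, 2]
    down[, , u] <- down[, , u] * (P[[as.character(v)]] %*% down[, , v])
  }
  up <- array(1, c(4, nsite, ntip + nnode))
  up[, , ntip + 1L] <- root_prior
  pre <- rev(seq_len(nrow(po)))  # root-down order
  kids <- split(edge[, 2], edge[, 1])
  for (i in pre) {
    u <- po[i, 1]; v <- po[i, 2]
    sibs <- setdiff(kids[[as.character(u)]], v)
    above <- up[, , u]
    for (s in sibs) above <- above * (P[[as.character(s)]] %*% down[, , s])
    up[, , v] <- crossprod(P[[as.character(v)]], above)
  }
  prob <- vector("list", nsite)
  site_ll <- colSums(root_prior * down[, , ntip + 1L])
  for (j in seq_len(nsite)) {
    m <- matrix(0, nnode, 4, dimnames = list(NULL, states))
    for (nd in ntip + seq_len(nnode)) {
      w <- if (nd == ntip + 1L) root_prior[, j] * down[, j, nd]
           else up[, j, nd] * down[, j, nd]
      m[nd - ntip, ] <- w / sum(w)
    }
    prob[[j]] <- m
  }
  list(prob = prob,
       states = NULL,
       loglik = sum(log(site_ll)),
       scale = scale)
}

reconstruct_indels <- function(tree, ip, kids) {
  ntip <- ape::Ntip(tree)
  out <- list()
  for (k in seq_len(ncol(ip$mat))) {
    key <- colnames(ip$mat)[k]
    tip_sets <- lapply(ip$mat[, k], function(x) if (x) "1" else "0")
    fs <- fitch_sets(tree, tip_sets)
    state <- character(ntip + tree$Nnode)
    resolve <- function(nd, parent_state) {
      s <- fs$sets[[nd]]
      pick <- if (!is.null(parent_state) && parent_state %in% s) parent_state
              else if ("0" %in% s) "0" else "1"   # absent at the root
      state[nd] <<- pick
      for (c in kids[[as.character(nd)]] %||% integer(0)) resolve(c, pick)
    }
    resolve(ntip + 1L, NULL)
    ed <- tree$edge
    gains <- which(state[ed[, 1]] == "0" & state[ed[, 2]] == "1")
    for (g in gains)
      out[[length(out) + 1L]] <- data.frame(
        node = ed[g, 2], key = key, token = unname(ip$tokens[key]),
        stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(node = integer(0), key = character(0),
                  token = character(0), stringsAsFactors = FALSE)
}

#' Extract per-branch synapomorphies
#'
#' A mutation is assigned to a branch when the reconstructed parent and child
#' states differ at a site; the token is written in PhyloTree notation
#' (transversions lowercase) with a trailing `!` when the branch reverts a
#' root-ward change at the same site back to the root state. Indel gains from
#' the presence/absence reconstruction are appended as annotation-level
#' tokens.
#'
#' @param anc an `mt_ancestral` from [reconstruct_ancestral()].
#' @return named list, one `mt_mutations` table per branch, named by the
#'   child node: tip labels for terminal branches, `"node<k>"` for internal
#'   ones.
#' @export
extract_synapomorphies <- function(anc) {
  tree <- anc$tree
  ntip <- ape::Ntip(tree)
  state_of <- function(nd, j) {
    if (nd <= ntip) {
      s <- anc$tip_states[tree$tip.label[nd], j]
      if (s %in% c("A", "C", "G", "T")) s else NA_character_
    } else anc$node_states[nd - ntip, j]
  }
  root <- ntip + 1L
  out <- list()
  for (i in seq_len(nrow(tree$edge))) {
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    toks <- character(0)
    for (j in seq_along(anc$sites)) {
      su <- state_of(u, j); sv <- state_of(v, j)
      if (is.na(su) || is.na(sv) || su == sv) next
      rootstate <- state_of(root, j)
      back <- !is.na(rootstate) && sv == rootstate && su != rootstate
      alt <- if (is_transition(su, sv)) sv else tolower(sv)
      toks <- c(toks, paste0(su, anc$sites[j], alt, if (back) "!" else ""))
    }
    idel <- anc$indels$token[anc$indels$node == v]
    toks <- c(toks, idel)
    nm <- if (v <= ntip) tree$tip.label[v] else paste0("node", v)
    out[[nm]] <- parse_mutations(toks)
  }
  out
}

#' Assemble a clade report table
#'
#' Builds the standard clade report: one row per named clade with its parent,
#' mean age (years BP), 95% HPD bounds, posterior support, stem length
#' (parent mean age minus clade mean age; left missing when the parent age is
#' unknown, never zero-filled) and defining mutations, sorted root-ward
#' (oldest first).
#'
#' @param clades data frame with columns `clade`, `parent`, `mean_age` and
#'   optionally `hpd_upper`, `hpd_lower`, `posterior`.
#' @param mutations optional named list (clade -> character tokens or
#'   `mt_mutations`).
#' @return a data frame with the computed `stem_length` column.
#' @export
build_clade_table <- function(clades, mutations = NULL) {
  stopifnot(all(c("clade", "parent", "mean_age") %in% names(clades)))
  if (anyNA(clades$mean_age))
    stop("missing mean age for clade(s): ",
         paste(clades$clade[is.na(clades$mean_age)], collapse = ", "),
         call. = FALSE)
  parent_age <- clades$mean_age[match(clades$parent, clades$clade)]
  out <- data.frame(
    clade = clades$clade, parent = clades$parent,
    mean_age = clades$mean_age,
    hpd_upper = clades$hpd_upper %||% NA_real_,
    hpd_lower = clades$hpd_lower %||% NA_real_,
    stem_length = parent_age - clades$mean_age,
    posterior = clades$posterior %||% NA_real_,
    stringsAsFactors = FALSE
  )
  if (!is.null(mutations)) {
    out$mutations <- vapply(out$clade, function(cl) {
      m <- mutations[[cl]]
      if (is.null(m)) return("")
      if (inherits(m, "mt_mutations")) m <- serialize_mutations(m)
      paste(m, collapse = " ")
    }, character(1))
  }
  out[order(-out$mean_age, out$clade), , drop = FALSE]
}
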