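## Named haplogroup tree with per-branch defining variants, cumulative
## genotype expansion, the definitive-placement classification rule,
## monophyly audit, and nomenclature restructuring.

#' Build a haplogroup tree
#'
#' @param nodes a data frame with columns `name`, `parent` (NA for the root)
#'   and `variants` (whitespace-separated token string), or a list of lists
#'   with those fields (`variants` as a character vector).
#' @return an object of class `mt_haplotree`.
#' @export
haplotree <- function(nodes) {
  if (is.data.frame(nodes)) {
    nodes <- lapply(seq_len(nrow(nodes)), function(i) list(
      name = nodes$name[i],
      parent = if (is.na(nodes$parent[i])) NULL else nodes$parent[i],
      variants = {
        v <- nodes$variants[i]
        if (is.na(v) || !nzchar(trimws(v))) character(0)
        else strsplit(trimws(v), "\\s+")[[1]]
      }))
  }
  names <- vapply(nodes, `[[`, character(1), "name")
  if (anyDuplicated(names))
    stop("duplicate haplogroup names: ",
         paste(unique(names[duplicated(names)]), collapse = ", "), call. = FALSE)
  lst <- list()
  root <- NULL
  for (nd in nodes) {
    parent <- nd$parent
    if (is.null(parent) || length(parent) == 0 || is.na(parent)) {
      if (!is.null(root)) stop("multiple roots in haplogroup tree", call. = FALSE)
      root <- nd$name
      parent <- NA_character_
    }
    lst[[nd$name]] <- list(
      name = nd$name, parent = parent,
      variants = parse_mutations(unlist(nd$variants)),
      children = character(0))
  }
  if (is.null(root)) stop("haplogroup tree has no root", call. = FALSE)
  for (nm in names) {
    p <- lst[[nm]]$parent
    if (!is.na(p)) {
      if (is.null(lst[[p]]))
        stop("unknown parent '", p, "' for haplogroup '", nm, "'", call. = FALSE)
      lst[[p]]$children <- c(lst[[p]]$children, nm)
    }
  }
  if (nrow(lst[[root]]$variants))
    stop("root haplogroup must carry no defining variants", call. = FALSE)
  for (nm in setdiff(names, root))
    if (nrow(lst[[nm]]$variants) == 0)
      stop("haplogroup '", nm, "' has no defining variants", call. = FALSE)
  ht <- structure(list(nodes = lst, root = root), class = "mt_haplotree")
  # reachability / acyclicity audit
  seen <- character(0)
  stack <- root
  while (length(stack)) {
    nm <- stack[1]; stack <- stack[-1]
    if (nm %in% seen) stop("cycle in haplogroup tree at '", nm, "'", call. = FALSE)
    seen <- c(seen, nm)
    stack <- c(stack, lst[[nm]]$children)
  }
  if (!setequal(seen, names))
    stop("haplogroups unreachable from root: ",
         paste(setdiff(names, seen), collapse = ", "), call. = FALSE)
  ht
}

#' @export
print.mt_haplotree <- function(x, ...) {
  cat("<mt_haplotree> ", length(x$nodes), " haplogroups, root ", x$root,
      "\n", sep = "")
  invisible(x)
}

#' Read a haplogroup tree from JSON or TSV
#'
#' JSON documents carry a `nodes` array of `{name, parent, variants}`
#' objects; the TSV flat form has columns `name`, `parent`, `variants`
#' (space-separated tokens, empty for the root).
#'
#' @param path file path (`.json` or `.tsv`).
#' @return an `mt_haplotree`.
#' @export
read_haplotree <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    nodes <- lapply(doc$nodes, function(nd) list(
      name = nd$name,
      parent = if (is.null(nd$parent)) NULL else nd$parent,
      variants = unlist(nd$variants)))
    haplotree(nodes)
  } else {
    df <- read.table(path, sep = "\t", header = TRUE, quote = "",
                     na.strings = c("NA", ""), stringsAsFactors = FALSE)
    haplotree(df)
  }
}

#' The packaged L5'7 haplogroup system
#'
#' The published clade system for the L5'7 branch of the human mtDNA tree:
#' L5'7 splitting into L5 (with L5a, L5a1, L5a2, L5b, L5b1, L5b*) and L7
#' (with L7a, L7a*, L7a1, L7b, L7b1, L7b2), each branch carrying its printed
#' defining variants.
#'
#' @return an `mt_haplotree`.
#' @export
l5p7_haplotree <- function() {
  read_haplotree(system.file("extdata", "l5p7_haplogroups.json",
                             package = "haplomt"))
}

#' The packaged L5'7 clade age table
#'
#' Printed mean node ages (years BP), 95% HPD bounds, stem lengths and
#' posterior supports for the L5'7 clade system, used by the worked examples.
#'
#' @return a data frame with one row per clade.
#' @export
l5p7_clade_ages <- function() {
  read.table(system.file("extdata", "l5p7_clade_ages.tsv", package = "haplomt"),
             sep = "\t", header = TRUE, quote = "", stringsAsFactors = FALSE)
}

root_path <- function(tree, clade) {
  if (is.null(tree$nodes[[clade]]))
    stop("unknown haplogroup '", clade, "'", call. = FALSE)
  path <- clade
  while (!is.na(tree$nodes[[path[1]]]$parent))
    path <- c(tree$nodes[[path[1]]]$parent, path)
  path
}

path_tokens <- function(tree, clade) {
  path <- root_path(tree, clade)
  unlist(lapply(path, function(nm) tree$nodes[[nm]]$variants$token))
}

#' Cumulative expected genotype of a haplogroup
#'
#' Unions the defining variants along the root-to-clade path, with
#' back-mutations cancelling the matching earlier change, and returns the net
#' variant profile relative to the reference (deterministically ordered by
#' position). Unspecified-count insertions are annotation-only and excluded.
#'
#' @param tree an `mt_haplotree`.
#' @param clade haplogroup label.
#' @param ref an `mt_reference`.
#' @return an `mt_profile` with full coverage.
#' @export
expected_genotype <- function(tree, clade, ref = mt_reference()) {
  stopifnot(inherits(tree, "mt_haplotree"))
  toks <- path_tokens(tree, clade)
  seq <- apply_variants(ref, parse_mutations(toks))
  call_variants(seq$bases, ref, sample_id = clade, insertions = seq$insertions)
}

#' Convert a haplogroup tree to a dated sample phylogeny
#'
#' Builds the rooted ultrametric `phylo` implied by a haplogroup tree and a
#' clade age table: every named clade with children becomes an internal node
#' dated at its mean age and additionally contributes one contemporary
#' sample tip (carrying its name); childless clades become tips; the root
#' gains an `outgroup` tip. Useful as the fixed topology for dating a
#' planted fixture ([plant_haplogroup_fixture()] uses the same tip ids).
#'
#' @param htree an `mt_haplotree`.
#' @param ages data frame with columns `clade`, `mean_age` and (for the root
#'   height) `stem_length`; defaults to the packaged table.
#' @return a rooted ultrametric `phylo` with branch lengths in years.
#' @export
haplotree_as_phylo <- function(htree, ages = l5p7_clade_ages()) {
  stopifnot(inherits(htree, "mt_haplotree"))
  age_of <- stats::setNames(ages$mean_age, ages$clade)
  stem_of <- stats::setNames(ages$stem_length, ages$clade)
  internal_clades <- names(htree$nodes)[vapply(htree$nodes, function(nd)
    length(nd$children) > 0, logical(1))]
  tip_ids <- c("outgroup",
               names(htree$nodes)[names(htree$nodes) != htree$root])
  ntip <- length(tip_ids)
  node_num <- stats::setNames(seq_len(ntip), tip_ids)
  inum <- ntip
  node_age <- numeric(ntip + length(internal_clades))
  for (cl in c(htree$root, setdiff(internal_clades, htree$root))) {
    inum <- inum + 1L
    node_num[[paste0(".node.", cl)]] <- inum
    node_age[inum] <- if (cl == htree$root) {
      top <- htree$nodes[[htree$root]]$children
      max(age_of[top] + stem_of[top])
    } else age_of[[cl]]
  }
  edges <- list()
  for (cl in internal_clades) {
    me <- node_num[[paste0(".node.", cl)]]
    kids <- htree$nodes[[cl]]$children
    extra_tip <- if (cl == htree$root) "outgroup" else cl
    for (k in kids) {
      child <- if (k %in% internal_clades) node_num[[paste0(".node.", k)]]
               else node_num[[k]]
      edges[[length(edges) + 1L]] <- c(me, child)
    }
    edges[[length(edges) + 1L]] <- c(me, node_num[[extra_tip]])
  }
  edge <- do.call(rbind, edges)
  tr <- list(edge = edge,
             edge.length = node_age[edge[, 1]] - node_age[edge[, 2]],
             tip.label = tip_ids, Nnode = length(internal_clades))
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

## ------------------------------------------------------- classification

## State map of a genotype profile: named character vector, key -> derived
## payload ("" for indels, alt base for SNPs). Reference state = key absent.
genotype_state <- function(profile) {
  v <- profile$variants
  if (!nrow(v)) return(character(0))
  key <- mutation_site_key(v)
  val <- ifelse(v$kind %in% c("transition", "transversion"), v$alt, "+")
  stats::setNames(val, key)
}

## Items expected on the branch parent -> node: data.frame describing, for
## every site the branch changes, the state expected in a descendant.
branch_expectation <- function(tree, node, ref) {
  parent <- tree$nodes[[node]]$parent
  gu <- genotype_state(expected_genotype(tree, parent, ref))
  gv <- genotype_state(expected_genotype(tree, node, ref))
  keys <- union(names(gu), names(gv))
  changed <- vapply(keys, function(k) !identical(gu[k][[1]], gv[k][[1]]), logical(1))
  keys <- keys[changed]
  if (!length(keys))
    return(data.frame(key = character(0), expect = character(0),
                      position = integer(0), span_end = integer(0),
                      kind = character(0), stringsAsFactors = FALSE))
  kind <- sub(":.*", "", keys)
  posfield <- sub("^[a-z]+:", "", keys)
  pos <- as.integer(sub("[-.].*$", "", sub("^([0-9]+).*$", "\\1", posfield)))
  span <- ifelse(kind == "del",
                 as.integer(sub("^[0-9]+-([0-9]+)$", "\\1", posfield)), pos)
  data.frame(key = keys,
             expect = ifelse(is.na(gv[keys]), "", gv[keys]),  # "" = reference
             position = pos, span_end = span,
             kind = c(snp = "snp", ins = "insertion", del = "deletion")[kind],
             stringsAsFactors = FALSE)
}

## Evaluate one branch expectation against a sample profile.
evaluate_branch <- function(exp_items, profile, mask) {
  st <- genotype_state(profile)
  n <- nrow(exp_items)
  callable <- logical(n); derived <- logical(n)
  for (i in seq_len(n)) {
    it <- exp_items[i, ]
    span <- it$position:it$span_end
    covered <- all(profile_covers(profile, span))
    unc <- any(profile$uncertain$position %in% span)
    masked <- if (it$kind == "snp") it$position %in% mask$snp_positions
              else any(it$position <= mask$indel_ranges$end &
                       it$span_end >= mask$indel_ranges$start)
    callable[i] <- covered && !unc && !masked
    if (!callable[i]) next
    have <- st[it$key][[1]]
    if (it$expect == "") {
      # back-mutation to the reference state: derived = no variant there,
      # and for SNPs no conflicting third state either
      derived[i] <- is.na(have)
    } else {
      derived[i] <- !is.na(have) && identical(have, it$expect)
    }
  }
  list(n_expected = n, n_callable = sum(callable), n_derived = sum(derived),
       callable = callable, derived = derived,
       fully = sum(callable) >= 1L && all(derived[callable]))
}

#' Classify a profile against a haplogroup tree
#'
#' Implements the definitive-placement rule: starting at the root, the walk
#' descends into a child only when all callable branch variants (inside the
#' covered range, not heteroplasmic, not masked, not annotation-only) are
#' derived and at least one is callable; when both a branch and its sister
#' qualify, or neither, the walk stops at the parent. The assignment is
#' definitive when every variant on the accepted path was callable and
#' derived, no sister branch qualified anywhere on the path, and every child
#' branch of the assigned clade is
#' positively excluded (all of its variants callable and ancestral; vacuous
#' for terminal clades). Heteroplasmic sites compatible with the derived base
#' count as not callable.
#'
#' @param p an `mt_profile` (the default hotspot mask is applied first;
#'   masking is idempotent).
#' @param tree an `mt_haplotree`.
#' @param ref an `mt_reference`.
#' @param mask an `mt_site_mask`.
#' @return an object of class `mt_classification`: list with `assigned`,
#'   `definitive`, `per_branch` (one row per evaluated branch), `missing`
#'   (expected but ancestral tokens), `ineligible` (expected but not callable
#'   tokens), and `conflicting_sister`.
#' @export
classify <- function(p, tree, ref = mt_reference(), mask = site_mask()) {
  stopifnot(inherits(p, "mt_profile"), inherits(tree, "mt_haplotree"))
  if (length(tree$nodes) == 0) stop("empty haplogroup tree", call. = FALSE)
  p <- apply_mask(p, mask)

  per_branch <- list()
  missing <- character(0); ineligible <- character(0)
  conflicting <- character(0)
  cur <- tree$root
  path_ok <- TRUE
  repeat {
    kids <- tree$nodes[[cur]]$children
    if (!length(kids)) { children_excluded <- TRUE; break }
    evals <- lapply(kids, function(k) {
      items <- branch_expectation(tree, k, ref)
      ev <- evaluate_branch(items, p, mask)
      ev$items <- items
      ev
    })
    names(evals) <- kids
    fully <- vapply(evals, `[[`, logical(1), "fully")
    for (k in kids) {
      ev <- evals[[k]]
      per_branch[[length(per_branch) + 1L]] <- data.frame(
        branch = k, parent = cur, n_expected = ev$n_expected,
        n_callable = ev$n_callable, n_derived = ev$n_derived,
        fully_derived = ev$fully, on_path = FALSE, stringsAsFactors = FALSE)
      ineligible <- c(ineligible, branch_item_tokens(ev, !ev$callable))
    }
    if (sum(fully) == 1L) {
      chosen <- kids[fully]
      for (k in setdiff(kids, chosen)) {
        ev <- evals[[k]]
        conflicting <- c(conflicting,
                         branch_item_tokens(ev, ev$callable & ev$derived))
        missing <- c(missing, branch_item_tokens(ev, ev$callable & !ev$derived))
      }
      per_branch[[length(per_branch)]]$on_path <-
        FALSE  # placeholder; fixed below by name
      for (i in seq_along(per_branch))
        if (per_branch[[i]]$branch == chosen && per_branch[[i]]$parent == cur)
          per_branch[[i]]$on_path <- TRUE
      cur <- chosen
    } else {
      if (sum(fully) > 1L) {
        path_ok <- FALSE
        for (k in kids[fully])
          conflicting <- c(conflicting, branch_item_tokens(
            evals[[k]], evals[[k]]$callable & evals[[k]]$derived))
      }
      for (k in kids) {
        ev <- evals[[k]]
        missing <- c(missing, branch_item_tokens(ev, ev$callable & !ev$derived))
      }
      # positive exclusion: every child fully callable and fully ancestral
      children_excluded <- sum(fully) == 0L && all(vapply(evals, function(ev)
        ev$n_callable == ev$n_expected && ev$n_derived == 0L, logical(1)))
      break
    }
  }
  pb <- if (length(per_branch)) do.call(rbind, per_branch) else
    data.frame(branch = character(0), parent = character(0),
               n_expected = integer(0), n_callable = integer(0),
               n_derived = integer(0), fully_derived = logical(0),
               on_path = logical(0))
  path_rows <- pb[pb$on_path, , drop = FALSE]
  path_fully_callable <- !nrow(path_rows) ||
    all(path_rows$n_callable == path_rows$n_expected)
  structure(list(
    assigned = cur,
    definitive = path_ok && children_excluded && path_fully_callable,
    per_branch = pb,
    missing = unique(missing),
    ineligible = unique(ineligible),
    conflicting_sister = unique(conflicting)
  ), class = "mt_classification")
}

branch_item_tokens <- function(ev, which) {
  it <- ev$items[which, , drop = FALSE]
  if (!nrow(it)) return(character(0))
  ifelse(it$expect == "", paste0(it$key, "(ancestral)"),
         ifelse(it$kind == "snp",
                paste0(it$position, it$expect), sub("^[a-z]+:", "", it$key)))
}

#' @export
print.mt_classification <- function(x, ...) {
  cat("<mt_classification> assigned ", x$assigned,
      if (x$definitive) " (definitive)" else " (ambiguous)", "\n", sep = "")
  if (length(x$conflicting_sister))
    cat("  conflicting sister variants: ",
        paste(x$conflicting_sister, collapse = " "), "\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------- monophyly

#' Audit a tip group for monophyly
#'
#' @param sample_tree a rooted `phylo` tree.
#' @param group character vector of tip labels.
#' @param label name of the audited group.
#' @return an object of class `mt_monophyly`: list with `label`,
#'   `is_monophyletic`, `offending_samples` (tips of the smallest containing
#'   clade that are outside the group), and `smallest_containing_clade`
#'   (internal node number in `sample_tree`).
#' @export
check_monophyly <- function(sample_tree, group, label = "group") {
  stopifnot(inherits(sample_tree, "phylo"))
  bad <- setdiff(group, sample_tree$tip.label)
  if (length(bad))
    stop("unknown tips: ", paste(bad, collapse = ", "), call. = FALSE)
  if (length(group) <= 1L || setequal(group, sample_tree$tip.label)) {
    return(structure(list(label = label, is_monophyletic = TRUE,
                          offending_samples = character(0),
                          smallest_containing_clade = NA_integer_),
                     class = "mt_monophyly"))
  }
  mrca <- ape::getMRCA(sample_tree, group)
  clade_tips <- ape::extract.clade(sample_tree, mrca)$tip.label
  offending <- setdiff(clade_tips, group)
  structure(list(label = label,
                 is_monophyletic = length(offending) == 0L,
                 offending_samples = offending,
                 smallest_containing_clade = mrca),
            class = "mt_monophyly")
}

#' @export
print.mt_monophyly <- function(x, ...) {
  cat("<mt_monophyly> ", x$label, ": ",
      if (x$is_monophyletic) "monophyletic"
      else paste0("NOT monophyletic (", length(x$offending_samples),
                  " intruding tip(s))"), "\n", sep = "")
  invisible(x)
}

## -------------------------------------------------------- restructuring

#' Rename haplogroups (nomenclature restructuring)
#'
#' Applies an old-to-new label map (for example elevating a misplaced
#' subclade to a new sister haplogroup), preserving every branch's defining
#' variants and the tree shape, and attaches an old/new audit table.
#'
#' @param tree an `mt_haplotree`.
#' @param map data frame with columns `old`, `new`.
#' @return the relabeled `mt_haplotree`, with attribute `audit`.
#' @export
restructure <- function(tree, map) {
  stopifnot(inherits(tree, "mt_haplotree"))
  if (is.null(map) || nrow(map) == 0) {
    attr(tree, "audit") <- data.frame(old = character(0), new = character(0))
    return(tree)
  }
  if (anyDuplicated(map$old))
    stop("rename map must be injective on old labels", call. = FALSE)
  unknown <- setdiff(map$old, names(tree$nodes))
  if (length(unknown))
    stop("rename of unknown haplogroup(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  untouched <- setdiff(names(tree$nodes), map$old)
  clash <- intersect(map$new, untouched)
  if (length(clash))
    stop("rename collides with existing label(s): ",
         paste(clash, collapse = ", "), call. = FALSE)
  lookup <- stats::setNames(map$new, map$old)
  rename <- function(x) ifelse(x %in% names(lookup), lookup[x], x)
  nodes <- lapply(tree$nodes, function(nd) {
    nd$name <- unname(rename(nd$name))
    if (!is.na(nd$parent)) nd$parent <- unname(rename(nd$parent))
    nd$children <- unname(rename(nd$children))
    nd
  })
  names(nodes) <- vapply(nodes, `[[`, character(1), "name")
  out <- structure(list(nodes = nodes, root = unname(rename(tree$root))),
                   class = "mt_haplotree")
  attr(out, "audit") <- data.frame(old = map$old, new = map$new,
                                   stringsAsFactors = FALSE)
  out
}

#' @rdname restructure
#' @param labels character vector of clade labels (e.g. per-sample
#'   assignments) to re-express under the new nomenclature.
#' @export
rename_labels <- function(labels, map) {
  lookup <- stats::setNames(map$new, map$old)
  unname(ifelse(labels %in% names(lookup), lookup[labels], labels))
}
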