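## End-to-end discovery pipeline: classify -> date -> collapse -> annotate
## -> clade table, with stage-tagged errors, resolved-config provenance and
## deterministic outputs.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Resolve a pipeline configuration
#'
#' @param config a list, or a path to a YAML file with the same fields:
#'   `profiles` (HSD path) and/or `alignment` (FASTA path), `haplotree`
#'   (JSON/TSV path; default the packaged L5'7 system), `out_dir`, `seed`,
#'   `steps`, `thin`, `topology`, `clock_mode`, `skyline_groups`,
#'   `collapse_threshold`, `informative_threshold`.
#' @return the resolved config list with defaults filled in.
#' @export
resolve_config <- function(config) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs needs the 'yaml' package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  defaults <- list(haplotree = NULL, profiles = NULL, alignment = NULL,
                   tree = NULL, out_dir = NULL, seed = NULL, steps = 2000L,
                   thin = NULL,
                   topology = NULL, clock_mode = "sample",
                   skyline_groups = 3L, collapse_threshold = 0.5,
                   informative_threshold = 0.9)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(cfg$topology))
    cfg$topology <- if (is.null(cfg$tree)) "nni" else "fixed"
  if (is.null(cfg$out_dir)) stop("config needs out_dir", call. = FALSE)
  if (is.null(cfg$seed)) stop("config needs seed", call. = FALSE)
  if (is.null(cfg$profiles) && is.null(cfg$alignment))
    stop("config needs profiles and/or alignment", call. = FALSE)
  cfg
}

## strictly-increasing internal heights for an hclust-derived starting tree
as_dated_tree <- function(hc, rate) {
  tr <- ape::as.phylo(hc)
  tr$edge.length <- tr$edge.length / rate
  h <- node_heights(tr)
  ntip <- ape::Ntip(tr)
  internal <- ntip + seq_len(tr$Nnode)
  eps <- max(h[internal], 1 / rate * 1e-6) * 1e-5
  h[internal] <- h[internal] + rank(h[internal], ties.method = "first") * eps
  # heights must respect parent > child after jitter
  repeat {
    bad <- h[tr$edge[, 1]] <= h[tr$edge[, 2]]
    if (!any(bad)) break
    h[tr$edge[bad, 1]] <- h[tr$edge[bad, 2]] + eps
  }
  tr$edge.length <- h[tr$edge[, 1]] - h[tr$edge[, 2]]
  tr
}

label_clades <- function(tree, assignments, htree) {
  # assignments: named vector sample -> haplogroup
  keys <- clade_keys(tree)
  ntip <- ape::Ntip(tree)
  out <- list()
  for (hg in setdiff(names(htree$nodes), htree$root)) {
    in_clade <- names(assignments)[vapply(assignments, function(a)
      hg %in% root_path(htree, a), logical(1))]
    in_clade <- intersect(in_clade, tree$tip.label)
    if (!length(in_clade)) next
    node <- if (length(in_clade) == 1L) {
      which(tree$tip.label == in_clade)
    } else {
      key <- paste(sort(in_clade), collapse = "|")
      hit <- which(keys == key)
      if (!length(hit)) next  # not monophyletic in the sample tree
      ntip + hit
    }
    out[[hg]] <- node
  }
  out
}

#' Run the full discovery pipeline
#'
#' Executes the complete workflow on one dataset: classify every profile
#' against the haplogroup tree, infer a dated tree by strict-clock MCMC
#' (NNI topology search from a UPGMA start, skyline tree prior), summarise
#' the maximum clade credibility tree, collapse weakly supported nodes,
#' reconstruct ancestral sequences, extract per-branch synapomorphies, and
#' emit a clade report table. All outputs (classification TSV, clade table
#' TSV, MCC tree in NEXUS and newick, posterior trace, resolved config with
#' seed) are written under `out_dir`; a failure raises a stage-tagged error
#' and leaves the outputs of completed stages in place. Reruns with the same
#' config and seed are byte-identical.
#'
#' @param config list or YAML path; see [resolve_config()].
#' @return invisibly, a list with `classifications`, `run` (the `mt_mcmc`),
#'   `mcc`, `collapsed`, `synapomorphies`, `clade_table`, `paths`.
#' @export
run_discovery <- function(config) {
  cfg <- resolve_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- mt_reference()
  htree <- stage("load", if (is.null(cfg$haplotree)) l5p7_haplotree()
                 else read_haplotree(cfg$haplotree))

  loaded <- stage("load", {
    if (!is.null(cfg$profiles)) {
      profiles <- read_hsd(cfg$profiles)
      names(profiles) <- vapply(profiles, `[[`, character(1), "sample_id")
      aln <- t(vapply(profiles, function(p)
        apply_variants(ref, p$variants)$bases, character(MT_GENOME_LENGTH)))
      rownames(aln) <- names(profiles)
    } else {
      aln <- read_alignment(cfg$alignment)
      profiles <- lapply(rownames(aln), function(id)
        call_variants(aln[id, ], ref, sample_id = id))
      names(profiles) <- rownames(aln)
    }
    list(profiles = profiles, aln = aln)
  })
  profiles <- loaded$profiles
  aln <- loaded$aln

  classifications <- stage("classify", {
    rows <- lapply(profiles, function(p) {
      cl <- classify(p, htree, ref)
      data.frame(sample_id = p$sample_id, assigned = cl$assigned,
                 definitive = cl$definitive,
                 n_conflicting = length(cl$conflicting_sister),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })

  prior <- average_rate_prior()
  run <- stage("date", {
    tr0 <- if (!is.null(cfg$tree)) {
      tr <- if (inherits(cfg$tree, "phylo")) cfg$tree
            else ape::read.tree(cfg$tree)
      if (!setequal(tr$tip.label, rownames(aln)))
        stop("fixed-topology tree tips do not match the samples")
      tr
    } else {
      d <- ape::dist.dna(ape::as.DNAbin(tolower(aln)), model = "JC69",
                         pairwise.deletion = TRUE)
      as_dated_tree(stats::hclust(d, "average"), prior$mean_rate)
    }
    mcmc_sample(aln, tr0, steps = cfg$steps, seed = cfg$seed,
                parts = partition_sites(ref), clock_prior = prior,
                thin = cfg$thin, topology = cfg$topology,
                tree_prior = "skyline", skyline_groups = cfg$skyline_groups,
                clock_mode = cfg$clock_mode)
  })
  mcc <- stage("summarize", summarize_mcc(run))
  collapsed <- stage("collapse",
                     collapse_low_support(mcc$tree, cfg$collapse_threshold))
  anc <- stage("annotate",
               reconstruct_ancestral(collapsed, profiles, ref, method = "ML"))
  synapomorphies <- stage("annotate", extract_synapomorphies(anc))

  clade_table <- stage("report", {
    assignments <- stats::setNames(classifications$assigned,
                                   classifications$sample_id)
    nodes <- label_clades(collapsed, assignments, htree)
    ntip <- ape::Ntip(collapsed)
    h <- node_heights(collapsed)
    keys <- clade_keys(collapsed)
    summary <- mcc$summary
    rows <- lapply(names(nodes), function(hg) {
      nd <- nodes[[hg]]
      age <- h[nd]
      key <- if (nd > ntip) keys[nd - ntip] else NA
      srow <- if (!is.na(key)) summary[summary$clade == key, , drop = FALSE]
              else summary[0, ]
      data.frame(clade = hg, parent = htree$nodes[[hg]]$parent,
                 mean_age = if (nrow(srow)) srow$mean_age else age,
                 hpd_upper = if (nrow(srow)) srow$hpd_upper else NA_real_,
                 hpd_lower = if (nrow(srow)) srow$hpd_lower else NA_real_,
                 posterior = if (nrow(srow)) srow$posterior else NA_real_,
                 stringsAsFactors = FALSE)
    })
    clades <- do.call(rbind, rows)
    # mutations on the branch subtending each clade's node
    muts <- lapply(names(nodes), function(hg) {
      nd <- nodes[[hg]]
      nm <- if (nd <= ntip) collapsed$tip.label[nd] else paste0("node", nd)
      synapomorphies[[nm]]
    })
    names(muts) <- names(nodes)
    build_clade_table(clades, muts)
  })

  paths <- stage("report", {
    p <- list(
      classifications = file.path(cfg$out_dir, "classifications.tsv"),
      clade_table = file.path(cfg$out_dir, "clade_table.tsv"),
      trace = file.path(cfg$out_dir, "trace.tsv"),
      config = file.path(cfg$out_dir, "resolved_config.json"))
    write.table(classifications, p$classifications, sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(clade_table, p$clade_table, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_trace(run, p$trace)
    p$mcc <- write_mcc(mcc, file.path(cfg$out_dir, "mcc"))
    cfg_out <- lapply(cfg[!vapply(cfg, is.null, logical(1))], function(x)
      if (is.atomic(x)) x else class(x)[1])
    jsonlite::write_json(cfg_out, p$config, auto_unbox = TRUE, pretty = TRUE)
    p
  })

  invisible(list(classifications = classifications, run = run, mcc = mcc,
                 collapsed = collapsed, synapomorphies = synapomorphies,
                 clade_table = clade_table, paths = paths))
}
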