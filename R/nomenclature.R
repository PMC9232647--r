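#' @useDynLib haplomt, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize rexp runif rgamma quantile sd var acf rbinom
#' @importFrom utils read.table write.table head tail
NULL

MT_GENOME_LENGTH <- 16569L

TRANSITION_PAIRS <- c(A = "G", G = "A", C = "T", T = "C")

is_transition <- function(ref, alt) TRANSITION_PAIRS[ref] == toupper(alt)

empty_mutations <- function() {
  structure(
    data.frame(
      kind = character(0), position = integer(0), span_end = integer(0),
      ref = character(0), alt = character(0), ins_index = integer(0),
      ins_unspecified = logical(0), back = integer(0), parens = logical(0),
      token = character(0), stringsAsFactors = FALSE
    ),
    class = c("mt_mutations", "data.frame")
  )
}

#' Parse PhyloTree-style mutation tokens
#'
#' Parses mtDNA variant tokens in PhyloTree notation: SNPs (`T3423C`,
#' transversions with a lowercase target such as `A12021c`), back mutations
#' flagged with a trailing `!` (`T146C!`), insertions (`459.1C`, `573.XC` for
#' an unspecified copy count), and deletions (`A249d`, `8281-8289d`).
#' Surrounding parentheses (PhyloTree's "unstable" annotation) are honoured
#' and preserved on serialization; `X`-indexed insertions are flagged as
#' annotation-only and excluded from likelihoods and synapomorphy counts.
#'
#' @param tokens character vector of whitespace-free tokens.
#' @return an object of class `mt_mutations`: a data frame with one row per
#'   token and columns `kind`, `position`, `span_end`, `ref`, `alt`,
#'   `ins_index`, `ins_unspecified`, `back`, `parens`, `token` (the canonical
#'   serialization).
#' @examples
#' parse_mutations(c("T3423C", "459.1C", "8281-8289d", "T146C!", "A12021c"))
#' @export
parse_mutations <- function(tokens) {
  if (length(tokens) == 0) return(empty_mutations())
  stopifnot(is.character(tokens))
  rows <- lapply(tokens, parse_one_mutation)
  out <- do.call(rbind, rows)
  class(out) <- c("mt_mutations", "data.frame")
  out
}

#' @rdname parse_mutations
#' @param token a single token.
#' @export
parse_mutation <- function(token) parse_mutations(token)

parse_one_mutation <- function(token) {
  raw <- token
  if (!nzchar(token) || grepl("\\s", token))
    stop("malformed mutation token: '", raw, "'", call. = FALSE)
  parens <- FALSE
  if (grepl("^\\(.*\\)$", token)) {
    parens <- TRUE
    token <- substr(token, 2L, nchar(token) - 1L)
  }
  row <- NULL
  m <- regmatches(token, regexec("^([0-9]+)\\.([0-9]+|X)([ACGT]+)$", token))[[1]]
  if (length(m)) {
    pos <- as.integer(m[2])
    unspec <- identical(m[3], "X")
    row <- data.frame(
      kind = "insertion", position = pos, span_end = pos,
      ref = NA_character_, alt = m[4],
      ins_index = if (unspec) NA_integer_ else as.integer(m[3]),
      ins_unspecified = unspec, back = 0L, parens = parens,
      token = "", stringsAsFactors = FALSE
    )
  }
  if (is.null(row)) {
    m <- regmatches(token, regexec("^([ACGT]?)([0-9]+)(-([0-9]+))?[dD](!*)$", token))[[1]]
    if (length(m)) {
      pos <- as.integer(m[3])
      span <- if (nzchar(m[5])) as.integer(m[5]) else pos
      if (nzchar(m[2]) && nzchar(m[5]))
        stop("malformed mutation token: '", raw,
             "' (range deletions carry no reference base)", call. = FALSE)
      row <- data.frame(
        kind = "deletion", position = pos, span_end = span,
        ref = if (nzchar(m[2])) m[2] else NA_character_, alt = NA_character_,
        ins_index = NA_integer_, ins_unspecified = FALSE,
        back = nchar(m[6]), parens = parens, token = "",
        stringsAsFactors = FALSE
      )
    }
  }
  if (is.null(row)) {
    m <- regmatches(token, regexec("^([ACGT])([0-9]+)([ACGTacgt])(!*)$", token))[[1]]
    if (length(m)) {
      ref <- m[2]; alt <- m[4]; pos <- as.integer(m[3])
      if (ref == toupper(alt))
        stop("malformed mutation token: '", raw,
             "' (reference and derived base identical)", call. = FALSE)
      kind <- if (is_transition(ref, alt)) "transition" else "transversion"
      row <- data.frame(
        kind = kind, position = pos, span_end = pos,
        ref = ref, alt = toupper(alt),
        ins_index = NA_integer_, ins_unspecified = FALSE,
        back = nchar(m[5]), parens = parens, token = "",
        stringsAsFactors = FALSE
      )
    }
  }
  if (is.null(row))
    stop("malformed mutation token: '", raw, "'", call. = FALSE)
  if (row$position < 1L || row$span_end > MT_GENOME_LENGTH)
    stop("mutation token '", raw, "' outside reference coordinates 1-",
         MT_GENOME_LENGTH, call. = FALSE)
  if (row$span_end < row$position)
    stop("mutation token '", raw, "' has span end before start", call. = FALSE)
  row$token <- serialize_row(row)
  row
}

serialize_row <- function(r) {
  core <- switch(r$kind,
    transition = paste0(r$ref, r$position, r$alt, strrep("!", r$back)),
    transversion = paste0(r$ref, r$position, tolower(r$alt), strrep("!", r$back)),
    insertion = paste0(r$position, ".",
                       if (r$ins_unspecified) "X" else r$ins_index, r$alt),
    deletion = paste0(
      if (!is.na(r$ref)) r$ref else "",
      r$position,
      if (r$span_end > r$position) paste0("-", r$span_end) else "",
      "d", strrep("!", r$back))
  )
  if (r$parens) paste0("(", core, ")") else core
}

#' Serialize mutations back to PhyloTree tokens
#'
#' Inverse of [parse_mutations()]: `parse_mutations(serialize_mutations(m))`
#' reproduces `m` for every well-formed mutation table.
#'
#' @param m an `mt_mutations` table.
#' @return character vector of canonical tokens.
#' @export
serialize_mutations <- function(m) {
  stopifnot(inherits(m, "mt_mutations"))
  if (nrow(m) == 0) return(character(0))
  vapply(seq_len(nrow(m)), function(i) serialize_row(m[i, , drop = FALSE]),
         character(1))
}

#' @export
print.mt_mutations <- function(x, ...) {
  cat("<mt_mutations> ", nrow(x), " variant(s): ",
      paste(x$token, collapse = " "), "\n", sep = "")
  invisible(x)
}

mutation_site_key <- function(m) {
  # identity key used for matching: position + event class + payload
  ifelse(m$kind == "insertion",
         paste0("ins:", m$position, ".",
                ifelse(m$ins_unspecified, "X", m$ins_index), ":", m$alt),
         ifelse(m$kind == "deletion",
                paste0("del:", m$position, "-", m$span_end),
                paste0("snp:", m$position)))
}

## ---------------------------------------------------------------- profiles

IUPAC_PARTIAL <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Build a sample variant profile
#'
#' A variant profile is a sample's full set of differences from the reference,
#' together with heteroplasmic (IUPAC-uncertain) sites and the covered
#' coordinate range. Uncovered positions are "not callable", which is distinct
#' from reference-equal; classification treats them as ineligible evidence.
#'
#' @param sample_id sample identifier.
#' @param variants an `mt_mutations` table (or character tokens, parsed on the
#'   fly).
#' @param uncertain data frame with columns `position`, `code` (IUPAC).
#' @param coverage coverage specification: a two-column matrix/data frame of
#'   closed 1-based intervals, or a string such as `"16024-576"` (wrap-around
#'   ranges split at the origin), or `NULL` for full coverage.
#' @return an object of class `mt_profile`.
#' @export
mt_profile <- function(sample_id, variants = empty_mutations(),
                       uncertain = NULL, coverage = NULL) {
  if (is.character(variants)) variants <- parse_mutations(variants)
  stopifnot(inherits(variants, "mt_mutations"))
  if (is.null(uncertain))
    uncertain <- data.frame(position = integer(0), code = character(0),
                            stringsAsFactors = FALSE)
  cov <- parse_coverage(coverage)
  p <- structure(
    list(sample_id = sample_id, variants = variants,
         uncertain = uncertain, coverage = cov),
    class = "mt_profile"
  )
  validate_profile(p)
  p
}

parse_coverage <- function(coverage) {
  if (is.null(coverage))
    return(data.frame(start = 1L, end = MT_GENOME_LENGTH))
  if (is.character(coverage)) {
    parts <- unlist(strsplit(coverage, ";", fixed = TRUE))
    ivs <- lapply(parts, function(s) {
      s <- trimws(s)
      if (grepl("^[0-9]+$", s)) return(data.frame(start = as.integer(s), end = as.integer(s)))
      m <- regmatches(s, regexec("^([0-9]+)-([0-9]+)$", s))[[1]]
      if (!length(m)) stop("bad coverage range: '", s, "'", call. = FALSE)
      a <- as.integer(m[2]); b <- as.integer(m[3])
      if (a <= b) data.frame(start = a, end = b)
      else rbind(data.frame(start = a, end = MT_GENOME_LENGTH),  # wrap at origin
                 data.frame(start = 1L, end = b))
    })
    coverage <- do.call(rbind, ivs)
  }
  coverage <- as.data.frame(coverage)
  names(coverage)[1:2] <- c("start", "end")
  coverage$start <- as.integer(coverage$start)
  coverage$end <- as.integer(coverage$end)
  stopifnot(all(coverage$start >= 1L), all(coverage$end <= MT_GENOME_LENGTH),
            all(coverage$start <= coverage$end))
  coverage[order(coverage$start), , drop = FALSE]
}

profile_covers <- function(p, positions) {
  cov <- p$coverage
  vapply(positions, function(x) any(x >= cov$start & x <= cov$end), logical(1))
}

validate_profile <- function(p) {
  v <- p$variants
  snp <- v[v$kind %in% c("transition", "transversion"), , drop = FALSE]
  if (anyDuplicated(snp$position))
    stop("profile '", p$sample_id, "': two SNP variants share position ",
         paste(unique(snp$position[duplicated(snp$position)]), collapse = ", "),
         call. = FALSE)
  if (nrow(v) && !all(profile_covers(p, v$position) & profile_covers(p, v$span_end)))
    stop("profile '", p$sample_id, "': variants outside covered range",
         call. = FALSE)
  if (nrow(p$uncertain) && !all(profile_covers(p, p$uncertain$position)))
    stop("profile '", p$sample_id, "': uncertain sites outside covered range",
         call. = FALSE)
  invisible(p)
}

#' @export
print.mt_profile <- function(x, ...) {
  cat("<mt_profile> ", x$sample_id, ": ", nrow(x$variants), " variant(s), ",
      nrow(x$uncertain), " uncertain site(s), covered ",
      paste(paste0(x$coverage$start, "-", x$coverage$end), collapse = ";"),
      "\n", sep = "")
  invisible(x)
}

## ------------------------------------------------------------------ masks

#' Hotspot site mask
#'
#' The default mask removes the four most recurrent SNP positions
#' (152, 195, 310, 16519) and ignores indels at the recurrent or
#' alignment-ambiguous ranges 309-315, 515-524, 3105-3107, 16183-16184 and
#' 16193, the standard homoplasy hotspots of the mtDNA control region and the
#' 3107 reference spacer.
#'
#' @param snp_positions integer vector of SNP positions to exclude.
#' @param indel_ranges two-column matrix/data frame of closed intervals within
#'   which insertions and deletions are ignored.
#' @return an object of class `mt_site_mask`.
#' @export
site_mask <- function(snp_positions = c(152L, 195L, 310L, 16519L),
                      indel_ranges = default_indel_ranges()) {
  ir <- as.data.frame(indel_ranges)
  names(ir)[1:2] <- c("start", "end")
  structure(list(snp_positions = as.integer(snp_positions),
                 indel_ranges = ir),
            class = "mt_site_mask")
}

default_indel_ranges <- function() {
  data.frame(start = c(309L, 515L, 3105L, 16183L, 16193L),
             end   = c(315L, 524L, 3107L, 16184L, 16193L))
}

#' Apply a hotspot mask to a profile
#'
#' Removes SNP variants at masked positions and indel variants whose span
#' intersects a masked indel range. Idempotent; never introduces variants.
#'
#' @param p an `mt_profile`.
#' @param mask an `mt_site_mask`; defaults to [site_mask()].
#' @return the masked `mt_profile`.
#' @export
apply_mask <- function(p, mask = site_mask()) {
  stopifnot(inherits(p, "mt_profile"), inherits(mask, "mt_site_mask"))
  v <- p$variants
  if (nrow(v)) {
    is_snp <- v$kind %in% c("transition", "transversion")
    drop_snp <- is_snp & v$position %in% mask$snp_positions
    drop_indel <- !is_snp & vapply(seq_len(nrow(v)), function(i) {
      any(v$position[i] <= mask$indel_ranges$end &
          v$span_end[i] >= mask$indel_ranges$start)
    }, logical(1))
    v <- v[!(drop_snp | drop_indel), , drop = FALSE]
    class(v) <- c("mt_mutations", "data.frame")
  }
  p$variants <- v
  p
}

## -------------------------------------------------- sequence <-> variants

#' Call a variant profile from a coordinate-aligned sequence
#'
#' Compares a 16,569-column aligned sequence to the reference. Gaps (`-`)
#' become deletions, IUPAC ambiguity codes (heteroplasmies) become uncertain
#' sites rather than variants, and `N`/`?` positions are treated as missing,
#' shrinking the covered range. Insertions relative to the reference are
#' supplied as a named list (`"459" = "C"`) and yield one token per inserted
#' base with increasing insertion index.
#'
#' @param seq character vector of length 16,569 (single characters), or a
#'   length-1 string.
#' @param ref an `mt_reference` (see [mt_reference()]).
#' @param sample_id sample identifier.
#' @param insertions named list or character vector: names are 1-based
#'   anchor positions, values the inserted base string.
#' @return an `mt_profile`.
#' @export
call_variants <- function(seq, ref, sample_id = "sample", insertions = NULL) {
  stopifnot(inherits(ref, "mt_reference"))
  seq <- as_base_vector(seq)
  if (length(seq) != MT_GENOME_LENGTH)
    stop("aligned sequence has length ", length(seq), ", expected ",
         MT_GENOME_LENGTH, call. = FALSE)
  rb <- ref$bases
  missing <- seq %in% c("N", "?")
  uncertain_idx <- which(!missing & seq %in% setdiff(names(IUPAC_PARTIAL),
                                                    c("A", "C", "G", "T", "N")))
  snp_idx <- which(!missing & seq %in% c("A", "C", "G", "T") & seq != rb)
  del_idx <- which(seq == "-")

  tokens <- character(0)
  if (length(snp_idx))
    tokens <- c(tokens, paste0(
      rb[snp_idx], snp_idx,
      ifelse(is_transition(rb[snp_idx], seq[snp_idx]),
             seq[snp_idx], tolower(seq[snp_idx]))))
  if (length(del_idx)) {
    runs <- split(del_idx, cumsum(c(1L, diff(del_idx) != 1L)))
    tokens <- c(tokens, vapply(runs, function(r) {
      if (length(r) == 1L) paste0(rb[r], r, "d")
      else paste0(r[1], "-", r[length(r)], "d")
    }, character(1)))
  }
  if (!is.null(insertions) && length(insertions)) {
    pos <- as.integer(names(insertions))
    for (i in seq_along(pos)) {
      chars <- strsplit(toupper(as.character(insertions[[i]])), "")[[1]]
      tokens <- c(tokens, paste0(pos[i], ".", seq_along(chars), chars))
    }
  }
  variants <- parse_mutations(tokens)
  variants <- variants[order(variants$position, variants$ins_index,
                             na.last = FALSE), , drop = FALSE]
  class(variants) <- c("mt_mutations", "data.frame")

  coverage <- if (any(!missing)) {
    idx <- which(!missing)
    runs <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
    do.call(rbind, lapply(runs, function(r)
      data.frame(start = r[1], end = r[length(r)])))
  } else data.frame(start = integer(0), end = integer(0))

  uncertain <- data.frame(position = uncertain_idx,
                          code = seq[uncertain_idx],
                          stringsAsFactors = FALSE)
  mt_profile(sample_id, variants, uncertain, coverage)
}

as_base_vector <- function(seq) {
  if (length(seq) == 1L && nchar(seq) > 1L) seq <- strsplit(seq, "")[[1]]
  toupper(seq)
}

#' Apply an ordered mutation list to the reference
#'
#' Inverse of [call_variants()]: plays an ordered list of mutations onto the
#' reference sequence. A `!`-flagged SNP applied at a site whose current base
#' equals the token's derived base reverts the site to the token's reference
#' base (cancelling the earlier change); applied at a site still carrying the
#' token's reference base it acts as an ordinary forward change (the
#' convention needed for back mutations whose first event lies outside the
#' clade under study). Insertions with unspecified copy number (`.X`) are
#' annotation-only and skipped.
#'
#' @param ref an `mt_reference`.
#' @param variants `mt_mutations` table or character tokens, in path order.
#' @return a list with `bases` (character vector, deleted positions as `-`)
#'   and `insertions` (named list position -> inserted string).
#' @export
apply_variants <- function(ref, variants) {
  stopifnot(inherits(ref, "mt_reference"))
  if (is.character(variants)) variants <- parse_mutations(variants)
  bases <- ref$bases
  ins <- list()
  conflicts <- character(0)
  for (i in seq_len(nrow(variants))) {
    r <- variants[i, , drop = FALSE]
    if (r$kind %in% c("transition", "transversion")) {
      cur <- bases[r$position]
      if (cur == r$ref) bases[r$position] <- r$alt
      else if (r$back > 0L && cur == r$alt) bases[r$position] <- r$ref
      else conflicts <- c(conflicts, paste0(
        r$token, " (site carries ", cur, ")"))
    } else if (r$kind == "deletion") {
      span <- r$position:r$span_end
      if (any(bases[span] == "-"))
        conflicts <- c(conflicts, paste0(r$token, " (already deleted)"))
      else bases[span] <- "-"
    } else if (r$kind == "insertion") {
      if (r$ins_unspecified) next  # annotation-only
      key <- as.character(r$position)
      cur <- if (is.null(ins[[key]])) "" else ins[[key]]
      if (r$ins_index != nchar(cur) + 1L)
        conflicts <- c(conflicts, paste0(r$token, " (insertion index gap)"))
      else ins[[key]] <- paste0(cur, r$alt)
    }
  }
  if (length(conflicts))
    stop("inconsistent variant set: ", paste(conflicts, collapse = "; "),
         call. = FALSE)
  list(bases = bases, insertions = ins)
}

## ---------------------------------------------------------------- file IO

#' Read and write HSD-style profile tables
#'
#' The HSD format is a tab-delimited table with columns sample id, covered
#' range (semicolon-separated, wrap-around ranges such as `16024-576`
#' allowed), haplogroup (may be `?`), and whitespace-separated variant tokens
#' in the remaining field(s).
#'
#' @param path file path.
#' @return `read_hsd`: a list of `mt_profile` objects, with any haplogroup
#'   column attached as attribute `haplogroup` on each profile.
#' @export
read_hsd <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!grepl("^(#|SampleId\\b)", lines, ignore.case = TRUE)]
  lapply(lines, function(ln) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("bad HSD line: '", ln, "'", call. = FALSE)
    tokens <- unlist(strsplit(paste(f[-(1:3)], collapse = " "), "\\s+"))
    tokens <- tokens[nzchar(tokens)]
    p <- mt_profile(f[1], parse_mutations(tokens), coverage = f[2])
    attr(p, "haplogroup") <- if (f[3] %in% c("?", "")) NA_character_ else f[3]
    p
  })
}

#' @rdname read_hsd
#' @param profiles list of `mt_profile` objects.
#' @export
write_hsd <- function(profiles, path) {
  lines <- vapply(profiles, function(p) {
    rng <- paste(paste0(p$coverage$start, "-", p$coverage$end), collapse = ";")
    hg <- attr(p, "haplogroup")
    paste(c(p$sample_id, rng, if (is.null(hg) || is.na(hg)) "?" else hg,
            serialize_mutations(p$variants)), collapse = "\t")
  }, character(1))
  writeLines(c("SampleId\tRange\tHaplogroup\tPolymorphisms", lines), path)
  invisible(path)
}

#' Read and write aligned FASTA
#'
#' Thin wrappers around \pkg{ape}'s FASTA support returning plain uppercase
#' character matrices (samples in rows), the convention used throughout the
#' package for coordinate-aligned mtDNA.
#'
#' @param path file path.
#' @return `read_alignment`: character matrix with rownames = sample ids.
#' @export
read_alignment <- function(path) {
  d <- ape::read.FASTA(path)
  m <- toupper(as.character(as.matrix(d)))
  m
}

#' @rdname read_alignment
#' @param aln character matrix, rows = samples.
#' @export
write_alignment <- function(aln, path) {
  ape::write.FASTA(ape::as.DNAbin(tolower(aln)), path)
  invisible(path)
}
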