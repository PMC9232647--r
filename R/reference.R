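## Packaged mtDNA reference: a deterministic synthetic stand-in for the
## rCRS/RSRS coordinate system. The base sequence is pseudo-random with
## human-mtDNA-like composition, except that every position named in the
## packaged L5'7 haplogroup fixture is forced to its published ancestral
## base, so that all printed mutation strings apply consistently. The
## functional annotation uses the standard human mtDNA gene map.

.haplomt_cache <- new.env(parent = emptyenv())

## Standard human mtDNA gene map (heavy-strand coordinates, 1-based closed).
mt_gene_map <- function() {
  list(
    coding = data.frame(
      gene = c("ND1", "ND2", "CO1", "CO2", "ATP8", "ATP6", "CO3", "ND3",
               "ND4L", "ND4", "ND5", "ND6", "CYB"),
      start = c(3307L, 4470L, 5904L, 7586L, 8366L, 8527L, 9207L, 10059L,
                10470L, 10760L, 12337L, 14149L, 14747L),
      end   = c(4262L, 5511L, 7445L, 8269L, 8572L, 9207L, 9990L, 10404L,
                10766L, 12137L, 14148L, 14673L, 15887L)
    ),
    trna = data.frame(
      start = c(577L, 1602L, 3230L, 4263L, 4329L, 4402L, 5512L, 5587L, 5657L,
                5761L, 5826L, 7446L, 7518L, 8295L, 9991L, 10405L, 12138L,
                12207L, 12266L, 14674L, 15888L, 15956L),
      end   = c(647L, 1670L, 3304L, 4331L, 4400L, 4469L, 5579L, 5655L, 5729L,
                5826L, 5891L, 7514L, 7585L, 8364L, 10058L, 10469L, 12206L,
                12265L, 12336L, 14742L, 15953L, 16023L)
    ),
    hvs = data.frame(
      segment = c("HVS-I", "HVS-II", "HVS-III"),
      start = c(16024L, 57L, 438L),
      end   = c(16569L, 372L, 574L)
    )
  )
}

## Per-position functional class over the whole genome.
mt_annotation <- function() {
  if (!is.null(.haplomt_cache$annotation)) return(.haplomt_cache$annotation)
  gm <- mt_gene_map()
  cls <- rep("other", MT_GENOME_LENGTH)
  for (i in seq_len(nrow(gm$hvs)))
    cls[gm$hvs$start[i]:gm$hvs$end[i]] <- "HVS"
  for (i in seq_len(nrow(gm$trna)))
    cls[gm$trna$start[i]:gm$trna$end[i]] <- "tRNA"
  for (i in seq_len(nrow(gm$coding))) {
    span <- gm$coding$start[i]:gm$coding$end[i]
    span <- span[!cls[span] %in% c("codon1", "codon2", "codon3")]
    cls[span] <- paste0("codon", ((span - gm$coding$start[i]) %% 3L) + 1L)
  }
  .haplomt_cache$annotation <- cls
  cls
}

## Small multiplicative congruential stream, independent of R's RNG, so that
## building the reference never perturbs user-visible random state.
lcg_stream <- function(n, seed = 20220527L) {
  x <- as.double(seed)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- (1103515245 * x + 12345) %% 2147483648
    out[i] <- x / 2147483648
  }
  out
}

#' The packaged mtDNA reference
#'
#' Returns the package's 16,569-position reference: a deterministic synthetic
#' stand-in for the rCRS/RSRS coordinate system (the true reference sequence
#' is not redistributed with the package). Base composition matches the human
#' mtDNA heavy strand, and every position named in the packaged L5'7
#' haplogroup fixture carries its published ancestral base so that the
#' printed mutation strings of the worked examples apply without conflict.
#' The per-position functional annotation (codon positions 1-3 from the
#' standard gene map, tRNA genes, hypervariable segments, other non-coding)
#' uses real human mtDNA gene coordinates.
#'
#' @return an object of class `mt_reference` with fields `name`, `bases`
#'   (character vector of length 16,569) and `annotation` (parallel character
#'   vector with levels codon1, codon2, codon3, tRNA, HVS, other).
#' @export
mt_reference <- function() {
  if (!is.null(.haplomt_cache$reference)) return(.haplomt_cache$reference)
  u <- lcg_stream(MT_GENOME_LENGTH)
  # approximate human mtDNA L-strand composition
  bases <- c("A", "C", "G", "T")[findInterval(u, cumsum(c(0.309, 0.313, 0.131))) + 1L]

  fix <- fixture_reference_bases()
  bases[!is.na(fix)] <- fix[!is.na(fix)]

  ref <- structure(
    list(name = "synthetic-rCRS-like", bases = bases,
         annotation = mt_annotation()),
    class = "mt_reference"
  )
  .haplomt_cache$reference <- ref
  ref
}

## Ancestral bases implied by the packaged haplogroup fixture, first token
## along any root-down path winning (paths are internally consistent).
fixture_reference_bases <- function() {
  fix <- rep(NA_character_, MT_GENOME_LENGTH)
  path <- system.file("extdata", "l5p7_haplogroups.json", package = "haplomt")
  if (!nzchar(path)) return(fix)  # during bootstrap before installation
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (node in doc$nodes) {
    toks <- unlist(node$variants)
    if (!length(toks)) next
    m <- parse_mutations(toks)
    snp <- m[!is.na(m$ref) & m$kind %in% c("transition", "transversion"), ]
    keep <- is.na(fix[snp$position])
    fix[snp$position[keep]] <- snp$ref[keep]
    del <- m[m$kind == "deletion" & !is.na(m$ref), ]
    keep <- is.na(fix[del$position])
    fix[del$position[keep]] <- del$ref[keep]
  }
  fix
}

#' @export
print.mt_reference <- function(x, ...) {
  cat("<mt_reference> ", x$name, ", ", length(x$bases), " bp\n", sep = "")
  invisible(x)
}
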