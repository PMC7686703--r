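# Community-state typing of cervicovaginal microbiome abundance tables.

#' Designated Lactobacillus species defining the L community type
#'
#' The four Lactobacilli that dominate a physiological cervicovaginal
#' microbiome. A sample whose combined relative abundance over these species
#' is at least 50\% is typed L (Lactobacilli-dominated), otherwise O (Other).
#' @return character vector of four species names.
#' @export
designatedLactobacilli <- function() {
  c("Lactobacillus crispatus", "Lactobacillus gasseri",
    "Lactobacillus iners", "Lactobacillus jensenii")
}

#' Normalize a taxon count/abundance table to relative abundances
#'
#' Divides each sample row by its total so rows sum to 1. Idempotent on
#' already-normalized input.
#'
#' @param counts non-negative numeric matrix or data.frame, samples as rows,
#'   taxa as columns.
#' @return numeric matrix of relative abundances, rows summing to 1.
#' @examples
#' normalizeAbundance(matrix(c(2, 2, 1, 3), 2, byrow = TRUE,
#'   dimnames = list(c("s1", "s2"), c("A", "B"))))
#' @export
normalizeAbundance <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0, na.rm = TRUE))
    stop("abundance values must be non-negative")
  tot <- rowSums(counts)
  zero <- which(tot == 0 | !is.finite(tot))
  if (length(zero)) {
    ids <- rownames(counts)[zero]
    if (is.null(ids)) ids <- as.character(zero)
    stop("sample(s) with zero total abundance: ",
         paste(ids, collapse = ", "))
  }
  counts / tot
}

#' Assign L/O community-type labels from relative abundances
#'
#' A sample is labelled \code{"L"} when the combined relative abundance of the
#' designated Lactobacillus species reaches at least \code{threshold} (the
#' boundary is inclusive: exactly 50\% is L), and \code{"O"} otherwise.
#' Taxon names are matched after case-folding and whitespace normalization;
#' a synonym map can fold naming variants onto the designated names.
#'
#' @param table relative-abundance matrix (samples x taxa); rows are
#'   renormalized to sum to 1 if they do not already.
#' @param lactobacilli character vector of designated species (default the
#'   four \code{\link{designatedLactobacilli}}).
#' @param threshold L-type cut-off on the summed designated fraction,
#'   in (0, 1); default 0.5.
#' @param synonyms optional named character vector mapping observed taxon
#'   names to canonical ones (\code{c("L. iners" = "Lactobacillus iners")}).
#' @return data.frame with columns \code{sample}, \code{label} ("L"/"O") and
#'   \code{lactobacillusFraction}.
#' @examples
#' tab <- matrix(c(0.6, 0.4, 0.2, 0.8), 2, byrow = TRUE,
#'   dimnames = list(c("s1", "s2"),
#'                   c("Lactobacillus crispatus", "Gardnerella vaginalis")))
#' assignCommunityType(tab)
#' @export
assignCommunityType <- function(table,
                                lactobacilli = designatedLactobacilli(),
                                threshold = 0.5,
                                synonyms = NULL) {
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie strictly inside (0, 1)")
  table <- normalizeAbundance(table)
  taxa <- colnames(table)
  if (is.null(taxa)) stop("abundance table must carry taxon column names")
  canon <- canonicalTaxon(taxa)
  if (!is.null(synonyms)) {
    m <- match(canon, canonicalTaxon(names(synonyms)))
    canon[!is.na(m)] <- canonicalTaxon(synonyms[m[!is.na(m)]])
  }
  want <- canonicalTaxon(lactobacilli)
  hit <- canon %in% want
  missing <- setdiff(want, canon)
  if (length(missing))
    warning("designated taxa absent from the table (contribute 0): ",
            paste(missing, collapse = ", "))
  frac <- rowSums(table[, hit, drop = FALSE])
  ids <- rownames(table)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(table)))
  data.frame(sample = ids,
             label = ifelse(frac >= threshold, "L", "O"),
             lactobacillusFraction = unname(frac),
             stringsAsFactors = FALSE)
}
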