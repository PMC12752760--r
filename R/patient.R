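#' Validate and normalise a six-allele HLA-I genotype
#'
#' A genotype is six allele calls, two per locus (A, B, C); homozygous loci
#' repeat the allele. Names are normalised with [normalizeAllele()].
#'
#' @param alleles character vector of six allele names.
#' @return character vector of six canonical names, ordered A, A, B, B, C, C.
#' @export
hlaGenotype <- function(alleles) {
  if (length(alleles) != 6L)
    stop("a genotype is exactly six HLA-I alleles")
  alleles <- normalizeAllele(alleles)
  loci <- .hlaLocus(alleles)
  counts <- table(factor(loci, c("A", "B", "C")))
  if (any(counts != 2L))
    stop("a genotype needs exactly two alleles per locus A/B/C; got ",
         paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  alleles[order(loci)]
}

#' Read a genotype table
#'
#' TSV with columns `individual_id`, `A1`, `A2`, `B1`, `B2`, `C1`, `C2`.
#'
#' @param path file path.
#' @return data.frame with canonical allele names.
#' @export
readGenotypeTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "A1", "A2", "B1", "B2", "C1", "C2")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("genotype table missing columns: ", paste(miss, collapse = ", "))
  for (col in need[-1]) tab[[col]] <- normalizeAllele(tab[[col]])
  tab[, need]
}

#' Personal minimal affinity over a six-allele genotype
#'
#' The strongest predicted affinity of any of the carrier's six HLA-I
#' alleles for the variant's mutant peptides: the minimum over
#' (window, allele in genotype) cells of the mutant grid, undefined (`NA`)
#' when that minimum is at or above `cutoff`. Duplicated alleles at
#' homozygous loci contribute once.
#'
#' @param genotype six allele names (validated via [hlaGenotype()]).
#' @param matrix an [AffinityMatrix-class]; all genotype alleles must be
#'   among its columns.
#' @param cutoff relevance threshold in nM.
#' @return affinity in nM, or `NA` when no allele binds below `cutoff`.
#' @export
personalMAS <- function(genotype, matrix, cutoff = 500) {
  genotype <- unique(hlaGenotype(genotype))
  missing <- setdiff(genotype, alleleNames(matrix))
  if (length(missing))
    stop("genotype allele(s) absent from the affinity matrix: ",
         paste(missing, collapse = ", "))
  best <- min(mutantAffinities(matrix)[, genotype, drop = FALSE])
  if (best < cutoff) best else NA_real_
}

#' Stratify carriers by personal MAS
#'
#' Four predicted neoantigenic-response strata: High for personal MAS
#' <= 10 nM, Intermediate for (10, 250\] nM, Low for (250, 500) nM, and
#' NoAffinity when no relevant binding exists (undefined MAS). Values at or
#' above 500 nM must be undefined upstream and raise an error.
#'
#' @param personalMas numeric vector of personal MAS values (nM, `NA` for
#'   no relevant binding).
#' @return factor with levels High, Intermediate, Low, NoAffinity.
#' @export
stratifyMAS <- function(personalMas) {
  bad <- !is.na(personalMas) & personalMas >= 500
  if (any(bad))
    stop("personal MAS >= 500 nM should be undefined (NA), got: ",
         paste(personalMas[bad], collapse = ", "))
  out <- ifelse(is.na(personalMas), "NoAffinity",
         ifelse(personalMas <= 10, "High",
         ifelse(personalMas <= 250, "Intermediate", "Low")))
  factor(out, levels = c("High", "Intermediate", "Low", "NoAffinity"))
}

#' Tumour-topology proportions by neoantigenic-response stratum
#'
#' Cross-tabulates first-cancer topologies (cancer-free carriers counted as
#' their own outcome class) against the personal MAS stratum; each
#' non-empty stratum row sums to 1. Empty strata yield a row of `NA`
#' proportions with a message.
#'
#' @param cohort a [CarrierCohort-class] whose data carries a `stratum`
#'   column (from [stratifyMAS()]).
#' @return matrix (stratum x outcome) of proportions; outcome columns are
#'   the tumour topologies plus `"cancer_free"`.
#' @export
stratumTopologyTable <- function(cohort) {
  d <- cohortData(cohort)
  if (!"stratum" %in% names(d))
    stop("cohort needs a 'stratum' column (see stratifyMAS)")
  outcome <- ifelse(d$event, d$topology, "cancer_free")
  strata <- factor(d$stratum, c("High", "Intermediate", "Low", "NoAffinity"))
  tab <- table(strata, factor(outcome, c(.TOPOLOGIES, "cancer_free")))
  prop <- prop.table(tab, margin = 1L)
  empty <- rowSums(tab) == 0L
  if (any(empty))
    message("empty stratum (proportions undefined): ",
            paste(rownames(tab)[empty], collapse = ", "))
  as.matrix(prop)
}
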