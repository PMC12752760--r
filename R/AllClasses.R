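#' Per-variant peptide-by-allele affinity grid
#'
#' An `AffinityMatrix` holds the predicted binding affinities (nM, IC50-like,
#' lower = stronger) of every candidate mutant nonamer of one missense
#' variant against a panel of HLA class I alleles, together with the paired
#' wild-type nonamer affinities. Rows are peptide windows (in order of their
#' 1-based start position in the protein), columns are canonical allele
#' names. The wild-type grid may be empty (0 x 0) when amplitude scoring is
#' not needed.
#'
#' @slot variant canonical HGVS-p label of the variant (e.g. `"p.R175H"`).
#' @slot windowStarts integer vector of 1-based window start positions.
#' @slot mutantPeptides,wildtypePeptides character vectors of nonamers, one
#'   per window; each mutant/wild-type pair differs at exactly one offset.
#' @slot mutant,wildtype numeric matrices (windows x alleles) of affinities
#'   in nM, strictly positive; `wildtype` is either 0 x 0 or the same shape
#'   as `mutant`.
#'
#' @seealso [buildAffinityMatrix()], [computeMAS()], [computeHCS()],
#'   [computeAMS()], [personalMAS()]
#' @exportClass AffinityMatrix
setClass("AffinityMatrix",
  slots = c(
    variant = "character",
    windowStarts = "integer",
    mutantPeptides = "character",
    wildtypePeptides = "character",
    mutant = "matrix",
    wildtype = "matrix"
  )
)

setValidity("AffinityMatrix", function(object) {
  msg <- character()
  m <- object@mutant
  w <- object@wildtype
  if (!is.numeric(m)) msg <- c(msg, "mutant grid must be numeric")
  if (nrow(m) != length(object@windowStarts))
    msg <- c(msg, "mutant grid rows must match windowStarts")
  if (nrow(m) != length(object@mutantPeptides))
    msg <- c(msg, "one mutant peptide per window required")
  if (is.null(colnames(m)) && ncol(m) > 0)
    msg <- c(msg, "mutant grid must carry allele column names")
  if (any(!is.finite(m)) || any(m <= 0))
    msg <- c(msg, "affinities must be finite and > 0 nM")
  if (length(w) > 0) {
    if (!identical(dim(w), dim(m)) || !identical(colnames(w), colnames(m)))
      msg <- c(msg, "wildtype grid must match mutant grid shape and alleles")
    if (any(!is.finite(w)) || any(w <= 0))
      msg <- c(msg, "wild-type affinities must be finite and > 0 nM")
    if (length(object@wildtypePeptides) != nrow(m))
      msg <- c(msg, "one wild-type peptide per window required")
  }
  if (length(msg)) msg else TRUE
})

#' HLA class I allele frequency table
#'
#' Population frequencies of HLA-I alleles at loci A, B and C, the substrate
#' of the World Coverage Score. Per-locus frequency sums may be below 1; the
#' residual mass stands for alleles absent from the table. Construct with
#' [AlleleFrequencyTable()].
#'
#' @slot table data.frame with columns `allele` (canonical name), `locus`
#'   (factor A/B/C) and `frequency` (in \[0,1\]).
#' @seealso [computeWCS()], [simAlleleFrequencies()], [simGenotypes()]
#' @exportClass AlleleFrequencyTable
setClass("AlleleFrequencyTable", slots = c(table = "data.frame"))

setValidity("AlleleFrequencyTable", function(object) {
  tab <- object@table
  msg <- character()
  need <- c("allele", "locus", "frequency")
  if (!all(need %in% names(tab)))
    return(paste("table needs columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(tab$allele)) msg <- c(msg, "alleles must be unique")
  if (!all(tab$locus %in% c("A", "B", "C")))
    msg <- c(msg, "locus must be one of A, B, C")
  if (any(tab$frequency < 0)) msg <- c(msg, "frequencies must be >= 0")
  sums <- tapply(tab$frequency, tab$locus, sum)
  if (any(sums > 1 + 1e-6, na.rm = TRUE))
    msg <- c(msg, "per-locus frequency sum exceeds 1")
  if (length(msg)) msg else TRUE
})

#' Cohort of germline variant carriers
#'
#' One row per individual: the variant carried, the age at first cancer (or
#' the censoring age for cancer-free carriers), the event indicator, the
#' tumour topology of the first cancer and the PNS category of the variant.
#' Optional columns (e.g. the six HLA-I allele calls `A1`..`C2`, a personal
#' MAS stratum) are carried through untouched. Construct with
#' [CarrierCohort()].
#'
#' @slot data data.frame with at least `individual_id`, `variant`, `event`
#'   (logical), `age` (years, >= 0), `topology` and `pns_category`.
#' @seealso [kmOnsetCurve()], [topologyRR()], [simCohort()]
#' @exportClass CarrierCohort
setClass("CarrierCohort", slots = c(data = "data.frame"))

.TOPOLOGIES <- c("adrenal", "brain", "breast", "bones", "soft_tissues",
                 "hematopoietic", "non_LFS")
.PNS_LEVELS <- c("Low", "Intermediate", "High")

setValidity("CarrierCohort", function(object) {
  d <- object@data
  msg <- character()
  need <- c("individual_id", "variant", "event", "age", "topology",
            "pns_category")
  miss <- setdiff(need, names(d))
  if (length(miss))
    return(paste("missing cohort columns:", paste(miss, collapse = ", ")))
  if (!is.logical(d$event)) msg <- c(msg, "event must be logical")
  if (any(d$age < 0)) msg <- c(msg, "ages must be >= 0")
  if (!all(d$topology %in% c(.TOPOLOGIES, "none")))
    msg <- c(msg, "unknown tumour topology")
  bad <- xor(d$topology == "none", !d$event)
  if (any(bad))
    msg <- c(msg, "topology must be 'none' exactly for event-free carriers")
  if (!all(d$pns_category %in% .PNS_LEVELS))
    msg <- c(msg, "pns_category must be Low/Intermediate/High")
  if (length(msg)) msg else TRUE
})
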