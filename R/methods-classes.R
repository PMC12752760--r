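#' Construct an allele-frequency table
#'
#' @param table data.frame with columns `allele`, `locus` (A/B/C) and
#'   `frequency`; allele names are normalised with [normalizeAllele()].
#' @return an [AlleleFrequencyTable-class] object.
#' @examples
#' aft <- AlleleFrequencyTable(data.frame(
#'   allele = c("A*02:01", "HLA-B07:02"),
#'   locus = c("A", "B"), frequency = c(0.28, 0.09)))
#' freqTable(aft)
#' @export
AlleleFrequencyTable <- function(table) {
  table <- as.data.frame(table)
  table$allele <- normalizeAllele(table$allele)
  table$locus <- as.character(table$locus)
  rownames(table) <- NULL
  methods::new("AlleleFrequencyTable", table = table)
}

#' Construct a carrier cohort
#'
#' @param data data.frame of individuals; see [CarrierCohort-class] for the
#'   required columns. `event` may be given as 0/1 and is coerced to logical.
#' @return a [CarrierCohort-class] object.
#' @export
CarrierCohort <- function(data) {
  data <- as.data.frame(data)
  if (!is.logical(data$event)) data$event <- as.logical(data$event)
  data$topology <- as.character(data$topology)
  data$pns_category <- as.character(data$pns_category)
  rownames(data) <- NULL
  methods::new("CarrierCohort", data = data)
}

#' @describeIn AffinityMatrix-class mutant peptide x allele affinity grid (nM).
#' @param x an `AffinityMatrix`.
#' @export
setMethod("mutantAffinities", "AffinityMatrix", function(x) x@mutant)

#' @describeIn AffinityMatrix-class wild-type grid (possibly 0 x 0).
#' @export
setMethod("wildtypeAffinities", "AffinityMatrix", function(x) x@wildtype)

#' @describeIn AffinityMatrix-class allele names of the grid columns.
#' @export
setMethod("alleleNames", "AffinityMatrix", function(x) colnames(x@mutant))

#' @describeIn AffinityMatrix-class HGVS-p label of the scored variant.
#' @export
setMethod("variantLabel", "AffinityMatrix", function(x) x@variant)

#' @describeIn AlleleFrequencyTable-class underlying data.frame
#'   (allele, locus, frequency).
#' @param x an `AlleleFrequencyTable`.
#' @export
setMethod("freqTable", "AlleleFrequencyTable", function(x) x@table)

#' @describeIn AlleleFrequencyTable-class alleles listed in the table.
#' @export
setMethod("alleleNames", "AlleleFrequencyTable", function(x) x@table$allele)

#' @describeIn CarrierCohort-class underlying per-individual data.frame.
#' @param x a `CarrierCohort`.
#' @export
setMethod("cohortData", "CarrierCohort", function(x) x@data)

setMethod("show", "AffinityMatrix", function(object) {
  cat("AffinityMatrix for", object@variant, "\n")
  cat(" ", nrow(object@mutant), "peptide windows x",
      ncol(object@mutant), "HLA-I alleles\n")
  cat("  wild-type grid:",
      if (length(object@wildtype)) "present" else "absent", "\n")
  mas <- suppressWarnings(min(object@mutant))
  cat("  minimum mutant affinity:", format(mas, digits = 4), "nM\n")
})

setMethod("show", "AlleleFrequencyTable", function(object) {
  tab <- object@table
  cat("AlleleFrequencyTable:", nrow(tab), "HLA-I alleles\n")
  for (l in c("A", "B", "C")) {
    rows <- tab$locus == l
    if (any(rows))
      cat(sprintf("  locus %s: %d alleles, frequency mass %.3f\n",
                  l, sum(rows), sum(tab$frequency[rows])))
  }
})

setMethod("show", "CarrierCohort", function(object) {
  d <- object@data
  cat("CarrierCohort:", nrow(d), "individuals,",
      sum(d$event), "with a first cancer\n")
  cat("  PNS categories:",
      paste(sprintf("%s=%d", .PNS_LEVELS,
                    tabulate(factor(d$pns_category, .PNS_LEVELS),
                             length(.PNS_LEVELS))),
            collapse = ", "), "\n")
})

#' Lengths of AffinityMatrix (number of peptide windows)
#' @param x an `AffinityMatrix`.
#' @export
setMethod("length", "AffinityMatrix", function(x) nrow(x@mutant))
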