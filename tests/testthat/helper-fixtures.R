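# small in-code fixtures shared across test files

# bare AffinityMatrix from explicit grids (bypasses record plumbing)
makeAM <- function(mutant, wildtype = NULL, variant = "p.T1000T?") {
  if (is.null(dim(mutant))) mutant <- matrix(mutant, nrow = 1)
  if (is.null(colnames(mutant)))
    colnames(mutant) <- sprintf("HLA-A*%02d:01", seq_len(ncol(mutant)))
  wt <- if (is.null(wildtype)) matrix(numeric(0), 0, 0) else {
    w <- wildtype
    if (is.null(dim(w))) w <- matrix(w, nrow = nrow(mutant))
    colnames(w) <- colnames(mutant)
    w
  }
  nw <- nrow(mutant)
  new("AffinityMatrix",
      variant = variant,
      windowStarts = seq_len(nw),
      mutantPeptides = strrep(LETTERS[seq_len(nw)], 9),
      wildtypePeptides = if (length(wt)) strrep(letters[seq_len(nw)], 9)
                         else character(0),
      mutant = mutant, wildtype = wt)
}

makeFreqs <- function(...) {
  AlleleFrequencyTable(data.frame(...))
}

# random frequency table for property tests
randomFreqs <- function(nPerLocus = 7, mass = 0.9) {
  rows <- do.call(rbind, lapply(c("A", "B", "C"), function(l) {
    f <- rgamma(nPerLocus, 0.5)
    data.frame(allele = sprintf("HLA-%s*%02d:01", l, seq_len(nPerLocus)),
               locus = l, frequency = f / sum(f) * mass)
  }))
  AlleleFrequencyTable(rows)
}

randomPeptide <- function(n = 1) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  vapply(seq_len(n),
         function(i) paste(sample(aa, 9, replace = TRUE), collapse = ""),
         character(1))
}

# minimal valid carrier cohort from parallel vectors
makeCohort <- function(age, event, category,
                       topology = NULL, variant = NULL, stratum = NULL) {
  n <- length(age)
  if (is.null(topology))
    topology <- ifelse(event, "breast", "none")
  d <- data.frame(
    individual_id = sprintf("i%03d", seq_len(n)),
    variant = if (is.null(variant)) "p.R175H" else variant,
    event = as.logical(event), age = age,
    topology = topology, pns_category = category,
    stringsAsFactors = FALSE)
  if (!is.null(stratum)) d$stratum <- stratum
  CarrierCohort(d)
}
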