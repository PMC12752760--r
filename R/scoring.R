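#' Per-variant neoantigenicity metrics
#'
#' The four metrics computed from an [AffinityMatrix-class]:
#'
#' * `computeMAS` — Minimal Affinity Score: the lowest (strongest) predicted
#'   affinity over all (window, allele) cells of the mutant grid, in nM.
#'   Affinities at or above `cutoff` (500 nM by default) are non-relevant,
#'   so a variant whose best cell is >= cutoff has an undefined MAS (`NA`).
#' * `computeHCS` — HLA Count Score: the number of responsive alleles, i.e.
#'   alleles with at least one window below `cutoff`.
#' * `computeAMS` — Amplitude Score: the mutant/wild-type affinity ratio at
#'   the MAS-defining cell (ties broken by the first cell in column-major
#'   order); `NA` when MAS is undefined. `inverted = TRUE` returns the
#'   wild-type/mutant ratio for amplitude-style usage. AMS is reported but
#'   never enters the PNS.
#' * `responsiveAlleles` — the allele names counted by `computeHCS`.
#'
#' @param x an [AffinityMatrix-class].
#' @param cutoff binder threshold in nM; affinities must be strictly below
#'   it to count.
#' @param inverted report wild-type/mutant instead of mutant/wild-type.
#' @return `computeMAS`/`computeAMS` a single numeric (or `NA`), `computeHCS`
#'   an integer, `responsiveAlleles` a character vector.
#' @name variant-metrics
NULL

#' @rdname variant-metrics
#' @export
setMethod("computeMAS", "AffinityMatrix", function(x, cutoff = 500) {
  m <- x@mutant
  if (length(m) == 0L) stop("empty affinity grid")
  best <- min(m)
  if (best < cutoff) best else NA_real_
})

#' @rdname variant-metrics
#' @export
setMethod("computeHCS", "AffinityMatrix", function(x, cutoff = 500) {
  m <- x@mutant
  if (length(m) == 0L) stop("empty affinity grid")
  sum(apply(m, 2L, min) < cutoff)
})

#' @rdname variant-metrics
#' @export
setMethod("responsiveAlleles", "AffinityMatrix", function(x, cutoff = 500) {
  m <- x@mutant
  if (length(m) == 0L) stop("empty affinity grid")
  colnames(m)[apply(m, 2L, min) < cutoff]
})

#' @rdname variant-metrics
#' @export
setMethod("computeAMS", "AffinityMatrix",
          function(x, cutoff = 500, inverted = FALSE) {
  if (length(x@wildtype) == 0L)
    stop("wild-type grid missing; build the matrix with wildtype = TRUE")
  mas <- computeMAS(x, cutoff)
  if (is.na(mas)) return(NA_real_)
  cell <- which.min(x@mutant)
  ratio <- x@mutant[cell] / x@wildtype[cell]
  if (inverted) 1 / ratio else ratio
})

#' World Coverage Score
#'
#' Estimated fraction of the world population carrying at least one
#' responsive HLA-I allele, under Hardy-Weinberg equilibrium within each
#' locus and independence across loci:
#' \deqn{WCS = 1 - \prod_{\ell \in \{A,B,C\}} (1 - s_\ell)^2,}
#' where \eqn{s_\ell} is the summed population frequency of the responsive
#' alleles at locus \eqn{\ell}, clamped to 1. An empty responsive set gives
#' 0; responsive alleles covering the full frequency mass at every locus
#' give 1.
#'
#' @param responsive character vector of responsive allele names (typically
#'   [responsiveAlleles()]); every allele must appear in `freqs`.
#' @param freqs an [AlleleFrequencyTable-class].
#' @return coverage in \[0,1\].
#' @examples
#' aft <- AlleleFrequencyTable(data.frame(
#'   allele = "HLA-A*02:01", locus = "A", frequency = 0.5))
#' computeWCS("HLA-A*02:01", aft)  # 1 - (1 - 0.5)^2 = 0.75
#' @export
computeWCS <- function(responsive, freqs) {
  tab <- freqTable(freqs)
  if (length(responsive) == 0L) return(0)
  responsive <- unique(normalizeAllele(responsive))
  missing <- setdiff(responsive, tab$allele)
  if (length(missing))
    stop("responsive allele(s) absent from the frequency table: ",
         paste(missing, collapse = ", "))
  hit <- tab[tab$allele %in% responsive, , drop = FALSE]
  s <- vapply(c("A", "B", "C"), function(l)
    min(1, sum(hit$frequency[hit$locus == l])), numeric(1))
  1 - prod((1 - s)^2)
}

#' Monte-Carlo check of the coverage model
#'
#' Samples diploid six-allele genotypes from the frequency table (including
#' the unlisted residual mass of each locus) and reports the fraction of
#' individuals carrying at least one responsive allele. Shares its genotype
#' sampler with [simGenotypes()]; used as the simulation cross-check of
#' [computeWCS()].
#'
#' @inheritParams computeWCS
#' @param n number of simulated genotypes.
#' @param seed RNG seed.
#' @return estimated coverage in \[0,1\].
#' @export
wcsMonteCarlo <- function(responsive, freqs, n = 1e5, seed = 1L) {
  responsive <- if (length(responsive)) unique(normalizeAllele(responsive))
                else character(0)
  g <- simGenotypes(freqs, n, seed = seed, listedOnly = FALSE)
  hit <- matrix(as.matrix(g[, -1]) %in% responsive, nrow = nrow(g))
  mean(rowSums(hit) > 0)
}

#' Assign PNS categories
#'
#' Low for PNS < 1, Intermediate for 1 <= PNS <= 2, High for PNS > 2.
#'
#' @param pns numeric vector of PNS values in \[0,3\] (a tolerance of 1e-8
#'   absorbs floating-point fuzz at the ends).
#' @return factor with levels Low, Intermediate, High.
#' @export
categorizePNS <- function(pns) {
  if (any(is.na(pns)) || any(pns < -1e-8 | pns > 3 + 1e-8))
    stop("PNS values must lie in [0, 3]")
  factor(ifelse(pns < 1, "Low", ifelse(pns <= 2, "Intermediate", "High")),
         levels = .PNS_LEVELS)
}

.minmax <- function(x, floor = NULL) {
  lo <- if (is.null(floor)) min(x) else floor
  hi <- max(x)
  if (hi - lo <= 0) {
    message("zero range in a score component; component set to 0 for all")
    return(rep(0, length(x)))
  }
  pmin(1, pmax(0, (x - lo) / (hi - lo)))
}

#' Score a set of variants: MAS/HCS/WCS/AMS, PNS and category
#'
#' Computes the four metrics for every variant's affinity grid, min-max
#' normalises three of them over the scored set — MAS negated before
#' normalisation so stronger binding scores higher, with an undefined MAS
#' entering as the worst value (the cutoff itself), which anchors the floor
#' at component 0; HCS and WCS with their floors anchored at 0 so a
#' no-binder variant scores exactly 0 — and sums them into the Predicted
#' Neoantigenic
#' Score (PNS, 0-3), categorised Low/Intermediate/High. AMS is carried along
#' but excluded from the PNS.
#'
#' @param matrices list of [AffinityMatrix-class] objects.
#' @param freqs an [AlleleFrequencyTable-class] for the coverage score.
#' @param cutoff binder threshold in nM.
#' @param logMAS normalise `-log10(MAS)` instead of `-MAS` (off by default).
#' @param ams compute the amplitude score (needs wild-type grids).
#' @return data.frame with one row per variant (`variant`, `MAS`, `HCS`,
#'   `WCS`, `AMS`, `norm_MAS`, `norm_HCS`, `norm_WCS`, `PNS`, `category`);
#'   the min-max anchors used are attached as `attr(, "anchors")` so a run
#'   can be reproduced or new variants scored against the same anchors.
#' @export
scoreVariants <- function(matrices, freqs, cutoff = 500, logMAS = FALSE,
                          ams = TRUE) {
  if (length(matrices) == 0L) stop("no variants to score")
  mas <- vapply(matrices, computeMAS, numeric(1), cutoff = cutoff)
  hcs <- vapply(matrices, computeHCS, numeric(1), cutoff = cutoff)
  wcs <- vapply(matrices, function(m)
    computeWCS(responsiveAlleles(m, cutoff), freqs), numeric(1))
  amsv <- if (ams) vapply(matrices, computeAMS, numeric(1), cutoff = cutoff)
          else rep(NA_real_, length(matrices))
  masFilled <- ifelse(is.na(mas), cutoff, mas)
  inv <- if (logMAS) -log10(masFilled) else -masFilled
  nm <- .minmax(inv)
  nh <- .minmax(hcs, floor = 0)
  nw <- .minmax(wcs, floor = 0)
  pns <- nm + nh + nw
  out <- data.frame(
    variant = vapply(matrices, variantLabel, character(1)),
    MAS = mas, HCS = as.integer(hcs), WCS = wcs, AMS = amsv,
    norm_MAS = nm, norm_HCS = nh, norm_WCS = nw,
    PNS = pns, category = categorizePNS(pns),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "anchors") <- list(
    mas_scale = if (logMAS) "-log10(nM)" else "-nM",
    mas_min = min(inv),
    mas_max = max(inv),
    hcs_min = 0, hcs_max = max(hcs),
    wcs_min = 0, wcs_max = max(wcs),
    cutoff_nM = cutoff)
  out
}

#' Write a score table and its run manifest
#'
#' `writeScoreTable()` emits the per-variant score data.frame as TSV;
#' `writeRunManifest()` records the normalisation anchors (and any extra
#' fields) as JSON so a scoring run is reproducible.
#'
#' @param scores data.frame from [scoreVariants()].
#' @param path output file.
#' @param extra named list merged into the manifest.
#' @export
writeScoreTable <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeScoreTable
#' @export
writeRunManifest <- function(scores, path, extra = list()) {
  manifest <- c(list(n_variants = nrow(scores)),
                attr(scores, "anchors"), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
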