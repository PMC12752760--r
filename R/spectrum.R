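#' Tumour-topology risk ratios between two carrier groups
#'
#' For each tumour topology among first cancers, compares its proportion
#' between two groups: RR = (cases_a / events_a) / (cases_b / events_b),
#' with a 95% Wald interval on log RR and a p-value from the 2x2 chi-square
#' test, Benjamini-Hochberg-adjusted across topologies. When any cell of
#' the 2x2 table is zero, the Haldane-Anscombe 0.5 continuity correction is
#' applied to the RR and its interval (flagged in the output). Topologies
#' absent from both groups are excluded with a message. Only individuals
#' with an observed first cancer enter the denominators.
#'
#' @param cohort a [CarrierCohort-class].
#' @param groupA,groupB values of `groupBy` defining the two groups
#'   (numerator and reference).
#' @param groupBy cohort column holding the group labels.
#' @param correction p-value adjustment across topologies (default `"BH"`).
#' @return data.frame with one row per testable topology: `topology`,
#'   `cases_a`, `n_a`, `cases_b`, `n_b`, `risk_ratio`, `lcl95`, `ucl95`,
#'   `p_raw`, `p_adjusted`, `continuity` (logical).
#' @export
topologyRR <- function(cohort, groupA, groupB, groupBy = "pns_category",
                       correction = "BH") {
  d <- cohortData(cohort)
  d <- d[d$event, , drop = FALSE]
  a <- d[d[[groupBy]] == groupA, , drop = FALSE]
  b <- d[d[[groupBy]] == groupB, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop("both groups need at least one first cancer")
  Na <- nrow(a); Nb <- nrow(b)
  rows <- lapply(.TOPOLOGIES, function(t) {
    xa <- sum(a$topology == t); xb <- sum(b$topology == t)
    if (xa + xb == 0L) {
      message("topology '", t, "' absent from both groups; not tested")
      return(NULL)
    }
    cont <- xa == 0L || xb == 0L || xa == Na || xb == Nb
    if (cont) {
      rr <- ((xa + 0.5) / (Na + 1)) / ((xb + 0.5) / (Nb + 1))
      se <- sqrt(1 / (xa + 0.5) - 1 / (Na + 1) +
                 1 / (xb + 0.5) - 1 / (Nb + 1))
    } else {
      rr <- (xa / Na) / (xb / Nb)
      se <- sqrt(1 / xa - 1 / Na + 1 / xb - 1 / Nb)
    }
    z <- stats::qnorm(0.975)
    p <- suppressWarnings(
      stats::chisq.test(matrix(c(xa, Na - xa, xb, Nb - xb), 2L)))$p.value
    data.frame(topology = t, cases_a = xa, n_a = Na, cases_b = xb, n_b = Nb,
               risk_ratio = rr,
               lcl95 = exp(log(rr) - z * se), ucl95 = exp(log(rr) + z * se),
               p_raw = p, continuity = cont, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no testable topology")
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = correction)
  rownames(res) <- NULL
  res[, c("topology", "cases_a", "n_a", "cases_b", "n_b", "risk_ratio",
          "lcl95", "ucl95", "p_raw", "p_adjusted", "continuity")]
}

#' Onset-age comparisons by topology across groups
#'
#' Within each tumour topology, the ages at first diagnosis of every pair of
#' groups are compared with a two-sided Wilcoxon rank-sum test;
#' Benjamini-Hochberg adjustment is applied across the whole family of
#' (topology x pair) tests. Strata with fewer than `minN` observations in
#' either group are skipped with a message.
#'
#' @inheritParams topologyRR
#' @param minN minimum observations per group per topology to test.
#' @return data.frame: `topology`, `group1`, `group2`, `n1`, `n2`,
#'   `median1`, `median2`, `p_raw`, `p_adjusted`.
#' @export
topologyAgeCompare <- function(cohort, groupBy = "pns_category",
                               correction = "BH", minN = 2L) {
  d <- cohortData(cohort)
  d <- d[d$event, , drop = FALSE]
  lev <- if (groupBy == "pns_category")
    intersect(.PNS_LEVELS, unique(d[[groupBy]]))
  else sort(unique(as.character(d[[groupBy]])))
  if (length(lev) < 2L) stop("need at least two groups")
  cmb <- utils::combn(lev, 2L)
  rows <- list()
  for (t in intersect(.TOPOLOGIES, unique(d$topology))) {
    for (j in seq_len(ncol(cmb))) {
      g1 <- cmb[1, j]; g2 <- cmb[2, j]
      a1 <- d$age[d$topology == t & d[[groupBy]] == g1]
      a2 <- d$age[d$topology == t & d[[groupBy]] == g2]
      if (length(a1) < minN || length(a2) < minN) {
        message("skipping ", t, " ", g1, " vs ", g2,
                ": fewer than ", minN, " observations per group")
        next
      }
      w <- suppressWarnings(stats::wilcox.test(a1, a2))
      p <- w$p.value
      if (is.nan(p)) p <- 1  # every observation tied: no evidence either way
      rows[[length(rows) + 1L]] <- data.frame(
        topology = t, group1 = g1, group2 = g2,
        n1 = length(a1), n2 = length(a2),
        median1 = stats::median(a1), median2 = stats::median(a2),
        p_raw = p, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) stop("no testable (topology, pair) stratum")
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_raw, method = correction)
  rownames(res) <- NULL
  res
}

#' Correlation between variant PNS and median onset age
#'
#' Correlates per-variant PNS with the median age at first cancer of its
#' carriers, over variants carried by at least `minN` individuals. The
#' correlation method is gated by Shapiro-Wilk normality tests on both
#' variables at `alpha`: Pearson when both pass, Spearman otherwise.
#'
#' @param pns numeric vector of per-variant PNS values.
#' @param medianOnset numeric vector of per-variant median onset ages.
#' @param n integer vector of carriers per variant.
#' @param minN minimum carriers for a variant to enter (the analysis is
#'   designed for frequent variants; 20 by default).
#' @param alpha significance level of the normality gate.
#' @return list with `estimate`, `p.value`, `method` (`"pearson"` or
#'   `"spearman"`), `n_variants`.
#' @export
pnsOnsetCorrelation <- function(pns, medianOnset, n = NULL, minN = 20L,
                                alpha = 0.05) {
  stopifnot(length(pns) == length(medianOnset))
  keep <- if (is.null(n)) rep(TRUE, length(pns)) else n >= minN
  x <- pns[keep]; y <- medianOnset[keep]
  if (length(x) < 3L)
    stop("fewer than 3 variants with at least ", minN, " carriers")
  normal <- function(v) {
    if (length(unique(v)) == 1L) return(FALSE)
    stats::shapiro.test(v)$p.value > alpha
  }
  method <- if (normal(x) && normal(y)) "pearson" else "spearman"
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  list(estimate = unname(ct$estimate), p.value = ct$p.value,
       method = method, n_variants = length(x))
}
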