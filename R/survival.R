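.onsetFrame <- function(cohort, groupBy) {
  d <- cohortData(cohort)
  if (!groupBy %in% names(d))
    stop("grouping column '", groupBy, "' not in the cohort")
  g <- d[[groupBy]]
  lev <- if (groupBy == "pns_category") intersect(.PNS_LEVELS, unique(g))
         else sort(unique(as.character(g)))
  data.frame(age = d$age, event = as.integer(d$event),
             group = factor(as.character(g), levels = lev))
}

#' Kaplan-Meier age-at-first-cancer curves
#'
#' Fits the product-limit estimator of age at first cancer per group
#' (carriers without cancer enter as censored at their last-known age) and
#' summarises each group's median onset age with its 95% confidence
#' interval. Onset curves are conventionally displayed inverted
#' (`1 - S(t)`, cumulative probability of a first cancer by age t); the
#' returned fit carries the usual `S(t)` from which the inverted curve is
#' `1 - fit$surv`.
#'
#' @param cohort a [CarrierCohort-class].
#' @param groupBy cohort column defining the groups (default the PNS
#'   category).
#' @param confType method for the median confidence interval:
#'   `"log-log"` (complementary log-log transform of S(t), the default) or
#'   `"plain"` (linear).
#' @return list with `fit` (the `survival::survfit` object) and `summary`
#'   (data.frame: `group`, `n`, `events`, `median`, `lcl95`, `ucl95`;
#'   medians are `NA` where no group median exists, e.g. all censored).
#' @export
kmOnsetCurve <- function(cohort, groupBy = "pns_category",
                         confType = c("log-log", "plain")) {
  confType <- match.arg(confType)
  df <- .onsetFrame(cohort, groupBy)
  fit <- survival::survfit(survival::Surv(age, event) ~ group, data = df,
                           conf.type = confType)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1,
                                       dimnames = list("all", names(tab)))
  res <- data.frame(
    group = sub("^group=", "", rownames(tab)),
    n = as.integer(tab[, "records"]),
    events = as.integer(tab[, "events"]),
    median = tab[, "median"],
    lcl95 = tab[, "0.95LCL"],
    ucl95 = tab[, "0.95UCL"],
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  list(fit = fit, summary = res)
}

#' Global log-rank test across onset curves
#'
#' @inheritParams kmOnsetCurve
#' @return list with `chisq`, `df` (number of groups minus 1) and `p`.
#' @export
logrankGlobal <- function(cohort, groupBy = "pns_category") {
  df <- .onsetFrame(cohort, groupBy)
  if (nlevels(droplevels(df$group)) < 2L)
    stop("log-rank needs at least two groups")
  sd <- survival::survdiff(survival::Surv(age, event) ~ group, data = df)
  k <- length(sd$n)
  list(chisq = unname(sd$chisq), df = k - 1L,
       p = stats::pchisq(sd$chisq, k - 1L, lower.tail = FALSE))
}

#' Pairwise log-rank tests with multiplicity correction
#'
#' Each pair of groups is tested with a two-group log-rank; raw p-values are
#' Bonferroni-corrected (multiplied by the number of pairs, clipped at 1) by
#' default.
#'
#' @inheritParams kmOnsetCurve
#' @param correction `"bonferroni"` (default), `"BH"` or `"none"`.
#' @return list with `pairs` (data.frame: `group1`, `group2`, `chisq`,
#'   `p_raw`, `p_adjusted`) and `p_matrix` (symmetric matrix of adjusted p).
#' @export
logrankPairwise <- function(cohort, groupBy = "pns_category",
                            correction = c("bonferroni", "BH", "none")) {
  correction <- match.arg(correction)
  df <- .onsetFrame(cohort, groupBy)
  lev <- levels(droplevels(df$group))
  if (length(lev) < 2L) stop("log-rank needs at least two groups")
  cmb <- utils::combn(lev, 2L)
  rows <- apply(cmb, 2L, function(pr) {
    sub <- droplevels(df[df$group %in% pr, , drop = FALSE])
    sd <- survival::survdiff(survival::Surv(age, event) ~ group, data = sub)
    p <- stats::pchisq(sd$chisq, 1L, lower.tail = FALSE)
    data.frame(group1 = pr[1], group2 = pr[2],
               chisq = unname(sd$chisq), p_raw = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_raw, method =
    switch(correction, bonferroni = "bonferroni", BH = "BH", none = "none"))
  pm <- matrix(NA_real_, length(lev), length(lev),
               dimnames = list(lev, lev))
  for (i in seq_len(nrow(res))) {
    pm[res$group1[i], res$group2[i]] <- res$p_adjusted[i]
    pm[res$group2[i], res$group1[i]] <- res$p_adjusted[i]
  }
  diag(pm) <- 1
  list(pairs = res, p_matrix = pm)
}
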