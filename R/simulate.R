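#' Configuration of the synthetic-data generators
#'
#' Bundles every knob of the simulators with the defaults used throughout
#' the package's tests: a 145-allele HLA-I panel, log-normal-ish affinities
#' driven by a per-variant latent immunogenicity, onset-age medians of
#' 25/29/34 years for the Low/Intermediate/High PNS categories, 20%
#' non-informative censoring, and tumour-topology shifts that deplete bone
#' and soft-tissue sarcomas and enrich non-LFS-spectrum cancers as PNS
#' rises.
#'
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @param nVariants number of variants scored in a bundle.
#' @param nAlleles named integer vector, alleles per locus (sums to 145 by
#'   default).
#' @param listedMass per-locus frequency mass of the listed alleles; the
#'   residual represents alleles absent from the table.
#' @param dirichletAlpha concentration of the per-locus Dirichlet draw.
#' @param logLoc,logScale location and noise SD of log10 affinities (nM);
#'   the default location puts roughly half the variants above the 500 nM
#'   relevance threshold on every allele (no binder at all), matching the
#'   sparsity observed on the real variant set.
#' @param effectSize SD of the per-variant latent immunogenicity (log10
#'   units); 0 removes the shared driver of MAS/HCS/WCS.
#' @param categoryMedians named vector of true median onset ages (years)
#'   per PNS category.
#' @param weibullShape shape of the Weibull onset distribution; the scale
#'   is set per category so the median matches `categoryMedians`.
#' @param censorRate fraction of carriers censored (cancer-free at last
#'   contact).
#' @param cohortSize named vector of carriers per PNS category; defaults
#'   chosen so expected event counts at the default censoring rate are
#'   about 385/612/152.
#' @param topologyBase named multinomial over tumour topologies of first
#'   cancers.
#' @param topologyMult named multiplicative shifts applied at full strength
#'   in the High category, at square-root strength in Intermediate, and not
#'   at all in Low; the shifted multinomial is renormalised.
#' @return a list of class `simConfig`.
#' @export
simConfig <- function(seed = 1L,
                      nVariants = 200L,
                      nAlleles = c(A = 45L, B = 60L, C = 40L),
                      listedMass = 0.95,
                      dirichletAlpha = 0.5,
                      logLoc = 5.85, logScale = 1.0,
                      effectSize = 1.0,
                      categoryMedians = c(Low = 25, Intermediate = 29,
                                          High = 34),
                      weibullShape = 2,
                      censorRate = 0.2,
                      cohortSize = c(Low = 481L, Intermediate = 765L,
                                     High = 190L),
                      topologyBase = c(adrenal = 0.07, brain = 0.12,
                                       breast = 0.24, bones = 0.11,
                                       soft_tissues = 0.15,
                                       hematopoietic = 0.08,
                                       non_LFS = 0.23),
                      topologyMult = c(bones = 0.3, soft_tissues = 0.4,
                                       non_LFS = 1.6)) {
  stopifnot(all(nAlleles >= 1L), listedMass > 0, listedMass <= 1,
            censorRate >= 0, censorRate < 1, all(categoryMedians > 0),
            weibullShape > 0, effectSize >= 0,
            abs(sum(topologyBase) - 1) < 1e-6, all(topologyBase >= 0),
            all(topologyMult > 0),
            all(names(categoryMedians) == .PNS_LEVELS),
            all(names(cohortSize) == .PNS_LEVELS))
  structure(as.list(environment()), class = "simConfig")
}

#' Simulate an HLA-I allele-frequency table
#'
#' Per-locus frequencies are a Dirichlet draw scaled to `listedMass`, so
#' sums stay below 1 and the residual mass stands for unlisted alleles.
#'
#' @param config a [simConfig()].
#' @param seed seed (defaults to `config$seed`).
#' @return an [AlleleFrequencyTable-class] with `sum(config$nAlleles)`
#'   alleles.
#' @export
simAlleleFrequencies <- function(config = simConfig(), seed = config$seed) {
  withr::with_seed(seed, {
    rows <- lapply(c("A", "B", "C"), function(l) {
      n <- config$nAlleles[[l]]
      g <- stats::rgamma(n, shape = config$dirichletAlpha)
      data.frame(
        allele = sprintf("HLA-%s*%02d:01", l, seq_len(n)),
        locus = l,
        frequency = g / sum(g) * config$listedMass,
        stringsAsFactors = FALSE)
    })
    AlleleFrequencyTable(do.call(rbind, rows))
  })
}

#' Simulate diploid six-allele HLA-I genotypes
#'
#' Two alleles per locus are drawn independently with the table's
#' frequencies (Hardy-Weinberg). With `listedOnly = TRUE` (the default for
#' cohort genotypes) frequencies are renormalised over the listed alleles;
#' with `listedOnly = FALSE` the residual mass is drawn as an explicit
#' `unlisted-<locus>` call, which is what the coverage Monte-Carlo check
#' needs.
#'
#' @param freqs an [AlleleFrequencyTable-class].
#' @param n number of individuals.
#' @param seed RNG seed.
#' @param listedOnly see above.
#' @return data.frame: `individual_id`, `A1`, `A2`, `B1`, `B2`, `C1`, `C2`.
#' @export
simGenotypes <- function(freqs, n, seed = 1L, listedOnly = TRUE) {
  tab <- freqTable(freqs)
  withr::with_seed(seed, {
    out <- data.frame(individual_id = sprintf("ind%05d", seq_len(n)),
                      stringsAsFactors = FALSE)
    for (l in c("A", "B", "C")) {
      sub <- tab[tab$locus == l, , drop = FALSE]
      alleles <- sub$allele
      p <- sub$frequency
      if (listedOnly) {
        p <- p / sum(p)
      } else {
        alleles <- c(alleles, paste0("unlisted-", l))
        p <- c(p, max(0, 1 - sum(p)))
      }
      draw <- matrix(sample(alleles, 2L * n, replace = TRUE, prob = p),
                     ncol = 2L)
      out[[paste0(l, "1")]] <- draw[, 1]
      out[[paste0(l, "2")]] <- draw[, 2]
    }
    out
  })
}

#' Simulate per-variant affinity matrices with a latent immunogenicity
#'
#' Each variant gets a latent immunogenicity `z ~ N(0, effectSize)`; log10
#' affinities of its mutant peptides are `logLoc - z + noise`, so high-z
#' variants have a lower MAS, more responsive alleles (higher HCS) and
#' higher population coverage (higher WCS) — the shared driver that induces
#' the strong inter-metric correlations the scoring stage expects.
#' Wild-type peptides are drawn without the latent shift. Affinities are
#' clamped to \[1, 50000\] nM.
#'
#' @param config a [simConfig()].
#' @param variants data.frame of variants (from [parseHgvsP()] or
#'   [enumerateMissenseSpace()]).
#' @param freqs an [AlleleFrequencyTable-class] naming the allele panel.
#' @param protein protein sequence the variants live on (default the
#'   packaged p53).
#' @param seed seed (defaults to `config$seed`).
#' @return list of [AffinityMatrix-class] objects, one per variant, with
#'   the latent draws attached as `attr(, "z")`.
#' @export
simAffinityMatrices <- function(config = simConfig(), variants, freqs,
                                protein = tp53Protein(),
                                seed = config$seed) {
  alleles <- alleleNames(freqs)
  seqchr <- .asResidues(protein)
  withr::with_seed(seed, {
    z <- stats::rnorm(nrow(variants), 0, config$effectSize)
    mats <- lapply(seq_len(nrow(variants)), function(i) {
      pairs <- enumerateNonamers(variants[i, , drop = FALSE], seqchr)
      nc <- nrow(pairs) * length(alleles)
      draw <- function(shift) {
        la <- config$logLoc - shift + stats::rnorm(nc, 0, config$logScale)
        matrix(pmin(50000, pmax(1, 10^la)), nrow = nrow(pairs),
               dimnames = list(NULL, alleles))
      }
      methods::new("AffinityMatrix",
                   variant = variants$label[i],
                   windowStarts = as.integer(pairs$window_start),
                   mutantPeptides = pairs$mutant_peptide,
                   wildtypePeptides = pairs$wildtype_peptide,
                   mutant = draw(z[i]), wildtype = draw(0))
    })
    attr(mats, "z") <- z
    mats
  })
}

.weibullScale <- function(median, shape) median / log(2)^(1 / shape)

.categoryTopologyProbs <- function(config, category) {
  expo <- c(Low = 0, Intermediate = 0.5, High = 1)[[category]]
  p <- config$topologyBase
  mult <- rep(1, length(p))
  names(mult) <- names(p)
  mult[names(config$topologyMult)] <- config$topologyMult
  p <- p * mult^expo
  p / sum(p)
}

#' Simulate a carrier cohort with PNS-dependent onset and tumour spectrum
#'
#' Onset ages are Weibull with the category's configured median
#' (scale = median / log(2)^(1/shape)). Censoring is non-informative: each
#' carrier also draws an independent last-contact age, uniform on (0, U)
#' with U set to the category's mean onset divided by `censorRate`, and the
#' earlier of onset and last contact is observed — so the expected censored
#' fraction equals `censorRate`. First-cancer topologies follow the base
#' multinomial shifted by the category multipliers. Variant labels are
#' assigned from `scores` within each category when given.
#'
#' @param config a [simConfig()].
#' @param scores optional data.frame from [scoreVariants()]; carriers of a
#'   category draw their variant uniformly from that category's variants.
#' @param freqs optional [AlleleFrequencyTable-class]; when given, six
#'   HLA-I allele calls are attached per individual.
#' @param seed seed (defaults to `config$seed`).
#' @return a [CarrierCohort-class].
#' @export
simCohort <- function(config = simConfig(), scores = NULL, freqs = NULL,
                      seed = config$seed) {
  withr::with_seed(seed, {
    parts <- lapply(.PNS_LEVELS, function(cat) {
      n <- config$cohortSize[[cat]]
      if (n == 0L) return(NULL)
      med <- config$categoryMedians[[cat]]
      shape <- config$weibullShape
      scale <- .weibullScale(med, shape)
      onset <- stats::rweibull(n, shape, scale)
      if (config$censorRate > 0) {
        meanOnset <- scale * gamma(1 + 1 / shape)
        lastContact <- stats::runif(n, 0, meanOnset / config$censorRate)
        cens <- lastContact < onset
      } else {
        lastContact <- onset
        cens <- rep(FALSE, n)
      }
      topo <- sample(names(config$topologyBase), n, replace = TRUE,
                     prob = .categoryTopologyProbs(config, cat))
      vlab <- if (!is.null(scores)) {
        pool <- scores$variant[scores$category == cat]
        if (length(pool) == 0L)
          stop("no scored variant in category ", cat)
        sample(pool, n, replace = TRUE)
      } else paste0("sim_", cat)
      data.frame(individual_id = NA_character_,
                 variant = vlab,
                 event = !cens,
                 age = pmin(onset, lastContact),
                 topology = ifelse(cens, "none", topo),
                 pns_category = cat,
                 stringsAsFactors = FALSE)
    })
    d <- do.call(rbind, parts)
    d$individual_id <- sprintf("carrier%05d", seq_len(nrow(d)))
    if (!is.null(freqs)) {
      g <- simGenotypes(freqs, nrow(d),
                        seed = sample.int(2147483646L, 1L))
      d <- cbind(d, g[, -1])
    }
    CarrierCohort(d)
  })
}

#' Generate a complete synthetic input bundle
#'
#' Runs the whole generator chain under one seed: allele frequencies, a
#' random sample of the TP53 single-nucleotide missense space, latent-driven
#' affinity matrices, the scored variant table, and a carrier cohort with
#' genotypes. When `outDir` is given, every pipeline input format is written
#' (frequency/affinity/score/cohort/genotype TSVs plus a JSON manifest of
#' the configuration and seed).
#'
#' @param config a [simConfig()].
#' @param seed seed (defaults to `config$seed`).
#' @param outDir optional output directory.
#' @return list with `freqs`, `variants`, `matrices`, `scores`, `cohort`,
#'   `config`, `seed`.
#' @export
simBundle <- function(config = simConfig(), seed = config$seed,
                      outDir = NULL) {
  subseeds <- withr::with_seed(seed, sample.int(2147483646L, 4L))
  freqs <- simAlleleFrequencies(config, seed = subseeds[1])
  space <- enumerateMissenseSpace(tp53Cds())
  variants <- withr::with_seed(subseeds[2], {
    space[sample.int(nrow(space), min(config$nVariants, nrow(space))), ,
          drop = FALSE]
  })
  rownames(variants) <- NULL
  mats <- simAffinityMatrices(config, variants, freqs, seed = subseeds[3])
  scores <- scoreVariants(mats, freqs)
  cohort <- simCohort(config, scores = scores, freqs = freqs,
                      seed = subseeds[4])
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(freqTable(freqs),
                       file.path(outDir, "allele_frequencies.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    recs <- do.call(rbind, lapply(mats, function(m) {
      data.frame(peptide = rep(m@mutantPeptides, ncol(m@mutant)),
                 allele = rep(colnames(m@mutant),
                              each = nrow(m@mutant)),
                 affinity_nM = as.vector(m@mutant))
    }))
    writeAffinityTable(recs, file.path(outDir, "affinities.tsv"))
    writeScoreTable(scores, file.path(outDir, "variant_scores.tsv"))
    utils::write.table(cohortData(cohort),
                       file.path(outDir, "cohort.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeRunManifest(scores, file.path(outDir, "manifest.json"),
                     extra = list(seed = seed,
                                  config = config[setdiff(names(config),
                                                          "seed")]))
  }
  list(freqs = freqs, variants = variants, matrices = mats,
       scores = scores, cohort = cohort, config = config, seed = seed)
}
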