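#' Normalise HLA class I allele names
#'
#' Accepts `"HLA-A*02:01"`, `"HLA-A02:01"` and `"A*02:01"` spellings and
#' returns the canonical `"HLA-<locus>*<group>:<protein>"` form.
#'
#' @param alleles character vector of allele names.
#' @return character vector of canonical names.
#' @examples
#' normalizeAllele(c("A*02:01", "HLA-B07:02"))
#' @export
normalizeAllele <- function(alleles) {
  m <- regmatches(alleles,
    regexec("^(?:HLA-)?([ABCabc])\\*?([0-9]+):([0-9]+)$", alleles))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("unrecognised HLA-I allele name(s): ",
         paste(alleles[bad], collapse = ", "))
  vapply(m, function(x)
    sprintf("HLA-%s*%s:%s", toupper(x[2]), x[3], x[4]), character(1))
}

.hlaLocus <- function(alleles) substr(normalizeAllele(alleles), 5, 5)

#' Parse a peptide x allele binding-affinity table
#'
#' Reads predicted affinities (nM) from either the whitespace-delimited
#' NetMHCpan-4.1-style long output (`dialect = "netmhcpan"`; the header line
#' carries `Pos`, `MHC`, `Peptide` and `Aff(nM)` columns, decorated
#' comment/separator lines are skipped) or a generic TSV with named columns
#' (`dialect = "tsv"`; a `peptide` column, an `allele`/`mhc`/`hla` column and
#' an affinity column matching `aff`). Rows with missing or non-positive
#' affinity are dropped with a message; duplicate (peptide, allele) rows
#' resolve to the minimum (strongest) affinity with a warning.
#'
#' @param path path to the file (or a character vector of lines).
#' @param dialect input format, see above.
#' @return data.frame with columns `peptide`, `allele` (canonical),
#'   `affinity_nM`.
#' @examples
#' f <- system.file("extdata", "netmhcpan_example.txt", package = "neoPNS")
#' parsePredictionTable(f, dialect = "netmhcpan")
#' @export
parsePredictionTable <- function(path, dialect = c("tsv", "netmhcpan")) {
  dialect <- match.arg(dialect)
  lines <- if (length(path) == 1L && file.exists(path)) readLines(path)
           else as.character(path)
  if (dialect == "netmhcpan") {
    keep <- !grepl("^\\s*(#|-)", lines) & nzchar(trimws(lines))
    lines <- lines[keep]
    toks <- strsplit(trimws(lines), "\\s+")
    header <- toks[[1]]
    ip <- match("Peptide", header); ia <- match("MHC", header)
    iv <- match("Aff(nM)", header)
    if (anyNA(c(ip, ia, iv)))
      stop("no recognisable Peptide/MHC/Aff(nM) header in NetMHCpan input")
    rows <- toks[-1]
    rows <- rows[vapply(rows, length, 1L) >= iv]
    df <- data.frame(
      peptide = vapply(rows, `[`, "", ip),
      allele = vapply(rows, `[`, "", ia),
      affinity_nM = as.numeric(vapply(rows, `[`, "", iv)),
      stringsAsFactors = FALSE)
  } else {
    tab <- if (length(path) == 1L && file.exists(path))
      utils::read.delim(path, stringsAsFactors = FALSE)
    else utils::read.delim(text = paste(lines, collapse = "\n"),
                           stringsAsFactors = FALSE)
    nm <- tolower(names(tab))
    ip <- which(nm == "peptide")[1]
    ia <- which(nm %in% c("allele", "mhc", "hla"))[1]
    iv <- grep("aff", nm)[1]
    if (anyNA(c(ip, ia, iv)))
      stop("no recognisable peptide/allele/affinity columns in TSV input")
    df <- data.frame(peptide = as.character(tab[[ip]]),
                     allele = as.character(tab[[ia]]),
                     affinity_nM = as.numeric(tab[[iv]]),
                     stringsAsFactors = FALSE)
  }
  drop <- is.na(df$affinity_nM) | df$affinity_nM <= 0
  if (any(drop)) {
    message("dropped ", sum(drop), " row(s) with missing or non-positive affinity")
    df <- df[!drop, , drop = FALSE]
  }
  df$allele <- normalizeAllele(df$allele)
  key <- paste(df$peptide, df$allele)
  if (anyDuplicated(key)) {
    warning("duplicate (peptide, allele) rows; keeping the minimum affinity")
    df <- do.call(rbind, lapply(split(df, key), function(g)
      g[which.min(g$affinity_nM), , drop = FALSE]))
  }
  rownames(df) <- NULL
  df[order(df$peptide, df$allele), , drop = FALSE]
}

#' @rdname parsePredictionTable
#' @param records data.frame as returned by `parsePredictionTable()`.
#' @export
writeAffinityTable <- function(records, path) {
  utils::write.table(records[, c("peptide", "allele", "affinity_nM")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# 32-bit FNV-1a over a string, in doubles (exact: all intermediates < 2^53)
.fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    lo <- bitwXor(as.integer(lo), as.integer(b))
    h <- hi * 65536 + lo
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  h
}

#' Parameters of the surrogate affinity predictor
#'
#' @param salt integer mixed into the hash so different simulations decohere.
#' @param fracBinders target fraction of (peptide, allele) pairs predicted
#'   below `threshold`.
#' @param minAffinity,maxAffinity range of emitted affinities (nM).
#' @param threshold binder threshold (nM) separating the two log-uniform
#'   branches.
#' @return a list of class `surrogateParams`.
#' @export
surrogateParams <- function(salt = 0L, fracBinders = 0.02,
                            minAffinity = 1, maxAffinity = 50000,
                            threshold = 500) {
  stopifnot(fracBinders > 0, fracBinders < 1,
            minAffinity > 0, minAffinity < threshold,
            threshold < maxAffinity)
  structure(list(salt = as.integer(salt), fracBinders = fracBinders,
                 minAffinity = minAffinity, maxAffinity = maxAffinity,
                 threshold = threshold),
            class = "surrogateParams")
}

#' Deterministic surrogate binding-affinity predictor
#'
#' A hash-based stand-in for an external MHC-I predictor: a pure function of
#' (peptide, allele, salt) emitting IC50-like affinities in nM. A fraction
#' `fracBinders` of pairs falls log-uniformly below `threshold` (binders),
#' the rest log-uniformly between `threshold` and `maxAffinity`, so
#' pipelines can be exercised offline with a realistic binder sparsity.
#'
#' @param peptide character vector of 9-mers.
#' @param allele character vector of allele names (recycled against
#'   `peptide`).
#' @param params a [surrogateParams()] list.
#' @return numeric vector of affinities (nM).
#' @examples
#' surrogateAffinity("HMTEVVRHC", "HLA-A*02:01")
#' @export
surrogateAffinity <- function(peptide, allele, params = surrogateParams()) {
  if (any(nchar(peptide) != 9L))
    stop("surrogate predictor expects 9-mer peptides")
  allele <- normalizeAllele(allele)
  n <- max(length(peptide), length(allele))
  peptide <- rep_len(peptide, n)
  allele <- rep_len(allele, n)
  keys <- paste(peptide, allele, params$salt, sep = "|")
  u <- (vapply(keys, .fnv1a32, numeric(1), USE.NAMES = FALSE) + 0.5) / 4294967296
  f <- params$fracBinders
  llo <- log10(params$minAffinity); lcut <- log10(params$threshold)
  lhi <- log10(params$maxAffinity)
  ifelse(u < f,
         10^(llo + (u / f) * (lcut - llo)),
         10^(lcut + ((u - f) / (1 - f)) * (lhi - lcut)))
}

#' Assemble a per-variant affinity matrix
#'
#' Builds the (peptide window x allele) mutant and wild-type affinity grids
#' of one variant from parsed predictor records, from the surrogate
#' predictor, or both (records first, surrogate as fallback when
#' `surrogate = TRUE`).
#'
#' @param variant canonical label of the variant the pairs belong to.
#' @param pairs data.frame from [enumerateNonamers()].
#' @param alleles character vector of allele names defining the columns.
#' @param records optional data.frame from [parsePredictionTable()].
#' @param surrogate use [surrogateAffinity()] for (peptide, allele) cells not
#'   covered by `records`; if `FALSE`, missing mutant cells are an error
#'   naming the absent pairs.
#' @param params surrogate parameters.
#' @param wildtype build the paired wild-type grid; disable only when
#'   amplitude scoring is not needed.
#' @return an [AffinityMatrix-class].
#' @examples
#' pairs <- enumerateNonamers("p.R175H", tp53Protein())
#' buildAffinityMatrix("p.R175H", pairs, c("HLA-A*02:01", "HLA-B*07:02"))
#' @export
buildAffinityMatrix <- function(variant, pairs, alleles, records = NULL,
                                surrogate = is.null(records),
                                params = surrogateParams(),
                                wildtype = TRUE) {
  alleles <- normalizeAllele(alleles)
  lookup <- function(peptides) {
    grid <- matrix(NA_real_, nrow = length(peptides), ncol = length(alleles),
                   dimnames = list(NULL, alleles))
    if (!is.null(records)) {
      key <- paste(records$peptide, records$allele)
      want <- expand.grid(peptide = peptides, allele = alleles,
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
      idx <- match(paste(want$peptide, want$allele), key)
      grid[] <- records$affinity_nM[idx]
    }
    if (surrogate && anyNA(grid)) {
      miss <- which(is.na(grid), arr.ind = TRUE)
      grid[miss] <- surrogateAffinity(peptides[miss[, 1]],
                                      alleles[miss[, 2]], params)
    }
    grid
  }
  mut <- lookup(pairs$mutant_peptide)
  if (anyNA(mut)) {
    miss <- which(is.na(mut), arr.ind = TRUE)
    stop("missing mutant affinities for: ",
         paste(sprintf("(%s, %s)", pairs$mutant_peptide[miss[, 1]],
                       alleles[miss[, 2]]), collapse = ", "))
  }
  wt <- if (wildtype) lookup(pairs$wildtype_peptide)
        else matrix(numeric(0), 0, 0)
  if (wildtype && anyNA(wt)) {
    miss <- which(is.na(wt), arr.ind = TRUE)
    stop("missing wild-type affinities for: ",
         paste(sprintf("(%s, %s)", pairs$wildtype_peptide[miss[, 1]],
                       alleles[miss[, 2]]), collapse = ", "))
  }
  methods::new("AffinityMatrix",
               variant = variant,
               windowStarts = as.integer(pairs$window_start),
               mutantPeptides = pairs$mutant_peptide,
               wildtypePeptides = if (wildtype) pairs$wildtype_peptide
                                  else character(0),
               mutant = mut, wildtype = wt)
}
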