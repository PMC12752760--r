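.AA1 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

.aa3to1 <- local({
  three <- toupper(Biostrings::AMINO_ACID_CODE[.AA1])
  stats::setNames(.AA1, three)
})

.aaToken <- function(tok, label) {
  tok1 <- toupper(tok)
  if (nchar(tok) == 1L) {
    if (!tok1 %in% .AA1)
      stop("unknown amino-acid code '", tok, "' in '", label, "'")
    return(tok1)
  }
  if (!tok1 %in% names(.aa3to1))
    stop("unknown amino-acid code '", tok, "' in '", label, "'")
  unname(.aa3to1[tok1])
}

#' Parse HGVS-p missense labels
#'
#' Accepts one-letter (`"p.R175H"`) and three-letter (`"p.Arg175His"`)
#' protein substitution labels, with or without the `p.` prefix, and returns
#' the canonical one-letter form.
#'
#' @param labels character vector of HGVS-p substitution labels.
#' @return data.frame with columns `label` (canonical, `p.` + one-letter),
#'   `position`, `ref`, `alt`.
#' @examples
#' parseHgvsP(c("p.R175H", "p.Arg213Gln"))
#' @export
parseHgvsP <- function(labels) {
  parse1 <- function(label) {
    body <- sub("^p\\.", "", label)
    m <- regmatches(body,
                    regexec("^([A-Za-z]{1,3})([0-9]+)([A-Za-z]{1,3})$", body))[[1]]
    if (length(m) != 4L)
      stop("malformed HGVS-p label '", label,
           "' (expected p.<RefAA><Pos><AltAA>)")
    ref <- .aaToken(m[2], label)
    alt <- .aaToken(m[4], label)
    pos <- as.integer(m[3])
    if (ref == alt)
      stop("'", label, "' is synonymous (ref == alt), not missense")
    data.frame(label = paste0("p.", ref, pos, alt),
               position = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(labels, parse1))
}

.asResidues <- function(protein) {
  if (methods::is(protein, "AAString") || methods::is(protein, "AAStringSet"))
    protein <- as.character(protein)[1]
  protein <- toupper(protein)
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", protein))
    stop("protein sequence contains non-amino-acid letters")
  protein
}

#' Enumerate candidate mutant nonamers around a missense position
#'
#' Every 9-residue window of the mutated protein that contains the variant
#' position is returned, paired with the corresponding wild-type window.
#' Interior positions (9 <= pos <= L-8) yield exactly nine windows; positions
#' within eight residues of a terminus yield the clipped count
#' `min(pos, L-8) - max(1, pos-8) + 1`.
#'
#' @param variant a one-row data.frame from [parseHgvsP()], or a label
#'   passed through it.
#' @param protein protein sequence (character or `Biostrings::AAString`);
#'   the reference residue at `variant$position` must match `variant$ref`.
#' @return data.frame with columns `window_start` (1-based),
#'   `offset_of_variant` (1..9), `mutant_peptide`, `wildtype_peptide`.
#' @examples
#' enumerateNonamers("p.R175H", tp53Protein())
#' @export
enumerateNonamers <- function(variant, protein) {
  if (is.character(variant)) variant <- parseHgvsP(variant)
  stopifnot(nrow(variant) == 1L)
  seq <- .asResidues(protein)
  L <- nchar(seq)
  pos <- variant$position
  if (L < 9L) stop("protein shorter than 9 residues")
  if (pos < 1L || pos > L) stop("variant position ", pos,
                                " outside protein of length ", L)
  if (substr(seq, pos, pos) != variant$ref)
    stop("reference mismatch at position ", pos, ": protein has '",
         substr(seq, pos, pos), "', variant says '", variant$ref, "'")
  mutseq <- seq
  substr(mutseq, pos, pos) <- variant$alt
  starts <- seq.int(max(1L, pos - 8L), min(L - 8L, pos))
  data.frame(
    window_start = starts,
    offset_of_variant = pos - starts + 1L,
    mutant_peptide = substring(mutseq, starts, starts + 8L),
    wildtype_peptide = substring(seq, starts, starts + 8L),
    stringsAsFactors = FALSE
  )
}

.asDna <- function(cds) {
  if (methods::is(cds, "DNAString") || methods::is(cds, "DNAStringSet"))
    cds <- as.character(cds)[1]
  toupper(cds)
}

#' Enumerate the single-nucleotide missense space of a coding sequence
#'
#' For every coding position and each of the three alternative bases, the
#' mutated codon is translated; substitutions whose product differs from the
#' reference amino acid and is not a stop are collected, and the distinct
#' set of protein-level (position, ref, alt) triples is returned. Stop-codon
#' positions never contribute. By default the initiator codon is skipped as
#' well: substitutions there abolish translation rather than produce a
#' missense protein, which is the convention under which the packaged TP53
#' coding sequence yields 2314 variants.
#'
#' @param cds coding DNA sequence (character or `Biostrings::DNAString`),
#'   length divisible by 3.
#' @param includeStartCodon also enumerate substitutions in codon 1.
#' @return data.frame with columns `position`, `ref`, `alt`, `label`, sorted
#'   by position then alt.
#' @examples
#' enumerateMissenseSpace("ATGGCTTAA")
#' @export
enumerateMissenseSpace <- function(cds, includeStartCodon = FALSE) {
  dna <- .asDna(cds)
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("CDS length not divisible by 3")
  code <- Biostrings::GENETIC_CODE
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  refAA <- unname(code[codons])
  if (any(is.na(refAA))) stop("CDS contains non-ACGT letters")
  nAA <- length(codons)
  if (refAA[nAA] == "*") { codons <- codons[-nAA]; refAA <- refAA[-nAA] }
  if (any(refAA == "*")) stop("internal stop codon in CDS")
  first <- if (includeStartCodon) 1L else 2L
  empty <- data.frame(position = integer(), ref = character(),
                      alt = character(), label = character(),
                      stringsAsFactors = FALSE)
  if (first > length(codons)) return(empty)
  out <- vector("list", length(codons))
  bases <- c("A", "C", "G", "T")
  for (i in first:length(codons)) {
    cod <- codons[i]
    hits <- character()
    for (k in 1:3) {
      for (b in setdiff(bases, substr(cod, k, k))) {
        mut <- cod
        substr(mut, k, k) <- b
        aa <- code[[mut]]
        if (aa != "*" && aa != refAA[i]) hits <- c(hits, aa)
      }
    }
    hits <- unique(hits)
    if (length(hits))
      out[[i]] <- data.frame(position = i, ref = refAA[i], alt = hits,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) return(empty)
  res <- res[order(res$position, res$alt), , drop = FALSE]
  res$label <- paste0("p.", res$ref, res$position, res$alt)
  rownames(res) <- NULL
  res
}

#' Packaged TP53 sequences
#'
#' `tp53Cds()` returns the packaged human TP53 coding sequence (1182 nt
#' including the stop codon; a reconstruction equivalent to the canonical
#' NM_000546 CDS, see the FASTA header) and `tp53Protein()` its 393-residue
#' translation.
#'
#' @return a `Biostrings::DNAString` / `Biostrings::AAString`.
#' @examples
#' nchar(tp53Protein())
#' @export
tp53Cds <- function() {
  f <- system.file("extdata", "TP53_CDS.fasta", package = "neoPNS",
                   mustWork = TRUE)
  Biostrings::readDNAStringSet(f)[[1]]
}

#' @rdname tp53Cds
#' @export
tp53Protein <- function() {
  f <- system.file("extdata", "p53_protein.fasta", package = "neoPNS",
                   mustWork = TRUE)
  Biostrings::readAAStringSet(f)[[1]]
}

#' Read and write sequence and variant files
#'
#' Thin wrappers over `Biostrings` FASTA I/O plus the two plain-text peptide
#' formats accepted by NetMHCpan-style tools, and the two-column variant
#' list (`variant_label`, `functional_class`).
#'
#' @param path file path.
#' @name variant-io
NULL

#' @rdname variant-io
#' @export
readProteinFasta <- function(path) Biostrings::readAAStringSet(path)

#' @rdname variant-io
#' @export
readCodingFasta <- function(path) Biostrings::readDNAStringSet(path)

#' @rdname variant-io
#' @param peptides character vector of peptides.
#' @param format `"lines"` (one peptide per line) or `"fasta"`.
#' @param names FASTA record names (defaults to `pep<i>`).
#' @export
writePeptides <- function(peptides, path, format = c("lines", "fasta"),
                          names = NULL) {
  format <- match.arg(format)
  if (format == "lines") {
    writeLines(peptides, path)
  } else {
    if (is.null(names)) names <- paste0("pep", seq_along(peptides))
    set <- Biostrings::AAStringSet(stats::setNames(peptides, names))
    Biostrings::writeXStringSet(set, path)
  }
  invisible(path)
}

#' @rdname variant-io
#' @export
readVariantTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"variant_label" %in% names(tab))
    stop("variant table needs a 'variant_label' column")
  parsed <- parseHgvsP(tab$variant_label)
  if ("functional_class" %in% names(tab)) {
    fc <- as.character(tab$functional_class)
    bad <- !is.na(fc) & fc != "" & !fc %in% c("A", "B", "C", "D")
    if (any(bad)) stop("functional_class must be one of A, B, C, D")
    parsed$functional_class <- ifelse(fc == "", NA_character_, fc)
  }
  parsed
}
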