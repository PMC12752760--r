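test_that("HGVS-p parsing handles both letter conventions and rejects junk", {
  v <- parseHgvsP("p.R175H")
  expect_equal(v$position, 175L)
  expect_equal(v$ref, "R")
  expect_equal(v$alt, "H")
  expect_equal(v$label, "p.R175H")

  v3 <- parseHgvsP("p.Arg213Gln")
  expect_equal(unlist(v3[, c("position", "ref", "alt")], use.names = FALSE),
               c("213", "R", "Q"))
  expect_equal(v3$label, "p.R213Q")

  # prefix optional, vectorised
  both <- parseHgvsP(c("R175H", "p.Gly245Ser"))
  expect_equal(both$label, c("p.R175H", "p.G245S"))

  expect_error(parseHgvsP("p.R175R"), "synonymous")
  expect_error(parseHgvsP("p.X175H"), "unknown amino-acid")
  expect_error(parseHgvsP("p.R175"), "malformed")
  expect_error(parseHgvsP("R175Hx"), "malformed|unknown")
})

test_that("nonamer windows cover the variant and pair off correctly", {
  prot <- paste(rep("ACDEFGHIK", 5), collapse = "")  # length 45
  # interior position: exactly 9 windows
  v <- parseHgvsP("p.F14Y")
  expect_equal(substr(prot, 14, 14), "F")
  p <- enumerateNonamers(v, prot)
  expect_equal(nrow(p), 9L)
  expect_equal(p$window_start, 6:14)

  # terminal positions clip to a single window
  expect_equal(nrow(enumerateNonamers("p.A1V", prot)), 1L)
  expect_equal(nrow(enumerateNonamers("p.K45R", prot)), 1L)

  # every pair differs at exactly the stated offset
  for (i in seq_len(nrow(p))) {
    mut <- strsplit(p$mutant_peptide[i], "")[[1]]
    wt <- strsplit(p$wildtype_peptide[i], "")[[1]]
    diff <- which(mut != wt)
    expect_equal(diff, p$offset_of_variant[i])
    expect_equal(mut[diff], "Y")
    expect_equal(wt[diff], "F")
  }

  expect_error(enumerateNonamers("p.A1V", "ACDEFGHI"), "shorter than 9")
  expect_error(enumerateNonamers("p.A99V", prot), "outside")
  expect_error(enumerateNonamers("p.C14Y", prot), "reference mismatch")
})

test_that("p.R175H windows tile residues 167..183 of the packaged p53", {
  p <- enumerateNonamers("p.R175H", tp53Protein())
  expect_equal(nrow(p), 9L)
  expect_equal(min(p$window_start), 167L)
  expect_equal(max(p$window_start) + 8L, 183L)
  prot <- as.character(tp53Protein())
  mutprot <- prot
  substr(mutprot, 175, 175) <- "H"
  # brute-force scan: all 9-mers of the mutated protein covering position 175
  all9 <- substring(mutprot, 1:(nchar(prot) - 8), 9:nchar(prot))
  covering <- all9[(1:(nchar(prot) - 8)) <= 175 & (1:(nchar(prot) - 8)) >= 167]
  expect_equal(p$mutant_peptide, covering)
})

# independent oracle: mutate the full CDS, translate whole, diff proteins
bruteMissense <- function(cds, includeStartCodon = TRUE) {
  tr <- function(x)
    as.character(Biostrings::translate(Biostrings::DNAString(x),
                                       no.init.codon = TRUE))
  ref <- sub("\\*$", "", tr(cds))
  out <- list()
  for (i in seq_len(nchar(cds))) {
    for (b in setdiff(c("A", "C", "G", "T"), substr(cds, i, i))) {
      mut <- cds
      substr(mut, i, i) <- b
      aa <- suppressWarnings(tr(mut))
      codon <- (i - 1) %/% 3 + 1
      if (codon > nchar(ref)) next  # stop codon position
      if (!includeStartCodon && codon == 1) next
      r <- substr(ref, codon, codon)
      a <- substr(aa, codon, codon)
      if (a != "*" && a != r) out[[length(out) + 1]] <- c(codon, r, a)
    }
  }
  if (!length(out)) return(matrix(character(0), 0, 3))
  m <- unique(do.call(rbind, out))
  m[order(as.integer(m[, 1]), m[, 3]), , drop = FALSE]
}

test_that("missense-space enumeration matches whole-sequence translation", {
  for (cds in c("ATGGCT", "ATG", "ATGGCTTGGAAATAA")) {
    got <- enumerateMissenseSpace(cds, includeStartCodon = TRUE)
    want <- bruteMissense(cds, includeStartCodon = TRUE)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$position, as.integer(want[, 1]))
    expect_equal(got$ref, unname(want[, 2]))
    expect_equal(got$alt, unname(want[, 3]))
    # default skips the initiator codon
    expect_equal(nrow(enumerateMissenseSpace(cds)),
                 nrow(bruteMissense(cds, includeStartCodon = FALSE)))
  }
  expect_error(enumerateMissenseSpace("ATGG"), "divisible by 3")
})

test_that("missense space is a set: distinct, order-free, ref-consistent", {
  cds <- "ATGCGTAGGAAACTT"  # codons M R R K L
  ms <- enumerateMissenseSpace(cds)
  expect_false(any(duplicated(ms[, c("position", "ref", "alt")])))
  # refs agree with the translated reference codon
  prot <- sub("\\*$", "",
              as.character(Biostrings::translate(Biostrings::DNAString(cds))))
  expect_true(all(ms$ref == substring(prot, ms$position, ms$position)))
  # idempotent
  expect_identical(ms, enumerateMissenseSpace(cds))
})

test_that("variant tables and peptide files round-trip", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant_label\tfunctional_class",
               "p.R175H\tA", "p.Arg213Gln\t"), tf)
  tab <- readVariantTable(tf)
  expect_equal(tab$label, c("p.R175H", "p.R213Q"))
  expect_equal(tab$functional_class, c("A", NA))

  writeLines(c("variant_label\tfunctional_class", "p.R175H\tZ"), tf)
  expect_error(readVariantTable(tf), "functional_class")

  peps <- c("HMTEVVRHC", "MTEVVRHCP")
  pf <- withr::local_tempfile(fileext = ".txt")
  writePeptides(peps, pf, format = "lines")
  expect_equal(readLines(pf), peps)
  ff <- withr::local_tempfile(fileext = ".fasta")
  writePeptides(peps, ff, format = "fasta")
  expect_equal(unname(as.character(Biostrings::readAAStringSet(ff))), peps)
})
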