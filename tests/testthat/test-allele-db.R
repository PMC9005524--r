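test_that("allele name parsing validates and round-trips nomenclature fields", {
  info <- parse_allele_name(c("A*01:01", "B*07:02:01", "C*04:01"))
  expect_equal(info$gene, c("A", "B", "C"))
  expect_equal(info$group, c("A*01", "B*07", "C*04"))
  expect_equal(info$protein, c("A*01:01", "B*07:02", "C*04:01"))
  expect_equal(info$name, c("A*01:01", "B*07:02:01", "C*04:01"))
  expect_error(parse_allele_name("D*01:01"), "malformed")
  expect_error(parse_allele_name("A-0101"), "malformed")
})

test_that("MSA rows reconstruct against the reference row", {
  lines <- c("# segments: exon1:8 intron1:4 exon2:8",
             "A*01:01 ACGTACGTAACCGGTTACGT",
             "A*01:02 --------------------",
             "A*01:03 T----------------..-",
             "A*02:01 ----****----GGTTACGT")
  db <- parse_msa(text = lines, kind = "gDNA")
  # all-match row is identical to the reference
  expect_equal(allele_sequence(db$records[["A*01:02"]]),
               "ACGTACGTAACCGGTTACGT")
  # substitution applied, gap characters removed
  expect_equal(db$records[["A*01:03"]]$segments$exon1, "TCGTACGT")
  expect_equal(db$records[["A*01:03"]]$segments$exon2, "GGTTAT")
  # '*' marks the segment missing
  expect_true(is.na(db$records[["A*02:01"]]$segments$exon1))
  expect_false(is.na(db$records[["A*02:01"]]$segments$intron1))
  expect_equal(db$msa_order, c("A*01:01", "A*01:02", "A*01:03", "A*02:01"))
})

test_that("malformed rows are rejected with the allele named", {
  lines <- c("# segments: exon1:8",
             "A*01:01 ACGTACGT",
             "A*01:02 ----")
  expect_error(parse_msa(text = lines), "A\\*01:02.*row length")
  expect_error(parse_msa(text = "# segments: exon1:4"), "empty")
})

test_that("fixture MSA reconstructs the generator's ground-truth sequences", {
  fx <- simulate_msa_fixture(n_alleles = 5L, seed = 17L)
  cdna <- parse_msa(text = fx$cdna, kind = "cDNA")
  gdna <- parse_msa(text = fx$gdna, kind = "gDNA")
  # unmasked gDNA rows parse straight back to the truth
  for (nm in fx$names) {
    if (length(fx$masked[[nm]]) == 0L) {
      expect_equal(allele_sequence(gdna$records[[nm]]), unname(fx$truth[nm]),
                   label = nm)
    }
  }
  # after imputation every allele matches the truth exactly
  db <- impute_database(cdna, gdna)
  for (nm in fx$names) {
    expect_equal(allele_sequence(db$records[[nm]]), unname(fx$truth[nm]),
                 label = nm)
  }
})

test_that("imputation follows the 4-digit, 2-digit, first-in-MSA donor cascade", {
  gdna_lines <- c(
    "# segments: exon1:6 intron1:4 exon2:6",
    "A*01:01 AAATTTGGGGCCCAAA",
    "A*01:03 ------------..--",       # 2-digit donor, earliest
    "A*01:04 ---C------------",       # 2-digit donor, later
    "A*01:02 ----------******",       # missing exon2, no 4-digit sibling
    "A*02:01:01 T---------------",
    "A*02:01:02 ------****------")    # missing intron1; 4-digit sibling exists
  cdna_lines <- c(
    "# segments: exon1:6 exon2:6",
    "A*01:01 AAATTTCCCAAA",
    "A*01:03 ----------..",
    "A*01:04 ---C--------",
    "A*01:02 ------------",
    "A*02:01:01 T-----------",
    "A*02:01:02 ------------")
  gdna <- parse_msa(text = gdna_lines, kind = "gDNA")
  cdna <- parse_msa(text = cdna_lines, kind = "cDNA")
  db <- impute_database(cdna, gdna)

  # 4-digit-identical donor preferred: intron1 of A*02:01:02 from A*02:01:01
  expect_equal(db$records[["A*02:01:02"]]$imputed[["intron1"]], "A*02:01:01")
  expect_equal(db$records[["A*02:01:02"]]$segments$intron1, "GGGG")
  # gDNA exon2 of A*01:02 is missing but its cDNA row is complete: no donor
  expect_equal(db$records[["A*01:02"]]$segments$exon2, "CCCAAA")
  expect_length(db$records[["A*01:02"]]$imputed, 0L)
  # complete allele untouched
  expect_length(db$records[["A*01:01"]]$imputed, 0L)
  expect_equal(allele_sequence(db$records[["A*01:01"]]), "AAATTTGGGGCCCAAA")
})

test_that("two-digit donor ties break by MSA listing order", {
  # A*01:05 lacks intron1 in gDNA; no 4-digit sibling; both A*01:03 and
  # A*01:04 qualify at the 2-digit tier -> the first listed wins.
  gdna_lines <- c(
    "# segments: exon1:4 intron1:4 exon2:4",
    "A*02:01 AAAAGGGGCCCC",
    "A*01:03 ----T-------",
    "A*01:04 ----CC------",
    "A*01:05 ----****----")
  cdna_lines <- c(
    "# segments: exon1:4 exon2:4",
    "A*02:01 AAAACCCC",
    "A*01:03 --------",
    "A*01:04 --------",
    "A*01:05 --------")
  db <- impute_database(parse_msa(text = cdna_lines, kind = "cDNA"),
                        parse_msa(text = gdna_lines, kind = "gDNA"))
  expect_equal(db$records[["A*01:05"]]$imputed[["intron1"]], "A*01:03")
  expect_equal(db$records[["A*01:05"]]$segments$intron1, "TGGG")
})

test_that("imputation is idempotent and never alters present segments", {
  fx <- simulate_msa_fixture(n_alleles = 6L, seed = 29L)
  cdna <- parse_msa(text = fx$cdna, kind = "cDNA")
  gdna <- parse_msa(text = fx$gdna, kind = "gDNA")
  db1 <- impute_database(cdna, gdna)
  # feeding the complete database back through changes nothing
  cdna2 <- db1
  cdna2$kind <- "cDNA"
  exons <- grep("^exon", db1$records[[1]]$segment_names, value = TRUE)
  cdna2$records <- lapply(db1$records, function(r) {
    r$segments <- r$segments[exons]; r$segment_names <- exons
    r$imputed <- character(0); r
  })
  db2 <- impute_database(cdna2, db1)
  for (nm in names(db1$records)) {
    expect_identical(db2$records[[nm]]$segments, db1$records[[nm]]$segments)
  }
  # segments present in the raw gDNA input survive imputation verbatim
  for (nm in fx$names) {
    for (sg in gdna$records[[nm]]$segment_names) {
      raw <- gdna$records[[nm]]$segments[[sg]]
      if (!is.na(raw)) expect_identical(db1$records[[nm]]$segments[[sg]], raw)
    }
  }
  expect_error(impute_database(structure(list(records = list(), msa_order = character(0)),
                                         class = "allele_db"), gdna),
               "empty")
})
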