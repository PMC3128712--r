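test_that("allele names normalize across legacy and colon spellings", {
  expect_equal(normalize_allele(c("DRB1*1301", "DRB1*13:01", " DRB1*0301")),
               c("DRB1*13:01", "DRB1*13:01", "DRB1*03:01"))
  expect_equal(normalize_allele("1301"), "13:01")
  expect_error(normalize_allele(""), "empty")
})

test_that("identity dashes expand against the reference row", {
  tab <- parse_allele_table(text = tiny_alignment_text())
  expect_equal(tab$positions, 1:3)
  expect_equal(unname(tab$seq["A*02:01", ]), c("N", "S", "F"))
  # a table whose rows all equal the reference is fully monomorphic
  mono <- parse_allele_table(text = paste("allele\t1\t2",
                                          "A*01:01\tN\tS",
                                          "A*02:01\t-\t-", sep = "\n"))
  prof <- find_polymorphic_positions(mono)
  expect_false(any(prof$polymorphic))
})

test_that("malformed alignment tables are rejected with the offending allele", {
  expect_error(parse_allele_table(text = paste("allele\t1\t2",
                                               "A*01:01\tN\tS",
                                               "A*02:01\tN", sep = "\n")),
               "ragged row for allele A\\*02:01")
  expect_error(parse_allele_table(text = paste("allele\t1",
                                               "A*0101\tN",
                                               "A*01:01\tS", sep = "\n")),
               "duplicate allele")
  expect_error(parse_allele_table(text = paste("allele\t1\t2",
                                               "A*01:01\tN\tB", sep = "\n")),
               "non-amino-acid")
  expect_error(parse_allele_table(text = paste("allele\t1",
                                               "A*01:01\t-", sep = "\n")),
               "reference")
})

test_that("three-letter residue codes are accepted and normalized", {
  tab <- parse_allele_table(text = paste("allele\t37\t86",
                                         "DRB1*03:01\tAsn\tVal",
                                         "DRB1*13:02\tAsn\tGly", sep = "\n"))
  expect_equal(unname(tab$seq[, "37"]), c("N", "N"))
  expect_equal(unname(tab$seq[, "86"]), c("V", "G"))
})

test_that("write/parse round trip reproduces the alignment exactly", {
  tab <- synthetic_drb1_alignment()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_allele_table(tab, f)
  back <- parse_allele_table(f)
  expect_identical(back$positions, tab$positions)
  expect_identical(back$seq, tab$seq)
})

test_that("the synthetic alignment carries the published residue 37/86 assignments", {
  tab <- synthetic_drb1_alignment()
  expect_equal(unname(tab$seq["DRB1*03:01", c("37", "86")]), c("N", "V"))
  expect_equal(unname(tab$seq["DRB1*13:01", c("37", "86")]), c("N", "V"))
  expect_equal(unname(tab$seq["DRB1*13:02", c("37", "86")]), c("N", "G"))
  expect_equal(unname(tab$seq["DRB1*09:01", c("37", "86")]), c("N", "G"))
  expect_equal(unname(tab$seq["DRB1*14:02", c("37", "86")]), c("N", "G"))
  # restricted to the five Asn37 alleles: 86 dimorphic {G,V}, 37 monomorphic
  five <- c("DRB1*03:01", "DRB1*09:01", "DRB1*13:01", "DRB1*13:02", "DRB1*14:02")
  prof <- find_polymorphic_positions(tab, five)
  expect_true(prof$polymorphic[prof$position == 86])
  expect_equal(prof$amino_acids[prof$position == 86], "G,V")
  expect_false(prof$polymorphic[prof$position == 37])
  expect_equal(prof$amino_acids[prof$position == 37], "N")
  expect_error(find_polymorphic_positions(tab, character(0)), "empty")
})

test_that("cohort translation assigns unordered per-residue amino-acid pairs", {
  tab <- synthetic_drb1_alignment()
  coh <- toy_cohort()
  rgm <- translate_cohort(coh, tab)
  j <- match(37, rgm$positions)
  # homozygote 03:01/03:01 carries Asn twice
  expect_equal(unname(c(rgm$pair1[1, j], rgm$pair2[1, j])), c("N", "N"))
  expect_equal(unname(residue_dosage(rgm, 37)[1, "N"]), 2L)
  # unknown alleles are named in the error
  bad <- cohort_genotypes("z", 1, "DRB1*99:99", "DRB1*03:01")
  expect_error(translate_cohort(bad, tab), "DRB1\\*99:99")
})

test_that("translation is invariant to chromosome order", {
  tab <- synthetic_drb1_alignment()
  coh <- toy_cohort()
  swapped <- cohort_genotypes(coh$sample_id, coh$status,
                              coh$allele2, coh$allele1)
  a <- translate_cohort(coh, tab)
  b <- translate_cohort(swapped, tab)
  expect_identical(a$pair1, b$pair1)
  expect_identical(a$pair2, b$pair2)
})

test_that("amino-acid allele counts equal brute-force chromosome enumeration", {
  tab <- synthetic_drb1_alignment()
  coh <- toy_cohort()
  rgm <- translate_cohort(coh, tab)
  chrom <- c(coh$allele1, coh$allele2)
  for (pos in c(11, 37, 71, 86)) {
    d <- residue_dosage(rgm, pos)
    brute <- table(tab$seq[chrom, as.character(pos)])
    for (aa in colnames(d)) {
      expect_equal(sum(d[, aa]), unname(brute[aa]), ignore_attr = TRUE)
    }
    # dosages across amino acids always sum to two chromosomes
    expect_true(all(rowSums(d) == 2L))
  }
})

test_that("unknown residues exclude a sample from that position only", {
  txt <- paste("allele\t1\t2",
               "A*01:01\tN\tS",
               "A*02:01\tX\tT",
               "A*03:01\tY\tS", sep = "\n")
  tab <- parse_allele_table(text = txt)
  coh <- cohort_genotypes(c("a", "b"), c(1, 0),
                          c("A*01:01", "A*02:01"), c("A*03:01", "A*03:01"))
  rgm <- translate_cohort(coh, tab)
  expect_true(rgm$excluded[2, "1"])
  expect_false(rgm$excluded[2, "2"])
  expect_equal(unname(rgm$n_excluded), c(1, 0))
  d <- residue_dosage(rgm, 1)
  expect_true(all(is.na(d[2, ])))
})
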