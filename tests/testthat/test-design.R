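# toy alignment with a dimorphic residue 1 {N,S} and a trimorphic residue 2
design_fixture <- function(n_nn = 5, n_ns = 4, n_ss = 3, status = NULL) {
  txt <- paste("allele\t1\t2",
               "A*01:01\tN\tF",
               "A*02:01\tS\tY",
               "A*03:01\tN\tL", sep = "\n")
  tab <- parse_allele_table(text = txt)
  a1 <- c(rep("A*01:01", n_nn), rep("A*01:01", n_ns), rep("A*02:01", n_ss))
  a2 <- c(rep("A*01:01", n_nn), rep("A*02:01", n_ns), rep("A*02:01", n_ss))
  n <- length(a1)
  if (is.null(status)) status <- rep_len(c(1, 0), n)
  coh <- cohort_genotypes(sprintf("s%02d", seq_len(n)), status, a1, a2)
  translate_cohort(coh, tab)
}

test_that("dosage design encodes copy numbers against the major reference", {
  rgm <- design_fixture()
  d <- dosage_design(rgm, 1)
  # N is the most frequent amino acid -> reference; single S column
  expect_equal(colnames(d$X), c("(Intercept)", "r1.S"))
  expect_equal(unname(d$X[, "r1.S"]),
               c(rep(0, 5), rep(1, 4), rep(2, 3)))
  # homozygotes for the non-reference amino acid score 2
  expect_equal(max(d$X[, "r1.S"]), 2)
})

test_that("a residue with k amino acids yields k-1 dosage columns", {
  rgm <- translate_cohort(generate_cohort(psc_demo_spec(seed = 11)),
                          synthetic_drb1_alignment())
  d <- dosage_design(rgm, 37)
  # five amino acids observed at residue 37 -> four columns + intercept
  expect_equal(ncol(d$X), 5L)
  expect_true(all(d$X[, -1] %in% 0:2))
})

test_that("monomorphic residues are rejected by the design builders", {
  txt <- paste("allele\t1\t2",
               "A*01:01\tN\tF",
               "A*02:01\tN\tY", sep = "\n")
  tab <- parse_allele_table(text = txt)
  coh <- cohort_genotypes(c("a", "b"), c(1, 0),
                          c("A*01:01", "A*02:01"), c("A*02:01", "A*01:01"))
  rgm <- translate_cohort(coh, tab)
  expect_error(dosage_design(rgm, 1), "not in the residue matrix")
})

test_that("genotype design pools pairs rare in either arm", {
  # 50/50 NN, 30/30 NS, 20/20 SS: three common categories -> 2 columns
  rgm <- design_fixture(n_nn = 100, n_ns = 60, n_ss = 40,
                        status = c(rep(1, 50), rep(0, 50), rep(1, 30),
                                   rep(0, 30), rep(1, 20), rep(0, 20)))
  d <- genotype_design(rgm, 1)
  expect_equal(ncol(d$X), 3L)
  expect_equal(sort(unique(d$categories[["1"]])), c("N/N", "N/S", "S/S"))

  # pairs seen once per arm pool as rare (and the pooled category, with two
  # occurrences per arm, is retained)
  txt <- paste("allele\t1",
               "A*01:01\tN", "A*02:01\tS", "A*03:01\tF", "A*04:01\tY",
               sep = "\n")
  tab <- parse_allele_table(text = txt)
  a1 <- c(rep("A*01:01", 12), "A*03:01", "A*03:01", "A*04:01", "A*04:01")
  a2 <- c(rep("A*01:01", 6), rep("A*02:01", 6),
          "A*03:01", "A*03:01", "A*04:01", "A*04:01")
  st <- c(rep(c(1, 0), 6), 1, 0, 1, 0)
  coh <- cohort_genotypes(sprintf("s%02d", 1:16), st, a1, a2)
  rgm2 <- translate_cohort(coh, tab)
  d2 <- genotype_design(rgm2, 1)
  expect_true("rare" %in% d2$categories[["1"]])
  expect_equal(sum(d2$categories[["1"]] == "rare"), 4L)

  # category census equals brute-force enumeration of the pooling rule
  pair <- paste(rgm2$pair1[, "1"], rgm2$pair2[, "1"], sep = "/")
  brute <- vapply(unique(pair), function(pp) {
    sum(pair == pp & st == 1) >= 2 && sum(pair == pp & st == 0) >= 2
  }, logical(1))
  expect_setequal(unique(d2$categories[["1"]]),
                  c(names(brute)[brute], if (any(!brute)) "rare"))
  expect_setequal(pair[d2$categories[["1"]] == "rare"], names(brute)[!brute])
})

test_that("an under-filled rare category merges into the reference with a warning", {
  txt <- paste("allele\t1",
               "A*01:01\tN", "A*02:01\tS", "A*03:01\tF", sep = "\n")
  tab <- parse_allele_table(text = txt)
  # one single rare F/F pair (1 case, 0 controls)
  a1 <- c(rep("A*01:01", 8), "A*03:01")
  a2 <- c(rep("A*01:01", 4), rep("A*02:01", 4), "A*03:01")
  st <- c(rep(c(1, 0), 4), 1)
  coh <- cohort_genotypes(sprintf("s%d", 1:9), st, a1, a2)
  rgm <- translate_cohort(coh, tab)
  expect_warning(d <- genotype_design(rgm, 1), "merged into the majority")
  expect_false("rare" %in% d$categories[["1"]])
})

test_that("a residue with a single observed pair has no degrees of freedom", {
  # every sample heterozygous N/S: position 1 is polymorphic yet shows a
  # single unordered pair
  rgm <- design_fixture(n_nn = 0, n_ns = 6, n_ss = 0)
  expect_error(genotype_design(rgm, 1), "single observed")
})
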