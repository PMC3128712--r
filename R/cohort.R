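#' Construct a case-control diplotype cohort
#'
#' @param sample_id unique sample identifiers.
#' @param status binary phenotype, 1 = case, 0 = control.
#' @param allele1,allele2 four-digit HLA-DRB1 allele names (either spelling;
#'   normalized with [normalize_allele()]).
#' @return a `cohort_genotypes` data frame.
#' @export
cohort_genotypes <- function(sample_id, status, allele1, allele2) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) stop("sample ids are not unique")
  status <- as.integer(status)
  if (anyNA(status) || !all(status %in% c(0L, 1L))) {
    stop("status must be strictly binary (0 = control, 1 = case)")
  }
  out <- data.frame(sample_id = sample_id,
                    status = status,
                    allele1 = normalize_allele(as.character(allele1)),
                    allele2 = normalize_allele(as.character(allele2)),
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_genotypes", "data.frame")
  out
}

#' Read a cohort CSV
#'
#' Expects the header `sample_id,status,allele1,allele2` with status in
#' \{0,1\}.
#'
#' @param file path to a CSV file.
#' @return a `cohort_genotypes` data frame.
#' @export
read_cohort <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "status", "allele1", "allele2")
  if (!all(need %in% names(df))) {
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  }
  cohort_genotypes(df$sample_id, df$status, df$allele1, df$allele2)
}

#' Write a cohort CSV
#' @param x a `cohort_genotypes` data frame.
#' @param file path to write to.
#' @return `file`, invisibly.
#' @export
write_cohort <- function(x, file) {
  stopifnot(inherits(x, "cohort_genotypes"))
  utils::write.csv(as.data.frame(x)[, c("sample_id", "status", "allele1", "allele2")],
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Translate a diplotype cohort into per-residue amino-acid genotypes
#'
#' Each individual carries two HLA-DRB1 alleles; at every polymorphic exon-2
#' position the individual is assigned the unordered pair of amino acids
#' encoded by the two alleles. Polymorphism is assessed over the alleles
#' actually present in the cohort. A sample whose allele carries the unknown
#' residue `X` at a position is excluded from that position only; the count
#' of such exclusions is kept per position.
#'
#' @param cohort a `cohort_genotypes` data frame.
#' @param alignment an `allele_alignment`.
#' @return a `residue_matrix`: list with `sample_id`, `status`, `positions`
#'   (polymorphic positions), `pair1`/`pair2` (n x p character matrices with
#'   `pair1 <= pair2` so pairs are order-insensitive), `excluded` (n x p
#'   logical) and `n_excluded` (per-position totals).
#' @export
translate_cohort <- function(cohort, alignment) {
  stopifnot(inherits(cohort, "cohort_genotypes"),
            inherits(alignment, "allele_alignment"))
  used <- unique(c(cohort$allele1, cohort$allele2))
  missing <- setdiff(used, alignment$alleles)
  if (length(missing)) {
    stop("cohort allele(s) not in the alignment: ", paste(missing, collapse = ", "))
  }
  prof <- find_polymorphic_positions(alignment, used)
  positions <- prof$position[prof$polymorphic]
  if (length(positions) == 0L) stop("no polymorphic positions among cohort alleles")
  cols <- as.character(positions)
  a1 <- alignment$seq[cohort$allele1, cols, drop = FALSE]
  a2 <- alignment$seq[cohort$allele2, cols, drop = FALSE]
  swap <- a1 > a2
  p1 <- ifelse(swap, a2, a1)
  p2 <- ifelse(swap, a1, a2)
  excl <- p1 == "X" | p2 == "X"
  dimnames(p1) <- dimnames(p2) <- dimnames(excl) <-
    list(cohort$sample_id, cols)
  structure(list(sample_id = cohort$sample_id,
                 status = as.integer(cohort$status),
                 positions = positions,
                 pair1 = p1, pair2 = p2,
                 excluded = excl,
                 n_excluded = colSums(excl)),
            class = "residue_matrix")
}

#' Per-amino-acid dosage counts at one residue
#'
#' @param x a `residue_matrix`.
#' @param position a polymorphic position present in `x`.
#' @param samples optional integer indices of samples to include.
#' @return integer matrix (samples x amino acids) of copy numbers in
#'   \{0,1,2\}; rows for excluded samples are `NA`.
#' @export
residue_dosage <- function(x, position, samples = seq_along(x$sample_id)) {
  stopifnot(inherits(x, "residue_matrix"))
  j <- match(position, x$positions)
  if (is.na(j)) stop("position ", position, " is not in the residue matrix")
  p1 <- x$pair1[samples, j]
  p2 <- x$pair2[samples, j]
  excl <- x$excluded[samples, j]
  aa <- sort(setdiff(unique(c(p1[!excl], p2[!excl])), "X"))
  d <- vapply(aa, function(a) (p1 == a) + (p2 == a), integer(length(p1)))
  d <- matrix(as.integer(d), nrow = length(p1),
              dimnames = list(x$sample_id[samples], aa))
  d[excl, ] <- NA_integer_
  d
}

#' @export
print.residue_matrix <- function(x, ...) {
  cat("Residue genotype matrix:", length(x$sample_id), "samples (",
      sum(x$status == 1L), "cases /", sum(x$status == 0L), "controls ),",
      length(x$positions), "polymorphic positions\n")
  if (any(x$n_excluded > 0)) {
    cat("Samples excluded for unknown residues:",
        sum(x$n_excluded), "sample-position pairs\n")
  }
  invisible(x)
}
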