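# Carrier- and allele-level 2x2 contingency statistics: Woolf odds ratios
# (optionally with Haldane's +0.5 correction), chi-square / Fisher
# association tests and Bonferroni adjustment.

#' Construct a 2x2 exposure table
#'
#' @param a exposed cases; @param b unexposed cases; @param c exposed
#'   controls; @param d unexposed controls.
#' @param level `"carrier"` (individual counts: at least one copy) or
#'   `"allele"` (chromosome counts).
#' @param label free-text exposure description.
#' @return a `contingency_2x2` object.
#' @export
contingency_2x2 <- function(a, b, c, d, level = c("carrier", "allele"),
                            label = "") {
  level <- match.arg(level)
  cells <- c(a = a, b = b, c = c, d = d)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  structure(list(a = a, b = b, c = c, d = d, level = level, label = label),
            class = "contingency_2x2")
}

#' Carrier-frequency 2x2 table
#'
#' Counts individuals carrying at least one copy of the exposure: an amino
#' acid at a residue (for a `residue_matrix`) or an allele (for a
#' `cohort_genotypes`). Samples excluded at the residue (unknown amino acid)
#' are dropped.
#'
#' @param x a `residue_matrix` or `cohort_genotypes`.
#' @param ... passed to methods.
#' @return a `contingency_2x2` with `level = "carrier"`.
#' @export
carrier_table <- function(x, ...) UseMethod("carrier_table")

#' @rdname carrier_table
#' @param position residue position; @param amino one-letter amino acid.
#' @export
carrier_table.residue_matrix <- function(x, position, amino, ...) {
  j <- match(position, x$positions)
  if (is.na(j)) stop("position ", position, " not in the residue matrix")
  ok <- !x$excluded[, j]
  carries <- (x$pair1[, j] == amino | x$pair2[, j] == amino) & ok
  y <- x$status
  contingency_2x2(sum(carries & y == 1L & ok), sum(!carries & y == 1L & ok),
                  sum(carries & y == 0L & ok), sum(!carries & y == 0L & ok),
                  level = "carrier", label = paste0(amino, position))
}

#' @rdname carrier_table
#' @param allele allele name (normalized internally).
#' @export
carrier_table.cohort_genotypes <- function(x, allele, ...) {
  al <- normalize_allele(allele)
  carries <- x$allele1 == al | x$allele2 == al
  y <- x$status
  contingency_2x2(sum(carries & y == 1L), sum(!carries & y == 1L),
                  sum(carries & y == 0L), sum(!carries & y == 0L),
                  level = "carrier", label = al)
}

#' Allele-frequency (chromosome-level) 2x2 table
#'
#' As [carrier_table()] but counting chromosomes: a homozygote contributes
#' two exposed units, and case/control margins equal twice the individual
#' counts.
#'
#' @inheritParams carrier_table
#' @return a `contingency_2x2` with `level = "allele"`.
#' @export
allele_table <- function(x, ...) UseMethod("allele_table")

#' @rdname allele_table
#' @param position residue position; @param amino one-letter amino acid.
#' @export
allele_table.residue_matrix <- function(x, position, amino, ...) {
  j <- match(position, x$positions)
  if (is.na(j)) stop("position ", position, " not in the residue matrix")
  ok <- !x$excluded[, j]
  copies <- (x$pair1[, j] == amino) + (x$pair2[, j] == amino)
  y <- x$status
  a <- sum(copies[ok & y == 1L])
  n1 <- 2L * sum(ok & y == 1L)
  c_ <- sum(copies[ok & y == 0L])
  n0 <- 2L * sum(ok & y == 0L)
  contingency_2x2(a, n1 - a, c_, n0 - c_,
                  level = "allele", label = paste0(amino, position))
}

#' @rdname allele_table
#' @param allele allele name (normalized internally).
#' @export
allele_table.cohort_genotypes <- function(x, allele, ...) {
  al <- normalize_allele(allele)
  copies <- (x$allele1 == al) + (x$allele2 == al)
  y <- x$status
  a <- sum(copies[y == 1L])
  c_ <- sum(copies[y == 0L])
  contingency_2x2(a, 2L * sum(y == 1L) - a, c_, 2L * sum(y == 0L) - c_,
                  level = "allele", label = al)
}

#' Woolf odds ratio with optional Haldane correction
#'
#' Point estimate `(a d)/(b c)` with the Woolf 95% confidence interval
#' `exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. With
#' `correction = "haldane"`, 0.5 is added to every cell first (always, not
#' only for zero cells). Both conventions are deliberately explicit because
#' published allele-level tables typically use Haldane throughout while
#' in-text carrier ratios often do not.
#'
#' @param table a `contingency_2x2`.
#' @param correction `"haldane"` or `"none"`.
#' @return an `or_result`: `or`, `ci_low`, `ci_high`, `correction`, `label`.
#' @export
woolf_or <- function(table, correction = c("haldane", "none")) {
  stopifnot(inherits(table, "contingency_2x2"))
  correction <- match.arg(correction)
  cells <- c(table$a, table$b, table$c, table$d)
  if (correction == "none" && any(cells == 0)) {
    stop("zero cell in the 2x2 table; use correction = 'haldane'")
  }
  if (correction == "haldane") cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  structure(list(or = or,
                 ci_low = exp(log(or) - 1.96 * se),
                 ci_high = exp(log(or) + 1.96 * se),
                 correction = correction, label = table$label),
            class = "or_result")
}

#' Chi-square or Fisher association test for a 2x2 table
#'
#' Pearson chi-square without continuity correction when all expected cell
#' counts are at least 5 (Cochran's rule), otherwise the two-sided Fisher
#' exact test (summing tables at most as probable as the observed one).
#'
#' @param table a `contingency_2x2`.
#' @return the two-sided p-value, with attribute `method`.
#' @export
association_test <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  m <- rbind(c(table$a, table$b), c(table$c, table$d))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("empty margin in the 2x2 table")
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    p <- fisher.test(m)$p.value
    attr(p, "method") <- "fisher"
  } else {
    p <- suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
    attr(p, "method") <- "chisq"
  }
  p
}

#' Bonferroni correction
#'
#' @param p p-value(s) in (0, 1].
#' @param m number of comparisons (>= 1).
#' @return `min(1, m * p)`, vectorized over `p`.
#' @export
bonferroni <- function(p, m) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  if (m < 1 || m != round(m)) stop("m must be a positive integer")
  pmin(1, m * p)
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  cat(sprintf("2x2 table (%s level) %s\n", x$level,
              if (nzchar(x$label)) paste0("[", x$label, "]") else ""))
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(c("case", "control"), c("exposed", "unexposed")))
  print(m)
  invisible(x)
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR%s = %.3f (95%% CI %.3f-%.3f) [%s correction]\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "",
              x$or, x$ci_low, x$ci_high, x$correction))
  invisible(x)
}

#' Residue-level epidemiology report
#'
#' Convenience wrapper assembling, for every amino acid at a residue, the
#' carrier- and allele-level counts, Woolf odds ratios and association
#' p-values in one data frame (the layout of published amino-acid frequency
#' tables).
#'
#' @param rgm a `residue_matrix`.
#' @param position residue position.
#' @param correction passed to [woolf_or()] (default `"haldane"`).
#' @param m_bonferroni number of comparisons for the adjusted p (default:
#'   none, returns `NA`).
#' @return data frame with one row per amino acid and level.
#' @export
residue_epistats <- function(rgm, position, correction = "haldane",
                             m_bonferroni = NULL) {
  j <- match(position, rgm$positions)
  if (is.na(j)) stop("position ", position, " not in the residue matrix")
  ok <- !rgm$excluded[, j]
  aa <- sort(setdiff(unique(c(rgm$pair1[ok, j], rgm$pair2[ok, j])), "X"))
  rows <- lapply(aa, function(a) {
    do.call(rbind, lapply(c("carrier", "allele"), function(lev) {
      tab <- if (lev == "carrier") carrier_table(rgm, position, a) else
        allele_table(rgm, position, a)
      o <- woolf_or(tab, correction)
      p <- association_test(tab)
      data.frame(position = position, amino = a, level = lev,
                 a = tab$a, b = tab$b, c = tab$c, d = tab$d,
                 pct_case = round(100 * tab$a / (tab$a + tab$b)),
                 pct_control = round(100 * tab$c / (tab$c + tab$d)),
                 or = o$or, ci_low = o$ci_low, ci_high = o$ci_high,
                 p = as.numeric(p),
                 p_bonferroni = if (is.null(m_bonferroni)) NA_real_ else
                   bonferroni(as.numeric(p), m_bonferroni),
                 method = attr(p, "method"), correction = correction)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
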