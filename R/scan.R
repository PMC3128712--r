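#' Stepwise conditional likelihood-ratio residue scan
#'
#' For every polymorphic residue not already conditioned on, fits the base
#' model (the conditioning residues only, or intercept-only when none) and
#' the full model (base + candidate) on the samples usable at all involved
#' residues, and tests the candidate with a likelihood-ratio chi-square.
#' Results are ranked by ascending p-value, reproducing the
#' single-/two-/three-residue stepwise scheme of amino-acid fine-mapping:
#' an empty `base_residues` gives the single-residue scan, one base residue
#' the two-residue conditional scan, and so on.
#'
#' A candidate whose fit fails (collinearity with the base residues, perfect
#' separation, non-convergence) is recorded with `ok = FALSE` and excluded
#' from the ranking; the scan itself never aborts.
#'
#' @param rgm a `residue_matrix` from [translate_cohort()].
#' @param base_residues positions conditioned on (default none).
#' @param coding `"dosage"` (per-copy additive) or `"genotype"`
#'   (amino-acid-pair indicators with rare-pair pooling).
#' @param candidates optional subset of positions to scan (default: all
#'   polymorphic positions not in `base_residues`).
#' @param min_count rare-pair pooling threshold for the genotype coding.
#' @return a `residue_scan` data frame: `position`, `n_used`, `statistic`,
#'   `df`, `p`, `rank` (NA for failed candidates), `ok`, `note`; sorted by
#'   ascending p with failures last.
#' @export
residue_scan <- function(rgm, base_residues = integer(),
                         coding = c("dosage", "genotype"),
                         candidates = NULL, min_count = 2) {
  stopifnot(inherits(rgm, "residue_matrix"))
  coding <- match.arg(coding)
  base_residues <- as.integer(base_residues)
  if (length(base_residues) && !all(base_residues %in% rgm$positions)) {
    stop("base residue(s) not polymorphic in this cohort")
  }
  cand <- if (is.null(candidates)) rgm$positions else as.integer(candidates)
  cand <- setdiff(cand, base_residues)
  if (length(cand) == 0L) stop("no candidate residues to scan")
  builder <- switch(coding,
                    dosage = function(res, keep) dosage_design(rgm, res, samples = keep),
                    genotype = function(res, keep)
                      genotype_design(rgm, res, min_count = min_count, samples = keep))

  rows <- lapply(cand, function(pos) {
    out <- data.frame(position = pos, n_used = NA_integer_,
                      statistic = NA_real_, df = NA_integer_, p = NA_real_,
                      ok = FALSE, note = "")
    tryCatch({
      jj <- match(c(base_residues, pos), rgm$positions)
      keep <- which(rowSums(rgm$excluded[, jj, drop = FALSE]) == 0L)
      y <- rgm$status[keep]
      full_d <- builder(c(base_residues, pos), keep)
      full_f <- fit_logistic(full_d, y)
      base_f <- if (length(base_residues)) {
        fit_logistic(builder(base_residues, keep), y)
      } else {
        fit_logistic(matrix(1, length(keep), 1,
                            dimnames = list(NULL, "(Intercept)")), y)
      }
      if (!full_f$converged || !base_f$converged) {
        out$note <- if (full_f$separation || base_f$separation) {
          "separation"
        } else "non-convergence"
        return(out)
      }
      l <- lrt(base_f, full_f)
      out$n_used <- length(keep)
      out$statistic <- l$statistic
      out$df <- l$df
      out$p <- l$p
      out$ok <- TRUE
      out
    }, error = function(e) {
      out$note <- conditionMessage(e)
      out
    })
  })
  res <- do.call(rbind, rows)
  res <- res[order(!res$ok, res$p, res$position), , drop = FALSE]
  res$rank <- NA_integer_
  res$rank[res$ok] <- rank(res$p[res$ok], ties.method = "min")
  rownames(res) <- NULL
  attr(res, "base_residues") <- base_residues
  attr(res, "coding") <- coding
  class(res) <- c("residue_scan", "data.frame")
  res
}

#' @export
print.residue_scan <- function(x, digits = 3, ...) {
  base <- attr(x, "base_residues")
  cat("Residue LR scan (", attr(x, "coding"), " coding); base model: ",
      if (length(base)) paste("residue", paste(base, collapse = "+")) else
        "intercept only", "\n", sep = "")
  y <- as.data.frame(x)
  y$p <- format.pval(y$p, digits = digits)
  print(y, row.names = FALSE)
  invisible(x)
}
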