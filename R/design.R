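# Regression design matrices for the residue scan.
#
# Two codings are supported. "dosage": one covariate per non-reference amino
# acid at a residue, valued 0/1/2 (copy number). "genotype": one indicator per
# observed unordered amino-acid pair, with pairs rarer than `min_count` in
# either arm pooled into a single "rare" category. LR tests downstream are
# invariant to the reference choice; for determinism the most frequent amino
# acid / pair is used as reference (alphabetical tie-break).

.design_keep <- function(rgm, residues, samples) {
  j <- match(residues, rgm$positions)
  if (anyNA(j)) {
    stop("position(s) not in the residue matrix: ",
         paste(residues[is.na(j)], collapse = ", "))
  }
  if (is.null(samples)) {
    samples <- which(rowSums(rgm$excluded[, j, drop = FALSE]) == 0L)
  }
  samples
}

#' Allele-dosage design matrix
#'
#' For each requested residue, one column per observed non-reference amino
#' acid holding its copy number (0, 1 or 2) in each individual, plus an
#' intercept. Column labels are `r<position>.<amino>`.
#'
#' @param rgm a `residue_matrix`.
#' @param residues positions to encode (must be polymorphic among the kept
#'   samples).
#' @param reference optional named list/character vector mapping position to
#'   the reference amino acid; default is the most frequent.
#' @param samples optional integer sample indices; default: all samples not
#'   excluded (unknown residue) at any requested position.
#' @return a `design_matrix` object: list with `X` (numeric matrix incl.
#'   intercept), `coding`, `residues`, `keep` (sample indices), `reference`.
#' @export
dosage_design <- function(rgm, residues, reference = NULL, samples = NULL) {
  stopifnot(inherits(rgm, "residue_matrix"), length(residues) >= 1L)
  keep <- .design_keep(rgm, residues, samples)
  if (length(keep) == 0L) stop("no usable samples for residues ",
                               paste(residues, collapse = ", "))
  cols <- list()
  refs <- list()
  for (pos in residues) {
    d <- residue_dosage(rgm, pos, keep)
    aa <- colnames(d)
    if (length(aa) < 2L) {
      stop("residue ", pos, " is monomorphic among the kept samples")
    }
    ref <- reference[[as.character(pos)]]
    if (is.null(ref)) {
      tot <- colSums(d)
      ref <- aa[order(-tot, aa)][1L]  # most frequent, alphabetical tie-break
    } else if (!ref %in% aa) {
      stop("requested reference '", ref, "' not observed at residue ", pos)
    }
    refs[[as.character(pos)]] <- ref
    keep_aa <- setdiff(aa, ref)
    block <- d[, keep_aa, drop = FALSE]
    colnames(block) <- paste0("r", pos, ".", keep_aa)
    cols[[as.character(pos)]] <- block
  }
  X <- cbind("(Intercept)" = 1, do.call(cbind, unname(cols)))
  structure(list(X = X, coding = "dosage", residues = residues,
                 keep = keep, reference = refs),
            class = "design_matrix")
}

#' Genotype (amino-acid pair) design matrix
#'
#' One indicator column per observed unordered amino-acid pair at each
#' residue, except that pairs with fewer than `min_count` occurrences in
#' cases or in controls are pooled into one `rare` category, and one
#' category (the most frequent) is omitted as reference. If the pooled
#' `rare` category itself remains below `min_count` in either arm it is
#' merged into the reference with a warning.
#'
#' @inheritParams dosage_design
#' @param min_count pooling threshold (pairs below it in either arm are
#'   grouped); default 2.
#' @return a `design_matrix` object (see [dosage_design()]); the per-residue
#'   category assignment is kept in `categories`.
#' @export
genotype_design <- function(rgm, residues, min_count = 2, reference = NULL,
                            samples = NULL) {
  stopifnot(inherits(rgm, "residue_matrix"), length(residues) >= 1L)
  keep <- .design_keep(rgm, residues, samples)
  if (length(keep) == 0L) stop("no usable samples")
  y <- rgm$status[keep]
  cols <- list()
  refs <- list()
  cats <- list()
  for (pos in residues) {
    j <- match(pos, rgm$positions)
    pair <- paste(rgm$pair1[keep, j], rgm$pair2[keep, j], sep = "/")
    if (length(unique(pair)) < 2L) {
      stop("residue ", pos, " has a single observed amino-acid pair (no df)")
    }
    ncase <- tapply(y == 1L, pair, sum)
    nctrl <- tapply(y == 0L, pair, sum)
    rare <- names(ncase)[ncase < min_count | nctrl < min_count]
    grp <- pair
    if (length(rare)) grp[pair %in% rare] <- "rare"
    if ("rare" %in% grp) {
      rc <- sum(y == 1L & grp == "rare")
      rn <- sum(y == 0L & grp == "rare")
      if (rc < min_count || rn < min_count) {
        # absorb an under-filled pooled category into the most frequent
        # pair; done before the reference is chosen so the fitted model
        # never depends on the reference choice
        common <- names(sort(table(grp[grp != "rare"]), decreasing = TRUE))
        if (length(common) == 0L) {
          stop("residue ", pos, " has no common category left after pooling")
        }
        warning("residue ", pos, ": pooled rare category still below ",
                min_count, " in one arm; merged into the majority category")
        grp[grp == "rare"] <- common[1L]
      }
    }
    tab <- sort(table(grp), decreasing = TRUE)
    ref <- names(tab)[order(-tab, names(tab))][1L]
    user_ref <- reference[[as.character(pos)]]
    if (!is.null(user_ref)) {
      if (!user_ref %in% names(tab)) {
        stop("requested reference category '", user_ref,
             "' not present at residue ", pos)
      }
      ref <- user_ref
    }
    lev <- setdiff(names(sort(table(grp), decreasing = TRUE)), ref)
    if (length(lev) == 0L) {
      stop("residue ", pos, " has a single category after pooling (no df)")
    }
    block <- vapply(lev, function(g) as.numeric(grp == g),
                    numeric(length(grp)))
    block <- matrix(block, ncol = length(lev),
                    dimnames = list(NULL, paste0("r", pos, ".g", lev)))
    cols[[as.character(pos)]] <- block
    refs[[as.character(pos)]] <- ref
    cats[[as.character(pos)]] <- grp
  }
  X <- cbind("(Intercept)" = 1, do.call(cbind, unname(cols)))
  structure(list(X = X, coding = "genotype", residues = residues,
                 keep = keep, reference = refs, categories = cats,
                 min_count = min_count),
            class = "design_matrix")
}
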