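#' Normalize HLA allele names
#'
#' Canonicalizes allele spellings to the colon-delimited protein-level form,
#' so that `"DRB1*1301"` and `"DRB1*13:01"` refer to the same allele. The
#' locus prefix (anything before `*`) is preserved verbatim; a bare four-digit
#' field (legacy spelling) is split into two two-digit fields.
#'
#' @param x character vector of allele names.
#' @return character vector of normalized names.
#' @examples
#' normalize_allele(c("DRB1*1301", "DRB1*13:01", "0301"))
#' @export
normalize_allele <- function(x) {
  if (!is.character(x)) stop("allele names must be character")
  x <- trimws(x)
  if (any(!nzchar(x) | is.na(x))) stop("empty or missing allele name")
  norm1 <- function(s) {
    parts <- strsplit(s, "*", fixed = TRUE)[[1L]]
    if (length(parts) > 2L) stop("malformed allele name: ", s, call. = FALSE)
    field <- parts[length(parts)]
    if (!grepl(":", field, fixed = TRUE) && grepl("^[0-9]{4}$", field)) {
      field <- paste0(substr(field, 1L, 2L), ":", substr(field, 3L, 4L))
    }
    if (length(parts) == 2L) paste0(parts[1L], "*", field) else field
  }
  vapply(x, norm1, character(1L), USE.NAMES = FALSE)
}

#' Parse an allele-alignment table
#'
#' Reads a tab-separated exon-2 amino-acid alignment: the first column is
#' `allele`, the remaining column headers are integer residue positions in
#' mature-protein numbering, and each cell holds a single residue code
#' (one-letter or three-letter; `X` = unknown). A dash `-` means
#' "identical to the reference", which is the first data row (the usual
#' IMGT-style alignment shorthand). Lines starting with `#` are comments.
#'
#' @param file path to a TSV file (ignored when `text` is given).
#' @param text optional character scalar/vector holding the table itself.
#' @return an object of class `allele_alignment`: a list with `positions`
#'   (integer vector), `alleles` (normalized names) and `seq` (character
#'   matrix, alleles x positions, one-letter codes).
#' @seealso [write_allele_table()], [find_polymorphic_positions()]
#' @examples
#' tsv <- system.file("extdata", "synthetic_drb1_alignment.tsv",
#'                    package = "hlafine")
#' aln <- parse_allele_table(tsv)
#' aln$seq["DRB1*13:02", c("37", "86")]
#' @export
parse_allele_table <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) {
    unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  } else {
    readLines(file, warn = FALSE)
  }
  lines <- lines[!grepl("^[[:space:]]*#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    stop("alignment table needs a header row and at least one allele row")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1L]])
  if (tolower(header[1L]) != "allele") {
    stop("first column of the alignment table must be named 'allele'")
  }
  positions <- suppressWarnings(as.integer(header[-1L]))
  if (anyNA(positions)) {
    stop("alignment column headers must be integer residue positions")
  }
  if (anyDuplicated(positions)) stop("duplicated residue positions in header")
  npos <- length(positions)

  alleles <- character(length(fields) - 1L)
  seqm <- matrix(NA_character_, nrow = length(fields) - 1L, ncol = npos)
  for (i in seq_along(alleles)) {
    row <- trimws(fields[[i + 1L]])
    name <- normalize_allele(row[1L])
    if (length(row) != npos + 1L) {
      stop("ragged row for allele ", name, ": expected ", npos,
           " residue cells, found ", length(row) - 1L)
    }
    alleles[i] <- name
    seqm[i, ] <- row[-1L]
  }
  if (anyDuplicated(alleles)) {
    stop("duplicate allele name(s) after normalization: ",
         paste(unique(alleles[duplicated(alleles)]), collapse = ", "))
  }
  # identity-dash expansion against the reference (first data row)
  if (any(seqm[1L, ] == "-")) {
    stop("reference allele (first row) may not contain '-' cells")
  }
  for (i in seq_len(nrow(seqm))[-1L]) {
    dash <- seqm[i, ] == "-"
    seqm[i, dash] <- seqm[1L, dash]
  }
  seqm[] <- .aa_normalize(as.vector(seqm))
  bad <- !(seqm %in% c(.AA1, "X"))
  if (any(bad)) {
    off <- arrayInd(which(bad)[1L], dim(seqm))
    stop("non-amino-acid character '", seqm[bad][1L], "' for allele ",
         alleles[off[1L, 1L]], " at position ", positions[off[1L, 2L]])
  }
  dimnames(seqm) <- list(alleles, as.character(positions))
  structure(list(positions = positions, alleles = alleles, seq = seqm),
            class = "allele_alignment")
}

#' Write an allele alignment back to TSV
#'
#' Emits the plain (fully expanded, no dash shorthand) dialect accepted by
#' [parse_allele_table()]; parsing the output reproduces the object exactly.
#'
#' @param x an `allele_alignment`.
#' @param file path to write to.
#' @return `file`, invisibly.
#' @export
write_allele_table <- function(x, file) {
  stopifnot(inherits(x, "allele_alignment"))
  header <- paste(c("allele", x$positions), collapse = "\t")
  rows <- vapply(seq_along(x$alleles), function(i) {
    paste(c(x$alleles[i], x$seq[i, ]), collapse = "\t")
  }, character(1L))
  writeLines(c(header, rows), file)
  invisible(file)
}

#' Profile residue polymorphism across a set of alleles
#'
#' A position is polymorphic when at least two distinct known amino acids
#' (unknown `X` excluded) are observed among the given alleles.
#'
#' @param x an `allele_alignment`.
#' @param alleles allele names to consider (default: all in the table).
#' @return a `residue_profile` data frame with columns `position`,
#'   `amino_acids` (comma-separated, sorted), `n_distinct`, `polymorphic`.
#' @export
find_polymorphic_positions <- function(x, alleles = x$alleles) {
  stopifnot(inherits(x, "allele_alignment"))
  alleles <- normalize_allele(alleles)
  if (length(alleles) == 0L) stop("empty allele set")
  missing <- setdiff(alleles, x$alleles)
  if (length(missing)) {
    stop("allele(s) absent from the alignment: ", paste(missing, collapse = ", "))
  }
  sub <- x$seq[alleles, , drop = FALSE]
  res <- lapply(seq_along(x$positions), function(j) {
    aa <- sort(setdiff(unique(sub[, j]), "X"))
    data.frame(position = x$positions[j],
               amino_acids = paste(aa, collapse = ","),
               n_distinct = length(aa),
               polymorphic = length(aa) >= 2L)
  })
  out <- do.call(rbind, res)
  class(out) <- c("residue_profile", "data.frame")
  out
}

#' @export
print.allele_alignment <- function(x, ...) {
  cat("Allele alignment:", length(x$alleles), "alleles x",
      length(x$positions), "positions (",
      min(x$positions), "-", max(x$positions), ")\n", sep = " ")
  invisible(x)
}
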