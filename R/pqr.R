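# PQR point-charge input: PDB-like ATOM/HETATM records whose last five
# whitespace-separated fields are x, y, z (Angstrom), charge (e) and
# radius (Angstrom).

#' Construct a charge system
#'
#' @param x,y,z coordinates in Angstrom.
#' @param charge partial charges in elementary-charge units.
#' @param radius atomic radii in Angstrom (>= 0).
#' @param name,resname optional atom/residue labels.
#' @return a `charge_system` (data frame of atoms plus total charge).
#' @export
charge_system <- function(x, y, z, charge, radius,
                          name = "X", resname = "UNK") {
  n <- length(x)
  atoms <- data.frame(name = rep_len(name, n), resname = rep_len(resname, n),
                      x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
                      charge = as.numeric(charge),
                      radius = as.numeric(radius))
  if (n > 0) {
    if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z", "charge", "radius")])))) {
      stop("non-finite coordinate, charge or radius")
    }
    if (any(atoms$radius < 0)) stop("radii must be non-negative")
  }
  structure(list(atoms = atoms, total_charge = sum(atoms$charge)),
            class = "charge_system")
}

#' Read a PQR file
#'
#' Whitespace-separated dialect: only `ATOM`/`HETATM` records are used; the
#' last five fields of each record are x, y, z, charge, radius.
#'
#' @param file path to a PQR file.
#' @return a `charge_system`.
#' @examples
#' read_pqr(system.file("extdata", "born_ion.pqr", package = "hlafine"))
#' @export
read_pqr <- function(file) {
  lines <- readLines(file, warn = FALSE)
  rec <- grepl("^(ATOM|HETATM)", lines)
  if (!any(rec)) return(charge_system(numeric(0), numeric(0), numeric(0),
                                      numeric(0), numeric(0)))
  idx <- which(rec)
  parsed <- lapply(idx, function(i) {
    f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]
    if (length(f) < 8L) stop("malformed PQR record at line ", i)
    num <- suppressWarnings(as.numeric(f[(length(f) - 4L):length(f)]))
    if (anyNA(num)) stop("non-numeric coordinate/charge/radius at line ", i)
    list(name = f[3L], resname = f[4L], num = num)
  })
  num <- do.call(rbind, lapply(parsed, `[[`, "num"))
  charge_system(num[, 1L], num[, 2L], num[, 3L], num[, 4L], num[, 5L],
                name = vapply(parsed, `[[`, "", "name"),
                resname = vapply(parsed, `[[`, "", "resname"))
}

#' Write a PQR file
#'
#' @param system a `charge_system`.
#' @param file path to write to.
#' @return `file`, invisibly.
#' @export
write_pqr <- function(system, file) {
  stopifnot(inherits(system, "charge_system"))
  a <- system$atoms
  lines <- sprintf("ATOM  %5d %-4s %-4s %4d    %8.4f %8.4f %8.4f %8.4f %8.4f",
                   seq_len(nrow(a)), a$name, a$resname, seq_len(nrow(a)),
                   a$x, a$y, a$z, a$charge, a$radius)
  writeLines(lines, file)
  invisible(file)
}

#' @export
print.charge_system <- function(x, ...) {
  cat("Charge system:", nrow(x$atoms), "atoms, total charge",
      format(x$total_charge, digits = 4), "e\n")
  invisible(x)
}
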