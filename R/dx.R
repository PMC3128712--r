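# OpenDX scalar-grid I/O for potential maps (the APBS/DelPhi-ecosystem
# interchange format). Data are written z-fastest, three values per line.

#' Write a potential map in OpenDX format
#'
#' @param map a `potential_map`.
#' @param file path to write to.
#' @return `file`, invisibly.
#' @export
write_dx <- function(map, file) {
  stopifnot(inherits(map, "potential_map"))
  g <- map$geom
  n <- g$n
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar grid written by hlafine",
    sprintf("object 1 class gridpositions counts %d %d %d", n, n, n),
    sprintf("origin %.6e %.6e %.6e", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", g$spacing),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", g$spacing),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", n, n, n),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            n^3)), con)
  # z varies fastest: traverse x, then y, then z innermost
  vals <- as.vector(aperm(map$phi, c(3L, 2L, 1L)))
  pad <- (-length(vals)) %% 3L
  if (pad) vals <- c(vals, rep(NA_real_, pad))
  m <- matrix(vals, ncol = 3L, byrow = TRUE)
  lines <- apply(m, 1L, function(r) paste(sprintf("%.6e", r[!is.na(r)]),
                                          collapse = " "))
  writeLines(lines, con)
  writeLines(c('attribute "dep" string "positions"',
               'object "regular positions regular connections" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(file)
}

#' Read an OpenDX scalar grid
#'
#' Supports the regular, axis-aligned cubic grids written by [write_dx()]
#' (and by APBS for such grids).
#'
#' @param file path to a DX file.
#' @return a `potential_map` (with `params = NULL` and no solver metadata).
#' @export
read_dx <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  cnt <- regmatches(lines, regexec(
    "gridpositions counts +([0-9]+) +([0-9]+) +([0-9]+)", lines))
  hit <- which(vapply(cnt, length, 0L) == 4L)[1L]
  if (is.na(hit)) stop("no gridpositions record found")
  n <- as.integer(cnt[[hit]][2:4])
  if (length(unique(n)) != 1L) stop("only cubic grids are supported")
  origin <- as.numeric(strsplit(trimws(sub("^origin", "",
    lines[grep("^origin", lines)[1L]])), " +")[[1L]])
  deltas <- lines[grep("^delta", lines)]
  dmat <- t(vapply(deltas, function(l)
    as.numeric(strsplit(trimws(sub("^delta", "", l)), " +")[[1L]]),
    numeric(3L)))
  spacing <- max(dmat)
  if (any(abs(dmat - diag(rep(spacing, 3L))) > 1e-9 * spacing)) {
    stop("only axis-aligned uniform grids are supported")
  }
  start <- grep("data follows", lines)[1L] + 1L
  stopline <- grep("^attribute|^object \"", lines)
  stopline <- stopline[stopline > start]
  end <- if (length(stopline)) min(stopline) - 1L else length(lines)
  vals <- as.numeric(unlist(strsplit(trimws(lines[start:end]), " +")))
  if (length(vals) != n[1L]^3) {
    stop("expected ", n[1L]^3, " data values, found ", length(vals))
  }
  phi <- aperm(array(vals, dim = rev(rep(n[1L], 3L))), c(3L, 2L, 1L))
  geom <- structure(list(origin = origin, spacing = spacing, n = n[1L]),
                    class = "pb_grid")
  structure(list(phi = phi, geom = geom, params = NULL,
                 iterations = NA_integer_, converged = NA,
                 max_update = NA_real_, max_residual = NA_real_,
                 history = numeric(0)),
            class = "potential_map")
}
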