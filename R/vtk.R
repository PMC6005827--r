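#' Write simulation fields as a VTK ImageData (.vti) file
#'
#' Exports the level set, mask, cell-centred velocity, pressure and WSS
#' magnitude as cell data of an ASCII VTK XML ImageData file, so any standard
#' VTK-based viewer can contour `phi = 0` to display the wall and color it by
#' the wall quantities. All fields must share one grid.
#'
#' @param state a `flow_state` (or `NULL` to write geometry only).
#' @param mask a `lumen_mask`.
#' @param levelset a `levelset_field` (or `NULL`).
#' @param wallfield a `wall_field` (or `NULL`); WSS magnitudes are scattered
#'   onto their wall-adjacent cells, zero elsewhere.
#' @param path output path (`.vti`).
#' @return `path`, invisibly.
#' @export
write_field_output <- function(state, mask, levelset = NULL, wallfield = NULL,
                               path = "fields.vti") {
  stopifnot(inherits(mask, "lumen_mask"))
  d <- mask$dims
  sp <- mask$spacing
  check_dims <- function(dd, what) {
    if (!all(dd == d)) stop("mismatched field shapes: ", what)
  }
  arrays <- list(M = array(as.numeric(mask$mask), d))
  if (!is.null(levelset)) {
    check_dims(levelset$dims, "levelset")
    arrays$phi <- levelset$phi
  }
  if (!is.null(state)) {
    check_dims(state$dims, "flow state")
    uc <- cell_velocity(state)
    arrays$velocity <- array(c(uc$u, uc$v, uc$w), c(d, 3))
    arrays$P <- state$P
  }
  if (!is.null(wallfield)) {
    wss <- array(0, d)
    wss[wallfield$cells] <- wallfield$tau_mag
    arrays$WSS <- wss
  }
  con <- file(path, "w")
  on.exit(close(con))
  o <- mask$origin
  cat(sprintf(
    paste0('<?xml version="1.0"?>\n',
           '<VTKFile type="ImageData" version="0.1" byte_order="LittleEndian">\n',
           '<ImageData WholeExtent="0 %d 0 %d 0 %d" Origin="%g %g %g" ',
           'Spacing="%g %g %g">\n<Piece Extent="0 %d 0 %d 0 %d">\n<CellData>\n'),
    d[1], d[2], d[3], o[1], o[2], o[3], sp[1], sp[2], sp[3],
    d[1], d[2], d[3]), file = con)
  for (nm in names(arrays)) {
    a <- arrays[[nm]]
    ncomp <- if (length(dim(a)) == 4) dim(a)[4] else 1L
    vals <- if (ncomp > 1) {
      # interleave components per cell
      m <- matrix(a, ncol = ncomp)
      as.numeric(t(m))
    } else as.numeric(a)
    cat(sprintf(
      '<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">\n',
      nm, ncomp), file = con)
    writeLines(paste(formatC(vals, format = "g", digits = 17),
                     collapse = " "), con)
    cat('</DataArray>\n', file = con)
  }
  cat('</CellData>\n</Piece>\n</ImageData>\n</VTKFile>\n', file = con)
  invisible(path)
}

#' Read cell-data arrays back from a .vti file written by this package
#'
#' Minimal reader for round-trip checks of [write_field_output()]; parses
#' the ASCII ImageData layout this package emits (not a general VTK reader).
#'
#' @param path a `.vti` file.
#' @return list with `dims`, `spacing`, `origin` and one array per cell-data
#'   field (vector fields as `dims x n` arrays).
#' @export
read_field_output <- function(path) {
  lines <- readLines(path)
  hdr <- grep("<ImageData", lines, value = TRUE)[1]
  attr_nums <- function(name) {
    m <- regmatches(hdr, regexpr(paste0(name, '="[^"]*"'), hdr))
    as.numeric(strsplit(sub(paste0(name, '="([^"]*)"'), "\\1", m), " +")[[1]])
  }
  ext <- attr_nums("WholeExtent")
  spacing <- attr_nums("Spacing")
  origin <- attr_nums("Origin")
  d <- c(ext[2], ext[4], ext[6])
  out <- list(dims = d, spacing = spacing[1:3], origin = origin[1:3])
  starts <- grep("<DataArray", lines)
  for (s in starts) {
    nm <- sub('.*Name="([^"]*)".*', "\\1", lines[s])
    ncomp <- as.integer(sub('.*NumberOfComponents="([0-9]+)".*', "\\1",
                            lines[s]))
    vals <- as.numeric(strsplit(trimws(lines[s + 1]), "[ \t]+")[[1]])
    out[[nm]] <- if (ncomp > 1) {
      m <- matrix(vals, ncol = ncomp, byrow = TRUE)
      array(as.numeric(m), c(d, ncomp))
    } else array(vals, d)
  }
  out
}
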