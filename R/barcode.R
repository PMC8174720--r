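GENOTYPE_SYMBOLS <- c("a", "b", "h", "-")

#' Map zygosity classes to band-pattern calls
#'
#' A marker typed by product size gives the same amplicon as the reference
#' variety for a HOM_REF accession (`a`), a different-size amplicon for a
#' HOM_ALT accession (`b`), both bands for a heterozygote (`h`), and no
#' call when missing (`-`).
#'
#' @param z factor or character vector of zygosity classes
#'   (`HOM_REF`, `HET`, `HOM_ALT`, `MISSING`)
#' @return character vector over `a`, `b`, `h`, `-`.
#' @export
call_from_zygosity <- function(z) {
  z <- as.character(z)
  bad <- !z %in% ZYGOSITY_LEVELS
  if (any(bad)) stop("unknown zygosity class: ", paste(unique(z[bad]),
                                                       collapse = ", "))
  unname(c(HOM_REF = "a", HET = "h", HOM_ALT = "b",
           MISSING = "-")[z])
}

#' Genotype-call matrix from variant calls
#'
#' Builds the accession x marker matrix of `a/b/h/-` calls relative to the
#' reference variety from an [indel_set], optionally restricted and
#' reordered to a marker panel.
#'
#' @param x an [indel_set]
#' @param marker_ids variant ids defining the panel and its order
#'   (default: all variants in `x`)
#' @param marker_labels optional replacement column labels (e.g.
#'   `TB1..TBn`), same length as `marker_ids`
#' @return character matrix, rows = accessions, columns = markers, values
#'   in `a/b/h/-`.
#' @export
genotype_calls <- function(x, marker_ids = NULL, marker_labels = NULL) {
  stopifnot(inherits(x, "indel_set"))
  if (is.null(marker_ids)) marker_ids <- x$variants$id
  idx <- match(marker_ids, x$variants$id)
  if (anyNA(idx)) stop("unknown marker id(s): ",
                       paste(marker_ids[is.na(idx)], collapse = ", "))
  g <- x$geno[idx, , drop = FALSE]
  m <- matrix(GENOTYPE_SYMBOLS[ifelse(is.na(g), 4L, ifelse(g == 0L, 1L,
              ifelse(g == 1L, 3L, 2L)))], nrow = nrow(g))
  m <- t(m)
  rownames(m) <- accessions(x)
  colnames(m) <- if (is.null(marker_labels)) marker_ids else marker_labels
  validate_genotype_matrix(m)
}

#' Validate a genotype-call matrix
#'
#' @param m character matrix of calls in `a/b/h/-`, rows = accessions
#'   (rownames required), columns = markers (colnames required)
#' @return `m`, invisibly validated.
#' @export
validate_genotype_matrix <- function(m) {
  if (!is.matrix(m) || !is.character(m))
    stop("genotype matrix must be a character matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("genotype matrix needs accession rownames and marker colnames")
  bad <- !m %in% GENOTYPE_SYMBOLS
  if (any(bad))
    stop("invalid genotype symbol(s): ", paste(unique(m[bad]),
                                               collapse = ", "))
  m
}

#' Read / write a genotype-call matrix as CSV
#'
#' Rows are accessions (first column `accession`), remaining columns are
#' markers, cell values in `a/b/h/-`.
#'
#' @param path CSV file path
#' @return for the reader, a validated genotype matrix.
#' @export
read_genotype_matrix <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(d)[1] != "accession")
    stop("first column of a genotype matrix CSV must be 'accession'")
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$accession
  validate_genotype_matrix(m)
}

#' @rdname read_genotype_matrix
#' @param m genotype matrix
#' @export
write_genotype_matrix <- function(m, path) {
  validate_genotype_matrix(m)
  d <- data.frame(accession = rownames(m), m, check.names = FALSE,
                  stringsAsFactors = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Encode a marker profile as a black-and-white barcode
#'
#' Renders one accession's ordered `a/b` profile as a binary cell grid:
#' white for `a` (same amplicon as the reference variety), black for `b`.
#' The 1D layout is a single row of one module per marker; the default 2D
#' layout is 5 rows x 10 columns filled row-major in panel order. Cells
#' beyond the panel size are padding. Under the default strict policy a
#' heterozygous or missing call is an error (the printed figures carry
#' only binary cells); the lenient policy renders `h` as half-tone and
#' `-` as light grey, flagged in the cell grid.
#'
#' @param calls character vector of calls in `a/b` (plus `h`/`-` under
#'   `policy = "lenient"`), names = marker ids (optional)
#' @param layout `"1D"` or `"2D"`
#' @param rows,cols grid dimensions for the 2D layout (default 5 x 10);
#'   ignored for 1D. `rows * cols` must be at least `length(calls)`.
#' @param accession_id optional id stored in the image metadata
#' @param policy `"strict"` (error on `h`/`-`) or `"lenient"`
#' @return object of class `barcode_image`: list with `layout`, `rows`,
#'   `cols`, `cells` (integer matrix: 0 white, 1 black, 2 het, 3 missing,
#'   `NA` padding), `markers`, `n`, `accession_id`.
#' @export
encode_barcode <- function(calls, layout = c("2D", "1D"), rows = 5L,
                           cols = 10L, accession_id = NULL,
                           policy = c("strict", "lenient")) {
  layout <- match.arg(layout)
  policy <- match.arg(policy)
  calls <- stats::setNames(as.character(calls), names(calls))
  bad <- !calls %in% GENOTYPE_SYMBOLS
  if (any(bad)) stop("invalid call symbol(s): ",
                     paste(unique(calls[bad]), collapse = ", "))
  n <- length(calls)
  if (n == 0) stop("empty profile")
  special <- calls %in% c("h", "-")
  if (policy == "strict" && any(special)) {
    mk <- if (is.null(names(calls))) which(special) else
      names(calls)[special]
    stop("heterozygous/missing call(s) under strict policy at: ",
         paste(mk, collapse = ", "))
  }
  if (layout == "1D") { rows <- 1L; cols <- n }
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows * cols < n)
    stop("grid ", rows, "x", cols, " too small for ", n, " markers")
  code <- c(a = 0L, b = 1L, h = 2L, `-` = 3L)[calls]
  cells <- matrix(c(unname(code), rep(NA_integer_, rows * cols - n)),
                  nrow = rows, ncol = cols, byrow = TRUE)
  structure(list(layout = layout, rows = rows, cols = cols, cells = cells,
                 markers = names(calls), n = n,
                 accession_id = accession_id),
            class = "barcode_image")
}

#' @export
print.barcode_image <- function(x, ...) {
  cat(sprintf("barcode_image (%s, %dx%d, %d markers%s)\n", x$layout,
              x$rows, x$cols, x$n,
              if (is.null(x$accession_id)) "" else
                paste0(", ", x$accession_id)))
  glyph <- c(".", "#", "+", "?")
  for (r in seq_len(x$rows)) {
    v <- x$cells[r, ]
    cat(paste(ifelse(is.na(v), " ", glyph[v + 1L]), collapse = ""), "\n")
  }
  invisible(x)
}

#' Decode a barcode image back to a marker profile
#'
#' Exact inverse of [encode_barcode()] for its own images: reads the cell
#' grid row-major, drops padding, and maps white to `a`, black to `b`
#' (half-tone to `h`, light grey to `-`).
#'
#' @param img a `barcode_image`
#' @return character vector of calls, named by marker when the image
#'   carries marker ids.
#' @export
decode_barcode <- function(img) {
  stopifnot(inherits(img, "barcode_image"))
  if (!is.matrix(img$cells) || nrow(img$cells) != img$rows ||
      ncol(img$cells) != img$cols)
    stop("cell grid does not match declared layout")
  v <- as.vector(t(img$cells))
  filled <- which(!is.na(v))
  if (length(filled) != img$n || (img$n > 0 && max(filled) != img$n))
    stop("cell count mismatch: expected ", img$n, " leading cells, found ",
         length(filled))
  calls <- GENOTYPE_SYMBOLS[match(v[seq_len(img$n)], c(0L, 1L, 2L, 3L))]
  names(calls) <- img$markers
  calls
}

#' @export
as.character.barcode_image <- function(x, ...) {
  paste(decode_barcode(x), collapse = "")
}

#' Write a barcode as a deterministic SVG
#'
#' One `rect` per cell plus a white quiet-zone border; identical profile
#' and layout give a byte-identical file.
#'
#' @param img a `barcode_image`
#' @param path output path; `NULL` returns the SVG string
#' @param cell cell edge length in px (default 10)
#' @param quiet quiet-zone width in cells (default 1)
#' @return the SVG string, invisibly when written to `path`.
#' @export
write_barcode_svg <- function(img, path = NULL, cell = 10, quiet = 1) {
  stopifnot(inherits(img, "barcode_image"))
  w <- (img$cols + 2 * quiet) * cell
  h <- (img$rows + 2 * quiet) * cell
  fill <- c("#ffffff", "#000000", "#808080", "#d3d3d3")
  lines <- c(sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
    w, h),
    sprintf('<rect x="0" y="0" width="%d" height="%d" fill="#ffffff"/>',
            w, h))
  for (r in seq_len(img$rows)) for (cc in seq_len(img$cols)) {
    v <- img$cells[r, cc]
    if (is.na(v)) next
    lines <- c(lines, sprintf(
      '<rect x="%d" y="%d" width="%d" height="%d" fill="%s"/>',
      (cc - 1 + quiet) * cell, (r - 1 + quiet) * cell, cell, cell,
      fill[v + 1L]))
  }
  svg <- paste(c(lines, "</svg>"), collapse = "\n")
  if (is.null(path)) return(svg)
  writeLines(svg, path)
  invisible(svg)
}

#' Write a barcode as a PNG
#'
#' Grayscale raster: white cells 1, black 0, half-tone 0.5, missing
#' 0.82, with a white quiet zone.
#'
#' @inheritParams write_barcode_svg
#' @param scale pixels per cell (default 10)
#' @return `path`, invisibly.
#' @export
write_barcode_png <- function(img, path, scale = 10, quiet = 1) {
  stopifnot(inherits(img, "barcode_image"))
  shade <- c(1, 0, 0.5, 0.82)
  grid <- matrix(1, img$rows + 2 * quiet, img$cols + 2 * quiet)
  for (r in seq_len(img$rows)) for (cc in seq_len(img$cols)) {
    v <- img$cells[r, cc]
    grid[r + quiet, cc + quiet] <- if (is.na(v)) 1 else shade[v + 1L]
  }
  big <- grid[rep(seq_len(nrow(grid)), each = scale),
              rep(seq_len(ncol(grid)), each = scale)]
  png::writePNG(big, path)
  invisible(path)
}

#' Barcode layout metadata sidecar
#'
#' JSON metadata enabling lossless decoding of a rendered barcode:
#' layout, grid size, marker order and accession id.
#'
#' @param img a `barcode_image`
#' @param path output JSON path; `NULL` returns the list
#' @return metadata list, invisibly when written.
#' @export
barcode_metadata <- function(img, path = NULL) {
  stopifnot(inherits(img, "barcode_image"))
  meta <- list(layout = img$layout, rows = img$rows, cols = img$cols,
               n_markers = img$n, markers = img$markers,
               accession_id = img$accession_id)
  if (is.null(path)) return(meta)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(meta)
}

#' Plot a barcode image
#'
#' @param x a `barcode_image`
#' @param ... passed to [graphics::image()]
#' @export
plot.barcode_image <- function(x, ...) {
  shade <- c(1, 0, 0.5, 0.82)
  z <- matrix(1, x$rows, x$cols)
  for (r in seq_len(x$rows)) for (cc in seq_len(x$cols)) {
    v <- x$cells[r, cc]
    z[r, cc] <- if (is.na(v)) 1 else shade[v + 1L]
  }
  graphics::image(t(z[rev(seq_len(x$rows)), , drop = FALSE]),
                  col = grDevices::grey(seq(0, 1, length.out = 256)),
                  zlim = c(0, 1), axes = FALSE, asp = x$rows / x$cols, ...)
  invisible(x)
}

#' Profile homology between two accessions
#'
#' Fraction of panel markers at which two profiles carry the identical
#' call. Under the default `"exclude"` policy, markers where either call
#' is missing are removed from the comparison and the denominator actually
#' used is attached as attribute `n_compared`; under `"strict"` a missing
#' call is an error.
#'
#' @param p1,p2 call vectors over the same panel, same order (names, when
#'   present on both, must agree)
#' @param missing_policy `"exclude"` or `"strict"`
#' @return homology fraction in `[0, 1]` with attribute `n_compared`.
#' @export
homology <- function(p1, p2, missing_policy = c("exclude", "strict")) {
  missing_policy <- match.arg(missing_policy)
  if (length(p1) != length(p2))
    stop("profiles cover different panel sizes")
  if (!is.null(names(p1)) && !is.null(names(p2)) &&
      !identical(names(p1), names(p2)))
    stop("profiles are ordered over different marker panels")
  miss <- p1 == "-" | p2 == "-"
  if (missing_policy == "strict" && any(miss))
    stop("missing call(s) at ", sum(miss), " marker(s) under strict policy")
  use <- !miss
  if (!any(use)) stop("no comparable markers between the two profiles")
  h <- sum(p1[use] == p2[use]) / sum(use)
  attr(h, "n_compared") <- sum(use)
  h
}
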