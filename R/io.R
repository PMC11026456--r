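# Plain-text I/O. The offline toolchain has no TIFF codec, so rasters and
# stacks are exchanged as CSV with commented header metadata; vector fields,
# contours and tracks are CSV; expression is MatrixMarket + id lists.

write_header <- function(path, meta) {
  con <- file(path, "w")
  for (nm in names(meta)) cat(sprintf("# %s=%s\n", nm, meta[[nm]]), file = con)
  close(con)
}

read_header <- function(path) {
  lines <- readLines(path, n = 20)
  lines <- lines[startsWith(lines, "# ")]
  kv <- strsplit(sub("^# ", "", lines), "=", fixed = TRUE)
  stats::setNames(lapply(kv, function(p) p[2]), vapply(kv, `[`, "", 1))
}

#' Read and write rasters as CSV
#'
#' Pixel values as a headerless CSV matrix preceded by commented metadata
#' lines (`# pixel_size_um=...`, and `# z_step_um=...`/`# n_slices=...` for
#' stacks, stored as vertically concatenated slices).
#'
#' @param image a [raster_image()] or [image_stack()].
#' @param path file path.
#' @return `read_raster_csv` returns a [raster_image()] or [image_stack()].
#' @export
write_raster_csv <- function(image, path) {
  if (inherits(image, "image_stack")) {
    d <- dim(image)
    write_header(path, list(pixel_size_um = attr(image, "pixel_size"),
                            z_step_um = attr(image, "z_step"),
                            n_slices = d[3]))
    flat <- do.call(rbind, lapply(seq_len(d[3]), function(k) image[, , k]))
    write.table(flat, path, append = TRUE, sep = ",", row.names = FALSE,
                col.names = FALSE)
  } else {
    write_header(path, list(pixel_size_um = attr(image, "pixel_size")))
    write.table(unclass(image), path, append = TRUE, sep = ",",
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_raster_csv
#' @export
read_raster_csv <- function(path) {
  meta <- read_header(path)
  m <- as.matrix(read.csv(path, header = FALSE, comment.char = "#"))
  dimnames(m) <- NULL
  px <- as.numeric(meta$pixel_size_um)
  if (!is.null(meta$n_slices)) {
    nz <- as.integer(meta$n_slices)
    nr <- nrow(m) / nz
    arr <- array(0, c(nr, ncol(m), nz))
    for (k in seq_len(nz)) arr[, , k] <- m[(k - 1) * nr + seq_len(nr), ]
    image_stack(arr, pixel_size = px, z_step = as.numeric(meta$z_step_um))
  } else raster_image(m, pixel_size = px)
}

#' Read and write vector fields as CSV
#'
#' Long format: `x_um, y_um, vx, vy, valid`, with units, spacing and origin
#' in commented metadata lines.
#'
#' @param field a [vector_field()].
#' @param path file path.
#' @return `read_vector_field_csv` returns a [vector_field()].
#' @export
write_vector_field_csv <- function(field, path) {
  co <- field_coords(field)
  write_header(path, list(units = field$units, spacing_um = field$spacing,
                          origin_um = paste(field$origin, collapse = ";"),
                          n_rows = nrow(field$vx), n_cols = ncol(field$vx)))
  df <- data.frame(x_um = as.numeric(co$x), y_um = as.numeric(co$y),
                   vx = as.numeric(field$vx), vy = as.numeric(field$vy),
                   valid = as.integer(field$valid))
  suppressWarnings(write.table(df, path, append = TRUE, sep = ",",
                               row.names = FALSE, col.names = TRUE))
  invisible(path)
}

#' @rdname write_vector_field_csv
#' @export
read_vector_field_csv <- function(path) {
  meta <- read_header(path)
  df <- read.csv(path, comment.char = "#")
  nr <- as.integer(meta$n_rows); nc <- as.integer(meta$n_cols)
  vector_field(matrix(df$vx, nr, nc), matrix(df$vy, nr, nc),
               spacing = as.numeric(meta$spacing_um),
               origin = as.numeric(strsplit(meta$origin_um, ";")[[1]]),
               units = meta$units,
               valid = matrix(df$valid == 1, nr, nc))
}

#' Read and write contour sets as CSV
#'
#' Columns `contour_id, vertex_index, x_um, y_um`.
#'
#' @param contours a [contour_set()].
#' @param path file path.
#' @return `read_contours_csv` returns a [contour_set()].
#' @export
write_contours_csv <- function(contours, path) {
  rows <- lapply(seq_along(contours$contours), function(i) {
    ct <- contours$contours[[i]]
    id <- if (is.na(ct$id)) i else ct$id
    data.frame(contour_id = id, vertex_index = seq_len(nrow(ct$vertices)),
               x_um = ct$vertices[, 1], y_um = ct$vertices[, 2])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_contours_csv
#' @export
read_contours_csv <- function(path) {
  df <- read.csv(path)
  ids <- unique(df$contour_id)
  contour_set(lapply(ids, function(id) {
    v <- df[df$contour_id == id, ]
    v <- v[order(v$vertex_index), ]
    contour(cbind(v$x_um, v$y_um), id = id)
  }))
}

#' Write an expression matrix as MatrixMarket plus id lists
#'
#' Writes `<prefix>.mtx`, `<prefix>_genes.txt` and `<prefix>_cells.txt`.
#'
#' @param matrix an [expression_matrix()].
#' @param prefix output path prefix.
#' @return `read_expression_mtx` returns an [expression_matrix()].
#' @export
write_expression_mtx <- function(matrix, prefix) {
  Matrix::writeMM(Matrix::Matrix(unclass(matrix), sparse = TRUE),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(matrix), paste0(prefix, "_genes.txt"))
  writeLines(colnames(matrix), paste0(prefix, "_cells.txt"))
  invisible(prefix)
}

#' @rdname write_expression_mtx
#' @export
read_expression_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  rownames(m) <- readLines(paste0(prefix, "_genes.txt"))
  colnames(m) <- readLines(paste0(prefix, "_cells.txt"))
  expression_matrix(m, state = "raw")
}
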