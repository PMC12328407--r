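# File formats: annotation CSV (two dialects), GloVe text embeddings,
# adjacency CSV with label headers, PNG heatmaps, metrics JSON.

#' Read an annotation table
#'
#' Auto-detects the dialect: either the pipe form (`image_id,labels` with
#' `labels` like `"a|b|c"`) or the wide binary form (one 0/1 column per
#' label). Label order is fixed by first appearance (column order in the
#' wide form; first occurrence in reading order in the pipe form).
#'
#' @param path CSV file.
#' @return binary `n x C` matrix, image ids as row names, labels as column
#'   names.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stopf("annotation file is empty: %s", path)
  if (ncol(df) == 2L && !all(df[[2L]] %in% c("0", "1"))) {
    # pipe dialect
    ids <- df[[1L]]
    sets <- strsplit(df[[2L]], "|", fixed = TRUE)
    labels <- unique(unlist(sets))
    y <- matrix(0, nrow(df), length(labels),
                dimnames = list(ids, labels))
    for (i in seq_along(sets)) y[i, sets[[i]]] <- 1
    return(y)
  }
  ids <- df[[1L]]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (any(is.na(vals)) || any(vals != 0 & vals != 1))
    stopf("wide annotation form must be binary: %s", path)
  rownames(vals) <- ids
  vals
}

#' Write an annotation table
#'
#' @param ann binary annotation matrix with label column names.
#' @param path output CSV.
#' @param dialect `"pipe"` (`image_id,labels`) or `"wide"` (one column per
#'   label).
#' @export
write_annotations <- function(ann, path, dialect = c("pipe", "wide")) {
  dialect <- match.arg(dialect)
  assert_binary_matrix(ann, "annotation matrix")
  ids <- rownames(ann) %||% sprintf("img_%04d", seq_len(nrow(ann)))
  if (dialect == "pipe") {
    sets <- apply(ann, 1L, function(r)
      paste(colnames(ann)[r == 1], collapse = "|"))
    utils::write.csv(data.frame(image_id = ids, labels = sets),
                     path, row.names = FALSE, quote = TRUE)
  } else {
    df <- data.frame(image_id = ids, check.names = FALSE)
    df[colnames(ann)] <- as.data.frame(ann, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  }
  invisible(path)
}

#' Write a labelled adjacency matrix as CSV
#'
#' Header row and first column carry the label names so matrices are
#' alignable across runs.
#'
#' @param mat `C x C` matrix with label dimnames (or `labels` supplied).
#' @param path output CSV.
#' @param labels optional label names.
#' @export
write_adjacency_csv <- function(mat, path, labels = NULL) {
  labels <- labels %||% rownames(mat) %||% colnames(mat) %||%
    sprintf("label_%02d", seq_len(nrow(mat)))
  dimnames(mat) <- list(labels, labels)
  utils::write.csv(mat, path, row.names = TRUE)
  invisible(path)
}

#' Read a labelled adjacency matrix
#' @param path CSV written by [write_adjacency_csv()].
#' @return `C x C` matrix with label dimnames.
#' @export
read_adjacency_csv <- function(path) {
  if (!file.exists(path)) stopf("adjacency file not found: %s", path)
  df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
  as.matrix(df)
}

#' Write a word-embedding table in GloVe text format
#' @param table named token -> numeric vector list.
#' @param path output file.
#' @export
write_embeddings <- function(table, path) {
  lines <- vapply(names(table), function(tok)
    paste(tok, paste(sprintf("%.8g", table[[tok]]), collapse = " ")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Render a matrix as a heatmap PNG
#'
#' Direct raster export (no graphics device): values are min-max scaled and
#' mapped on a white-to-dark-blue ramp, darker meaning a stronger entry;
#' each matrix cell becomes a `cell` x `cell` pixel block.
#'
#' @param mat numeric matrix.
#' @param path output PNG.
#' @param cell pixels per matrix cell (default 24).
#' @export
write_heatmap_png <- function(mat, path, cell = 24L) {
  rng <- range(mat, finite = TRUE)
  z <- if (diff(rng) > 0) (mat - rng[1L]) / diff(rng) else mat * 0
  big <- kronecker(z, matrix(1, cell, cell))
  img <- array(0, c(dim(big), 3L))
  img[, , 1L] <- 1 - 0.85 * big          # R
  img[, , 2L] <- 1 - 0.70 * big          # G
  img[, , 3L] <- 1 - 0.35 * big          # B
  png::writePNG(img, path)
  invisible(path)
}

#' Write a metric report as JSON
#' @param report a [metric_report()].
#' @param path output JSON file.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read images from a directory into a batch array
#'
#' @param dir directory of PNG images (searched non-recursively).
#' @param size expected square side; images of any other size are an error
#'   (the synthetic generator always matches).
#' @return array `(3, size, size, n)` plus image ids as dimnames on the
#'   batch axis.
#' @export
read_image_dir <- function(dir, size) {
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0L) stopf("no PNG images found in %s", dir)
  out <- array(0, c(3L, size, size, length(files)))
  for (i in seq_along(files)) {
    img <- png::readPNG(files[[i]])
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (dim(img)[1L] != size || dim(img)[2L] != size)
      stopf("image %s is %dx%d, expected %dx%d", files[[i]],
            dim(img)[1L], dim(img)[2L], size, size)
    out[, , , i] <- aperm(img[, , 1:3, drop = FALSE], c(3L, 1L, 2L))
  }
  dimnames(out) <- list(NULL, NULL, NULL,
                        sub("\\.png$", "", basename(files)))
  out
}
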