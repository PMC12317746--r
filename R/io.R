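# On-disk formats. All text formats are comma-separated with a header row,
# UTF-8. Doubles are printed with "%.17g" so values round-trip exactly.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  ints <- is.finite(x) & x == round(x) & abs(x) < 2^53
  out[ints] <- sprintf("%.0f", x[ints])
  out
}

write_csv_exact <- function(df, path) {
  cols <- lapply(df, function(col) {
    if (is.double(col)) fmt_num(col) else as.character(col)
  })
  m <- do.call(cbind, cols)
  lines <- c(paste(names(df), collapse = ","),
             apply(m, 1L, paste, collapse = ","))
  writeLines(lines, path, useBytes = TRUE)
}

#' Read one SRT sample from disk
#'
#' Supported formats: `"mtx_dir"` -- a 10x-style directory with
#' `matrix.mtx` (genes x units, Matrix Market), `genes.tsv`,
#' `barcodes.tsv` and a sidecar `positions.csv` (`unit_id,x,y`);
#' `"csv_pair"` -- `counts.csv` (units in rows, first column `unit_id`,
#' one column per gene) plus `coords.csv` (`unit_id,x,y`); `"h5"` -- a
#' single HDF5 file with datasets `/counts` (units x genes), `/coords`,
#' `/gene_ids`, `/unit_ids`. An optional `annotations.csv`
#' (`unit_id,label`) sidecar (or `/annotations` dataset) restores
#' ground-truth labels.
#'
#' @param path Directory (`mtx_dir`, `csv_pair`) or file (`h5`).
#' @param format One of `"mtx_dir"`, `"csv_pair"`, `"h5"`.
#' @return A validated [srt_sample()] with source gene/unit ordering
#'   preserved.
#' @seealso [write_srt_sample()]
#' @export
read_srt_sample <- function(path, format = c("csv_pair", "mtx_dir", "h5")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  sample_id <- sub("\\.h5$", "", basename(path))
  if (format == "csv_pair") {
    cf <- file.path(path, "counts.csv")
    xf <- file.path(path, "coords.csv")
    for (f in c(cf, xf)) if (!file.exists(f)) stop("missing file: ", f)
    cnt <- utils::read.csv(cf, check.names = FALSE, colClasses = "character")
    crd <- utils::read.csv(xf, check.names = FALSE)
    unit_ids <- cnt[[1L]]
    counts <- as.matrix(cnt[, -1L, drop = FALSE])
    storage.mode(counts) <- "double"
    if (nrow(crd) != nrow(counts))
      stop("counts has ", nrow(counts), " units but coords has ", nrow(crd))
    if (!identical(as.character(crd$unit_id), unit_ids))
      stop("unit ids of counts.csv and coords.csv disagree")
    coords <- as.matrix(crd[, c("x", "y")])
    storage.mode(coords) <- "double"
    gene_ids <- colnames(counts)
  } else if (format == "mtx_dir") {
    mf <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    pf <- file.path(path, "positions.csv")
    for (f in c(mf, gf, bf, pf)) if (!file.exists(f)) stop("missing file: ", f)
    m <- Matrix::readMM(mf)              # genes x units, 10x orientation
    gene_ids <- utils::read.delim(gf, header = FALSE)[[1L]]
    unit_ids <- utils::read.delim(bf, header = FALSE)[[1L]]
    counts <- t(as.matrix(m))
    crd <- utils::read.csv(pf)
    if (nrow(crd) != nrow(counts))
      stop("counts has ", nrow(counts), " units but positions.csv has ",
           nrow(crd))
    if (!identical(as.character(crd$unit_id), as.character(unit_ids)))
      stop("unit ids of barcodes.tsv and positions.csv disagree")
    coords <- as.matrix(crd[, c("x", "y")])
    storage.mode(coords) <- "double"
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("the 'rhdf5' package is required for h5 files")
    counts <- rhdf5::h5read(path, "counts")
    coords <- rhdf5::h5read(path, "coords")
    gene_ids <- as.character(rhdf5::h5read(path, "gene_ids"))
    unit_ids <- as.character(rhdf5::h5read(path, "unit_ids"))
  }
  ann <- NULL
  if (format %in% c("csv_pair", "mtx_dir")) {
    af <- file.path(path, "annotations.csv")
    if (file.exists(af)) {
      a <- utils::read.csv(af, colClasses = "character")
      ann <- a$label[match(unit_ids, a$unit_id)]
    }
    sample_id <- basename(normalizePath(path))
  } else if ("annotations" %in% rhdf5::h5ls(path)$name) {
    ann <- as.character(rhdf5::h5read(path, "annotations"))
  }
  srt_sample(sample_id, counts, coords, gene_ids = as.character(gene_ids),
             unit_ids = as.character(unit_ids), annotations = ann)
}

#' Write one SRT sample to disk
#'
#' Inverse of [read_srt_sample()]: integer counts round-trip bit-for-bit
#' and doubles to full stored precision in every format. Annotations, when
#' present, are written alongside (`annotations.csv` or `/annotations`).
#'
#' @param sample An [srt_sample()].
#' @param path Destination directory (`mtx_dir`, `csv_pair`; created if
#'   absent) or `.h5` file path.
#' @param format One of `"csv_pair"`, `"mtx_dir"`, `"h5"`.
#' @return `path`, invisibly.
#' @export
write_srt_sample <- function(sample, path,
                             format = c("csv_pair", "mtx_dir", "h5")) {
  format <- match.arg(format)
  validate_srt_sample(sample)
  if (nrow(sample$counts) == 0L) stop("refusing to write an empty sample")
  if (format == "csv_pair") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    cnt <- data.frame(unit_id = sample$unit_ids, check.names = FALSE)
    for (j in seq_along(sample$gene_ids))
      cnt[[sample$gene_ids[j]]] <- sample$counts[, j]
    write_csv_exact(cnt, file.path(path, "counts.csv"))
    crd <- data.frame(unit_id = sample$unit_ids,
                      x = as.double(sample$coords[, 1L]),
                      y = as.double(sample$coords[, 2L]))
    write_csv_exact(crd, file.path(path, "coords.csv"))
  } else if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- Matrix::Matrix(t(sample$counts), sparse = TRUE)
    nz <- Matrix::summary(m)
    lines <- c("%%MatrixMarket matrix coordinate real general",
               paste(nrow(m), ncol(m), nrow(nz)),
               paste(nz$i, nz$j, fmt_num(as.double(nz$x))))
    writeLines(lines, file.path(path, "matrix.mtx"), useBytes = TRUE)
    writeLines(sample$gene_ids, file.path(path, "genes.tsv"))
    writeLines(sample$unit_ids, file.path(path, "barcodes.tsv"))
    crd <- data.frame(unit_id = sample$unit_ids,
                      x = as.double(sample$coords[, 1L]),
                      y = as.double(sample$coords[, 2L]))
    write_csv_exact(crd, file.path(path, "positions.csv"))
  } else {
    if (!requireNamespace("rhdf5", quietly = TRUE))
      stop("the 'rhdf5' package is required for h5 files")
    if (file.exists(path)) unlink(path)
    rhdf5::h5createFile(path)
    rhdf5::h5write(sample$counts, path, "counts")
    rhdf5::h5write(sample$coords, path, "coords")
    rhdf5::h5write(sample$gene_ids, path, "gene_ids")
    rhdf5::h5write(sample$unit_ids, path, "unit_ids")
    if (!is.null(sample$annotations))
      rhdf5::h5write(as.character(sample$annotations), path, "annotations")
    rhdf5::h5closeAll()
  }
  if (format %in% c("csv_pair", "mtx_dir") && !is.null(sample$annotations)) {
    write_csv_exact(
      data.frame(unit_id = sample$unit_ids,
                 label = as.character(sample$annotations)),
      file.path(path, "annotations.csv"))
  }
  invisible(path)
}

#' Write per-unit domain labels as a tidy CSV
#'
#' Emits one row per unit with columns `sample_id, unit_id, x, y, domain`,
#' pooling all samples. Every unit of every sample must carry a label.
#'
#' @param assignment A `domain_assignment` (from [run_pipeline()] or
#'   [propagate_labels()]) or a named list mapping sample id to a named
#'   vector `unit_id -> domain`.
#' @param samples The list of [srt_sample()] objects (source of
#'   coordinates).
#' @param path Output CSV path.
#' @return The tidy data frame, invisibly.
#' @export
write_labels <- function(assignment, samples, path) {
  unit_domain <- if (inherits(assignment, "domain_assignment"))
    assignment$unit_domain else assignment
  names(samples) <- vapply(samples, `[[`, "", "sample_id")
  rows <- lapply(names(unit_domain), function(sid) {
    s <- samples[[sid]]
    if (is.null(s)) stop("no sample object for '", sid, "'")
    lab <- unit_domain[[sid]]
    if (anyNA(lab) || !all(s$unit_ids %in% names(lab)))
      stop("sample '", sid, "': some units have no domain label")
    lab <- lab[s$unit_ids]
    data.frame(sample_id = sid, unit_id = s$unit_ids,
               x = as.double(s$coords[, 1L]), y = as.double(s$coords[, 2L]),
               domain = unname(lab))
  })
  df <- do.call(rbind, rows)
  write_csv_exact(df, path)
  invisible(df)
}

#' Read a domain-label CSV back into an assignment map
#'
#' @param path CSV written by [write_labels()].
#' @return Named list: sample id -> named vector `unit_id -> domain`.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, colClasses = c(sample_id = "character",
                                             unit_id = "character"))
  out <- split(df, df$sample_id)
  lapply(out, function(d) stats::setNames(d$domain, d$unit_id))
}
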