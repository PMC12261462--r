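# Time-series single-cell expression container and readers/writers.
#
# A `sc_timeseries` holds one cells x genes matrix per measured timepoint,
# a shared gene axis, per-timepoint cell identifiers, and a free-form `meta`
# provenance record (original time labels, normalisation steps, gene masks).

#' Construct a time-series expression object
#'
#' @param matrices list of numeric cells x genes matrices, one per timepoint,
#'   all sharing the same gene axis.
#' @param timepoints integer vector of timepoint labels, same length as
#'   `matrices`. After [load_timeseries()] relabeling these are consecutive
#'   integers starting at 0; objects produced by [heldout_split()] may have
#'   gaps (held-out timepoints removed).
#' @param gene_names character vector, one name per gene column.
#' @param cell_ids optional list of per-timepoint cell id vectors.
#' @param meta free-form provenance list.
#' @return an object of class `sc_timeseries`.
#' @export
timeseries <- function(matrices, timepoints, gene_names = NULL, cell_ids = NULL,
                       meta = list()) {
  matrices <- lapply(matrices, as.matrix)
  g <- ncol(matrices[[1L]])
  if (is.null(gene_names)) gene_names <- colnames(matrices[[1L]]) %||% paste0("gene", seq_len(g))
  if (is.null(cell_ids))
    cell_ids <- lapply(seq_along(matrices), function(i)
      rownames(matrices[[i]]) %||% paste0("t", timepoints[i], "_cell", seq_len(nrow(matrices[[i]]))))
  obj <- structure(
    list(timepoints = as.integer(timepoints), matrices = matrices,
         gene_names = as.character(gene_names), cell_ids = cell_ids, meta = meta),
    class = "sc_timeseries")
  validate_timeseries(obj)
  obj
}

validate_timeseries <- function(x, consecutive = FALSE) {
  if (length(x$matrices) != length(x$timepoints))
    stopf("timeseries: %d matrices for %d timepoints", length(x$matrices), length(x$timepoints))
  if (is.unsorted(x$timepoints, strictly = TRUE))
    stopf("timeseries: timepoints must be strictly increasing")
  if (consecutive && !identical(x$timepoints, seq(0L, length(x$timepoints) - 1L)))
    stopf("timeseries: timepoints must be consecutive integers starting at 0")
  g <- length(x$gene_names)
  for (i in seq_along(x$matrices)) {
    M <- x$matrices[[i]]
    if (ncol(M) != g)
      stopf("timeseries: matrix at timepoint %d has %d genes, expected %d",
            x$timepoints[i], ncol(M), g)
    if (nrow(M) < 1L) stopf("timeseries: timepoint %d has no cells", x$timepoints[i])
    if (anyNA(M) || any(!is.finite(M)))
      stopf("timeseries: non-finite values at timepoint %d", x$timepoints[i])
  }
  invisible(x)
}

#' @method print sc_timeseries
#' @export
print.sc_timeseries <- function(x, ...) {
  cat(sprintf("<sc_timeseries> %d timepoints, %d genes\n",
              length(x$timepoints), length(x$gene_names)))
  n <- vapply(x$matrices, nrow, 0L)
  cat("  t = ", paste(x$timepoints, collapse = ", "), "\n", sep = "")
  cat("  cells = ", paste(n, collapse = ", "), "\n", sep = "")
  if (length(x$meta$steps)) cat("  steps: ", paste(x$meta$steps, collapse = " -> "), "\n", sep = "")
  invisible(x)
}

n_cells <- function(x) vapply(x$matrices, nrow, 0L)

pooled_matrix <- function(x) do.call(rbind, x$matrices)

# ---- time-label parsing ---------------------------------------------------

# Map raw per-cell time labels to an ordered value: numeric labels order
# numerically; duration strings ("8h", "1d", "2 weeks") are converted to
# hours; anything else is a hard error listing the offending labels.
parse_time_labels <- function(labels) {
  raw <- as.character(labels)
  num <- suppressWarnings(as.numeric(raw))
  if (!anyNA(num)) return(num)
  m <- regmatches(raw, regexec("^\\s*([0-9]*\\.?[0-9]+)\\s*(min|minute|h|hr|hour|d|day|w|week)s?\\s*$",
                               tolower(raw)))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad))
    stopf("unparseable time labels: %s", paste(unique(raw[bad]), collapse = ", "))
  mult <- c(min = 1 / 60, minute = 1 / 60, h = 1, hr = 1, hour = 1,
            d = 24, day = 24, w = 168, week = 168)
  vapply(m, function(mm) as.numeric(mm[2L]) * mult[[mm[3L]]], 0)
}

# Relabel arbitrary per-cell time labels as consecutive integers starting at 0;
# returns list(index = per-cell integer, mapping = data.frame).
relabel_timepoints <- function(labels) {
  val <- parse_time_labels(labels)
  uv <- sort(unique(val))
  idx <- match(val, uv) - 1L
  first <- !duplicated(val)
  mapping <- data.frame(original = as.character(labels)[first][order(val[first])],
                        value = uv, index = seq_along(uv) - 1L,
                        stringsAsFactors = FALSE)
  list(index = idx, mapping = mapping)
}

group_by_time <- function(X, labels, cell_ids, meta = list()) {
  rel <- relabel_timepoints(labels)
  tps <- sort(unique(rel$index))
  mats <- lapply(tps, function(t) X[rel$index == t, , drop = FALSE])
  ids <- lapply(tps, function(t) cell_ids[rel$index == t])
  meta$time_mapping <- rel$mapping
  timeseries(mats, tps, colnames(X), ids, meta)
}

# ---- readers --------------------------------------------------------------

#' Load time-series expression data
#'
#' Reads one of three on-disk layouts and groups cells by timepoint, relabeling
#' timepoints as consecutive integers starting at 0 (the original label-to-index
#' mapping is kept in `meta$time_mapping`).
#'
#' Supported formats:
#' \describe{
#'   \item{`mtx`}{a directory with `matrix.mtx` (cells x genes, MatrixMarket),
#'     `genes.tsv` (one gene name per line) and `barcodes.tsv` (TSV with a
#'     `cell` column and a time column named by `time_key`).}
#'   \item{`delimited`}{a single TSV/CSV: a `cell` column, the `time_key`
#'     column, and one column per gene.}
#'   \item{`h5ad`}{an AnnData HDF5 container; read through the system `python`
#'     (`anndata`), with the time label taken from `obs[[time_key]]`.}
#' }
#'
#' @param path file (delimited, h5ad) or directory (mtx).
#' @param format one of `"auto"`, `"mtx"`, `"delimited"`, `"h5ad"`.
#' @param time_key name of the per-cell time label column.
#' @return an [sc_timeseries][timeseries] object of raw counts.
#' @export
load_timeseries <- function(path, format = c("auto", "mtx", "delimited", "h5ad"),
                            time_key = "time") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("no such file or directory: %s", path)
  if (format == "auto") {
    format <- if (dir.exists(path)) "mtx"
    else if (grepl("\\.h5ad$", path)) "h5ad"
    else "delimited"
  }
  switch(format,
    mtx = load_mtx_dir(path, time_key),
    delimited = load_delimited(path, time_key),
    h5ad = load_h5ad(path, time_key))
}

check_counts <- function(X, where) {
  if (any(X < 0)) stopf("negative counts in %s", where)
  X
}

load_mtx_dir <- function(path, time_key) {
  mfile <- file.path(path, "matrix.mtx")
  gfile <- file.path(path, "genes.tsv")
  bfile <- file.path(path, "barcodes.tsv")
  for (f in c(mfile, gfile, bfile)) if (!file.exists(f)) stopf("missing file: %s", f)
  X <- as.matrix(Matrix::readMM(mfile))
  genes <- readLines(gfile)
  bc <- read.delim(bfile, stringsAsFactors = FALSE)
  if (!time_key %in% names(bc))
    stopf("barcodes.tsv lacks time column '%s'", time_key)
  if (nrow(bc) != nrow(X))
    stopf("barcodes.tsv has %d rows but matrix has %d cells", nrow(bc), nrow(X))
  if (length(genes) != ncol(X))
    stopf("genes.tsv has %d genes but matrix has %d columns", length(genes), ncol(X))
  miss <- is.na(bc[[time_key]]) | bc[[time_key]] == ""
  if (any(miss))
    stopf("missing time label for cells: %s",
          paste(head(bc$cell[miss] %||% which(miss), 10L), collapse = ", "))
  colnames(X) <- genes
  check_counts(X, path)
  group_by_time(X, bc[[time_key]], bc$cell %||% paste0("cell", seq_len(nrow(X))),
                meta = list(source = path, format = "mtx"))
}

load_delimited <- function(path, time_key) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
  if (!time_key %in% names(df)) stopf("'%s' column not found in %s", time_key, path)
  cellcol <- if ("cell" %in% names(df)) df$cell else paste0("cell", seq_len(nrow(df)))
  miss <- is.na(df[[time_key]]) | df[[time_key]] == ""
  if (any(miss))
    stopf("missing time label for cells: %s", paste(head(cellcol[miss], 10L), collapse = ", "))
  genecols <- setdiff(names(df), c("cell", time_key))
  X <- as.matrix(df[, genecols, drop = FALSE])
  storage.mode(X) <- "double"
  colnames(X) <- genecols
  check_counts(X, path)
  group_by_time(X, df[[time_key]], cellcol, meta = list(source = path, format = "delimited"))
}

# ---- writers --------------------------------------------------------------

#' Save time-series expression data
#'
#' Inverse of [load_timeseries()]; the mtx layout additionally stores `meta`
#' as JSON so a round trip preserves provenance.
#'
#' @param data an `sc_timeseries`.
#' @param path output directory (mtx) or file (delimited, h5ad).
#' @param format `"mtx"`, `"delimited"` or `"h5ad"`.
#' @param time_key column name used for the time label on write.
#' @export
save_timeseries <- function(data, path, format = c("mtx", "delimited", "h5ad"),
                            time_key = "time") {
  format <- match.arg(format)
  validate_timeseries(data)
  X <- pooled_matrix(data)
  tlab <- rep(data$timepoints, n_cells(data))
  cells <- unlist(data$cell_ids, use.names = FALSE)
  switch(format,
    mtx = {
      dir.create(path, showWarnings = FALSE, recursive = TRUE)
      Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE), file.path(path, "matrix.mtx"))
      writeLines(data$gene_names, file.path(path, "genes.tsv"))
      bc <- data.frame(cell = cells, time = tlab)
      names(bc)[2L] <- time_key
      write.table(bc, file.path(path, "barcodes.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      jsonlite::write_json(data$meta, file.path(path, "meta.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
    },
    delimited = {
      sep <- if (grepl("\\.csv$", path)) "," else "\t"
      df <- data.frame(cell = cells, time = tlab, check.names = FALSE)
      names(df)[2L] <- time_key
      df <- cbind(df, as.data.frame(X, check.names = FALSE))
      write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
    },
    h5ad = save_h5ad(data, path, time_key))
  invisible(path)
}

# ---- h5ad via the system python (anndata) ---------------------------------
# No HDF5 binding is available in R here; the h5ad dialect is bridged through
# a python subprocess that converts to/from the mtx layout above.

python_bin <- function() {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stopf("h5ad support needs a `python` with anndata on PATH")
  py
}

run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  on.exit(unlink(f))
  out <- suppressWarnings(system2(python_bin(), f, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status") %||% 0L
  if (status != 0L) stopf("python bridge failed:\n%s", paste(out, collapse = "\n"))
  invisible(out)
}

load_h5ad <- function(path, time_key) {
  tmp <- tempfile("h5ad_in_")
  on.exit(unlink(tmp, recursive = TRUE))
  run_python(c(
    "import anndata, numpy as np, scipy.sparse as sp, scipy.io, os, csv",
    sprintf("ad = anndata.read_h5ad(%s)", shQuote(path)),
    sprintf("os.makedirs(%s, exist_ok=True)", shQuote(tmp)),
    "X = ad.X.toarray() if sp.issparse(ad.X) else np.asarray(ad.X)",
    sprintf("scipy.io.mmwrite(os.path.join(%s, 'matrix.mtx'), sp.csr_matrix(X))", shQuote(tmp)),
    sprintf("open(os.path.join(%s, 'genes.tsv'), 'w').write('\\n'.join(map(str, ad.var_names)) + '\\n')", shQuote(tmp)),
    sprintf("tk = %s", shQuote(time_key)),
    "if tk not in ad.obs.columns: raise SystemExit('time column %r not in obs' % tk)",
    sprintf("w = csv.writer(open(os.path.join(%s, 'barcodes.tsv'), 'w'), delimiter='\\t')", shQuote(tmp)),
    "w.writerow(['cell', tk])",
    "for c, t in zip(ad.obs_names, ad.obs[tk]): w.writerow([c, t])"))
  load_mtx_dir(tmp, time_key)
}

save_h5ad <- function(data, path, time_key) {
  tmp <- tempfile("h5ad_out_")
  save_timeseries(data, tmp, "mtx", time_key = time_key)
  on.exit(unlink(tmp, recursive = TRUE))
  run_python(c(
    "import anndata, numpy as np, pandas as pd, scipy.io, os",
    sprintf("tmp = %s", shQuote(tmp)),
    "X = np.asarray(scipy.io.mmread(os.path.join(tmp, 'matrix.mtx')).todense())",
    "genes = [l.strip() for l in open(os.path.join(tmp, 'genes.tsv'))]",
    "obs = pd.read_csv(os.path.join(tmp, 'barcodes.tsv'), sep='\\t', index_col=0)",
    "obs.index = obs.index.astype(str)",
    "ad = anndata.AnnData(X=X.astype(np.float64), obs=obs, var=pd.DataFrame(index=genes))",
    sprintf("ad.write_h5ad(%s)", shQuote(path))))
  invisible(path)
}
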