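#' Read a feature matrix from delimited text or Matrix-Market files
#'
#' Delimited text (`csv`/`tsv`) is read with samples as rows, an optional
#' header row and an optional leading non-numeric ID column. Matrix-Market
#' (`mtx`) files follow the single-cell convention of features x samples and
#' are transposed on load; optional `features.tsv` / `barcodes.tsv` sidecars
#' in the same directory supply feature and sample identifiers.
#'
#' @param path input file.
#' @param format `"auto"` (from the extension), `"csv"`, `"tsv"` or `"mtx"`.
#' @param orientation for `mtx`: `"samples_cols"` (default, transposed on
#'   load) or `"samples_rows"`.
#' @return list with `X` (dense numeric matrix, rows = samples) and `ids`
#'   (character sample identifiers).
#' @export
read_matrix <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                        orientation = c("samples_cols", "samples_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv",
                     mtx = "mtx",
                     stop("cannot infer format from extension '.", ext,
                          "'; pass format explicitly"))
  }

  if (format == "mtx") {
    M <- tryCatch(Matrix::readMM(path), error = function(e) {
      stop("failed to parse Matrix-Market file ", path, ": ",
           conditionMessage(e))
    })
    if (orientation == "samples_cols") M <- Matrix::t(M)
    X <- as.matrix(M)
    dirn <- dirname(path)
    barcodes <- file.path(dirn, "barcodes.tsv")
    ids <- if (file.exists(barcodes)) {
      bc <- readLines(barcodes)
      if (length(bc) != nrow(X)) {
        stop("barcodes.tsv has ", length(bc), " entries but the matrix has ",
             nrow(X), " samples")
      }
      bc
    } else {
      as.character(seq_len(nrow(X)))
    }
    features <- file.path(dirn, "features.tsv")
    if (file.exists(features)) {
      fl <- readLines(features)
      if (length(fl) != ncol(X)) {
        stop("features.tsv has ", length(fl), " entries but the matrix has ",
             ncol(X), " features")
      }
      colnames(X) <- vapply(strsplit(fl, "\t"), `[[`, "", 1L)
    }
    rownames(X) <- ids
    return(list(X = X, ids = ids))
  }

  sep <- if (format == "csv") "," else "\t"
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop("ragged rows in ", path, ": line ", bad, " has ", widths[bad],
         " fields, expected ", widths[1L])
  }
  is_num <- function(v) !anyNA(suppressWarnings(as.numeric(v)))
  header <- !is_num(fields[[1L]][-1L]) || !is_num(fields[[1L]])
  # more precisely: header iff any non-ID cell of row 1 is non-numeric
  header <- !is_num(fields[[1L]][-1L])
  body <- fields[if (header) -1L else TRUE]
  if (!length(body)) stop("no data rows in ", path)
  id_col <- !is_num(vapply(body, `[[`, "", 1L))
  ids <- if (id_col) vapply(body, `[[`, "", 1L)
         else as.character(seq_along(body))
  strip <- if (id_col) -1L else TRUE
  rows <- lapply(seq_along(body), function(r) {
    v <- suppressWarnings(as.numeric(body[[r]][strip]))
    if (anyNA(v)) {
      stop("non-numeric cell in ", path, " at data row ", r)
    }
    v
  })
  X <- do.call(rbind, rows)
  rownames(X) <- ids
  if (header) {
    hdr <- fields[[1L]]
    colnames(X) <- hdr[if (id_col) -1L else seq_len(ncol(X))][seq_len(ncol(X))]
  }
  list(X = X, ids = ids)
}

#' Write sample labels as a two-column CSV
#'
#' @param path output path.
#' @param ids sample identifiers.
#' @param labels integer labels.
#' @return `path`, invisibly.
#' @export
write_labels <- function(path, ids, labels) {
  utils::write.csv(data.frame(id = ids, label = labels),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a label column from a CSV/TSV file
#'
#' Accepts either a bare single column of labels or an `id,label` table
#' (the last column is taken as the label).
#'
#' @param path input path.
#' @return integer label vector.
#' @export
read_labels <- function(path) {
  tab <- utils::read.csv(path, header = looks_like_header(path))
  lab <- tab[[ncol(tab)]]
  as.integer(as.factor(lab))
}

looks_like_header <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "[,\t]")[[1L]]
  anyNA(suppressWarnings(as.numeric(first)))
}
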