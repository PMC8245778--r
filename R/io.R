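# TSV readers/writers for the three pipeline inputs. All files are
# tab-separated UTF-8 with a single header line; the missing token is "NA".
# Gene/sample id matching everywhere is case-sensitive exact string.

#' Read a gene x sample expression matrix from TSV
#'
#' Expects a header row of sample ids and a first column of gene ids; values
#' are numeric or the missing token `NA`. Duplicate gene or sample ids,
#' ragged rows, and non-numeric cells are rejected with the offending line
#' named.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix (genes x samples) with dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort_data("expression file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) abort_data("%s: need a header and at least one gene row", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids)) {
    abort_data("%s: duplicate sample id '%s' in header",
               path, sample_ids[duplicated(sample_ids)][1L])
  }
  ncol_exp <- length(header)
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  gene_ids <- character(length(body))
  values <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != ncol_exp) {
      abort_data("%s: line %d has %d fields, expected %d", path, i + 1L, length(row), ncol_exp)
    }
    gene_ids[i] <- row[1L]
    cell <- row[-1L]
    v <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(v) & cell != "NA")
    if (length(bad)) {
      abort_data("%s: line %d: non-numeric value '%s' for sample '%s'",
                 path, i + 1L, cell[bad[1L]], sample_ids[bad[1L]])
    }
    values[i, ] <- v
  }
  dup <- which(duplicated(gene_ids))
  if (length(dup)) {
    abort_data("%s: duplicate gene id '%s' at line %d", path, gene_ids[dup[1L]], dup[1L] + 1L)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: header `gene_id` + sample ids, one row per
#' gene, missing entries written as `NA`. Round-trips exactly (values are
#' written with full precision).
#'
#' @param expr Numeric matrix with gene/sample dimnames.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  check_expression(expr)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(expr)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(rownames(expr)[i], format_num(expr[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

# full-precision, locale-independent numeric formatting shared by all writers
format_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else format(v, digits = 17, trim = TRUE)
  }, character(1))
}

check_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) abort_data("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    abort_data("expression matrix must carry gene and sample ids as dimnames")
  }
  if (anyDuplicated(rownames(expr))) abort_data("duplicate gene ids in expression matrix")
  if (anyDuplicated(colnames(expr))) abort_data("duplicate sample ids in expression matrix")
  invisible(expr)
}

read_tsv_table <- function(path, required, numeric_cols) {
  if (!file.exists(path)) abort_data("file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE,
                          na.strings = "NA", fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss)) abort_data("%s: missing column(s): %s", path, paste(miss, collapse = ", "))
  for (col in numeric_cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      if (any(is.na(vn) & !is.na(v))) abort_data("%s: column '%s' has non-numeric values", path, col)
      df[[col]] <- vn
    }
  }
  if (anyDuplicated(df$sample_id)) {
    abort_data("%s: duplicate sample id '%s'", path, df$sample_id[duplicated(df$sample_id)][1L])
  }
  df
}

#' Read a segmentation volume table (sample_id, EV, NV)
#' @param path TSV path with columns `sample_id`, `EV`, `NV`.
#' @return data.frame.
#' @export
read_segmentation <- function(path) {
  read_tsv_table(path, c("sample_id", "EV", "NV"), c("EV", "NV"))
}

#' Read a clinical table (sample_id, os_time, os_event, age, optional subtype)
#' @param path TSV path.
#' @return data.frame; `subtype` filled with "unknown" when absent.
#' @export
read_clinical <- function(path) {
  df <- read_tsv_table(path, c("sample_id", "os_time", "os_event", "age"),
                       c("os_time", "os_event", "age"))
  if (is.null(df$subtype)) df$subtype <- "unknown"
  if (any(!is.na(df$os_time) & df$os_time <= 0)) abort_data("%s: os_time must be > 0", path)
  if (!all(stats::na.omit(df$os_event) %in% c(0, 1))) abort_data("%s: os_event must be 0 or 1", path)
  df
}

#' Write a data frame as single-header TSV
#' @param df data.frame.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col)) format_num(col) else {
        out <- as.character(col); out[is.na(out)] <- "NA"; out
      }
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}
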