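#' Expression matrix of two-channel log2 ratios with a detection mask
#'
#' Container for a genes x samples matrix of log2(Cy5 sample / Cy3 common
#' reference) ratios together with a parallel logical mask flagging cells
#' whose fluorescence fell below the scanner's detection limit. Masked cells
#' are treated as missing by every downstream computation (means, tests,
#' medians); their numeric content is ignored.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row names
#'   are gene identifiers, column names sample identifiers; both mandatory
#'   and duplicate-free.
#' @param below_detection logical matrix of the same dimension, `TRUE` where
#'   the measurement is below detection. Defaults to `is.na(values)`.
#' @return An object of class `"expr_matrix"`: a list with elements
#'   `values` and `below_detection`.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' em <- expr_matrix(m)
#' dim(em)
#' @export
expr_matrix <- function(values, below_detection = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must carry gene ids as rownames and sample ids as colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated gene id: ", rownames(values)[duplicated(rownames(values))][1])
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample id: ", colnames(values)[duplicated(colnames(values))][1])
  if (is.null(below_detection)) below_detection <- is.na(values)
  if (!is.logical(below_detection) || !identical(dim(below_detection), dim(values)))
    stop("`below_detection` must be a logical matrix with the dimensions of `values`")
  if (anyNA(below_detection))
    stop("`below_detection` must not contain NA")
  dimnames(below_detection) <- dimnames(values)
  if (anyNA(values[!below_detection]))
    stop("detected cells must be numeric, not NA")
  structure(list(values = values, below_detection = below_detection),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x an `expr_matrix`.
#' @return Character vector of identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
`[.expr_matrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  b <- x$below_detection[i, j, drop = FALSE]
  expr_matrix(v, b)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples (%.1f%% below detection)\n",
              nrow(x$values), ncol(x$values),
              100 * mean(x$below_detection)))
  invisible(x)
}

#' Read a tab-delimited expression matrix
#'
#' Expects a header row `gene_id<TAB>sample ids...` followed by one row per
#' gene. Below-detection cells are encoded by a sentinel token (`"NA"` by
#' default, or the empty string). Malformed input (ragged rows, duplicate
#' identifiers, non-numeric cells) raises an error naming the offending line.
#'
#' @param path file path.
#' @param sentinel token marking below-detection cells, `"NA"` or `""`.
#' @return An [expr_matrix] whose masked cells hold `NA`.
#' @seealso [write_expr_matrix()] for the inverse operation.
#' @export
read_expr_matrix <- function(path, sentinel = "NA") {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty file: ", path)
  # the trailing guard byte keeps strsplit from dropping empty last fields
  fields <- lapply(strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE),
                   function(f) { f[length(f)] <- sub("\x01$", "", f[length(f)]); f })
  header <- fields[[1L]]
  if (length(header) < 2L)
    stop("line 1: header must contain a gene_id column and at least one sample")
  samples <- header[-1L]
  if (anyDuplicated(samples))
    stop("line 1: duplicated sample id: ", samples[duplicated(samples)][1])
  ncol_exp <- length(header)
  body <- fields[-1L]
  n <- length(body)
  genes <- character(n)
  vals <- matrix(NA_real_, n, ncol_exp - 1L)
  for (i in seq_len(n)) {
    row <- body[[i]]
    if (length(row) != ncol_exp)
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1L, ncol_exp, length(row)))
    genes[i] <- row[1L]
    cells <- row[-1L]
    is_sent <- cells == sentinel
    parsed <- suppressWarnings(as.numeric(cells[!is_sent]))
    if (anyNA(parsed))
      stop(sprintf("line %d: non-numeric value '%s' for gene '%s'",
                   i + 1L, cells[!is_sent][is.na(parsed)][1], row[1L]))
    v <- rep(NA_real_, ncol_exp - 1L)
    v[!is_sent] <- parsed
    vals[i, ] <- v
  }
  dup <- genes[duplicated(genes)]
  if (length(dup)) stop("duplicated gene id: ", dup[1])
  dimnames(vals) <- list(genes, samples)
  expr_matrix(vals)
}

#' Write an expression matrix as tab-delimited text
#'
#' Detected values are formatted with `%.17g`, enough digits that
#' write-then-read reproduces every double bit-exactly; masked cells are
#' written as the sentinel.
#'
#' @param x an [expr_matrix].
#' @param path output file path.
#' @param sentinel token to write for below-detection cells.
#' @param header optional character vector of comment lines (each prefixed
#'   `"# "`) placed before the table.
#' @return `path`, invisibly.
#' @export
write_expr_matrix <- function(x, path, sentinel = "NA", header = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  fmt <- matrix(sprintf("%.17g", x$values), nrow(x$values))
  fmt[x$below_detection] <- sentinel
  rows <- c(
    if (length(header)) paste0("# ", header),
    paste(c("gene_id", colnames(x$values)), collapse = "\t"),
    paste(rownames(x$values), apply(fmt, 1L, paste, collapse = "\t"),
          sep = "\t")
  )
  writeLines(rows, path)
  invisible(path)
}

#' Convert primary intensity ratios to log2 ratios
#'
#' The scanner reports the ratio of the Cy5 (sample) to the Cy3 (common
#' reference) intensity per probe; the analysis operates on its log2. A
#' detected ratio must be strictly positive.
#'
#' @param ratios numeric matrix of primary ratios (genes x samples, named),
#'   or an [expr_matrix] holding ratios.
#' @param below_detection optional logical mask (used when `ratios` is a bare
#'   matrix).
#' @return An [expr_matrix] of log2 ratios with the mask preserved.
#' @examples
#' m <- matrix(c(2, 1, 0.25, 4), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' ratios_to_log2(m)$values
#' @export
ratios_to_log2 <- function(ratios, below_detection = NULL) {
  if (inherits(ratios, "expr_matrix")) {
    below_detection <- ratios$below_detection
    ratios <- ratios$values
  }
  if (is.null(below_detection)) below_detection <- is.na(ratios)
  bad <- !below_detection & (is.na(ratios) | ratios <= 0)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive ratio at gene '%s', sample '%s'",
                 rownames(ratios)[idx[1L]], colnames(ratios)[idx[2L]]))
  }
  out <- ratios
  out[!below_detection] <- log2(ratios[!below_detection])
  expr_matrix(out, below_detection)
}

#' Median-center each sample
#'
#' Subtracts from every sample (column) the median of its detected log
#' ratios, so each sample's detected median becomes exactly zero. This is the
#' package's normalisation contract: minimal, idempotent, and independent of
#' the detection mask, which it leaves untouched.
#'
#' @param x an [expr_matrix].
#' @return The centered [expr_matrix].
#' @export
median_center <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  det <- !x$below_detection
  n_det <- colSums(det)
  if (any(n_det == 0L))
    stop("sample with no detected values: ",
         colnames(x$values)[n_det == 0L][1])
  v <- x$values
  v[!det] <- NA
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  out <- sweep(x$values, 2L, med, "-")
  expr_matrix(out, x$below_detection)
}

#' Read and write the per-sample annotation table
#'
#' Tab-delimited with one row per sample. Required columns: `sample_id` and
#' `lvsi` (values `"positive"`/`"negative"`); the clinical covariates (`age`,
#' `bmi`, `stage`, `histology`, `grade`, `myoinvasion`, `ln_metastasis`,
#' `recurrence`, `surv_time`, `surv_event`) are carried when present.
#'
#' @param path file path.
#' @return A `data.frame` with one row per sample.
#' @export
read_sample_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_sample_table(df)
  df
}

#' @rdname read_sample_table
#' @param samples sample annotation `data.frame`.
#' @param header optional comment lines written before the table.
#' @export
write_sample_table <- function(samples, path, header = NULL) {
  validate_sample_table(samples)
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(samples, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

validate_sample_table <- function(df) {
  if (!all(c("sample_id", "lvsi") %in% names(df)))
    stop("sample table must contain columns 'sample_id' and 'lvsi'")
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id: ", df$sample_id[duplicated(df$sample_id)][1])
  if (anyNA(df$lvsi) || !all(df$lvsi %in% c("positive", "negative")))
    stop("'lvsi' must be 'positive' or 'negative' for every sample")
  invisible(df)
}

# Coerce LVSI labels to a logical vector (TRUE = positive), aligned with the
# sample order of an expression matrix when one is given.
lvsi_logical <- function(labels, x = NULL) {
  if (is.data.frame(labels)) {
    validate_sample_table(labels)
    lab <- labels$lvsi == "positive"
    names(lab) <- labels$sample_id
  } else if (is.logical(labels)) {
    lab <- labels
  } else {
    if (!all(labels %in% c("positive", "negative")))
      stop("labels must be 'positive'/'negative' or logical")
    lab <- labels == "positive"
    names(lab) <- names(labels)
  }
  if (!is.null(x)) {
    ids <- sample_ids(x)
    if (!is.null(names(lab))) {
      if (!all(ids %in% names(lab)))
        stop("labels missing for samples: ",
             paste(setdiff(ids, names(lab)), collapse = ", "))
      lab <- lab[ids]
    } else if (length(lab) != length(ids)) {
      stop("unnamed labels must match the number of samples")
    }
  }
  lab
}
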