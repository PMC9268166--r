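#' Lipophilicity tables
#'
#' A `lipo_table` is the package's universal input: a numeric matrix with
#' compounds in rows and lipophilicity measures (or descriptors) in columns,
#' with character row names identifying the compounds.
#'
#' @param values numeric matrix (compounds x measures), no missing values.
#' @param compound_ids character vector of row identifiers.
#' @param measure_names character vector of column labels.
#' @param provenance one of `"fixture"`, `"user"`, `"synthetic"`.
#' @return an object of class `lipo_table` (a numeric matrix with dimnames
#'   and a `provenance` attribute).
#' @export
lipo_table <- function(values, compound_ids = rownames(values),
                       measure_names = colnames(values),
                       provenance = "user") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(compound_ids) || is.null(measure_names))
    stop("compound_ids and measure_names are required")
  compound_ids <- as.character(compound_ids)
  measure_names <- as.character(measure_names)
  if (length(compound_ids) != nrow(values))
    stop("length of compound_ids does not match row count")
  if (length(measure_names) != ncol(values))
    stop("length of measure_names does not match column count")
  if (anyDuplicated(compound_ids))
    stop("duplicated compound identifiers: ",
         paste(unique(compound_ids[duplicated(compound_ids)]), collapse = ", "))
  if (any(!is.finite(values)))
    stop("lipo_table values must be finite (no missing entries)")
  dimnames(values) <- list(compound_ids, measure_names)
  provenance <- match.arg(provenance, c("fixture", "user", "synthetic"))
  structure(values, class = c("lipo_table", "matrix", "array"),
            provenance = provenance)
}

#' @export
print.lipo_table <- function(x, ...) {
  cat(sprintf("lipo_table: %d compounds x %d measures (%s)\n",
              nrow(x), ncol(x), attr(x, "provenance")))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

# subsetting keeps class and provenance when the result is still a matrix
#' @export
`[.lipo_table` <- function(x, i, j, ..., drop = TRUE) {
  out <- NextMethod()
  if (is.matrix(out))
    out <- structure(out, class = class(x), provenance = attr(x, "provenance"))
  out
}

#' Packaged computational logP table (27 sulfonamides x 7 measures)
#'
#' Calculated logP values for the 27 anticancer sulfonamide derivatives:
#' iLogP, XLogP3, WLogP, MLogP, Silicos-IT logP, their consensus mean, and
#' KOWWIN logP.
#'
#' @return a 27 x 7 `lipo_table`.
#' @export
load_logp_table <- function() {
  path <- system.file("extdata", "sulfonamide_logp.csv",
                      package = "lipochemo", mustWork = TRUE)
  read_lipo_table(path)
}

#' Packaged chromatographic lipophilicity table (27 sulfonamides x 9 columns)
#'
#' Chromatographic hydrophobicity indices (CHI on IAM and C18 phases), their
#' transformed surrogates (logk_IAM, CHI logD), extrapolated retention factors
#' logk_w on C8/CN/phenyl phases, plus calculated pKa and anticancer potency
#' (pIC50 against HCT-116).
#'
#' @return a 27 x 9 `lipo_table`.
#' @export
load_chromatographic_table <- function() {
  path <- system.file("extdata", "sulfonamide_chromatographic.csv",
                      package = "lipochemo", mustWork = TRUE)
  read_lipo_table(path)
}

#' The 12-measure SRD input table
#'
#' Combines the seven computational logP scales with the five chromatographic
#' lipophilicity surrogates (logk_IAM, CHI logD, logk_w on C8/CN/Ph). CHI_IAM
#' and CHI_C18 are excluded as rank-equivalent affine preimages of logk_IAM /
#' CHI logD; pKa and pIC50 are not lipophilicity measures.
#'
#' @param include_pic50 also append the pIC50 column (used for the clustered
#'   heatmap axis, not for SRD).
#' @return a 27 x 12 (or 27 x 13) `lipo_table`.
#' @export
load_srd_table <- function(include_pic50 = FALSE) {
  logp <- load_logp_table()
  chrom <- load_chromatographic_table()
  cols <- c("logk_IAM", "CHI_logD", "logkw_C8", "logkw_CN", "logkw_Ph")
  if (include_pic50) cols <- c(cols, "pIC50")
  vals <- cbind(unclass(logp), unclass(chrom)[, cols, drop = FALSE])
  lipo_table(vals, provenance = "fixture")
}

#' Read a compound-by-measure table from delimited text
#'
#' Expects one header row of measure names and a leading identifier column.
#' Non-numeric cells in measure columns are reported and the offending column
#' dropped; duplicated identifiers and ragged rows are errors.
#'
#' @param path file path.
#' @param delimiter field delimiter (default comma).
#' @param provenance provenance tag stored on the result.
#' @return a `lipo_table`.
#' @export
read_lipo_table <- function(path, delimiter = ",", provenance = "user") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("file has no data rows: ", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  ncols <- length(fields[[1L]])
  bad <- which(vapply(fields, length, 1L) != ncols)
  if (length(bad))
    stop("ragged row at line ", bad[1L], " in ", path,
         " (expected ", ncols, " fields)")
  header <- trimws(fields[[1L]])
  body <- fields[-1L]
  ids <- trimws(vapply(body, `[`, "", 1L))
  if (anyDuplicated(ids))
    stop("duplicated compound identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  cells <- t(vapply(body, function(f) trimws(f[-1L]), character(ncols - 1L)))
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  dropped <- which(colSums(is.na(num)) > 0L)
  if (length(dropped)) {
    message("dropping non-numeric column(s): ",
            paste(header[-1L][dropped], collapse = ", "))
    num <- num[, -dropped, drop = FALSE]
  }
  keep <- if (length(dropped)) header[-1L][-dropped] else header[-1L]
  lipo_table(num, compound_ids = ids, measure_names = keep,
             provenance = if (basename(path) %in%
                              c("sulfonamide_logp.csv",
                                "sulfonamide_chromatographic.csv"))
               "fixture" else provenance)
}

#' Write a lipo_table to delimited text
#'
#' @param x a `lipo_table` or numeric matrix with dimnames.
#' @param path output file.
#' @param delimiter field delimiter.
#' @param id_name header label for the identifier column.
#' @export
write_lipo_table <- function(x, path, delimiter = ",", id_name = "compound") {
  df <- data.frame(rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_name
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Remove constant and near-constant descriptor columns
#'
#' Standard descriptor-matrix cleaning: columns whose sample variance does not
#' exceed `variance_tol` are dropped before model building.
#'
#' @param x numeric matrix or `lipo_table`.
#' @param variance_tol non-negative variance threshold; columns with variance
#'   `<= variance_tol` are removed. Default `1e-8` (an absolute threshold on
#'   the unscaled descriptors).
#' @return the filtered matrix, with attribute `removed` naming dropped
#'   columns.
#' @export
drop_near_constant <- function(x, variance_tol = 1e-8) {
  if (variance_tol < 0) stop("variance_tol must be >= 0")
  v <- apply(x, 2L, stats::var)
  drop <- v <= variance_tol
  if (all(drop)) stop("all columns are (near-)constant at this tolerance")
  out <- x[, !drop, drop = FALSE]
  attr(out, "removed") <- colnames(x)[drop]
  if (length(attr(out, "removed")))
    message("removed ", sum(drop), " near-constant column(s): ",
            paste(attr(out, "removed"), collapse = ", "))
  out
}
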