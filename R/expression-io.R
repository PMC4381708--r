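#' Expression tables with detection calls
#'
#' An `expr_table` holds a probe-by-sample matrix of summarized microarray
#' signal intensities (MAS5 scale, non-negative) together with an optional
#' parallel matrix of detection calls. Calls use the three-letter vocabulary
#' `P` (present), `M` (marginal) and `A` (absent); any other code is rejected.
#' Tables without calls are first-class citizens: confirmation data sets often
#' ship intensities only, in which case call-aware steps fall back to
#' intensity-only behaviour.
#'
#' @param signal numeric matrix, probes in rows, samples in columns. Row and
#'   column names are the probe and sample identifiers and must be unique.
#' @param calls optional character matrix of the same shape and dimnames as
#'   `signal`, entries in `c("P", "M", "A")`.
#' @return An object of class `expr_table`: a list with elements `signal`,
#'   `calls` (matrix or `NULL`), `probe_ids` and `sample_ids`.
#' @examples
#' sig <- matrix(c(100, 20, 250, 15), 2,
#'               dimnames = list(c("1000_at", "1001_s_at"), c("s1", "s2")))
#' cls <- matrix(c("P", "A", "P", "A"), 2, dimnames = dimnames(sig))
#' expression_table(sig, cls)
#' @export
expression_table <- function(signal, calls = NULL) {
  if (!is.matrix(signal) || !is.numeric(signal))
    stop("`signal` must be a numeric matrix")
  if (is.null(rownames(signal)) || is.null(colnames(signal)))
    stop("`signal` must carry probe (row) and sample (column) names")
  if (anyDuplicated(rownames(signal)))
    stop("duplicate probe identifiers in expression table")
  if (anyDuplicated(colnames(signal)))
    stop("duplicate sample identifiers in expression table")
  if (anyNA(signal))
    stop("missing signal intensities are not allowed")
  if (any(signal < 0))
    stop("negative signal intensity: intensities are MAS5-scale and must be >= 0")
  if (!is.null(calls)) {
    if (!is.matrix(calls) || !identical(dim(calls), dim(signal)))
      stop("`calls` must be a matrix with the same shape as `signal`")
    if (!identical(dimnames(calls), dimnames(signal)))
      stop("`calls` must have the same probe and sample names as `signal`")
    bad <- !(calls %in% c("P", "M", "A"))
    dim(bad) <- dim(calls)
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop(sprintf("unknown detection call '%s' at probe '%s', sample '%s'",
                   calls[idx[1], idx[2]],
                   rownames(calls)[idx[1]], colnames(calls)[idx[2]]))
    }
  }
  structure(list(signal = signal, calls = calls,
                 probe_ids = rownames(signal), sample_ids = colnames(signal)),
            class = "expr_table")
}

#' @export
print.expr_table <- function(x, ...) {
  cat(sprintf("Expression table: %d probe sets x %d samples (%s detection calls)\n",
              length(x$probe_ids), length(x$sample_ids),
              if (is.null(x$calls)) "no" else "with"))
  invisible(x)
}

#' @export
dim.expr_table <- function(x) dim(x$signal)

#' Does an expression table carry detection calls?
#' @param x an [expression_table()].
#' @return `TRUE` if a call matrix is present.
#' @export
has_calls <- function(x) !is.null(x$calls)

#' Read a tab-delimited expression table
#'
#' The dialect is one header row, a probe-identifier column first, then one
#' signal column per sample, each optionally followed by a call column named
#' `<sample><call_suffix>`. Tables whose header contains no call columns are
#' read in intensity-only mode (`calls` stays `NULL`). Column order beyond the
#' probe column is free: samples are identified by header name.
#'
#' @param path path to the file.
#' @param call_suffix suffix identifying call columns (default `"_call"`).
#' @return An [expression_table()].
#' @export
read_expression_table <- function(path, call_suffix = "_call") {
  if (!file.exists(path)) stop("expression table not found: ", path)
  d <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  hdr <- names(d)
  if (anyDuplicated(hdr))
    stop("duplicate column headers in expression table: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  if (ncol(d) < 2) stop("expression table needs a probe column and >= 1 sample column")
  probes <- d[[1]]
  call_cols <- hdr[-1][endsWith(hdr[-1], call_suffix)]
  sample_cols <- setdiff(hdr[-1], call_cols)
  sig <- vapply(sample_cols, function(s) {
    v <- suppressWarnings(as.numeric(d[[s]]))
    if (anyNA(v)) stop("non-numeric signal value in column '", s, "'")
    v
  }, numeric(nrow(d)))
  sig <- matrix(sig, nrow = nrow(d),
                dimnames = list(probes, sample_cols))
  calls <- NULL
  if (length(call_cols)) {
    expected <- paste0(sample_cols, call_suffix)
    missing_c <- setdiff(call_cols, expected)
    if (length(missing_c))
      stop("call columns without a matching sample column: ",
           paste(missing_c, collapse = ", "))
    if (!setequal(call_cols, expected))
      stop("tables mixing with-call and without-call samples are not supported")
    calls <- vapply(sample_cols, function(s) d[[paste0(s, call_suffix)]],
                    character(nrow(d)))
    calls <- matrix(calls, nrow = nrow(d), dimnames = list(probes, sample_cols))
  }
  expression_table(sig, calls)
}

#' Write an expression table in the package dialect
#'
#' Inverse of [read_expression_table()]: signal values are printed with
#' [format()] at full precision so a read/write round trip reproduces values
#' and call codes exactly.
#'
#' @param x an [expression_table()].
#' @param path output path.
#' @param call_suffix suffix for call columns.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, call_suffix = "_call") {
  stopifnot(inherits(x, "expr_table"))
  out <- data.frame(probe_id = x$probe_ids, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (s in x$sample_ids) {
    out[[s]] <- format(x$signal[, s], trim = TRUE, digits = 15)
    if (has_calls(x)) out[[paste0(s, call_suffix)]] <- x$calls[, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify probe-set identifiers by suffix
#'
#' Affymetrix probe-set identifiers end in `_at`, `_s_at` or `_x_at`; the
#' suffix encodes probe specificity (`_x_at` designs may cross-hybridize).
#' Identifiers without an `_at` suffix (e.g. control probes) are `OTHER`.
#'
#' @param probe_ids character vector of probe-set identifiers.
#' @return factor with levels `AT`, `S_AT`, `X_AT`, `OTHER`.
#' @examples
#' probe_suffix_class(c("201250_s_at", "217356_x_at", "218086_at", "AFFX-control"))
#' @export
probe_suffix_class <- function(probe_ids) {
  cls <- ifelse(endsWith(probe_ids, "_x_at"), "X_AT",
         ifelse(endsWith(probe_ids, "_s_at"), "S_AT",
         ifelse(endsWith(probe_ids, "_at"),   "AT", "OTHER")))
  factor(cls, levels = c("AT", "S_AT", "X_AT", "OTHER"))
}

#' Read a probe-to-gene annotation table
#'
#' Two tab-delimited columns, `probe_id` and `gene_symbol` (HGNC); extra
#' columns are ignored. Each probe must map to exactly one non-empty symbol;
#' exact duplicate rows are collapsed, conflicting ones are an error.
#'
#' @param path path to the annotation TSV.
#' @return data frame with columns `probe_id`, `gene_symbol`, `suffix_class`.
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  d <- utils::read.delim(path, colClasses = "character")
  if (ncol(d) < 2) stop("annotation needs columns probe_id and gene_symbol")
  d <- data.frame(probe_id = d[[1]], gene_symbol = d[[2]],
                  stringsAsFactors = FALSE)
  d <- unique(d)
  if (any(!nzchar(trimws(d$gene_symbol))))
    stop("empty gene symbol in annotation for probe(s): ",
         paste(d$probe_id[!nzchar(trimws(d$gene_symbol))], collapse = ", "))
  dup <- unique(d$probe_id[duplicated(d$probe_id)])
  if (length(dup))
    stop("probe(s) annotated with conflicting gene symbols: ",
         paste(dup, collapse = ", "))
  d$suffix_class <- probe_suffix_class(d$probe_id)
  d
}

#' Read a patient pairing configuration
#'
#' Maps each patient to one tumor and one adjacent-normal sample. Accepted
#' formats: tab-delimited with columns `patient`, `tumor`, `normal`, or a YAML
#' list of mappings with the same keys (chosen by file extension `.yaml` /
#' `.yml`).
#'
#' @param path path to the pairing file.
#' @return An object of class `sample_pairing`: data frame with columns
#'   `patient`, `tumor`, `normal`.
#' @export
read_pairing <- function(path) {
  if (!file.exists(path)) stop("pairing file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    d <- do.call(rbind, lapply(y, function(r)
      data.frame(patient = as.character(r$patient), tumor = as.character(r$tumor),
                 normal = as.character(r$normal), stringsAsFactors = FALSE)))
    if (is.null(d)) d <- data.frame(patient = character(), tumor = character(),
                                    normal = character())
  } else {
    d <- utils::read.delim(path, colClasses = "character")
    need <- c("patient", "tumor", "normal")
    if (!all(need %in% names(d)))
      stop("pairing file must have columns: ", paste(need, collapse = ", "))
    d <- d[, need]
  }
  sample_pairing(d)
}

#' Construct and validate a sample pairing
#'
#' @param d data frame with character columns `patient`, `tumor`, `normal`.
#' @return the validated `sample_pairing` object.
#' @export
sample_pairing <- function(d) {
  stopifnot(is.data.frame(d), all(c("patient", "tumor", "normal") %in% names(d)))
  if (nrow(d) == 0) {
    warning("empty pairing: no patients defined")
  } else {
    if (anyDuplicated(d$patient))
      stop("duplicate patient label(s) in pairing")
    if (any(d$tumor == d$normal))
      stop("tumor and normal sample of a patient must differ: patient(s) ",
           paste(d$patient[d$tumor == d$normal], collapse = ", "))
    all_s <- c(d$tumor, d$normal)
    if (anyDuplicated(all_s))
      stop("sample(s) referenced by more than one patient/tissue: ",
           paste(unique(all_s[duplicated(all_s)]), collapse = ", "))
  }
  rownames(d) <- NULL
  structure(d, class = c("sample_pairing", "data.frame"))
}

#' Check that a pairing refers only to samples present in a table
#'
#' @param pairing a [sample_pairing()].
#' @param table an [expression_table()].
#' @return `pairing`, invisibly; errors if a referenced sample is missing.
#' @export
validate_pairing <- function(pairing, table) {
  stopifnot(inherits(pairing, "sample_pairing"), inherits(table, "expr_table"))
  missing_s <- setdiff(c(pairing$tumor, pairing$normal), table$sample_ids)
  if (length(missing_s))
    stop("pairing refers to sample(s) absent from the expression table: ",
         paste(missing_s, collapse = ", "))
  invisible(pairing)
}
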