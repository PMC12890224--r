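#' Construct an omics matrix
#'
#' Light container for one omics layer: a numeric samples-by-features matrix
#' with sample identifiers as row names and feature identifiers as column
#' names, plus a label naming the layer (e.g. `"gene"`, `"mirna"`,
#' `"methylation"`).
#'
#' @param values Numeric matrix, samples in rows, features in columns.
#'   Row and column names are required (they are the identifiers).
#' @param omics_name Character label for the layer.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, omics_name = "omics") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("omics_matrix requires row names (sample IDs) and column names (feature IDs)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample IDs in omics matrix '", omics_name, "'")
  storage.mode(values) <- "double"
  structure(list(values = values, omics_name = as.character(omics_name)[1]),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("<omics_matrix '%s': %d samples x %d features, %d missing>\n",
              x$omics_name, nrow(x$values), ncol(x$values),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Construct a survival table
#'
#' Per-sample right-censored outcome: observed time `O` (event time if
#' `event == 1`, censoring time otherwise) and the event indicator.
#'
#' @param sample_id Character vector of sample identifiers.
#' @param time Non-negative observed times.
#' @param event Event indicators, each 0 (censored) or 1 (event observed).
#' @return A `data.frame` with class `survival_table` and columns
#'   `sample_id`, `time`, `event`.
#' @export
survival_table <- function(sample_id, time, event) {
  sample_id <- as.character(sample_id)
  time <- as.numeric(time)
  event <- as.numeric(event)
  if (length(time) != length(sample_id) || length(event) != length(sample_id))
    stop("sample_id, time and event must have equal length")
  if (anyDuplicated(sample_id)) stop("duplicate sample IDs in survival table")
  if (anyNA(time) || any(time < 0)) stop("survival times must be non-negative and non-missing")
  if (anyNA(event) || !all(event %in% c(0, 1)))
    stop("event indicator must be 0 or 1 for every sample")
  structure(data.frame(sample_id = sample_id, time = time, event = event,
                       stringsAsFactors = FALSE),
            class = c("survival_table", "data.frame"))
}

.missing_tokens <- c("", "na", "nan", "null")

.read_delim_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    colClasses = "character", check.names = FALSE,
                    comment.char = "", stringsAsFactors = FALSE)
}

#' Read one omics matrix from CSV/TSV
#'
#' Expects a header row of feature IDs and the first column holding sample
#' IDs; delimiter (comma or tab) is detected from the header line. Empty
#' cells and the tokens `NA`/`NaN`/`null` (case-insensitive) are read as
#' missing; any other non-numeric cell is a fatal error reported with its
#' row and column.
#'
#' @param path Path to a CSV or TSV file.
#' @param omics_name Label for the layer; defaults to the file base name.
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path, omics_name = NULL) {
  if (is.null(omics_name))
    omics_name <- sub("\\.[^.]*$", "", basename(path))
  tab <- .read_delim_table(path)
  if (ncol(tab) < 2L) stop("omics file has no feature columns: ", path)
  ids <- tab[[1L]]
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  low <- tolower(trimws(raw))
  raw[low %in% .missing_tokens] <- NA_character_
  suppressWarnings(num <- array(as.numeric(raw), dim = dim(raw)))
  bad <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-numeric value '%s' in %s at sample '%s' (row %d), feature '%s' (column %d)",
      raw[bad[1, 1], bad[1, 2]], path, ids[bad[1, 1]], bad[1, 1],
      colnames(raw)[bad[1, 2]], bad[1, 2]))
  }
  dimnames(num) <- list(ids, colnames(raw))
  omics_matrix(num, omics_name)
}

#' Read a survival table from CSV/TSV
#'
#' Expects columns `sample_id`, `time`, `event` (header required).
#'
#' @param path Path to a CSV or TSV file.
#' @return A [survival_table()].
#' @export
read_survival_table <- function(path) {
  tab <- .read_delim_table(path)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(tab)))
    stop("survival table must have columns sample_id, time, event; found: ",
         paste(names(tab), collapse = ", "))
  survival_table(tab$sample_id, as.numeric(tab$time), as.numeric(tab$event))
}

#' Load and align a multi-omics survival dataset
#'
#' Reads every omics matrix and the survival table, restricts all of them to
#' the intersection of their sample IDs and puts the rows in one common
#' order (the survival-table order filtered to the intersection).
#'
#' @param omics_paths Character vector of omics CSV/TSV paths.
#' @param survival_path Path to the survival CSV/TSV.
#' @param omics_names Optional labels, one per omics path.
#' @return A list with elements `omics` (list of [omics_matrix()]) and
#'   `survival` ([survival_table()]), all row-aligned.
#' @export
load_dataset <- function(omics_paths, survival_path, omics_names = NULL) {
  if (is.null(omics_names)) omics_names <- rep(list(NULL), length(omics_paths))
  omics <- mapply(read_omics_matrix, omics_paths, omics_names, SIMPLIFY = FALSE)
  surv <- read_survival_table(survival_path)
  align_dataset(omics, surv)
}

#' Align omics matrices and a survival table on shared sample IDs
#'
#' @param omics List of [omics_matrix()] objects.
#' @param surv A [survival_table()].
#' @return As [load_dataset()].
#' @export
align_dataset <- function(omics, surv) {
  ids <- surv$sample_id
  for (m in omics) ids <- intersect(ids, rownames(m$values))
  if (length(ids) == 0L)
    stop("no samples shared between the omics matrices and the survival table")
  ids <- surv$sample_id[surv$sample_id %in% ids]   # survival-table order
  omics <- lapply(omics, function(m)
    omics_matrix(m$values[ids, , drop = FALSE], m$omics_name))
  keep <- match(ids, surv$sample_id)
  surv <- survival_table(surv$sample_id[keep], surv$time[keep], surv$event[keep])
  list(omics = omics, survival = surv)
}

#' Write an omics matrix to CSV/TSV
#'
#' Emits the dialect [read_omics_matrix()] reads: header row of feature IDs,
#' first column `sample_id`.
#'
#' @param m An [omics_matrix()].
#' @param path Output path; a `.tsv` extension selects tab delimiting.
#' @export
write_omics_matrix <- function(m, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- data.frame(sample_id = rownames(m$values), m$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a survival table to CSV/TSV
#'
#' @param surv A [survival_table()].
#' @param path Output path; a `.tsv` extension selects tab delimiting.
#' @export
write_survival_table <- function(surv, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(as.data.frame(surv), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
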