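#' Write a subject time-series table
#'
#' Tab-delimited text: a header row of volume indices (`V1`..`VT`), then
#' one row per node with the node id in the first column.
#'
#' @param timeseries N x T numeric matrix (nodes as rows).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_subject_table <- function(timeseries, path) {
  ts <- as.matrix(timeseries)
  df <- data.frame(node = if (is.null(rownames(ts)))
    paste0("node", seq_len(nrow(ts))) else rownames(ts),
    ts, stringsAsFactors = FALSE)
  colnames(df) <- c("node", paste0("V", seq_len(ncol(ts))))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and validate a subject time-series table
#'
#' Parses a tab-delimited nodes x volumes table (header row of volume
#' indices, node ids in the first column). Ragged rows, non-numeric cells
#' and duplicated node ids are rejected with the offending row/column
#' named.
#'
#' @param path Input file path.
#' @return N x T numeric matrix with node ids as row names and a
#'   `report` attribute (list: n_nodes, n_volumes, n_missing).
#' @export
read_subject_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("time-series file has no data rows: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol_head <- length(fields[[1]])
  widths <- lengths(fields[-1])
  if (any(widths != ncol_head)) {
    bad <- which(widths != ncol_head)[1] + 1L
    stop("ragged row ", bad, ": expected ", ncol_head, " fields, found ",
         widths[bad - 1L])
  }
  ids <- vapply(fields[-1], `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate node id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  n_nodes <- length(ids)
  n_vol <- ncol_head - 1L
  ts <- matrix(NA_real_, n_nodes, n_vol,
               dimnames = list(ids, fields[[1]][-1]))
  for (i in seq_len(n_nodes)) {
    vals <- suppressWarnings(as.numeric(fields[[i + 1L]][-1]))
    raw <- fields[[i + 1L]][-1]
    bad <- which(is.na(vals) & !(raw %in% c("NA", "")))
    if (length(bad) > 0)
      stop("non-numeric cell at row ", i + 1L, ", column ", bad[1] + 1L,
           ": '", raw[bad[1]], "'")
    ts[i, ] <- vals
  }
  attr(ts, "report") <- list(n_nodes = n_nodes, n_volumes = n_vol,
                             n_missing = sum(is.na(ts)))
  ts
}

#' Write a connectivity matrix as delimited text
#'
#' @param conn A `connectivity_matrix`.
#' @param path Output file path (tab-delimited).
#' @return Invisibly, `path`.
#' @export
write_connectivity <- function(conn, path) {
  utils::write.table(unclass(conn), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a connectivity matrix written by [write_connectivity()]
#'
#' @param path Input file path.
#' @return A `connectivity_matrix`.
#' @export
read_connectivity <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  connectivity_matrix(m)
}

#' Read a cohort metadata table
#'
#' @param path CSV written by [write_cohort()] (or equivalent): one row
#'   per subject with outcome, EEG category, covariates and guideline
#'   predictors.
#' @return Data frame.
#' @export
read_cohort_metadata <- function(path) {
  md <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "outcome", "eeg_category", "arrest_to_mri_h",
                "hospital", "comatose", "pupils_ssep_absent",
                "eeg_guideline")
  missing <- setdiff(required, names(md))
  if (length(missing) > 0)
    stop("metadata is missing column(s): ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(md$outcome), c("good", "poor"))
  if (length(bad) > 0)
    stop("invalid outcome label(s): ", paste(bad, collapse = ", "))
  md
}

#' Write a resolved configuration as YAML
#'
#' @param config A `cohort_config` (or plain list of settings).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  cfg <- lapply(unclass(config), function(x) {
    if (is.matrix(x)) apply(x, 1, as.list, simplify = FALSE) else x
  })
  yaml::write_yaml(cfg, path)
  invisible(path)
}
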