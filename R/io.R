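# Plain-text cohort exchange format: a manifest CSV plus one delimited numeric
# matrix per subject (rows = timepoints, columns = ROIs, no header).

#' Write a cohort to disk
#'
#' Writes `manifest.csv` (columns `subject_id`, `site`, `group`,
#' `timeseries_path`) and one whitespace-delimited matrix file per subject
#' under `dir`. Paths in the manifest are relative to the manifest.
#'
#' @param cohort Cohort tibble as returned by [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- sprintf("%s.txt", cohort$subject_id)
  for (i in seq_len(nrow(cohort))) {
    write.table(cohort$timeseries[[i]], file.path(dir, paths[i]),
                row.names = FALSE, col.names = FALSE)
  }
  manifest <- data.frame(subject_id = cohort$subject_id, site = cohort$site,
                         group = cohort$group, timeseries_path = paths)
  manifest_path <- file.path(dir, "manifest.csv")
  write.csv(manifest, manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Read a cohort from a manifest
#'
#' @param manifest_path Path to a `manifest.csv` written by [write_cohort()]
#'   (or assembled by hand with the same columns). Time-series files may be
#'   whitespace- or comma-delimited, one row per timepoint, no header.
#' @return Cohort tibble with a `timeseries` list-column.
#' @export
read_cohort <- function(manifest_path) {
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "site", "group", "timeseries_path")
  missing <- setdiff(needed, names(manifest))
  if (length(missing)) {
    abort(paste0("manifest lacks column(s): ", paste(missing, collapse = ", ")))
  }
  root <- dirname(manifest_path)
  ts <- lapply(manifest$timeseries_path, function(p) {
    f <- if (file.exists(p)) p else file.path(root, p)
    sep <- if (grepl(",", readLines(f, n = 1L))) "," else ""
    as.matrix(read.table(f, header = FALSE, sep = sep))
  })
  ts <- lapply(ts, function(m) {
    dimnames(m) <- NULL
    if (anyNA(m)) abort("time series contains missing values")
    m
  })
  tibble(subject_id = manifest$subject_id, site = manifest$site,
         group = manifest$group, timeseries = ts)
}

#' Write a binary graph as an undirected edge list
#'
#' One `i j` pair per line with `i < j`, 0-based node indices (the exchange
#' convention; in-package objects index nodes from 1).
#'
#' @param graph Binary adjacency matrix from [binarize()].
#' @param file Output path.
#' @return Invisibly, `file`.
#' @export
write_edge_list <- function(graph, file) {
  idx <- which(upper.tri(graph) & graph > 0, arr.ind = TRUE)
  write.table(cbind(idx[, 1] - 1L, idx[, 2] - 1L), file,
              row.names = FALSE, col.names = FALSE)
  invisible(file)
}
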