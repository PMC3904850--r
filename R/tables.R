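# Access to the published per-subject performance tables shipped with the
# package (healthy-control and Alzheimer's-disease validation cohorts, one
# table per rater), transcribed to dot-decimal CSV.

#' Read a bundled per-subject performance table
#'
#' Tables 1-2 hold the 30 healthy controls (first/second rater), tables 3-4
#' the 10 Alzheimer's-disease patients (first/second rater). Columns:
#' \code{id}, \code{structure} (midbrain/pons), \code{manual_volume},
#' \code{labs_volume} (mm^3), \code{dice}, \code{hausdorff},
#' \code{volume_ratio}.
#'
#' @param table table number 1-4, or a path to a CSV in the same layout.
#' @return A data.frame.
#' @export
#' @examples
#' t1 <- readPerformanceTable(1)
#' summarizeMetrics(t1$dice[t1$structure == "midbrain"])
readPerformanceTable <- function(table) {
  path <- if (is.numeric(table)) {
    system.file("extdata", sprintf("table%d.csv", as.integer(table)),
                package = "labseg", mustWork = TRUE)
  } else table
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "structure", "manual_volume", "labs_volume", "dice",
            "hausdorff", "volume_ratio")
  if (!all(need %in% names(df)))
    stop("readPerformanceTable: missing columns in ", path)
  df
}

#' Column summaries of a performance table
#'
#' Reproduces the Mean / St.dev rows of a per-subject table: for each
#' structure and each metric column, the arithmetic mean and sample
#' standard deviation over subjects.
#'
#' @param df data.frame from \code{\link{readPerformanceTable}}.
#' @return data.frame with structure, metric, mean, sd.
#' @export
summarizePerformanceTable <- function(df) {
  metrics <- c("manual_volume", "labs_volume", "dice", "hausdorff",
               "volume_ratio")
  out <- do.call(rbind, lapply(split(df, df$structure), function(g) {
    do.call(rbind, lapply(metrics, function(m) {
      s <- summarizeMetrics(g[[m]])
      data.frame(structure = g$structure[1], metric = m,
                 mean = s[["mean"]], sd = s[["sd"]])
    }))
  }))
  rownames(out) <- NULL
  out
}
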