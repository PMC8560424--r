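#' Read a stimulus-aligned amplitude table
#'
#' Reads the long delimited-text schema used throughout the package:
#' columns `cell_id`, `condition`, `run_index`, `train_role`,
#' `stim_index`, `time_s`, `amplitude` (comma- or tab-delimited by file
#' extension). Validation errors report the offending column and data
#' line.
#'
#' @param path Path to a `.csv` or `.tsv` file.
#' @return A validated data frame in the schema above (possibly empty).
#' @export
read_amplitude_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c("cell_id", "condition", "run_index", "train_role",
                "stim_index", "time_s", "amplitude")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  if (nrow(df) == 0) {
    warning("amplitude table is empty: ", path)
    return(df[required])
  }
  for (col in c("run_index", "stim_index", "time_s", "amplitude")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0)
      stop("non-numeric value in column '", col, "' at data line ",
           bad[1], " of ", path)
    df[[col]] <- as.numeric(df[[col]])
  }
  grp <- interaction(df$cell_id, df$condition, df$run_index, drop = TRUE)
  unsorted <- vapply(split(df$time_s, grp), is.unsorted, logical(1))
  if (any(unsorted))
    stop("stimulus times not ascending within group(s): ",
         paste(names(unsorted)[unsorted], collapse = ", "))
  df[required]
}

#' Write an amplitude table
#'
#' @param df Data frame in the amplitude-table schema (see
#'   [read_amplitude_table()]).
#' @param path Output path (`.csv` or `.tsv`).
#' @return `path`, invisibly.
#' @export
write_amplitude_table <- function(df, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert an amplitude table to a list of EPSC trains
#'
#' @param df Data frame from [read_amplitude_table()] or
#'   [as_amplitude_table()].
#' @return Named list of [epsc_train()] objects, one per
#'   (cell, condition, run) group.
#' @export
as_epsc_trains <- function(df) {
  grp <- interaction(df$cell_id, df$condition, df$run_index, drop = TRUE)
  lapply(split(df, grp), function(g) {
    g <- g[order(g$stim_index), ]
    epsc_train(g$time_s, g$amplitude, cell_id = g$cell_id[1],
               condition = g$condition[1], run_index = g$run_index[1],
               train_role = g$train_role[1])
  })
}

#' Serialize model parameters to a flat JSON document
#'
#' @param base A [base_params()].
#' @param trains Optional list of [train_consumption()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_params <- function(base, trains = list(), path) {
  stopifnot(inherits(base, "base_params"))
  doc <- list(gamma_b = base$gamma_b, gamma_1 = base$gamma_1, h = base$h,
              K_rel = base$K_rel,
              trains = lapply(trains, function(tc) {
                list(train_index = tc$train_index, gamma_max = tc$gamma_max,
                     h_t = tc$h_t, K_t = tc$K_t, atp0_rel = tc$atp0_rel)
              }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path Path written by [write_model_params()].
#' @return List with `base` ([base_params()]) and `trains` (list of
#'   [train_consumption()]).
#' @export
read_model_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- base_params(doc$gamma_b, doc$gamma_1, doc$h, doc$K_rel)
  trains <- list()
  if (!is.null(doc$trains) && length(doc$trains) > 0) {
    tr <- doc$trains
    trains <- lapply(seq_len(nrow(tr)), function(i) {
      train_consumption(tr$train_index[i], tr$gamma_max[i], tr$h_t[i],
                        tr$K_t[i], tr$atp0_rel[i])
    })
  }
  list(base = base, trains = trains)
}

#' Export a trajectory or curve as two-column delimited text
#'
#' @param df Data frame whose first two columns are time (s) and a value
#'   (e.g. an `atp_trajectory` or `failure_curve`).
#' @param path Output path.
#' @param header Optional comment lines (each prefixed with `#`) written
#'   before the one-line column header.
#' @return `path`, invisibly.
#' @export
write_curve <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  writeLines(paste(names(df)[1], names(df)[2], sep = ","), con)
  utils::write.table(df[, 1:2], con, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
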