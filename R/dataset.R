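#' The measurement dataset CSV schema
#'
#' Column names of the flat dataset exchanged by the pipeline: identifier,
#' temperature, 8 baseline-phase channels, 8 sample-phase channels and the
#' 8 target concentrations.
#'
#' @return character vector of 26 column names.
#' @export
dataset_columns <- function() {
  c("sample_id", "temp_C",
    paste0("u0_", channel_names()),
    paste0("ux_", channel_names()),
    paste0("c_", ion_names()))
}

#' Convert measurement records to the flat dataset form
#'
#' @param records list of `measurement_record` objects.
#' @return data.frame with columns [dataset_columns()].
#' @export
records_to_dataset <- function(records) {
  rows <- lapply(records, function(r) {
    row <- c(list(sample_id = r$sample_id, temp_C = r$temperature),
             as.list(setNames(r$u0, paste0("u0_", channel_names()))),
             as.list(setNames(r$ux, paste0("ux_", channel_names()))),
             as.list(setNames(r$targets[ion_names()],
                              paste0("c_", ion_names()))))
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[, dataset_columns()]
}

#' Convert a flat dataset back to measurement records
#'
#' @param dataset data.frame in the [dataset_columns()] schema.
#' @return list of `measurement_record` objects.
#' @export
dataset_to_records <- function(dataset) {
  check_dataset(dataset)
  lapply(seq_len(nrow(dataset)), function(i) {
    row <- dataset[i, ]
    structure(list(
      sample_id = as.character(row$sample_id),
      u0 = setNames(as.numeric(row[paste0("u0_", channel_names())]),
                    channel_names()),
      ux = setNames(as.numeric(row[paste0("ux_", channel_names())]),
                    channel_names()),
      temperature = as.numeric(row$temp_C),
      targets = setNames(as.numeric(row[paste0("c_", ion_names())]),
                         ion_names()),
      seed = NA_integer_
    ), class = "measurement_record")
  })
}

check_dataset <- function(dataset) {
  missing <- setdiff(dataset_columns(), names(dataset))
  if (length(missing))
    stop_input("dataset is missing column(s): ", paste(missing, collapse = ", "))
  invisible(dataset)
}

#' Write / read a measurement dataset CSV
#'
#' Plain CSV with the exact [dataset_columns()] header.
#'
#' @param dataset data.frame in the dataset schema.
#' @param path file path.
#' @return `read_dataset` returns the data.frame; `write_dataset` returns
#'   `path` invisibly. I/O failures are reported with the offending path.
#' @export
write_dataset <- function(dataset, path) {
  check_dataset(dataset)
  tryCatch(write.csv(dataset[, dataset_columns()], path, row.names = FALSE),
           error = function(e)
             stop_input("failed to write dataset to '", path, "': ",
                        conditionMessage(e)))
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop_input("dataset file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop_input("failed to read dataset from '", path, "': ",
                              conditionMessage(e)))
  check_dataset(df)
  df
}
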