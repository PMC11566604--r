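# File interchange: long-format trace CSV, multi-page TIFF stacks, ground
# truth / summaries as JSON.

#' Read and write long-format trace tables
#'
#' Traces travel as CSV with columns `time_s`, `region`, `channel`,
#' `cell_type` (optional), `value`, plus any columns added by
#' [process_traces()].
#'
#' @param traces Long trace tibble.
#' @param path File path.
#' @return `write_traces_csv()` returns `path` invisibly; `read_traces_csv()`
#'   returns a tibble.
#' @export
write_traces_csv <- function(traces, path) {
  readr::write_csv(traces, path)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Write and read a frame stack as multi-page 32-bit float TIFF
#'
#' Intensities are stored scaled by `max_value` into `[0, 1]` as 32-bit
#' floats, so the round trip is exact to single precision (far below the
#' 0.5-gray-level quantization budget of the ROI round trip).
#'
#' @param frames T x H x W numeric array.
#' @param path File path.
#' @param max_value Scale recorded into the reader's back-transform.
#' @return `write_frames_tiff()` returns `path` invisibly;
#'   `read_frames_tiff()` returns the array.
#' @export
write_frames_tiff <- function(frames, path, max_value = 255) {
  pages <- lapply(seq_len(dim(frames)[1]), function(t) frames[t, , ] / max_value)
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' @rdname write_frames_tiff
#' @export
read_frames_tiff <- function(path, max_value = 255) {
  pages <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]] * max_value
  arr
}

#' Export ground truth or summaries as JSON
#'
#' @param x A list or tibble (tibbles become row-wise records).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_json_summary <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  invisible(path)
}

#' Export a connectivity graph as edge and node CSVs
#'
#' @param graph An `"fp_graph"` object.
#' @param edge_path,node_path Output CSV paths.
#' @return Invisible list of both paths.
#' @export
write_graph_csv <- function(graph, edge_path, node_path) {
  edges <- graph$edges
  edges$state <- graph$state
  edges$cell_type <- graph$cell_type
  readr::write_csv(edges, edge_path)
  readr::write_csv(graph$nodes, node_path)
  invisible(list(edges = edge_path, nodes = node_path))
}

#' Read a connectivity matrix back from a labeled CSV
#'
#' @param path CSV with row labels in the first column.
#' @return An `"fp_connectivity"` object (state/cell_type unset).
#' @export
read_connectivity_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  structure(list(r = m, n_samples = NA_integer_, state = NA_character_,
                 cell_type = NA_character_, undefined = character()),
            class = "fp_connectivity")
}

#' Write a connectivity matrix as a labeled CSV
#'
#' @param connectivity An `"fp_connectivity"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_connectivity_csv <- function(connectivity, path) {
  df <- tibble::as_tibble(connectivity$r, rownames = "region")
  readr::write_csv(df, path)
  invisible(path)
}
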