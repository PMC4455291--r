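#' Read and write response tables as CSV
#'
#' The interchange schema is a plain CSV with header
#' `sample_index,stimulus,episode,ch01,...,chNN`. Channel-to-class membership
#' travels in a comment-style first line `#channel_class: 1,1,...` so that one
#' file is self-contained. Columns may appear in any order in the header; they
#' are parsed into canonical order. Writing is atomic (write to a temporary
#' file in the target directory, then rename).
#'
#' @param data a `response_matrix`
#' @param path output file path
#' @return `write_response_csv` returns `path` invisibly;
#'   `read_response_csv` returns a `response_matrix`
#' @export
write_response_csv <- function(data, path) {
  stopifnot(inherits(data, "response_matrix"))
  df <- data.frame(sample_index = data$sample_index,
                   stimulus = data$stimulus, episode = data$episode)
  vals <- as.data.frame(data$values)
  df <- cbind(df, vals)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  con <- file(tmp, "w")
  writeLines(paste0("#channel_class: ",
                    paste(data$channel_class, collapse = ",")), con)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   con, row.names = FALSE, quote = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_response_csv
#' @param path CSV file path
#' @export
read_response_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop("file too short: ", path)
  has_cc <- startsWith(lines[1], "#channel_class:")
  cc <- NULL
  if (has_cc) {
    cc <- as.integer(strsplit(sub("^#channel_class:\\s*", "", lines[1]),
                              ",")[[1]])
    lines <- lines[-1]
  }
  header <- strsplit(lines[1], ",")[[1]]
  required <- c("sample_index", "stimulus", "episode")
  miss <- setdiff(required, header)
  if (length(miss) > 0) stop("missing column(s): ", paste(miss, collapse = ", "))
  ch_cols <- sort(grep("^ch[0-9]+$", header, value = TRUE))
  if (length(ch_cols) == 0) stop("no channel columns (ch01, ch02, ...) found")
  df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                        check.names = FALSE)
  for (col in c(required, ch_cols)) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad) > 0)
      stop(sprintf("non-numeric value in column '%s' at line %d of %s",
                   col, bad[1] + 1L + has_cc, path))
  }
  if (anyDuplicated(df$sample_index))
    stop("duplicate sample_index at line ",
         which(duplicated(df$sample_index))[1] + 1L + has_cc)
  if (is.null(cc)) cc <- rep(1L, length(ch_cols))
  response_matrix(as.matrix(df[ch_cols]), df$stimulus, df$episode, cc,
                  df$sample_index)
}

#' Serialise a network to / from JSON
#'
#' @param net a `glom_network`
#' @param path JSON file path
#' @return `write_network_json` returns `path` invisibly; `read_network_json`
#'   returns the `glom_network`
#' @export
write_network_json <- function(net, path) {
  stopifnot(inherits(net, "glom_network"))
  obj <- list(L = net$L, N = net$N,
              class_mask = net$class_mask, c = net$c, d = net$d,
              f = as.vector(net$f), f_dim = dim(net$f),
              rates = as.list(net$rates))
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(obj, tmp, digits = NA, auto_unbox = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(L = as.integer(obj$L), N = as.integer(obj$N),
                 class_mask = as.matrix(obj$class_mask),
                 c = as.matrix(obj$c), d = as.matrix(obj$d),
                 f = array(obj$f, dim = obj$f_dim),
                 rates = unlist(obj$rates)),
            class = "glom_network")
}

#' Write a trace of mitral-cell outputs as CSV
#'
#' @param trace a `glom_trace` from [process_sequence()]
#' @param path output path
#' @export
write_trace_csv <- function(trace, path) {
  stopifnot(inherits(trace, "glom_trace"))
  df <- data.frame(sample_index = trace$sample_index,
                   stimulus = trace$stimulus)
  df <- cbind(df, as.data.frame(trace$mc_outputs))
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run manifest
#'
#' Records everything needed to reproduce a run bit-identically: the config
#' snapshot, the master seed, the package version, md5 checksums of the input
#' files and the list of output files. Written once per run, atomically.
#'
#' @param path output JSON path
#' @param config the configuration list used
#' @param seed the master seed
#' @param inputs character vector of input file paths (checksummed)
#' @param outputs character vector of output file paths
#' @export
write_manifest <- function(path, config, seed, inputs = character(),
                           outputs = character()) {
  man <- list(package = "glomenose",
              version = as.character(utils::packageVersion("glomenose")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              master_seed = as.integer(seed),
              config = config,
              input_checksums = as.list(tools::md5sum(inputs)),
              outputs = as.list(outputs))
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".json")
  jsonlite::write_json(man, tmp, digits = NA, auto_unbox = TRUE, null = "null")
  file.rename(tmp, path)
  invisible(path)
}
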