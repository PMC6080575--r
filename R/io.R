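#' Write a network as a square TSV matrix
#'
#' @param net a \code{\link{network}}.
#' @param path output file; first column and header row carry node names.
#' @export
write_network_tsv <- function(net, path) {
  stopifnot(inherits(net, "network"))
  df <- data.frame(node = net$node_names, net$weights, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a square TSV matrix as a network
#'
#' @param path file written by \code{\link{write_network_tsv}}, or any
#'   square delimited matrix with a header row of node names (optionally a
#'   leading node-name column).
#' @param timepoint_label ordinal time label to attach.
#' @return a \code{\link{network}}.
#' @export
read_network_tsv <- function(path, timepoint_label = NA) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.character(df[[1]])) {
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
  } else rn <- colnames(df)
  w <- as.matrix(df)
  rownames(w) <- rn
  network(w, node_names = colnames(w), timepoint_label = timepoint_label)
}

#' Write a developmental-networks stack as TSV
#'
#' Rows are connections labelled \code{"a--b"}, columns are time labels.
#'
#' @param X a \code{\link{developmental_networks}} stack.
#' @param path output file.
#' @export
write_stack_tsv <- function(X, path) {
  stopifnot(inherits(X, "developmental_networks"))
  df <- data.frame(connection = X$edge_names, X$X, check.names = FALSE)
  colnames(df) <- c("connection", X$time_labels)
  attr_line <- sprintf("# nodes: %s", paste(X$node_names, collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr_line, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a developmental-networks stack from TSV
#'
#' @param path file written by \code{\link{write_stack_tsv}}.
#' @return a \code{\link{developmental_networks}} stack.
#' @export
read_stack_tsv <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# nodes:"))
    dm_stop("stack file lacks the '# nodes:' header line",
            "devmeta_validation_error")
  node_names <- strsplit(sub("^# nodes: ", "", first), "\t")[[1]]
  df <- utils::read.table(path, sep = "\t", header = TRUE, skip = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1, drop = FALSE])
  developmental_networks(X, node_names = node_names,
                         time_labels = as.numeric(colnames(df)[-1]))
}

#' Read per-age measurement tables and covariates from delimited files
#'
#' Each measurement file holds one time point (rows = subjects, first
#' column = subject ID, remaining columns = ROIs); its time label is the
#' first number in the file name. The covariate file is keyed by subject
#' ID in its first column.
#'
#' @param files character vector of measurement file paths.
#' @param covariates_file path to the covariate table.
#' @param sep field separator (default tab).
#' @return list of \code{\link{measurement_table}} objects ordered by time
#'   label.
#' @export
read_measurement_tables <- function(files, covariates_file, sep = "\t") {
  cov <- utils::read.table(covariates_file, sep = sep, header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(cov[[1]])
  labels <- vapply(unname(files), function(f) {
    m <- regmatches(basename(f), regexpr("[0-9]+(\\.[0-9]+)?", basename(f)))
    if (length(m) == 0)
      dm_stop("cannot parse a time label from file name '%s'",
              "devmeta_config_error", basename(f))
    as.numeric(m)
  }, 0, USE.NAMES = FALSE)
  files <- files[order(labels)]
  labels <- sort(labels)
  lapply(seq_along(files), function(i) {
    df <- utils::read.table(files[i], sep = sep, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    sub_ids <- as.character(df[[1]])
    values <- as.matrix(df[, -1, drop = FALSE])
    hit <- match(sub_ids, ids)
    if (anyNA(hit))
      dm_stop("subjects missing from covariate file: %s",
              "devmeta_config_error",
              paste(sub_ids[is.na(hit)], collapse = ", "))
    measurement_table(values, timepoint_label = labels[i],
                      covariates = cov[hit, -1, drop = FALSE])
  })
}

#' Write a trajectory matrix as TSV
#' @param result a \code{dmd_result}.
#' @param path output file.
#' @export
write_trajectories_tsv <- function(result, path) {
  df <- data.frame(time = result$time_labels, result$V, check.names = FALSE)
  colnames(df) <- c("time", paste0("DM", seq_len(ncol(result$V))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one stage state of U as a labelled edge table
#' @param result a \code{dmd_result}.
#' @param t stage index.
#' @param path output file.
#' @export
write_stage_state_tsv <- function(result, t, path) {
  U <- result$U[[t]]
  ep <- edge_endpoints(length(result$node_names))
  df <- data.frame(node_a = result$node_names[ep[, 1]],
                   node_b = result$node_names[ep[, 2]], U,
                   check.names = FALSE)
  colnames(df) <- c("node_a", "node_b", paste0("DM", seq_len(ncol(U))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
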