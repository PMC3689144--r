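#' Write analysis result tables to TSV
#'
#' Every result object in the package serializes to a tab-separated table
#' with a documented header; floating point values are written at 6
#' decimals and missing values as the token `NA`.
#'
#' @param x a result object (`linkage_result`, list of `linkage_result`,
#'   `slv_report`, `fst_matrix`, `mantel_result`) or a plain data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  df <- as_result_table(x)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(is.na(v), NA_character_, formatC(v, digits = 6, format = "f")))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write results to ", path)
  invisible(path)
}

as_result_table <- function(x) UseMethod("as_result_table")

#' @export
as_result_table.data.frame <- function(x) x

#' @export
as_result_table.linkage_result <- function(x) {
  data.frame(subset = x$label, n = x$n, n_st = NA_integer_, V_D = x$V_D,
             V_E = x$V_E, I_A = x$I_A, I_SA = x$I_SA, P = x$P,
             resamples = x$resamples, stringsAsFactors = FALSE)
}

#' @export
as_result_table.list <- function(x) {
  if (length(x) == 0)
    return(data.frame(subset = character(), n = integer(),
                      n_st = integer(), V_D = double(), V_E = double(),
                      I_A = double(), I_SA = double(), P = double(),
                      resamples = integer()))
  do.call(rbind, lapply(x, as_result_table))
}

#' @export
as_result_table.epidemic_contrast <- function(x) {
  rbind(as_result_table(x$isolates), as_result_table(x$unique_sts))
}

#' @export
as_result_table.slv_report <- function(x) x$records

#' @export
as_result_table.mantel_result <- function(x) {
  data.frame(rho = x$rho, significance_percent = x$significance_percent,
             permutations = x$permutations, stringsAsFactors = FALSE)
}

#' @export
as_result_table.fst_matrix <- function(x) {
  lev <- x$levels
  rows <- list()
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j < i && !is.na(x$fst[i, j]))
      rows[[length(rows) + 1]] <- data.frame(
        subset_a = lev[j], subset_b = lev[i], F_ST = x$fst[i, j],
        P = if (is.null(x$P)) NA_real_ else x$P[i, j],
        permutations = x$permutations, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a square labelled distance matrix to TSV
#' @param d a `dist` object or square matrix with labels.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  df <- data.frame(label = rownames(m), m, stringsAsFactors = FALSE,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a square labelled distance matrix from TSV
#' @param path file written by [write_distance_matrix()] (first column
#'   `label`, remaining columns one per label).
#' @return a `dist` object.
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$label
  if (!identical(rownames(m), colnames(m)))
    stop("distance matrix labels are not symmetric in ", path)
  stats::as.dist(m)
}

#' Write a JSON run manifest next to an output file
#'
#' Records the command name, parameters, seed, package version and SHA-256
#' style checksums (md5) of the input files, so any analysis run can be
#' reproduced and its inputs verified.
#'
#' @param command short command name.
#' @param parameters named list of parameters.
#' @param seed RNG seed used (or NULL).
#' @param inputs character vector of input file paths to checksum.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(command, parameters = list(), seed = NULL,
                               inputs = character(), path) {
  manifest <- list(
    command = command,
    parameters = parameters,
    seed = seed,
    package_version = as.character(utils::packageVersion("mlsapop")),
    input_checksums = as.list(tools::md5sum(inputs)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
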