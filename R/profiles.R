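#' Construct a locus description table
#'
#' A locus table records, for each typed locus, its name, aligned length in
#' nucleotides, reading-frame offset and NCBI genetic code id.  The frame
#' offset is the 0-based position of the first complete codon in the aligned
#' fragment; code 11 is the bacterial/archaeal translation table.
#'
#' @param name character vector of locus names.
#' @param aligned_length integer vector of alignment lengths (nt).
#' @param frame_offset integer in 0:2, recycled.
#' @param genetic_code_id NCBI translation table id, recycled.
#' @return a data.frame with one row per locus.
#' @export
locus_table <- function(name, aligned_length, frame_offset = 0L,
                        genetic_code_id = 11L) {
  stopifnot(length(name) >= 1, !anyDuplicated(name))
  aligned_length <- as.integer(aligned_length)
  if (any(aligned_length <= 0)) stop("aligned_length must be positive")
  frame_offset <- rep_len(as.integer(frame_offset), length(name))
  if (any(frame_offset < 0 | frame_offset > 2))
    stop("frame_offset must be 0, 1 or 2")
  data.frame(name = as.character(name),
             aligned_length = aligned_length,
             frame_offset = frame_offset,
             genetic_code_id = rep_len(as.integer(genetic_code_id),
                                       length(name)),
             stringsAsFactors = FALSE)
}

#' Construct an isolate table
#'
#' The central container: one row per isolate, with its id, subpopulation
#' labels (spring, year) and the allelic profile -- one 1-based allele index
#' per locus, in a fixed locus order recorded in the `"loci"` attribute.
#'
#' @param isolate_id character vector of unique ids.
#' @param spring character subpopulation label.
#' @param year integer sampling year (NA = unknown).
#' @param profiles integer matrix, one column per locus; column names are
#'   the locus names.
#' @return a data.frame of class `"isolate_table"`.
#' @export
isolate_table <- function(isolate_id, spring, year, profiles) {
  profiles <- as.matrix(profiles)
  storage.mode(profiles) <- "integer"
  if (is.null(colnames(profiles))) stop("profiles must have locus column names")
  if (anyDuplicated(isolate_id)) stop("duplicate isolate ids")
  if (any(profiles < 1L, na.rm = TRUE)) stop("allele indices must be >= 1")
  out <- data.frame(isolate_id = as.character(isolate_id),
                    spring = as.character(spring),
                    year = as.integer(year),
                    profiles, stringsAsFactors = FALSE,
                    check.names = FALSE)
  attr(out, "loci") <- colnames(profiles)
  class(out) <- c("isolate_table", "data.frame")
  out
}

#' Locus names of an isolate or sequence-type table
#' @param x an `isolate_table` or `sequence_type_table`.
#' @return character vector of locus names in profile order.
#' @export
loci_of <- function(x) attr(x, "loci")

#' Extract the allelic-profile matrix
#' @param x an `isolate_table` or `sequence_type_table`.
#' @return integer matrix, rows = isolates (or STs), columns = loci.
#' @export
profile_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[, loci_of(x), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- if (inherits(x, "sequence_type_table"))
    as.character(x$st) else x$isolate_id
  m
}

#' @export
print.isolate_table <- function(x, ...) {
  cat(sprintf("Isolate table: %d isolates, %d loci (%s)\n",
              nrow(x), length(loci_of(x)),
              paste(loci_of(x), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Read an MLST-style allelic profile table
#'
#' Expects a tab-separated file with header columns `isolate_id`, `spring`,
#' `year`, followed by one integer allele column per locus; locus order is
#' taken from the header.  Lines starting with `#` are comments.
#'
#' @param path file path.
#' @return an [isolate_table()].
#' @export
read_profile_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("isolate_id", "spring", "year")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("profile table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  loci <- setdiff(names(df), need)
  if (length(loci) == 0) stop("profile table has no locus columns")
  if (nrow(df) == 0) {
    warning("profile table ", path, " has no isolates")
    return(isolate_table(character(), character(), integer(),
                         matrix(integer(), 0, length(loci),
                                dimnames = list(NULL, loci))))
  }
  if (anyDuplicated(df$isolate_id)) {
    bad <- which(duplicated(df$isolate_id))[1]
    stop("duplicate isolate_id at line ", bad + 1, ": ", df$isolate_id[bad])
  }
  raw <- as.matrix(df[, loci, drop = FALSE])
  suppressWarnings(prof <- matrix(as.integer(raw), nrow(raw), ncol(raw),
                                  dimnames = dimnames(raw)))
  bad <- which(is.na(prof) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("non-integer allele index '", raw[bad[1, 1], bad[1, 2]],
         "' at line ", bad[1, 1] + 1, " (locus ", loci[bad[1, 2]], ")")
  if (anyNA(prof))
    stop("missing allele index at line ",
         which(rowSums(is.na(prof)) > 0)[1] + 1)
  if (any(prof < 1))
    stop("allele index < 1 at line ",
         which(rowSums(prof < 1) > 0)[1] + 1)
  isolate_table(df$isolate_id, df$spring, df$year, prof)
}

#' Write an allelic profile table to TSV
#' @param x an `isolate_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Group isolates into sequence types
#'
#' Isolates sharing an identical allelic profile across all loci form one
#' sequence type (ST).  STs are numbered 1..n in order of first appearance.
#'
#' @param x an `isolate_table`.
#' @return a data.frame of class `"sequence_type_table"` with columns `st`,
#'   one allele column per locus, `count`, `isolate_ids` (semicolon-joined)
#'   and `springs` (semicolon-joined distinct spring labels).
#' @export
assign_sequence_types <- function(x) {
  prof <- profile_matrix(x)
  key <- apply(prof, 1, paste, collapse = ";")
  st <- match(key, unique(key))
  idx <- split(seq_len(nrow(x)), st)
  first <- vapply(idx, `[`, integer(1), 1)
  out <- data.frame(st = seq_along(idx),
                    prof[first, , drop = FALSE],
                    count = lengths(idx),
                    isolate_ids = vapply(idx, function(i)
                      paste(x$isolate_id[i], collapse = ";"), character(1)),
                    springs = vapply(idx, function(i)
                      paste(sort(unique(x$spring[i])), collapse = ";"),
                      character(1)),
                    stringsAsFactors = FALSE, check.names = FALSE,
                    row.names = NULL)
  attr(out, "loci") <- loci_of(x)
  class(out) <- c("sequence_type_table", "data.frame")
  out
}

#' Expand a sequence-type table back to one row per isolate
#'
#' Inverse of [assign_sequence_types()] up to isolate order.  Spring labels
#' are recovered from the stored isolate membership where available.
#'
#' @param stt a `sequence_type_table`.
#' @param isolates optional original `isolate_table` to recover labels from.
#' @return an `isolate_table`.
#' @export
expand_sequence_types <- function(stt, isolates = NULL) {
  if (!is.null(isolates)) {
    ids <- unlist(strsplit(stt$isolate_ids, ";", fixed = TRUE))
    keep <- isolates[match(ids, isolates$isolate_id), ]
    return(isolate_table(keep$isolate_id, keep$spring, keep$year,
                         profile_matrix(keep)))
  }
  rep_i <- rep(seq_len(nrow(stt)), stt$count)
  prof <- profile_matrix(stt)[rep_i, , drop = FALSE]
  ids <- unlist(lapply(seq_len(nrow(stt)), function(i)
    paste0("ST", stt$st[i], "_", seq_len(stt$count[i]))))
  spring <- rep(vapply(strsplit(stt$springs, ";", fixed = TRUE),
                       `[`, character(1), 1), stt$count)
  isolate_table(ids, spring, NA_integer_, prof)
}

#' @export
print.sequence_type_table <- function(x, ...) {
  cat(sprintf("Sequence types: %d STs, %d isolates, %d loci\n",
              nrow(x), sum(x$count), length(loci_of(x))))
  print.data.frame(utils::head(as.data.frame(x)[, c("st", loci_of(x),
                                                    "count", "springs")], 10))
  invisible(x)
}
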