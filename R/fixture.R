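#' Load the packaged Thermoanaerobacter uzonensis MLSA dataset
#'
#' The fixture encodes the published Uzon Caldera hot-spring survey: 49
#' sequence types over eight protein-coding loci (gyrB, lepA, leuS, pyrG,
#' recA, recG, rplB, rpoB), expanded to the 106 genotyped isolates with
#' their spring (and, where recorded, year) of origin, plus the sparse
#' nucleotide distances between the variant alleles of the 11
#' single-locus-variant pairs.  Two multi-isolate STs from Thermophilny
#' span the 2005 and 2006 samplings without a published per-year split;
#' their isolates carry `year = NA`, so per-year Thermophilny subsets
#' cannot be reconstructed exactly (whole-spring subsets can).
#'
#' @return list with components:
#'   \describe{
#'     \item{isolates}{an [isolate_table()] of 106 isolates.}
#'     \item{sequence_types}{the matching `sequence_type_table` (49 STs).}
#'     \item{catalogs}{named list of distance-only [allele_catalog()]
#'       objects for loci with known variant-allele distances.}
#'     \item{loci}{a [locus_table()] with the aligned fragment lengths.}
#'   }
#' @export
load_uzon_fixture <- function() {
  dir <- system.file("extdata", package = "mlsapop", mustWork = TRUE)
  st_raw <- utils::read.delim(file.path(dir, "uzon_sequence_types.tsv"),
                              comment.char = "#", stringsAsFactors = FALSE,
                              check.names = FALSE)
  loci_df <- utils::read.delim(file.path(dir, "uzon_loci.tsv"),
                               comment.char = "#",
                               stringsAsFactors = FALSE)
  loci <- locus_table(loci_df$name, loci_df$aligned_length,
                      loci_df$frame_offset, loci_df$genetic_code_id)
  locus_names <- loci$name

  # expand each ST by its provenance entries (spring:year:count | ...)
  rows <- list()
  for (i in seq_len(nrow(st_raw))) {
    prov <- strsplit(st_raw$provenance[i], "|", fixed = TRUE)[[1]]
    parts <- strsplit(prov, ":", fixed = TRUE)
    k <- 0
    for (p in parts) {
      cnt <- as.integer(p[3])
      yr <- suppressWarnings(as.integer(p[2]))
      for (r in seq_len(cnt)) {
        k <- k + 1
        rows[[length(rows) + 1]] <-
          list(id = sprintf("ST%02d_%02d", st_raw$st[i], k),
               spring = p[1], year = yr, st = st_raw$st[i])
      }
    }
    stopifnot(k == st_raw$count[i])
  }
  ids <- vapply(rows, `[[`, character(1), "id")
  spring <- vapply(rows, `[[`, character(1), "spring")
  year <- vapply(rows, function(r) as.integer(r$year), integer(1))
  st_of <- vapply(rows, `[[`, double(1), "st")
  prof <- as.matrix(st_raw[match(st_of, st_raw$st), locus_names])
  rownames(prof) <- NULL
  isolates <- isolate_table(ids, spring, year, prof)

  dist_df <- utils::read.delim(file.path(dir, "uzon_allele_distances.tsv"),
                               comment.char = "#", stringsAsFactors = FALSE)
  catalogs <- lapply(split(dist_df, dist_df$locus), function(dd)
    allele_catalog(dd$locus[1], sequences = NULL,
                   distances = dd[, c("allele_a", "allele_b", "nt_diff")]))

  list(isolates = isolates,
       sequence_types = assign_sequence_types(isolates),
       catalogs = catalogs,
       loci = loci)
}
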