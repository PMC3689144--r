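#' Configuration for the forward-time MLSA simulator
#'
#' Describes a haploid island-model population: `n_demes` demes (hot
#' springs) of constant size `deme_size`, evolved for `generations`
#' Wright-Fisher generations over `n_loci` loci of `locus_length` nt.
#' Events are applied each generation in a fixed, documented order:
#' resampling, then migration, then recombination, then mutation.
#'
#' @param n_demes number of demes.
#' @param deme_size haploid individuals per deme.
#' @param generations number of generations.
#' @param n_loci number of typed loci.
#' @param locus_length aligned locus length (nt).
#' @param mu per-locus, per-individual, per-generation probability of a new
#'   allele (infinite-alleles; realized as k random substitutions with
#'   k ~ 1 + Geometric(1/2) on the parent allele's sequence).
#' @param r per-locus, per-individual probability of replacing the allele
#'   with that of a random same-deme individual (gene-conversion-style
#'   recombination).
#' @param m per-individual probability of being replaced by a migrant copied
#'   from a random other deme.
#' @param clone_boost sampling-time expansion factor for one sequence type:
#'   the modal sampled ST's isolate count is multiplied by this factor,
#'   emulating an epidemic clone (1 = none).
#' @param sample_size isolates sampled per deme (without replacement).
#' @param seed RNG seed; the same seed yields byte-identical output.
#' @return object of class `"simulation_config"`.
#' @export
simulation_config <- function(n_demes = 1L, deme_size = 60L,
                              generations = 120L, n_loci = 8L,
                              locus_length = 400L, mu = 0.01, r = 0,
                              m = 0, clone_boost = 1L, sample_size = 25L,
                              seed = 1L) {
  for (p in c(mu = mu, r = r, m = m))
    if (p < 0 || p > 1) stop("probabilities must be in [0, 1]")
  sizes <- c(n_demes, deme_size, generations, n_loci, locus_length,
             clone_boost, sample_size)
  if (any(sizes < 1)) stop("all sizes must be >= 1")
  if (sample_size > deme_size) stop("sample_size exceeds deme_size")
  if (n_demes < 2 && m > 0) stop("migration requires at least two demes")
  structure(list(n_demes = as.integer(n_demes),
                 deme_size = as.integer(deme_size),
                 generations = as.integer(generations),
                 n_loci = as.integer(n_loci),
                 locus_length = as.integer(locus_length),
                 mu = mu, r = r, m = m,
                 clone_boost = as.integer(clone_boost),
                 sample_size = as.integer(sample_size),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate an MLSA dataset from a multi-deme haploid population
#'
#' Forward-time Wright-Fisher simulation under the infinite-alleles model
#' realized on sequences: every mutation event creates a previously unseen
#' allele string, so allele calling, nucleotide distances and diversity
#' statistics are all exercised end-to-end on the output.  Sampled isolates
#' are labelled by their deme (`deme_1`, ...) in the `spring` field.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory; when given, per-locus FASTA
#'   alignments, a profile TSV and a JSON run manifest are written there.
#' @return list with components `isolates` (an [isolate_table()]),
#'   `catalogs` (per-locus [allele_catalog()] from [call_alleles()]),
#'   `alignments` (per-locus named sequence vectors), `truth` (realized
#'   event counts, per-deme final allele frequencies and the ground-truth
#'   distinct-allele count among sampled isolates) and `config`.
#' @export
simulate_mlsa <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  nd <- config$n_demes; N <- nd * config$deme_size
  L <- config$n_loci
  deme <- rep(seq_len(nd), each = config$deme_size)
  bases <- c("A", "C", "G", "T")

  # allele registries: per locus, vector of allele sequences (index = id)
  registry <- lapply(seq_len(L), function(j)
    paste(sample(bases, config$locus_length, replace = TRUE),
          collapse = ""))
  pop <- matrix(1L, N, L)
  ev <- c(mutation = 0L, recombination = 0L, migration = 0L)

  mutate_seq <- function(seq, existing) {
    repeat {
      k <- 1L + stats::rgeom(1, 0.5)
      s <- strsplit(seq, "", fixed = TRUE)[[1]]
      pos <- sample.int(length(s), min(k, length(s)))
      s[pos] <- vapply(s[pos], function(b)
        sample(setdiff(bases, b), 1), character(1))
      out <- paste(s, collapse = "")
      if (!(out %in% existing)) return(out)
    }
  }

  for (g in seq_len(config$generations)) {
    # Wright-Fisher resampling within each deme
    parent <- unlist(lapply(seq_len(nd), function(k) {
      rows <- which(deme == k)
      sample(rows, length(rows), replace = TRUE)
    }))
    pop <- pop[parent, , drop = FALSE]
    # migration: whole-individual replacement from a random other deme
    if (config$m > 0 && nd > 1) {
      mig <- which(stats::runif(N) < config$m)
      if (length(mig)) {
        snapshot <- pop
        for (i in mig) {
          src_deme <- sample(setdiff(seq_len(nd), deme[i]), 1)
          donor <- sample(which(deme == src_deme), 1)
          pop[i, ] <- snapshot[donor, ]
        }
        ev["migration"] <- ev["migration"] + length(mig)
      }
    }
    # recombination: per-locus allele replacement from a same-deme donor
    if (config$r > 0) {
      hits <- which(matrix(stats::runif(N * L) < config$r, N, L),
                    arr.ind = TRUE)
      if (nrow(hits)) {
        snapshot <- pop
        for (h in seq_len(nrow(hits))) {
          i <- hits[h, 1]; j <- hits[h, 2]
          donor <- sample(which(deme == deme[i]), 1)
          pop[i, j] <- snapshot[donor, j]
        }
        ev["recombination"] <- ev["recombination"] + nrow(hits)
      }
    }
    # mutation: infinite alleles, new sequence string per event
    hits <- which(matrix(stats::runif(N * L) < config$mu, N, L),
                  arr.ind = TRUE)
    if (nrow(hits)) {
      for (h in seq_len(nrow(hits))) {
        i <- hits[h, 1]; j <- hits[h, 2]
        new_seq <- mutate_seq(registry[[j]][pop[i, j]], registry[[j]])
        registry[[j]] <- c(registry[[j]], new_seq)
        pop[i, j] <- length(registry[[j]])
      }
      ev["mutation"] <- ev["mutation"] + nrow(hits)
    }
  }

  # final allele frequencies per deme per locus (internal ids)
  final_freqs <- lapply(seq_len(nd), function(k)
    lapply(seq_len(L), function(j) {
      tab <- table(pop[deme == k, j])
      as.numeric(tab) / sum(tab)
    }))

  # sample isolates per deme, without replacement
  picked <- unlist(lapply(seq_len(nd), function(k)
    sample(which(deme == k), config$sample_size)))
  samp <- pop[picked, , drop = FALSE]
  samp_deme <- deme[picked]

  # clonal expansion at sampling time: multiply the modal ST's count
  if (config$clone_boost > 1L) {
    key <- apply(samp, 1, paste, collapse = ";")
    modal <- names(sort(table(key), decreasing = TRUE))[1]
    idx <- which(key == modal)
    extra <- rep(idx[1], (config$clone_boost - 1L) * length(idx))
    samp <- rbind(samp, samp[extra, , drop = FALSE])
    samp_deme <- c(samp_deme, samp_deme[extra])
  }
  ids <- sprintf("sim_%03d", seq_len(nrow(samp)))

  locus_names <- sprintf("locus_%02d", seq_len(L))
  alignments <- lapply(seq_len(L), function(j) {
    s <- registry[[j]][samp[, j]]
    names(s) <- ids
    attr(s, "locus") <- locus_names[j]
    s
  })
  names(alignments) <- locus_names

  called <- lapply(alignments, call_alleles)
  prof <- do.call(cbind, lapply(called, `[[`, "indices"))
  colnames(prof) <- locus_names
  isolates <- isolate_table(ids, paste0("deme_", samp_deme), NA_integer_,
                            prof)
  catalogs <- lapply(called, `[[`, "catalog")

  truth <- list(events = as.list(ev),
                distinct_alleles_sampled =
                  apply(samp, 2, function(a) length(unique(a))),
                registry_sizes = vapply(registry, length, integer(1)),
                final_allele_freqs = final_freqs)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (j in seq_len(L))
      write_locus_alignment(alignments[[j]],
                            file.path(out_dir,
                                      paste0(locus_names[j], ".fasta")))
    write_profile_table(isolates, file.path(out_dir, "profiles.tsv"))
    write_run_manifest("simulate", parameters = unclass(config),
                       seed = config$seed,
                       inputs = character(),
                       path = file.path(out_dir, "manifest.json"))
  }

  list(isolates = isolates, catalogs = catalogs, alignments = alignments,
       truth = truth, config = config)
}

#' Canned simulation regimes
#'
#' Four ready-made configurations spanning the qualitative population
#' structures the analysis distinguishes:
#' \describe{
#'   \item{clonal}{no recombination; strong multilocus linkage is expected
#'     (I_SA > 0, significant).}
#'   \item{panmictic_recombining}{one deme with frequent allele exchange;
#'     I_SA is expected near 0.}
#'   \item{epidemic}{recombining background plus a sampling-time clonal
#'     expansion; the isolate-level I_SA exceeds the ST-level value.}
#'   \item{island_low_migration}{several demes, rare migration; marked
#'     between-deme differentiation (high F_ST), decreasing as migration
#'     increases.}
#' }
#'
#' @param seed RNG seed installed into every regime.
#' @return named list of [simulation_config()] objects.
#' @export
make_regimes <- function(seed = 1L) {
  list(
    clonal = simulation_config(n_demes = 1, deme_size = 60,
                               generations = 120, n_loci = 8,
                               locus_length = 300, mu = 0.01, r = 0, m = 0,
                               sample_size = 25, seed = seed),
    panmictic_recombining = simulation_config(n_demes = 1, deme_size = 60,
                                              generations = 120,
                                              n_loci = 8,
                                              locus_length = 300,
                                              mu = 0.01, r = 0.5, m = 0,
                                              sample_size = 25,
                                              seed = seed),
    epidemic = simulation_config(n_demes = 1, deme_size = 60,
                                 generations = 120, n_loci = 8,
                                 locus_length = 300, mu = 0.01, r = 0.5,
                                 m = 0, clone_boost = 6, sample_size = 25,
                                 seed = seed),
    island_low_migration = simulation_config(n_demes = 4, deme_size = 40,
                                             generations = 120,
                                             n_loci = 8,
                                             locus_length = 300,
                                             mu = 0.01, r = 0.1, m = 0.01,
                                             sample_size = 15,
                                             seed = seed))
}
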