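test_that("pairwise differences match brute force with pairwise deletion", {
  expect_equal(as.vector(pairwise_nt_differences(c(a = "ACGT",
                                                   b = "ACGT"))), 0)
  d <- pairwise_nt_differences(c(a = "AAAA", b = "TTAA"))
  expect_equal(as.vector(d), 2)
  dp <- pairwise_nt_differences(c(a = "AAAA", b = "TTAA"),
                                p_distance = TRUE)
  expect_equal(as.vector(dp), 0.5)
  # missing sites excluded pair by pair
  d2 <- pairwise_nt_differences(c(a = "AN-T", b = "TNTT"))
  expect_equal(as.vector(d2), 1)
  al <- random_alignment(8, 50, missing_rate = 0.04, seed = 31)
  dm <- as.matrix(pairwise_nt_differences(al))
  m <- do.call(rbind, strsplit(unname(al), ""))
  for (i in 1:7) for (j in (i + 1):8) {
    ok <- !(m[i, ] %in% c("N", "-")) & !(m[j, ] %in% c("N", "-"))
    expect_equal(dm[i, j], sum(m[i, ok] != m[j, ok]))
  }
})

test_that("AMOVA F_ST hits the closed-form anchors", {
  # two demes each fixed for its own haplotype: all variance is between
  seqs <- c(setNames(rep("AAAAA", 10), paste0("a", 1:10)),
            setNames(rep("TTTTT", 10), paste0("b", 1:10)))
  d <- pairwise_nt_differences(seqs)
  part <- rep(c("A", "B"), each = 10)
  expect_equal(pairwise_fst(d, part, "A", "B"), 1)
  # both demes monomorphic for the same haplotype: no variance at all
  seqs0 <- setNames(rep("AAAAA", 20), paste0("s", 1:20))
  expect_equal(pairwise_fst(pairwise_nt_differences(seqs0), part,
                            "A", "B"), 0)
  # subsets below two members are undefined
  expect_true(is.na(pairwise_fst(d, c("A", rep("B", 19)), "A", "B")))
})

test_that("balanced two-deme AMOVA equals the classical pi-based estimator", {
  # with equal deme sizes the AMOVA df corrections cancel and
  # F_ST = (pi_between - pi_within) / pi_between exactly
  for (s in 1:5) {
    set.seed(s + 40)
    al <- c(random_alignment(8, 60, seed = s),
            random_alignment(8, 60, seed = s + 100))
    names(al) <- sprintf("x%02d", 1:16)
    part <- rep(c("p", "q"), each = 8)
    dm <- as.matrix(pairwise_nt_differences(al))
    within <- c(dm[1:8, 1:8][upper.tri(diag(8))],
                dm[9:16, 9:16][upper.tri(diag(8))])
    between <- as.vector(dm[1:8, 9:16])
    pw <- mean(within); pb <- mean(between)
    expect_equal(pairwise_fst(stats::as.dist(dm), part, "p", "q"),
                 (pb - pw) / pb, tolerance = 1e-9)
  }
  # duplicated heterogeneous multisets: the unbiased estimator's known
  # small-sample value is exactly -1/(n-1), not zero
  base <- random_alignment(6, 40, seed = 77)
  dup <- c(base, base)
  names(dup) <- sprintf("d%02d", 1:12)
  expect_equal(pairwise_fst(pairwise_nt_differences(dup),
                            rep(c("u", "v"), each = 6), "u", "v"),
               -1 / 5, tolerance = 1e-9)
})

test_that("F_ST falls with migration across island-model simulations", {
  mean_fst <- function(cfg) {
    sim <- simulate_mlsa(cfg)
    d <- pairwise_nt_differences(concatenate_loci(sim$isolates,
                                                  sim$catalogs))
    mean(fst_matrix(d, sim$isolates$spring)$fst, na.rm = TRUE)
  }
  res <- sapply(1:6, function(s) {
    base <- make_regimes(seed = s)$island_low_migration
    sapply(c(0, 0.01, 0.1), function(mm) {
      cfg <- base
      cfg$m <- mm
      mean_fst(cfg)
    })
  })
  avg <- rowMeans(res)
  expect_gt(avg[1], avg[2])
  expect_gt(avg[2], avg[3])
})

test_that("F_ST permutation test is calibrated and deterministic", {
  # strongly diverged demes: significant
  seqs <- c(setNames(rep(c("AAAAAAAA", "AAAAAAAT"), 5), paste0("a", 1:10)),
            setNames(rep(c("TTTTTTTT", "TTTTTTTA"), 5), paste0("b", 1:10)))
  d <- pairwise_nt_differences(seqs)
  part <- rep(c("A", "B"), each = 10)
  r <- fst_significance(d, part, "A", "B", permutations = 999, seed = 5)
  expect_lte(r$P, 0.01)
  r2 <- fst_significance(d, part, "A", "B", permutations = 999, seed = 5)
  expect_identical(r$P, r2$P)
  # single shared haplotype: F = 0 and P = 1
  seqs0 <- setNames(rep("ACGT", 12), paste0("s", 1:12))
  r0 <- fst_significance(pairwise_nt_differences(seqs0),
                         rep(c("A", "B"), each = 6), "A", "B",
                         permutations = 199, seed = 1)
  expect_equal(r0$F_ST, 0)
  expect_equal(r0$P, 1)
  # panmixia: P values super-uniform (empirical CDF never far above x)
  set.seed(8)
  pool <- random_alignment(16, 40, seed = 8)
  pvals <- vapply(1:120, function(k) {
    al <- pool[sample(16)]
    names(al) <- sprintf("m%02d", 1:16)
    fst_significance(pairwise_nt_differences(al),
                     rep(c("A", "B"), each = 8), "A", "B",
                     permutations = 100, seed = k)$P
  }, numeric(1))
  for (x in c(0.05, 0.1, 0.25))
    expect_lte(mean(pvals <= x), x + 3 * sqrt(x * (1 - x) / 120))
})

test_that("Mantel test anchors: self-correlation, degenerate input, vegan", {
  set.seed(9)
  m <- as.matrix(dist(matrix(rnorm(24), 12)))
  dimnames(m) <- list(sprintf("s%d", 1:12), sprintf("s%d", 1:12))
  self <- mantel_spearman(m, m, permutations = 199, seed = 3)
  expect_equal(self$rho, 1)
  # constant matrix: undefined with warning
  const <- m
  const[] <- 1
  diag(const) <- 0
  expect_warning(r <- mantel_spearman(m, const, permutations = 99,
                                      seed = 1), "constant")
  expect_true(is.na(r$rho))
  expect_error(mantel_spearman(m, m[1:5, 1:5]), "differ in size")
  m2 <- m
  dimnames(m2) <- list(sprintf("t%d", 1:12), sprintf("t%d", 1:12))
  expect_error(mantel_spearman(m, m2), "labels")
  # rho agrees with vegan's Spearman Mantel statistic
  skip_if_not_installed("vegan")
  g <- as.matrix(dist(matrix(rnorm(24), 12)))
  dimnames(g) <- dimnames(m)
  ours <- mantel_spearman(m, g, permutations = 99, seed = 2)$rho
  ref <- vegan::mantel(as.dist(m), as.dist(g), method = "spearman",
                       permutations = 0)$statistic
  expect_equal(ours, unname(ref), tolerance = 1e-12)
})

test_that("Mantel significance is uniform under independence", {
  set.seed(10)
  sig <- vapply(1:200, function(k) {
    a <- as.matrix(dist(matrix(rnorm(20), 10)))
    b <- as.matrix(dist(matrix(rnorm(20), 10)))
    mantel_spearman(a, b, permutations = 199, seed = k)$significance_percent
  }, numeric(1))
  expect_gt(median(sig), 35)
  expect_lt(median(sig), 65)
})
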