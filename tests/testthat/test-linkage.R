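test_that("mismatch distribution counts differing loci per pair", {
  expect_equal(mismatch_distribution(rbind(c(1, 1), c(1, 1))), 0L)
  expect_equal(mismatch_distribution(rbind(c(1, 1), c(2, 2))), 2L)
  # hand-enumerated 7-isolate spring subset: 6 identical pairs, 3 pairs
  # differing at one locus, 12 pairs differing at seven loci
  it <- uzon$isolates
  puls <- profile_matrix(it[it$spring == "Pulsating Spring", ,
                            drop = FALSE])
  K <- mismatch_distribution(puls)
  expect_length(K, choose(7, 2))
  expect_equal(as.vector(table(K)), c(6, 3, 12))
  expect_equal(sort(unique(K)), c(0L, 1L, 7L))
  # mean(K) equals a brute-force pair loop exactly
  bf <- mean(apply(combn(nrow(puls), 2), 2, function(ix)
    sum(puls[ix[1], ] != puls[ix[2], ])))
  expect_equal(mean(K), bf)
  expect_error(mismatch_distribution(matrix(1, 1, 2)), "two profiles")
})

test_that("I_SA reproduces the published values under the locked conventions", {
  it <- uzon$isolates
  stt <- uzon$sequence_types
  expect_equal(round(i_sa(it)$I_SA, 3), 0.086)
  expect_equal(round(i_sa(profile_matrix(stt))$I_SA, 3), 0.028)
  puls <- profile_matrix(it[it$spring == "Pulsating Spring", ,
                            drop = FALSE])
  r <- i_sa(puls)
  expect_equal(round(r$I_SA, 3), 0.841)
  expect_equal(r$I_A, r$V_D / r$V_E - 1)
  expect_equal(r$I_SA, r$I_A / (r$l - 1))
})

test_that("rejected variance conventions are detectably different", {
  # regression lock: sample-variance V_D with unbiased h_j is the only
  # convention pair reproducing the 7-isolate worked value of 0.841; the
  # three biased alternatives give 0.805, 0.794 and 0.760 and must fail
  # if ever reintroduced.
  it <- uzon$isolates
  puls <- profile_matrix(it[it$spring == "Pulsating Spring", ,
                            drop = FALSE])
  alt_isa <- function(M, vd_sample, h_unbiased) {
    n <- nrow(M); l <- ncol(M)
    K <- apply(combn(n, 2), 2, function(ix) sum(M[ix[1], ] != M[ix[2], ]))
    np <- length(K)
    VD <- sum((K - mean(K))^2) / if (vd_sample) np - 1 else np
    h <- apply(M, 2, function(a) {
      p <- as.numeric(table(a)) / n
      hh <- 1 - sum(p^2)
      if (h_unbiased) hh * n / (n - 1) else hh
    })
    VE <- sum(h * (1 - h))
    (VD / VE - 1) / (l - 1)
  }
  expect_equal(round(alt_isa(puls, TRUE, TRUE), 3), 0.841)
  expect_equal(round(alt_isa(puls, TRUE, FALSE), 3), 0.805)
  expect_equal(round(alt_isa(puls, FALSE, TRUE), 3), 0.794)
  expect_equal(round(alt_isa(puls, FALSE, FALSE), 3), 0.760)
  # the implementation agrees with the locked convention to full precision
  expect_equal(i_sa(puls)$I_SA, alt_isa(puls, TRUE, TRUE),
               tolerance = 1e-12)
  for (bad in list(c(TRUE, FALSE), c(FALSE, TRUE), c(FALSE, FALSE)))
    expect_false(isTRUE(all.equal(i_sa(puls)$I_SA,
                                  alt_isa(puls, bad[1], bad[2]),
                                  tolerance = 1e-4)))
})

test_that("I_SA is invariant to allele relabeling and isolate order", {
  prof <- random_profiles(15, 5, n_alleles = 4, seed = 9)
  base <- i_sa(prof)$I_SA
  relab <- prof
  for (j in seq_len(ncol(prof))) {
    map <- sample(100, 4)
    relab[, j] <- map[prof[, j]]
  }
  expect_equal(i_sa(relab)$I_SA, base, tolerance = 1e-12)
  expect_equal(i_sa(prof[sample(15), ])$I_SA, base, tolerance = 1e-12)
})

test_that("degenerate inputs yield NA with a warning", {
  mono <- matrix(1L, 5, 4, dimnames = list(NULL, letters[1:4]))
  expect_warning(r <- i_sa(mono), "monomorphic")
  expect_true(is.na(r$I_SA))
  # below the minimum sample size the result is NA without computation
  expect_true(is.na(i_sa(random_profiles(2, 4), min_n = 3)$I_SA))
  # and configurable: n = 3 is computed when min_n allows it
  expect_false(is.na(i_sa(random_profiles(3, 4, seed = 4),
                          min_n = 3)$I_SA))
})

test_that("permutation null is centred at zero and P values behave", {
  prof <- random_profiles(20, 6, n_alleles = 5, seed = 13)
  sig <- i_sa_significance(prof, resamples = 1000, seed = 99)
  se <- sd(sig$null) / sqrt(length(sig$null))
  expect_lt(abs(mean(sig$null)), 3 * se + 1e-3)
  # determinism under seed
  sig2 <- i_sa_significance(prof, resamples = 1000, seed = 99)
  expect_identical(sig$P, sig2$P)
  expect_identical(sig$null, sig2$null)
  # strongly linked data: small P
  it <- uzon$isolates
  puls <- profile_matrix(it[it$spring == "Pulsating Spring", ,
                            drop = FALSE])
  expect_lte(i_sa_significance(puls, resamples = 999, seed = 1)$P, 0.01)
  # profiles identical at every locus across isolates: every permutation
  # ties, so the index is undefined (monomorphic) -> NA propagates
  mono <- matrix(2L, 6, 3, dimnames = list(NULL, letters[1:3]))
  expect_warning(s <- i_sa_significance(mono, resamples = 100, seed = 1))
  expect_true(is.na(s$P))
  expect_error(i_sa_significance(prof, resamples = 10), ">= 100")
})

test_that("epidemic contrast drops from isolate level to ST level", {
  ec <- epidemic_contrast(uzon$isolates)
  expect_equal(round(ec$isolates$I_SA, 3), 0.086)
  expect_equal(round(ec$unique_sts$I_SA, 3), 0.028)
  expect_gt(ec$isolates$I_SA, ec$unique_sts$I_SA)
  # when every isolate is already a distinct ST the two results coincide
  prof <- random_profiles(12, 6, n_alleles = 12, seed = 21)
  prof <- prof[!duplicated(apply(prof, 1, paste, collapse = ";")), ]
  it <- isolate_table(sprintf("i%d", seq_len(nrow(prof))), "s", 2006L,
                      prof)
  ec2 <- epidemic_contrast(it)
  expect_equal(ec2$isolates$I_SA, ec2$unique_sts$I_SA)
})
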