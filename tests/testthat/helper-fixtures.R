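# Shared helpers: tiny generated fixtures and independent brute-force
# oracles.  The oracles deliberately use naive loops so they stay
# independent of the vectorized package code they check.

random_alignment <- function(n, len, missing_rate = 0, seed = 1) {
  set.seed(seed)
  chars <- c("A", "C", "G", "T")
  seqs <- replicate(n, {
    s <- sample(chars, len, replace = TRUE)
    if (missing_rate > 0) {
      miss <- runif(len) < missing_rate
      s[miss] <- sample(c("N", "-"), sum(miss), replace = TRUE)
    }
    paste(s, collapse = "")
  })
  names(seqs) <- sprintf("seq%02d", seq_len(n))
  seqs
}

random_profiles <- function(n, l, n_alleles = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(sample.int(n_alleles, n * l, replace = TRUE), n, l)
  colnames(m) <- sprintf("loc%d", seq_len(l))
  m
}

# column-by-column recount of segregating sites
bf_variable_sites <- function(seqs) {
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  cnt <- 0
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col != "N" & col != "-"]
    if (length(unique(col)) >= 2) cnt <- cnt + 1
  }
  cnt
}

# naive O(n^2 L) pair loop for pi
bf_pi <- function(seqs) {
  n <- length(seqs)
  m <- do.call(rbind, strsplit(unname(seqs), ""))
  acc <- 0
  np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    diffs <- 0; comp <- 0
    for (k in seq_len(ncol(m))) {
      a <- m[i, k]; b <- m[j, k]
      if (a %in% c("N", "-") || b %in% c("N", "-")) next
      comp <- comp + 1
      if (a != b) diffs <- diffs + 1
    }
    acc <- acc + diffs / comp
    np <- np + 1
  }
  acc / np
}

# brute-force SLV scan over an ST profile matrix
bf_slvs <- function(prof) {
  out <- NULL
  n <- nrow(prof)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    nd <- sum(prof[i, ] != prof[j, ])
    if (nd == 1) out <- rbind(out, c(i, j))
  }
  out
}

# the fixture, loaded once per test file
uzon <- load_uzon_fixture()
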