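# Independent brute-force oracles used to check the package implementations.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rc_oracle <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A", N = "N")
  paste(rev(unname(comp[strsplit(toupper(s), "")[[1]]])), collapse = "")
}

# every window of the UTR compared against the site string
oracle_scan_starts <- function(utr, site) {
  k <- nchar(site)
  n <- nchar(utr)
  if (n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  starts[substring(utr, starts, starts + k - 1L) == site]
}

# exact two-sided Mann-Whitney p by enumerating all group labelings
oracle_mwu_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  list(U = u_obs, p = min(1, p))
}

# direct summation of the hypergeometric upper tail
oracle_hyper <- function(k, set_size, n_targets, universe) {
  hi <- min(set_size, n_targets)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(j) {
    choose(n_targets, j) * choose(universe - n_targets, set_size - j) /
      choose(universe, set_size)
  }, numeric(1)))
}

# exhaustive (start, len) search for the longest mature stretch whose
# reverse complement is a substring of the oligo
oracle_verify <- function(oligo, mature) {
  L <- nchar(mature); W <- nchar(oligo)
  best <- c(start = NA_integer_, len = 0L)
  for (len in seq_len(min(L, W))) {
    for (start in seq_len(L - len + 1L)) {
      if (grepl(rc_oracle(substr(mature, start, start + len - 1L)),
                oligo, fixed = TRUE) && len > best["len"]) {
        best <- c(start = start, len = len)
      }
    }
  }
  best
}

# build a nuc_sequence list from a named character vector
as_family <- function(x, alphabet = "DNA") {
  Map(function(id, s) nuc_sequence(id, s, alphabet), names(x), x)
}
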