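# Small fixtures built in code; everything derives from seeded simulation.

tiny_panel <- function() {
  probe_annotation(
    probe = c("CPA3", "IL5", "GENE_X", "HK1", "HK2",
              "POS_A(32)", "POS_B(8)", "NEG_A", "NEG_B"),
    class = c(rep("Endogenous", 3), rep("Housekeeping", 2),
              rep("Positive", 2), rep("Negative", 2)),
    accession = sprintf("ACC_%d", 1:9),
    concentration = c(rep(NA, 5), 32, 8, NA, NA)
  )
}

tiny_counts <- function(n_lanes = 4, seed = 7) {
  set.seed(seed)
  ann <- tiny_panel()
  lambda <- c(CPA3 = 300, IL5 = 80, GENE_X = 1500, HK1 = 400, HK2 = 600,
              `POS_A(32)` = 2000, `POS_B(8)` = 500, NEG_A = 8, NEG_B = 8)
  m <- vapply(seq_len(n_lanes), function(i) rpois(nrow(ann), lambda[ann$probe]),
              integer(nrow(ann)))
  dimnames(m) <- list(ann$probe, sprintf("L%02d", seq_len(n_lanes)))
  raw_count_set(m, ann)
}

default_cohort <- function(seed = 101, ...) {
  cfg <- sim_config(seed = seed, ...)
  sim <- simulate_counts(cfg)
  meta <- simulate_metadata(cfg)
  norm <- normalize_lanes(sim$counts)
  list(cfg = cfg, sim = sim, meta = meta, norm = norm,
       group = factor(sim$truth$group,
                      levels = c("Control", "EoE_no_FI", "EoE_FI")))
}

# Exact-rational hypergeometric mass via prime factorization of factorials:
# exponent bookkeeping is exact integer arithmetic, with a single final
# float evaluation, so it is valid far beyond where binomial products
# overflow 2^53.
prime_sieve <- function(n) {
  if (n < 2) return(integer(0))
  is_p <- rep(TRUE, n); is_p[1] <- FALSE
  for (i in 2:floor(sqrt(n))) if (is_p[i]) is_p[seq(i * i, n, by = i)] <- FALSE
  which(is_p)
}

factorial_exponents <- function(n, primes) {
  vapply(primes, function(p) {
    e <- 0; q <- p
    while (q <= n) { e <- e + n %/% q; q <- q * p }
    e
  }, numeric(1))
}

fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d; N <- sum(tab)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  primes <- prime_sieve(max(N, 2))
  fe <- function(n) factorial_exponents(n, primes)
  const <- fe(r1) + fe(r2) + fe(c1) + fe(c2) - fe(N)
  mass <- function(k) {
    expo <- const - fe(k) - fe(r1 - k) - fe(c1 - k) - fe(r2 - c1 + k)
    prod(primes^expo)
  }
  ks <- max(0, c1 - r2):min(r1, c1)
  m <- vapply(ks, mass, numeric(1))
  obs <- mass(a)
  sum(m[m <= obs * (1 + 1e-7)])
}
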