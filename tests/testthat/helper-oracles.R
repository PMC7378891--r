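# Independent enumeration oracles, kept free of the package's code paths.

# Two-sided Fisher exact p by brute enumeration over all tables with the
# observed margins, probabilities from choose().
fisherOracle <- function(a, b, c_, d) {
  m1 <- a + c_; m2 <- b + d; r1 <- a + b; N <- m1 + m2
  support <- max(0, r1 - m2):min(r1, m1)
  prob <- vapply(support, function(x)
    choose(m1, x) * choose(m2, r1 - x) / choose(N, r1), numeric(1))
  obs <- prob[match(a, support)]
  min(1, sum(prob[prob <= obs * (1 + 1e-7)]))
}

# Two-sided Mann-Whitney p by exhaustive label permutation; U computed by
# direct pairwise comparison.
mwOracle <- function(x, y) {
  pooled <- c(x, y); nx <- length(x)
  uStat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  mu <- nx * length(y) / 2
  obs <- abs(uStat(x, y) - mu)
  splits <- utils::combn(length(pooled), nx)
  us <- apply(splits, 2, function(idx) uStat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= obs - 1e-9)
}
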