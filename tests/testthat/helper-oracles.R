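# independent oracles used across the suite -------------------------------

# nested-integral evaluation of P(p_(1) > c1, ..., p_(n) > cn) for n iid
# uniforms by recursive one-dimensional quadrature (n <= 4): the integrand
# at level k integrates the level below from c_k to t
nested_integral_survival <- function(cv, rel.tol = 1e-11) {
  n <- length(cv)
  level <- function(k, t) {
    if (k == 0L) return(rep(1, length(t)))
    vapply(t, function(tt) {
      if (tt <= cv[k]) return(0)
      stats::integrate(function(s) level(k - 1L, s), cv[k], tt,
                       rel.tol = rel.tol, abs.tol = 0)$value
    }, numeric(1))
  }
  factorial(n) * level(n, 1)
}

# Monte-Carlo estimate of the boundary-crossing probability
# P(exists r: U_(r) <= c_r), generating the order statistics directly from
# exponential spacings so no per-row sort is needed
mc_crossing_prob <- function(cv, draws = 1e6, chunk = 2e5) {
  n <- length(cv)
  hits <- 0
  done <- 0
  tri <- upper.tri(diag(n + 1), diag = TRUE) * 1
  while (done < draws) {
    b <- min(chunk, draws - done)
    E <- matrix(stats::rexp(b * (n + 1)), b, n + 1)
    cs <- E %*% tri                      # row cumsums
    U <- cs[, 1:n, drop = FALSE] / cs[, n + 1]
    cross <- rowSums(U <= matrix(cv, b, n, byrow = TRUE)) > 0
    hits <- hits + sum(cross)
    done <- done + b
  }
  hits / draws
}

# quadratic-time reference Benjamini-Hochberg step-up
bh_brute <- function(p) {
  m <- length(p)
  vapply(seq_len(m), function(i) {
    cand <- vapply(seq_len(m), function(j) {
      if (p[j] >= p[i]) min(1, m * p[j] / sum(p <= p[j])) else Inf
    }, numeric(1))
    min(cand)
  }, numeric(1))
}

# printed type-I benchmark rates at cutoff 0.05, 100000 null replicates
type1_benchmark <- local({
  m <- rbind(
    `2`   = c(wfisher = 0.0492, ordmeta = 0.0490, stouffer = 0.0492,
              wz = 0.0484, lancaster = 0.0486, fisher = 0.0487),
    `10`  = c(wfisher = 0.0499, ordmeta = 0.0490, stouffer = 0.0506,
              wz = 0.0505, lancaster = 0.0512, fisher = 0.0500),
    `30`  = c(wfisher = 0.0497, ordmeta = 0.0501, stouffer = 0.0496,
              wz = 0.0497, lancaster = 0.0491, fisher = 0.0496),
    `100` = c(wfisher = 0.0504, ordmeta = 0.0503, stouffer = 0.0498,
              wz = 0.0489, lancaster = 0.0493, fisher = 0.0504))
  m
})

# published directional ordmeta combined p-values for the BMI example loci
# (3 significant digits), excluding the two loci whose printed value
# underflowed the publishing pipeline's double-precision complement
bmi_expected <- c(rs7903146 = 1.82e-10, rs489693 = 7.34e-08,
                  rs2206277 = 1.19e-06, rs12243326 = 2.03e-09,
                  rs987237 = 2.02e-07)

bmi_fixture <- function() {
  system.file("extdata", "bmi_loci_synchronized.tsv", package = "metacomb")
}
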