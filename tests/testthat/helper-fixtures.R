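# Shared fixture builders; everything is generated in code under fixed
# seeds.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# A scale from a plain numeric vector in alphabetical amino-acid order.
make_scale <- function(id, v, ...) {
  hydro_scale(id, stats::setNames(v, AA20), ...)
}

# Seeded random scales for property-style loops.
random_test_scales <- function(n, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    make_scale(sprintf("s%02d", i), round(stats::runif(20, -5, 5), 3)))
}

# All-soluble peptide record with uniform coil annotation.
coil_record <- function(id, seq)
  peptide_record(id, seq, strrep("C", nchar(seq)), strrep("S", nchar(seq)))

# Neutral propensities: every residue 1 on both faces (EBSS = 0 always).
neutral_propensities <- function()
  ebss_propensities(stats::setNames(rep(1, 20), AA20),
                    stats::setNames(rep(1, 20), AA20))

# Shoelace polygon area of the 2-D convex hull of a point set; the
# brute-force oracle for 2-D hull volumes.
polygon_hull_area <- function(P) {
  idx <- grDevices::chull(P)
  V <- P[idx, , drop = FALSE]
  n <- nrow(V)
  j <- c(2:n, 1)
  abs(sum(V[, 1] * V[j, 2] - V[j, 1] * V[, 2])) / 2
}

# Brute-force one-sided Fisher p: exact hypergeometric tail by direct
# summation of binomial-coefficient ratios for the 2x2 table
# [x, n1 - x; xr, n2 - xr].
fisher_tail_oracle <- function(x, n1, xr, n2) {
  K <- x + xr          # total successes
  N <- n1 + n2
  hi <- min(K, n1)
  sum(vapply(x:hi, function(i)
    exp(lchoose(K, i) + lchoose(N - K, n1 - i) - lchoose(N, n1)),
    numeric(1)))
}

# Small synthetic pool pair shared by several tests.
test_pool_pair <- function(n = 40, strength = 1, seed = 101,
                           kinds = c("tm_helix", "tm_sheet"))
  generate_pool_pair(kinds[1], kinds[2], n, strength, seed = seed)
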