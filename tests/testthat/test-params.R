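test_that("average hydrophobicity is the windowed mean and stays within scale range", {
  ones <- make_scale("ones", c(rep(1, 19), 2))   # constant scales are rejected
  expect_equal(average_hydrophobicity(strrep("A", 8), ones), 1)
  kd <- bundled_scales()$kd
  set.seed(2)
  for (i in 1:10) {
    w <- paste(sample(AA20, 10, TRUE), collapse = "")
    a <- average_hydrophobicity(w, kd)
    expect_gte(a, min(kd$values)); expect_lte(a, max(kd$values))
  }
  expect_error(average_hydrophobicity("AXZ", kd), "unknown residue")
})

test_that("hydrophobic moment closed forms hold", {
  kd <- bundled_scales()$kd
  # single non-zero term at i = 0: cos(0) = 1, so moment = h / L
  s <- make_scale("delta", c(1, rep(0, 18), 0.5))
  expect_equal(hydrophobic_moment(paste0("A", strrep("C", 9)), s, 100), 0.1)
  expect_equal(hydrophobic_moment(paste0("A", strrep("C", 9)), s, 180), 0.1)
  # delta = 180: sin terms vanish; equals |alternating sum| / L
  set.seed(4)
  for (i in 1:20) {
    w <- sample(AA20, sample(5:15, 1), TRUE)
    h <- kd$values[w]
    direct <- abs(sum(h * (-1)^(seq_along(h) - 1))) / length(h)
    expect_equal(hydrophobic_moment(w, kd, 180), direct, tolerance = 1e-12)
    expect_equal(alternating_hydrophobicity(w, kd),
                 hydrophobic_moment(w, kd, 180), tolerance = 1e-12)
    # reversal invariance at 180 degrees (absolute value)
    expect_equal(hydrophobic_moment(rev(w), kd, 180),
                 hydrophobic_moment(w, kd, 180), tolerance = 1e-12)
  }
})

test_that("alternating hydrophobicity rewards perfect alternation, cancels constants", {
  # A = +1, C = -1, rest 0
  v <- setNames(rep(0, 20), AA20); v["A"] <- 1; v["C"] <- -1
  s <- hydro_scale("pm", v)
  expect_equal(alternating_hydrophobicity(strrep("AC", 5), s), 1)
  # constant-valued window, even length: exact cancellation
  expect_equal(alternating_hydrophobicity(strrep("A", 10), s), 0)
})

test_that("EBSS alternates faces, maximizes over phase, and needs 10 residues", {
  neut <- neutral_propensities()
  expect_equal(ebss(strrep("A", 12), neut), 0)
  # outward(L) = 2, everything else 1: "LALALALALA" scores (5 log 2)/10
  ov <- setNames(rep(1, 20), AA20); ov["L"] <- 2
  pr <- ebss_propensities(ov, setNames(rep(1, 20), AA20))
  expect_equal(ebss(strrep("LA", 5), pr), 5 * log(2) / 10, tolerance = 1e-12)
  # phase-max dominates both fixed phases
  set.seed(6)
  pr2 <- default_ebss_propensities()
  for (i in 1:10) {
    w <- sample(AA20, 10, TRUE)
    lo <- log(pr2$outward[w]); li <- log(pr2$inward[w])
    even <- (seq_len(10) - 1) %% 2 == 0
    ph0 <- (sum(lo[even]) + sum(li[!even])) / 10
    ph1 <- (sum(li[even]) + sum(lo[!even])) / 10
    expect_equal(ebss(w, pr2), max(ph0, ph1), tolerance = 1e-12)
  }
  expect_error(ebss(strrep("A", 9), neut), "at least 10")
  expect_error(ebss_propensities(setNames(rep(0, 20), AA20),
                                 setNames(rep(1, 20), AA20)), "> 0")
})

test_that("window extrema slide correctly and satisfy max >= min", {
  kd <- bundled_scales()$kd
  pr <- default_ebss_propensities()
  # single window: max equals min for every parameter
  w10 <- coil_record("w10", "ACDEFGHIKL")
  v <- window_extrema(w10, kd, pr)
  expect_equal(unname(v[seq(1, 9, 2)]), unname(v[seq(2, 10, 2)]))
  # direct cross-check of the single-window values
  expect_equal(v[["max_average"]], average_hydrophobicity("ACDEFGHIKL", kd))
  expect_equal(v[["max_moment_alpha"]],
               hydrophobic_moment("ACDEFGHIKL", kd, 100))
  expect_equal(v[["max_ebss"]], ebss("ACDEFGHIKL", pr))
  # homopolymer: all windows identical
  v2 <- window_extrema(coil_record("homo", strrep("A", 14)), kd, pr)
  expect_equal(unname(v2[seq(1, 9, 2)]), unname(v2[seq(2, 10, 2)]))
  # 12-mer: 3 windows; extrema bound each window's values
  p12 <- coil_record("p12", "ACDEFGHIKLMN")
  v3 <- window_extrema(p12, kd, pr)
  for (off in 0:2) {
    w <- substr("ACDEFGHIKLMN", off + 1, off + 10)
    expect_lte(average_hydrophobicity(w, kd), v3[["max_average"]])
    expect_gte(average_hydrophobicity(w, kd), v3[["min_average"]])
  }
  expect_error(window_extrema(coil_record("short", "ACDEFGHIK"), kd, pr),
               "shorter than the window")
  # random peptides: max >= min always
  set.seed(10)
  for (i in 1:10) {
    p <- coil_record("r", paste(sample(AA20, sample(10:30, 1), TRUE),
                                collapse = ""))
    v <- window_extrema(p, kd, pr)
    expect_true(all(v[seq(1, 9, 2)] >= v[seq(2, 10, 2)]))
    expect_true(all(is.finite(v)))
  }
})

test_that("positive scaling of a scale scales the scale-based parameters linearly", {
  kd <- bundled_scales()$kd
  kd3 <- hydro_scale("kd3", kd$values * 3)
  set.seed(11)
  for (i in 1:5) {
    w <- paste(sample(AA20, 12, TRUE), collapse = "")
    expect_equal(average_hydrophobicity(w, kd3),
                 3 * average_hydrophobicity(w, kd), tolerance = 1e-12)
    expect_equal(hydrophobic_moment(w, kd3, 100),
                 3 * hydrophobic_moment(w, kd, 100), tolerance = 1e-12)
    expect_equal(alternating_hydrophobicity(w, kd3),
                 3 * alternating_hydrophobicity(w, kd), tolerance = 1e-12)
  }
})

test_that("combination masks pick max/min per parameter and enumerate 32 points", {
  kd <- bundled_scales()$kd
  p <- coil_record("p", "ACDEFGHIKLMNPQRS")
  v <- window_extrema(p, kd)
  expect_equal(unname(select_combination(v, 0)),
               unname(v[c(1, 3, 5, 7, 9)]))   # all maxima
  expect_equal(unname(select_combination(v, 31)),
               unname(v[c(2, 4, 6, 8, 10)]))  # all minima
  pts <- vapply(0:31, function(m) select_combination(v, m), numeric(5))
  expect_equal(nrow(unique(t(pts))), 32)      # generic peptide: all distinct
  expect_error(select_combination(v, 32), "0..31")
  expect_error(select_combination(v, -1), "0..31")
  # matrix form selects columns consistently
  pool <- peptide_pool("random", list(p, coil_record("q", "ACDEFGHIKLAC")),
                       "structure")
  M <- pool_extrema(pool, kd)
  expect_equal(unname(select_combination(M, 5)[1, ]),
               unname(select_combination(window_extrema(p, kd), 5)))
})
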