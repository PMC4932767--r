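test_that("two-column parser round-trips values and validates input", {
  lines <- c("#id: toy", paste(AA20, seq_len(20), sep = "\t"))
  sc <- parse_scale_table(lines, "two_column")
  expect_length(sc, 1)
  expect_identical(unname(sc$toy$values[AA20]), as.numeric(1:20))
  expect_equal(sc$toy$values[["A"]], 1)
  expect_equal(sc$toy$values[["V"]], 18)

  # missing amino acid names the deficit
  expect_error(parse_scale_table(lines[-which(AA20 == "W") - 1L], "two_column"),
               "19 of 20 amino acids")
  # duplicate ids
  expect_error(parse_scale_table(c(lines, lines), "two_column"), "duplicate")
  # non-numeric value
  bad <- lines
  bad[3] <- "C\tabc"
  expect_error(parse_scale_table(bad, "two_column"), "non-numeric")
})

test_that("AAindex flat parser maps the I block positionally", {
  path <- system.file("extdata", "aaindex_sample.txt", package = "hydrosep")
  sc <- parse_scale_table(path, "aaindex_flat")
  expect_named(sc, c("KYTJ820101", "HOPT810101"))
  # hand-parsed cross-check: AAindex order row 1 = A R N D C Q E G H I,
  # row 2 = L K M F P S T W Y V
  kd <- sc$KYTJ820101$values
  expect_equal(kd[["A"]], 1.8)
  expect_equal(kd[["R"]], -4.5)
  expect_equal(kd[["I"]], 4.5)
  expect_equal(kd[["L"]], 3.8)
  expect_equal(kd[["V"]], 4.2)
  # agrees with the bundled two-column copy of the same scale
  expect_equal(kd, bundled_scales()$kd$values)
})

test_that("scale constructor rejects degenerate and incomplete scales", {
  expect_error(make_scale("const", rep(1, 20)), "degenerate")
  expect_error(hydro_scale("short", setNames(1:19, AA20[-20])), "19 of 20")
  expect_error(make_scale("inf", c(Inf, 2:20)), "finite")
})

test_that("reverse_scale negates, is an involution, and anti-correlates", {
  s <- bundled_scales()$kd
  r <- reverse_scale(s)
  expect_equal(unname(r$values), -unname(s$values))
  expect_equal(r$values[["A"]], -1.8)
  expect_identical(r$category, "inverted")
  expect_equal(reverse_scale(r)$values, s$values)
  expect_equal(cor(s$values, r$values), -1)
})

test_that("min-max normalization is an order-preserving map onto [0, 1]", {
  s <- make_scale("lin", seq(0, 95, by = 5))
  n <- minmax_normalize(s)
  expect_equal(unname(n$values), seq(0, 1, length.out = 20))
  expect_equal(minmax_normalize(n)$values, n$values)   # idempotent
  for (s in random_test_scales(5, seed = 7)) {
    n <- minmax_normalize(s)
    expect_equal(range(n$values), c(0, 1))
    expect_identical(order(n$values), order(s$values))
    expect_identical(which.max(n$values), which.max(s$values))
  }
})

test_that("correlation dissimilarity is sign-blind, symmetric and exact", {
  s <- bundled_scales()$kd
  expect_equal(scale_dissimilarity(s, s), 0)
  expect_equal(scale_dissimilarity(s, reverse_scale(s)), 0)
  # constructed pair with Pearson correlation exactly 0.6
  set.seed(3)
  a <- rnorm(20)
  z <- residuals(lm(rnorm(20) ~ a))
  b <- 0.6 * scale(a)[, 1] + sqrt(1 - 0.36) * scale(z)[, 1]
  sa <- make_scale("a", a); sb <- make_scale("b", b)
  expect_equal(cor(sa$values, sb$values), 0.6, tolerance = 1e-12)
  expect_equal(scale_dissimilarity(sa, sb), 0.8, tolerance = 1e-12)
  # symmetry and range over random pairs
  sc <- random_test_scales(6, seed = 11)
  for (i in 1:5) for (j in (i + 1):6) {
    d <- scale_dissimilarity(sc[[i]], sc[[j]])
    expect_equal(d, scale_dissimilarity(sc[[j]], sc[[i]]))
    expect_gte(d, 0); expect_lte(d, 1)
  }
})

test_that("UPGMA heights and threshold cut follow average-linkage arithmetic", {
  D <- matrix(c(0, .2, .6,
                .2, 0, .6,
                .6, .6, 0), 3, dimnames = list(c("A", "B", "C"),
                                               c("A", "B", "C")))
  lk <- hydrosep:::upgma_linkage(D, rownames(D))
  expect_equal(lk$height, c(0.1, 0.3))     # join heights = dist / 2
  cl_tight <- hydrosep:::upgma_from_matrix(D, threshold = 0.05)$clusters
  expect_length(unique(cl_tight), 3)       # all singletons
  cl_loose <- hydrosep:::upgma_from_matrix(D, threshold = 0.25)$clusters
  expect_identical(cl_loose[["A"]], cl_loose[["B"]])
  expect_false(cl_loose[["C"]] == cl_loose[["A"]])
})

test_that("UPGMA matches the stats::hclust average-linkage oracle", {
  set.seed(42)
  for (n in 4:8) {
    M <- matrix(runif(n * n), n)
    D <- (M + t(M)) / 2
    diag(D) <- 0
    dimnames(D) <- list(paste0("x", 1:n), paste0("x", 1:n))
    lk <- hydrosep:::upgma_linkage(D, rownames(D))
    hc <- hclust(as.dist(D), method = "average")
    expect_equal(sort(lk$height), sort(hc$height / 2), tolerance = 1e-12)
  }
})

test_that("a scale always clusters with its inversion and trees are ultrametric", {
  sc <- random_test_scales(4, seed = 5)
  all_sc <- c(sc, lapply(sc, reverse_scale))
  cl <- upgma_cluster(all_sc, threshold = 0.01)
  for (s in sc)
    expect_identical(cl$clusters[[s$id]], cl$clusters[[paste0(s$id, "_inv")]])
  expect_false(is.unsorted(cl$hclust$height))          # ultrametric heights
  expect_true(all(diag(cl$dissimilarity) == 0))
  expect_equal(cl$dissimilarity, t(cl$dissimilarity))
  # Newick export parses back to the same leaf set
  nwk <- tempfile(fileext = ".nwk")
  export_clustering(cl, newick = nwk)
  tr <- ape::read.tree(nwk)
  expect_setequal(tr$tip.label, cl$scale_ids)
})

test_that("amino-acid difference analysis flags extremes on the unit scale", {
  s <- bundled_scales()$kd
  res <- aa_difference_matrix(s)
  expect_equal(res$matrix, t(res$matrix))
  expect_true(all(diag(res$matrix) == 0))
  # normalized extremes: I (most hydrophobic) vs R (least) differ by 1
  expect_equal(res$matrix["I", "R"], 1)
  expect_true(any(res$distant$aa1 == "I" & res$distant$aa2 == "R" |
                  res$distant$aa1 == "R" & res$distant$aa2 == "I"))
  # equal-valued residues (D, N, Q, E all -3.5) are flagged similar
  expect_equal(res$matrix["D", "N"], 0)
  expect_true(any((res$similar$aa1 == "D" & res$similar$aa2 == "N") |
                  (res$similar$aa1 == "N" & res$similar$aa2 == "D")))
})
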