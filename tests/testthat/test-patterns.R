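test_that("k-mer counting and normalization follow the counting identity", {
  p <- peptide_pool("random", list(coil_record("a", "AAAA")), "structure")
  km <- count_kmers(p, 2)
  expect_equal(km$count[["AA"]], 3)
  expect_equal(km$fo[["AA"]], 1)
  # peptides shorter than k contribute nothing
  p2 <- peptide_pool("random", list(coil_record("a", "ACDEF"),
                                    coil_record("b", "AC")), "structure")
  km3 <- count_kmers(p2, 3)
  expect_equal(sum(km3$count), 3)      # only the 5-mer contributes 5-3+1
  expect_equal(sum(km3$fo), 1)
  # total identity over random pools
  set.seed(31)
  seqs <- vapply(1:8, function(i)
    paste(sample(AA20, sample(4:20, 1), TRUE), collapse = ""), character(1))
  pool <- peptide_pool("random", lapply(seq_along(seqs), function(i)
    coil_record(paste0("r", i), seqs[i])), "structure")
  for (k in 2:5)
    expect_equal(sum(count_kmers(pool, k)$count),
                 sum(pmax(0, nchar(seqs) - k + 1)))
  expect_error(count_kmers(pool, 6), "between 2 and 5")
})

test_that("Markov background models normalize and degrade gracefully", {
  mono <- peptide_pool("random",
                       list(coil_record("a", strrep("A", 50))), "structure")
  m1 <- fit_markov(mono, order = 1)
  expect_gt(hydrosep:::markov_conditional(m1, "A", "A"), 0.7)
  expect_equal(pattern_probability(m1, "AA"),
               m1$initial[["A"]] * hydrosep:::markov_conditional(m1, "A", "A"))
  # order 0 reduces to a composition product
  set.seed(32)
  pool <- peptide_pool("random", lapply(1:5, function(i)
    coil_record(paste0("r", i),
                paste(sample(AA20, 30, TRUE), collapse = ""))), "structure")
  m0 <- fit_markov(pool, order = 0)
  expect_equal(pattern_probability(m0, "ACD"),
               m0$initial[["A"]] * m0$initial[["C"]] * m0$initial[["D"]],
               tolerance = 1e-12)
  # exhaustive sum over all 400 dimers is 1
  m <- fit_markov(pool, order = 1)
  dimers <- as.vector(outer(AA20, AA20, paste0))
  expect_equal(sum(vapply(dimers, function(d) pattern_probability(m, d),
                          numeric(1))), 1, tolerance = 1e-6)
})

test_that("coverage is complete for identical pools and excludes private patterns", {
  base <- lapply(1:6, function(i)
    coil_record(paste0("r", i), strrep("ACDEF", 4)))
  p1 <- peptide_pool("random", base, "structure")
  p2 <- peptide_pool("s-helix", base, "structure")
  cov <- coverage_by_length(list(p1, p2), 2:4)
  expect_equal(unname(cov), c(1, 1, 1))
  # a pattern private to one pool lowers coverage below 1
  p3 <- peptide_pool("s-sheet", c(base, list(coil_record("x", "WWWWWWWWWW"))),
                     "structure")
  cov2 <- coverage_by_length(list(p1, p3), 2:2)
  expect_lt(cov2[["k2"]], 1)
  # non-increasing trend on fixed-size random pools
  set.seed(33)
  pools <- lapply(c("random", "s-helix", "s-sheet"), function(lab)
    peptide_pool(lab, lapply(1:40, function(i)
      coil_record(paste0(lab, i),
                  paste(sample(AA20, 25, TRUE), collapse = ""))), "structure"))
  cov3 <- coverage_by_length(pools, 2:5)
  expect_true(all(diff(cov3) <= 0))
})

test_that("Fisher enrichment matches the exhaustive hypergeometric oracle", {
  # engineered pools with small, known margins
  focal <- peptide_pool("s-helix", list(coil_record("f", strrep("ACE", 10))),
                        "structure")
  other <- peptide_pool("random", list(coil_record("o", strrep("DFG", 12))),
                        "structure")
  tab <- enrichment_table(list(focal, other), k = 2)
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    n1 <- sum(tab$count[tab$pool == row$pool])
    all_counts <- lapply(list(focal, other), function(p)
      count_kmers(p, 2)$count)
    names(all_counts) <- c("s-helix", "random")
    ref <- all_counts[[setdiff(c("s-helix", "random"), row$pool)]]
    xr <- if (row$pattern %in% names(ref)) ref[[row$pattern]] else 0
    n2 <- sum(ref)
    expect_equal(row$p, fisher_tail_oracle(row$count, n1, xr, n2),
                 tolerance = 1e-12)
  }
  # BH adjustment within the pool family
  fam <- tab[tab$pool == "s-helix", ]
  expect_equal(fam$p_adj, p.adjust(fam$p, "BH"), tolerance = 1e-15)
})

test_that("fold thresholds flag 50x but not 500x at a 100-fold ratio", {
  # focal: pattern 'WW' once among 100 dimers; reference: once in 10000
  focal_seq <- paste0("WW", strrep("AC", 50))            # 101 dimers
  ref_seq <- paste0("WW", strrep("AC", 5000))
  focal <- peptide_pool("s-helix", list(coil_record("f", focal_seq)),
                        "structure")
  other <- peptide_pool("random", list(coil_record("o", ref_seq)),
                        "structure")
  tab <- enrichment_table(list(focal, other), k = 2)
  ww <- tab[tab$pool == "s-helix" & tab$pattern == "WW", ]
  expect_equal(ww$fold_all, (1 / 101) / (1 / 10001), tolerance = 1e-9)
  expect_true(ww$flag50)
  expect_false(ww$flag500)
})

test_that("a planted rare 5-mer is recovered with flags and significance", {
  set.seed(34)
  mk_pool <- function(lab, plant) {
    recs <- lapply(1:60, function(i) {
      s <- sample(setdiff(AA20, c("W", "H")), 24, TRUE)
      if (plant && i <= 36) s[10:14] <- c("W", "W", "H", "W", "W")
      coil_record(paste0(lab, i), paste(s, collapse = ""))
    })
    peptide_pool(lab, recs, "structure")
  }
  pools <- list(mk_pool("s-helix", TRUE), mk_pool("random", FALSE),
                mk_pool("s-sheet", FALSE))
  tab <- enrichment_table(pools, k = 5)
  hit <- tab[tab$pool == "s-helix" & tab$pattern == "WWHWW", ]
  expect_equal(nrow(hit), 1)
  expect_true(hit$flag50)
  expect_lt(hit$p_adj, 0.05)
  # the motif never reaches the other pools' tables
  expect_false(any(tab$pattern == "WWHWW" & tab$pool != "s-helix"))
})
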