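test_that("SSE dissection extracts runs, extends TM runs, drops short soluble runs", {
  # 3C + 11H + 2C, all soluble: only the helix run is long enough
  p <- peptide_record("p1", strrep("A", 16), "CCCHHHHHHHHHHHCC",
                      strrep("S", 16))
  segs <- dissect_sse_segments(p)
  expect_length(segs, 1)
  expect_identical(segs[[1]]$label, "s-helix")
  expect_identical(segs[[1]]$record$sse, strrep("H", 11))

  # 6-residue TM helix inside a 30-mer is padded to exactly 10
  sse <- paste0(strrep("C", 12), strrep("H", 6), strrep("C", 12))
  topo <- paste0(strrep("S", 12), strrep("M", 6), strrep("S", 12))
  p2 <- peptide_record("p2", strrep("L", 30), sse, topo)
  segs2 <- dissect_sse_segments(p2)
  tm <- Filter(function(s) s$label == "tm-helix", segs2)
  expect_length(tm, 1)
  expect_equal(nchar(tm[[1]]$record$sequence), 10)
  expect_true(grepl("HHHHHH", tm[[1]]$record$sse))

  # all-coil length 9: below the minimum length
  p3 <- coil_record("p3", strrep("G", 9))
  expect_length(dissect_sse_segments(p3), 0)
})

test_that("tryptic digest cleaves after K/R and keeps annotations in register", {
  p <- coil_record("d1", "AAKLLRGG")
  fr <- tryptic_digest(p)
  expect_identical(vapply(fr, function(f) f$sequence, character(1)),
                   c("AAK", "LLR", "GG"))
  # no K/R: identity
  p2 <- coil_record("d2", "AAGGLL")
  expect_identical(tryptic_digest(p2)[[1]]$sequence, "AAGGLL")
  # degenerate cleavage
  p3 <- coil_record("d3", "KKK")
  expect_identical(vapply(tryptic_digest(p3), function(f) f$sequence,
                          character(1)), c("K", "K", "K"))
  # property: fragments reassemble and annotations stay in register
  set.seed(8)
  for (i in 1:10) {
    n <- sample(15:60, 1)
    seq <- paste(sample(AA20, n, replace = TRUE), collapse = "")
    sse <- paste(sample(c("H", "E", "C"), n, replace = TRUE), collapse = "")
    topo <- paste(sample(c("M", "S"), n, replace = TRUE), collapse = "")
    p <- peptide_record("r", seq, sse, topo)
    fr <- tryptic_digest(p)
    expect_identical(paste(vapply(fr, function(f) f$sequence, character(1)),
                           collapse = ""), seq)
    expect_identical(paste(vapply(fr, function(f) f$sse, character(1)),
                           collapse = ""), sse)
    expect_identical(paste(vapply(fr, function(f) f$topo, character(1)),
                           collapse = ""), topo)
  }
})

test_that("fragment classification follows dominance, continuity and krtm rules", {
  mk <- function(sse, topo = strrep("S", nchar(sse)))
    peptide_record("f", strrep("A", nchar(sse)), sse, topo)
  # 75% H in one block, soluble: dominated and continuous
  expect_identical(classify_fragment(mk("HHHHHHHHHCCC")), "dc-helix")
  # same content split in two blocks: discontinuous
  expect_identical(classify_fragment(mk("HHHHHCCCHHHH")), "dd-helix")
  # 50/50 E and C: no dominance, H absent
  expect_identical(classify_fragment(mk("ECECECECECEC")), "no-helix")
  # all three present, none above 70%
  expect_identical(classify_fragment(mk("HHHHEEEECCCC")), "all")
  # membrane residues force krtm regardless of dominance
  topo <- paste0("MMM", strrep("S", 7))
  expect_identical(classify_fragment(mk(paste0("EEE", strrep("C", 7)), topo)),
                   "krtm-sheet")
  expect_identical(classify_fragment(mk(strrep("H", 10),
                                        paste0("M", strrep("S", 9)))),
                   "krtm-helix")
  # dominance is strict: 69% dominated is not, 70% is not, 71% is
  s69 <- mk(paste0(strrep("H", 69), strrep("C", 31)))
  s70 <- mk(paste0(strrep("H", 70), strrep("C", 30)))
  s71 <- mk(paste0(strrep("H", 71), strrep("C", 29)))
  expect_identical(classify_fragment(s69), "no-sheet")
  expect_identical(classify_fragment(s70), "no-sheet")
  expect_identical(classify_fragment(s71), "dc-helix")
  # fragments below ten residues are unclassified
  expect_true(is.na(classify_fragment(mk("HHHHHHHHH"))))
})

test_that("classification is total: every long fragment gets exactly one digest label", {
  set.seed(12)
  labels <- hydrosep:::DIGEST_POOL_LABELS
  for (i in 1:50) {
    n <- sample(10:40, 1)
    p <- peptide_record("t", paste(sample(AA20, n, TRUE), collapse = ""),
                        paste(sample(c("H", "E", "C"), n, TRUE), collapse = ""),
                        paste(sample(c("M", "S"), n, TRUE,
                                     prob = c(0.2, 0.8)), collapse = ""))
    lab <- classify_fragment(p)
    expect_length(lab, 1)
    expect_true(lab %in% labels)
  }
})

test_that("pool assembly composes both strategies, filters and deduplicates", {
  helix12 <- peptide_record("h1", "ALELALQKALEL", strrep("H", 12),
                            strrep("S", 12))
  pools <- assemble_pools(list(helix12, helix12))   # duplicate input
  expect_s3_class(pools, "peptide_pools")
  expect_equal(length(pools[["s-helix"]]$records), 1)   # dissection, deduped
  # digest splits after the K, leaving fragments of 8 and 4: nothing >= 10
  expect_equal(length(pools[["dc-helix"]]$records), 0)
  # a K/R-free helix lands in both s-helix and dc-helix
  helix_nok <- peptide_record("h2", "ALELALQLALEL", strrep("H", 12),
                              strrep("S", 12))
  pools2 <- assemble_pools(list(helix_nok))
  expect_equal(length(pools2[["s-helix"]]$records), 1)
  expect_equal(length(pools2[["dc-helix"]]$records), 1)
  # invariants on a synthetic batch
  gen <- generate_proteins(synthetic_spec(seed = 77, n_proteins = 15))
  pools3 <- assemble_pools(gen$proteins)
  for (lab in hydrosep:::ALL_POOL_LABELS) {
    for (r in pools3[[lab]]$records) {
      expect_gte(nchar(r$sequence), 10)
      if (startsWith(lab, "krtm")) expect_true(grepl("M", r$topo))
      if (startsWith(lab, "dc-")) {
        dom <- names(which.max(table(strsplit(r$sse, "")[[1]])))
        expect_equal(sum(rle(strsplit(r$sse, "")[[1]])$values == dom), 1)
      }
    }
  }
  expect_identical(sum(pools3$summary$n_peptides),
                   sum(vapply(hydrosep:::ALL_POOL_LABELS,
                              function(l) length(pools3[[l]]$records),
                              integer(1))))
})

test_that("annotated records round-trip through the combined TSV reader", {
  gen <- generate_proteins(synthetic_spec(seed = 3, n_proteins = 4))
  tsv <- tempfile(fileext = ".tsv")
  hydrosep:::write_records_tsv(gen$proteins, tsv)
  back <- read_annotated_fasta(fasta = NULL, tsv = tsv)
  expect_equal(length(back), 4)
  expect_identical(back[[2]]$sequence, gen$proteins[[2]]$sequence)
  expect_identical(back[[2]]$sse, gen$proteins[[2]]$sse)
})
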