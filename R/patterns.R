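pool_sequences <- function(pool) {
  if (inherits(pool, "peptide_pool"))
    vapply(pool$records, function(r) r$sequence, character(1))
  else as.character(pool)
}

all_kmers <- function(seqs, k) {
  unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
}

#' Count overlapping k-mers in a pool
#'
#' Counts every overlapping amino-acid pattern of length `k` (2-5)
#' across all peptides, and the frequency of occurrence (FO): each count
#' divided by the pool's total k-mer count, so the FO values sum to one.
#'
#' @param pool a [peptide_pool] (or character vector of sequences).
#' @param k pattern length, 2 to 5.
#' @return list with `count` (named integer) and `fo` (named numeric).
#' @export
count_kmers <- function(pool, k) {
  if (k < 2L || k > 5L) stop("pattern length k must be between 2 and 5")
  seqs <- pool_sequences(pool)
  if (!length(seqs)) stop("pool is empty")
  km <- all_kmers(seqs, k)
  if (!length(km)) return(list(count = integer(0), fo = numeric(0)))
  tab <- table(km)
  cnt <- setNames(as.integer(tab), names(tab))
  list(count = cnt, fo = cnt / sum(cnt))
}

#' Fit a Markov chain to a peptide pool
#'
#' Maximum-likelihood composition and transition estimates with add-one
#' smoothing, in the spirit of the background models used for motif
#' scanning.  For contexts shorter than the model order (at the start of
#' a pattern) the truncated-context estimate is used, so pattern
#' probabilities of a fixed length sum to one over all `20^k` patterns.
#'
#' @param pool a [peptide_pool] or character vector of sequences.
#' @param order Markov order >= 0 (0 = composition only).
#' @return an object of class `markov_model`.
#' @export
fit_markov <- function(pool, order = 1L) {
  if (order < 0L) stop("order must be >= 0")
  seqs <- pool_sequences(pool)
  if (!length(seqs)) stop("pool is empty")
  comp <- table(factor(unlist(strsplit(seqs, ""), use.names = FALSE),
                       levels = AA_ALPHA))
  initial <- (as.numeric(comp) + 1) / (sum(comp) + 20)
  names(initial) <- AA_ALPHA
  transitions <- list()
  if (order >= 1L) for (o in seq_len(order)) {
    ctx <- all_kmers(seqs, o + 1L)
    if (length(ctx)) {
      pre <- substring(ctx, 1L, o)
      nxt <- substring(ctx, o + 1L, o + 1L)
      cnt <- table(pre, factor(nxt, levels = AA_ALPHA))
    } else {
      cnt <- table(character(0), factor(character(0), levels = AA_ALPHA))
    }
    transitions[[o]] <- cnt
  }
  structure(list(order = as.integer(order), initial = initial,
                 transitions = transitions),
            class = "markov_model")
}

markov_conditional <- function(model, context, nxt) {
  o <- nchar(context)
  if (o == 0L) return(model$initial[[nxt]])
  tab <- model$transitions[[o]]
  row <- if (context %in% rownames(tab)) as.numeric(tab[context, ]) else
    rep(0, 20L)
  (row[match(nxt, AA_ALPHA)] + 1) / (sum(row) + 20)
}

#' Probability of a pattern under a Markov model
#'
#' `p(a1) * prod p(a_i | preceding context)` with the context truncated
#' to the model order.
#'
#' @param model a [fit_markov] result.
#' @param pattern amino-acid string.
#' @return probability in `(0, 1)`.
#' @export
pattern_probability <- function(model, pattern) {
  aa <- strsplit(pattern, "")[[1L]]
  if (any(!aa %in% AA_ALPHA))
    stop(sprintf("pattern '%s' contains a non-standard letter", pattern))
  p <- model$initial[[aa[1L]]]
  for (i in seq_along(aa)[-1L]) {
    o <- min(model$order, i - 1L)
    ctx <- if (o > 0L) paste(aa[(i - o):(i - 1L)], collapse = "") else ""
    p <- p * markov_conditional(model, ctx, aa[i])
  }
  p
}

#' Shared-pattern coverage by pattern length
#'
#' For each pattern length, the fraction of the observed patterns (union
#' over pools) that occur in every pool.  With pools of fixed size this
#' fraction decays as patterns get longer and rarer.
#'
#' @param pools named list of [peptide_pool] objects (>= 2 non-empty).
#' @param k_range pattern lengths (default 2:5).
#' @return named numeric vector, one fraction per k.
#' @export
coverage_by_length <- function(pools, k_range = 2:5) {
  pools <- Filter(function(p) length(pool_sequences(p)) > 0, as_pool_list(pools))
  if (length(pools) < 2L) stop("need at least two non-empty pools")
  out <- vapply(k_range, function(k) {
    sets <- lapply(pools, function(p) unique(all_kmers(pool_sequences(p), k)))
    univ <- unique(unlist(sets, use.names = FALSE))
    if (!length(univ)) return(NA_real_)
    shared <- Reduce(intersect, sets)
    length(shared) / length(univ)
  }, numeric(1))
  setNames(out, paste0("k", k_range))
}

as_pool_list <- function(pools) {
  if (inherits(pools, "peptide_pools"))
    pools <- pools[names(pools) %in% ALL_POOL_LABELS]
  stopifnot(all(vapply(pools, inherits, logical(1), "peptide_pool")))
  names(pools) <- vapply(pools, function(p) p$label, character(1))
  pools
}

#' Pool-specific k-mer enrichment
#'
#' For every pattern observed in a pool, computes its frequency of
#' occurrence (FO) in that pool, in the union of all remaining pools and
#' in the union of the remaining pools generated by the same strategy
#' (GBSS), the corresponding fold enrichments (reference FO floored at
#' one pseudo-count over the reference total so that patterns absent
#' elsewhere get a large finite fold), a one-sided Fisher exact p value
#' against the pooled reference, and Benjamini-Hochberg adjusted p
#' values within each pool's pattern family.  Flags mark at least
#' 50-fold and at least 500-fold enrichment in either reference.
#'
#' @param pools named list of [peptide_pool] objects (or a
#'   `peptide_pools` container); at least two non-empty pools.
#' @param k pattern length, 2 to 5.
#' @param alpha significance level stored alongside the adjusted p
#'   values (default 0.05).
#' @param include_focal_in_reference keep the focal pool inside the
#'   pooled reference (default FALSE: the reference is all other pools).
#' @return data frame of class `pattern_stats` with one row per
#'   (pool, pattern).
#' @export
enrichment_table <- function(pools, k, alpha = 0.05,
                             include_focal_in_reference = FALSE) {
  if (k < 2L || k > 5L) stop("pattern length k must be between 2 and 5")
  pools <- Filter(function(p) length(pool_sequences(p)) > 0, as_pool_list(pools))
  if (length(pools) < 2L) stop("need at least two non-empty pools")
  counts <- lapply(pools, function(p) count_kmers(p, k)$count)
  totals <- vapply(counts, sum, numeric(1))
  strategies <- vapply(pools, function(p) p$strategy, character(1))
  add_counts <- function(lst) {
    pats <- unique(unlist(lapply(lst, names), use.names = FALSE))
    out <- setNames(numeric(length(pats)), pats)
    for (cc in lst) out[names(cc)] <- out[names(cc)] + cc
    out
  }
  rows <- list()
  for (nm in names(pools)) {
    cnt <- counts[[nm]]
    if (!length(cnt)) next
    others <- setdiff(names(pools), nm)
    ref_cnt <- add_counts(counts[others])
    ref_tot <- sum(totals[others])
    gb <- others[strategies[others] == strategies[[nm]]]
    gb_cnt <- add_counts(counts[gb])
    gb_tot <- sum(totals[gb])
    if (ref_tot == 0) stop("empty reference: all remaining pools have no k-mers")
    fo_pool <- cnt / totals[[nm]]
    x_ref <- unname(ref_cnt[names(cnt)]); x_ref[is.na(x_ref)] <- 0
    fo_rem <- x_ref / ref_tot
    x_gb <- unname(gb_cnt[names(cnt)]); x_gb[is.na(x_gb)] <- 0
    fo_gb <- if (gb_tot > 0) x_gb / gb_tot else rep(NA_real_, length(cnt))
    floor_ref <- 1 / (ref_tot + 1)
    floor_gb <- if (gb_tot > 0) 1 / (gb_tot + 1) else NA_real_
    fold_all <- fo_pool / pmax(fo_rem, floor_ref)
    fold_gbss <- if (gb_tot > 0) fo_pool / pmax(fo_gb, floor_gb) else
      rep(NA_real_, length(cnt))
    # one-sided Fisher exact test (enrichment) on the 2x2 table
    # [x, pool_total - x; x_fisher, fisher_total - x_fisher]
    if (include_focal_in_reference) {
      x_f <- x_ref + cnt
      tot_f <- ref_tot + totals[[nm]]
    } else {
      x_f <- x_ref
      tot_f <- ref_tot
    }
    p <- phyper(cnt - 1, cnt + x_f,
                (totals[[nm]] - cnt) + (tot_f - x_f),
                totals[[nm]], lower.tail = FALSE)
    p_adj <- p.adjust(p, method = "BH")
    fold_best <- pmax(fold_all, fold_gbss, na.rm = TRUE)
    rows[[nm]] <- data.frame(
      pool = nm, pattern = names(cnt), count = as.integer(cnt),
      fo_pool = as.numeric(fo_pool), fo_remaining = as.numeric(fo_rem),
      fo_remaining_gbss = as.numeric(fo_gb),
      fold_all = as.numeric(fold_all), fold_gbss = as.numeric(fold_gbss),
      p = as.numeric(p), p_adj = as.numeric(p_adj),
      significant = as.numeric(p_adj) < alpha,
      flag50 = fold_best >= 50, flag500 = fold_best >= 500,
      row.names = NULL)
  }
  out <- do.call(rbind, rows)
  attr(out, "k") <- as.integer(k)
  attr(out, "alpha") <- alpha
  class(out) <- c("pattern_stats", "data.frame")
  out
}

#' Write an enrichment table as TSV
#'
#' @param stats a `pattern_stats` data frame.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_pattern_stats <- function(stats, path) {
  write.table(stats, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
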