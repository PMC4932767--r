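# Project two point sets onto the affine span of their union when that
# span has lower dimension than the ambient space.  This happens by
# construction whenever a selected coordinate is redundant (the default
# alternating hydrophobicity equals the 180-degree moment exactly, so
# masks agreeing on those two parameters yield points in a fixed
# hyperplane); hypervolumes are then measured within the common span.
joint_affine_reduce <- function(Pa, Pb) {
  X <- rbind(Pa, Pb)
  center <- colMeans(X)
  ctr <- sweep(X, 2L, center)
  sv <- svd(ctr, nu = 0L)
  tol <- max(1e-9 * max(1, max(abs(X))), 1e-12 * max(sv$d, 1))
  rank <- sum(sv$d > tol)
  if (rank >= ncol(X) || rank == 0L) return(list(Pa = Pa, Pb = Pb))
  B <- sv$v[, seq_len(rank), drop = FALSE]
  list(Pa = sweep(Pa, 2L, center) %*% B,
       Pb = sweep(Pb, 2L, center) %*% B)
}

# Core of a scenario evaluation once the two pools are already reduced to
# 5-D points: reduce to the common affine span, build clouds, strip the
# convex envelope once, score.
separation_from_points <- function(Pa, Pb, method = "mc", mc_samples = 1e5,
                                   seed = 1L, strip = TRUE) {
  red <- joint_affine_reduce(as.matrix(Pa), as.matrix(Pb))
  Pa <- red$Pa; Pb <- red$Pb
  ca <- build_hull(Pa)
  cb <- build_hull(Pb)
  if (strip) {
    ca <- strip_envelope(ca)
    cb <- strip_envelope(cb)
  }
  separation_score(ca, cb, method = method, mc_samples = mc_samples,
                   seed = seed)
}

#' Evaluate one separation scenario
#'
#' A scenario is one hydrophobicity scale, one parameter combination
#' (mask 0-31 selecting max or min of each of the five window
#' parameters) and one pair of peptide pools.  Each peptide becomes a
#' 5-D point, each pool a convex cloud; the convex envelopes are removed
#' once, and the separation capacity score S is computed from the
#' overlap of the stripped clouds.  Results are deterministic for a
#' fixed seed.
#'
#' @param pool_a,pool_b [peptide_pool] objects with at least 6 peptides
#'   each (a 5-D hull needs d + 1 points).
#' @param scale a [hydro_scale].
#' @param combo combination mask in `0..31` (see [select_combination]).
#' @param propensities an [ebss_propensities] object.
#' @param window_len sliding-window length (default 10).
#' @param method,mc_samples,seed passed to [cloud_overlap].
#' @param strip remove the convex envelope before scoring (default TRUE).
#' @return a `separation_result` (see [separation_score]) with the
#'   scenario recorded in attributes `scale_id`, `combo`, `pools`.
#' @export
evaluate_scenario <- function(pool_a, pool_b, scale, combo = 0L,
                              propensities = default_ebss_propensities(),
                              window_len = 10L,
                              method = "mc", mc_samples = 1e5, seed = 1L,
                              strip = TRUE) {
  for (p in list(pool_a, pool_b))
    if (length(p$records) < 6L)
      stop(sprintf("pool '%s' has %d peptides; at least 6 are needed for a 5-D cloud",
                   p$label, length(p$records)))
  Pa <- select_combination(pool_extrema(pool_a, scale, propensities, window_len), combo)
  Pb <- select_combination(pool_extrema(pool_b, scale, propensities, window_len), combo)
  res <- separation_from_points(Pa, Pb, method = method,
                                mc_samples = mc_samples, seed = seed,
                                strip = strip)
  attr(res, "scale_id") <- scale$id
  attr(res, "combo") <- as.integer(combo)
  attr(res, "pools") <- c(pool_a$label, pool_b$label)
  res
}

#' Full scenario sweep
#'
#' Evaluates every unordered pool pair under every combination mask for
#' every scale, producing exactly
#' `length(scales) * length(combos) * choose(length(pools), 2)` rows.
#'
#' @param pools named list of [peptide_pool] objects (>= 2).
#' @param scales list of [hydro_scale] objects.
#' @param combos combination masks (default all 32).
#' @inheritParams evaluate_scenario
#' @return long-format data frame with columns `scale_id`, `combo`,
#'   `pool_a`, `pool_b`, `V1`, `V2`, `Vov`, `P1`, `P2`, `Pov`, `Sv`,
#'   `Sp`, `S`.
#' @export
scenario_sweep <- function(pools, scales, combos = 0:31,
                           propensities = default_ebss_propensities(),
                           window_len = 10L, method = "mc",
                           mc_samples = 1e5, seed = 1L, strip = TRUE) {
  if (length(pools) < 2L) stop("need at least two pools")
  if (is_hydro_scale(scales)) scales <- list(scales)
  pairs <- combn(length(pools), 2L)
  rows <- list()
  for (sc in scales) {
    ext <- lapply(pools, pool_extrema, scale = sc,
                  propensities = propensities, window_len = window_len)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1L, k]; j <- pairs[2L, k]
      for (cm in combos) {
        res <- separation_from_points(
          select_combination(ext[[i]], cm), select_combination(ext[[j]], cm),
          method = method, mc_samples = mc_samples, seed = seed, strip = strip)
        rows[[length(rows) + 1L]] <- data.frame(
          scale_id = sc$id, combo = as.integer(cm),
          pool_a = pools[[i]]$label, pool_b = pools[[j]]$label,
          V1 = res$V1, V2 = res$V2, Vov = res$Vov,
          P1 = res$P1, P2 = res$P2, Pov = res$Pov,
          Sv = res$Sv, Sp = res$Sp, S = res$S)
      }
    }
  }
  do.call(rbind, rows)
}

#' Overall separation score of one scale
#'
#' Collapses a scale's scenario scores over pool pairs and parameter
#' combinations into a single number.  Modes: `"best-combo-mean"`
#' (default; per pool pair take the best S over the combinations, then
#' average over pairs), `"mean-mean"` (average over combinations, then
#' over pairs) and `"fixed-combo"` (average over pairs at one mask).
#'
#' @param scale a [hydro_scale] (or its id, when `sweep` is supplied).
#' @param pools named list of [peptide_pool] objects.
#' @param combos combination masks considered.
#' @param mode aggregation mode.
#' @param fixed_combo mask used by `"fixed-combo"`.
#' @param sweep optional precomputed [scenario_sweep] data frame to
#'   aggregate instead of recomputing.
#' @inheritParams evaluate_scenario
#' @return a single number in `[0, 1]`.
#' @export
scale_overall_score <- function(scale, pools = NULL, combos = 0:31,
                                mode = c("best-combo-mean", "mean-mean",
                                         "fixed-combo"),
                                fixed_combo = 0L,
                                propensities = default_ebss_propensities(),
                                window_len = 10L, method = "mc",
                                mc_samples = 1e5, seed = 1L, strip = TRUE,
                                sweep = NULL) {
  mode <- match.arg(mode)
  sid <- if (is_hydro_scale(scale)) scale$id else as.character(scale)
  if (is.null(sweep)) {
    if (mode == "fixed-combo") combos <- fixed_combo
    sweep <- scenario_sweep(pools, list(scale), combos = combos,
                            propensities = propensities,
                            window_len = window_len, method = method,
                            mc_samples = mc_samples, seed = seed,
                            strip = strip)
  }
  sw <- sweep[sweep$scale_id == sid, , drop = FALSE]
  if (!nrow(sw)) stop(sprintf("no scenarios for scale '%s'", sid))
  pair <- paste(sw$pool_a, sw$pool_b, sep = "|")
  per_pair <- switch(mode,
    "best-combo-mean" = tapply(sw$S, pair, max),
    "mean-mean" = tapply(sw$S, pair, mean),
    "fixed-combo" = tapply(sw$S[sw$combo == fixed_combo],
                           pair[sw$combo == fixed_combo], mean))
  mean(per_pair)
}

#' Best pairwise separation matrix
#'
#' For every unordered pool pair, the maximum S over all scales and
#' combinations, with the winning scale and mask recorded.
#'
#' @param pools named list of [peptide_pool] objects (>= 2).
#' @param scales list of [hydro_scale] objects.
#' @inheritParams scenario_sweep
#' @param sweep optional precomputed [scenario_sweep] data frame.
#' @return list of square matrices `S` (numeric; diagonal 0), `scale`
#'   and `combo` (provenance of each best entry).
#' @export
pairwise_best_matrix <- function(pools, scales, combos = 0:31,
                                 propensities = default_ebss_propensities(),
                                 window_len = 10L, method = "mc",
                                 mc_samples = 1e5, seed = 1L, strip = TRUE,
                                 sweep = NULL) {
  if (is.null(sweep))
    sweep <- scenario_sweep(pools, scales, combos = combos,
                            propensities = propensities,
                            window_len = window_len, method = method,
                            mc_samples = mc_samples, seed = seed,
                            strip = strip)
  labs <- vapply(pools, function(p) p$label, character(1))
  m <- length(labs)
  S <- matrix(0, m, m, dimnames = list(labs, labs))
  scl <- matrix(NA_character_, m, m, dimnames = list(labs, labs))
  cmb <- matrix(NA_integer_, m, m, dimnames = list(labs, labs))
  for (k in seq_len(nrow(sweep))) {
    i <- sweep$pool_a[k]; j <- sweep$pool_b[k]
    if (is.na(scl[i, j]) || sweep$S[k] > S[i, j]) {
      S[i, j] <- S[j, i] <- sweep$S[k]
      scl[i, j] <- scl[j, i] <- sweep$scale_id[k]
      cmb[i, j] <- cmb[j, i] <- sweep$combo[k]
    }
  }
  diag(S) <- 0
  list(S = S, scale = scl, combo = cmb)
}

#' Average separation score per scale cluster
#'
#' @param clustering a `scale_clustering` from [upgma_cluster].
#' @param per_scale_scores named numeric vector of overall scores (names
#'   = scale ids); every scored scale must appear in the clustering.
#' @return named numeric vector, one mean score per cluster label.
#' @export
cluster_average_score <- function(clustering, per_scale_scores) {
  stopifnot(inherits(clustering, "scale_clustering"))
  ids <- names(per_scale_scores)
  unknown <- setdiff(ids, clustering$scale_ids)
  if (length(unknown))
    stop(sprintf("scale id(s) not in the clustering: %s",
                 paste(unknown, collapse = ", ")))
  cl <- clustering$clusters[ids]
  tapply(per_scale_scores, cl, mean)
}

#' Parameter influence among the best scenarios
#'
#' For each of the ten parameter choices (five parameters, max or min),
#' the absolute difference between its frequency among the top-ranked
#' fraction of scenarios (by S; deterministic tie-break on scale id,
#' combo and pool pair) and its frequency among all scenarios.
#'
#' @param scenarios data frame with at least columns `combo` and `S`
#'   (e.g. from [scenario_sweep]).
#' @param top_fraction fraction of scenarios forming the top set
#'   (default 0.05).
#' @return named numeric vector of length 10 in extrema index order
#'   (max/min of EBSS, alternating, moment-alpha, moment-beta, average).
#' @export
parameter_influence <- function(scenarios, top_fraction = 0.05) {
  if (nrow(scenarios) < 20L)
    stop("need at least 20 scenarios for a parameter-influence analysis")
  n_top <- floor(nrow(scenarios) * top_fraction)
  if (n_top < 1L) stop("top scenario set is empty; increase top_fraction")
  tie_cols <- intersect(c("scale_id", "combo", "pool_a", "pool_b"),
                        names(scenarios))
  ord <- do.call(order, c(list(-scenarios$S), scenarios[tie_cols]))
  top <- scenarios[ord[seq_len(n_top)], , drop = FALSE]
  freq10 <- function(df) {
    bits <- vapply(0:4, function(k)
      bitwAnd(bitwShiftR(as.integer(df$combo), k), 1L), integer(nrow(df)))
    bits <- matrix(bits, ncol = 5L)
    as.vector(rbind(colMeans(bits == 0L), colMeans(bits == 1L)))
  }
  infl <- abs(freq10(top) - freq10(scenarios))
  setNames(infl, EXTREMA_NAMES)
}

#' Write scenario results as TSV
#'
#' @param sweep data frame from [scenario_sweep].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_scenarios <- function(sweep, path) {
  write.table(sweep, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
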