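#' Random hydrophobicity scales within a corpus value interval
#'
#' The global minimum and maximum amino-acid values of a scale corpus
#' form the sampling interval; each of the 20 residues of each new scale
#' gets an independent uniform draw from it.
#'
#' @param corpus non-empty list of [hydro_scale] objects.
#' @param n number of scales (default 200).
#' @param seed integer RNG seed.
#' @return named list of `n` scales with category `"random"`.
#' @export
random_scales <- function(corpus, n = 200L, seed = 1L) {
  if (!length(corpus)) stop("scale corpus is empty")
  vals <- unlist(lapply(corpus, function(s) s$values), use.names = FALSE)
  lo <- min(vals); hi <- max(vals)
  set.seed(as.integer(seed))
  out <- lapply(seq_len(n), function(i)
    hydro_scale(sprintf("rand%04d", i),
                setNames(runif(20L, lo, hi), AA_ALPHA),
                name = sprintf("random scale %d in [%.3g, %.3g]", i, lo, hi),
                category = "random"))
  setNames(out, vapply(out, function(s) s$id, character(1)))
}

#' Separation fitness of a scale
#'
#' Mean separation capacity S over all unordered pairs of the evaluation
#' pools, computed at one fixed parameter combination (default mask 0 =
#' all five maxima).  Deterministic for a fixed seed: each pool pair
#' gets its own derived Monte-Carlo seed.
#'
#' @param scale a [hydro_scale].
#' @param eval_pools named list of [peptide_pool] objects (>= 2, each
#'   with >= 6 peptides).
#' @param combo combination mask (default 0).
#' @param propensities an [ebss_propensities] object.
#' @param window_len sliding-window length.
#' @param mc_samples Monte-Carlo draws per overlap (default 2e4).
#' @param seed base RNG seed.
#' @return mean S in `[0, 1]`.
#' @export
scale_fitness <- function(scale, eval_pools, combo = 0L,
                          propensities = default_ebss_propensities(),
                          window_len = 10L, mc_samples = 2e4, seed = 1L) {
  if (length(eval_pools) < 2L) stop("need at least two evaluation pools")
  ext <- lapply(eval_pools, pool_extrema, scale = scale,
                propensities = propensities, window_len = window_len)
  pts <- lapply(ext, select_combination, combo = combo)
  pairs <- combn(length(pts), 2L)
  s_vals <- vapply(seq_len(ncol(pairs)), function(k) {
    separation_from_points(pts[[pairs[1L, k]]], pts[[pairs[2L, k]]],
                           method = "mc", mc_samples = mc_samples,
                           seed = as.integer(seed) + k)$S
  }, numeric(1))
  mean(s_vals)
}

evo_round <- function(aa, n, lo, hi) {
  stopifnot(all(aa %in% AA_ALPHA), n >= 1L, lo < hi)
  data.frame(aa = aa, n = as.integer(n), lo = lo, hi = hi)
}

#' Default six-round evolution schedule
#'
#' Single-amino-acid perturbations of the current best scale, uniform in
#' the round's interval: rounds 1 and 2 perturb every amino acid (50
#' children each) in the positive `[0.001, 5]` and negative
#' `[-5, -0.001]` interval respectively; round 3 uses 100 children per
#' amino acid with `[0.001, 10]` for E and Y and `[-10, -0.001]` for A,
#' H, F and L; round 4 uses 200 per amino acid with `[0.001, 20]` for E
#' and `[-20, -0.001]` for A and H; round 5 uses 400 children for E in
#' `[0.001, 40]`; round 6 perturbs every amino acid again with 25
#' positive and 25 negative children.  Child counts per round:
#' 1000, 1000, 600, 600, 400, 1000.
#'
#' @return list of six data frames (`aa`, `n`, `lo`, `hi`), one per
#'   round.
#' @export
default_evolution_schedule <- function() {
  list(
    evo1 = evo_round(AA_ALPHA, 50L, 0.001, 5),
    evo2 = evo_round(AA_ALPHA, 50L, -5, -0.001),
    evo3 = rbind(evo_round(c("E", "Y"), 100L, 0.001, 10),
                 evo_round(c("A", "H", "F", "L"), 100L, -10, -0.001)),
    evo4 = rbind(evo_round("E", 200L, 0.001, 20),
                 evo_round(c("A", "H"), 200L, -20, -0.001)),
    evo5 = evo_round("E", 400L, 0.001, 40),
    evo6 = rbind(evo_round(AA_ALPHA, 25L, 0.001, 5),
                 evo_round(AA_ALPHA, 25L, -5, -0.001)))
}

#' Scaled-down evolution schedule
#'
#' Keeps the per-round amino-acid sets and intervals of the default
#' schedule but distributes a fixed number of children per round as
#' evenly as possible across the round's entries, for desk-scale runs.
#'
#' @param children_per_round total children per round (default 50).
#' @return schedule list as in [default_evolution_schedule].
#' @export
scaled_evolution_schedule <- function(children_per_round = 50L) {
  lapply(default_evolution_schedule(), function(rd) {
    m <- nrow(rd)
    base <- children_per_round %/% m
    extra <- children_per_round %% m
    rd$n <- as.integer(base + (seq_len(m) <= extra))
    rd[rd$n > 0L, , drop = FALSE]
  })
}

#' In-silico evolution of a hydrophobicity scale
#'
#' Starts from a population of random scales drawn inside the corpus
#' value interval, then runs the schedule's rounds of single-residue
#' perturbations of the current best scale.  Elitism: the best scale
#' (and its stored fitness) is only replaced by a strictly fitter child,
#' so the best-fitness trajectory never decreases.  After each of the
#' first two rounds, the top 100 children are summarized per amino acid
#' (an influence report used to motivate the later, narrower rounds).
#'
#' @param corpus list of [hydro_scale] objects defining the random-scale
#'   value interval.
#' @param eval_pools evaluation pools for [scale_fitness].
#' @param schedule list of round data frames
#'   (default [default_evolution_schedule]).
#' @param seed integer RNG seed controlling every random draw.
#' @param n_random size of the round-0 random population (default 200).
#' @param combo,propensities,window_len,mc_samples passed to
#'   [scale_fitness].
#' @return an object of class `evolution_state`: `value_interval`,
#'   `best_trajectory` (data frame over rounds 0..length(schedule)),
#'   `best_scale`, `rounds` (per-round child summaries), `influence`
#'   (per-amino-acid report after rounds 1-2), `population` (final
#'   round's children), `fitness` (their fitness values), `rng_seed`.
#' @export
evolve_scale <- function(corpus, eval_pools,
                         schedule = default_evolution_schedule(),
                         seed = 1L, n_random = 200L, combo = 0L,
                         propensities = default_ebss_propensities(),
                         window_len = 10L, mc_samples = 2e4) {
  vals <- unlist(lapply(corpus, function(s) s$values), use.names = FALSE)
  interval <- c(min(vals), max(vals))
  fit1 <- function(s) scale_fitness(s, eval_pools, combo = combo,
                                    propensities = propensities,
                                    window_len = window_len,
                                    mc_samples = mc_samples, seed = seed)
  pop0 <- random_scales(corpus, n = n_random, seed = seed)
  f0 <- vapply(pop0, fit1, numeric(1))
  best_i <- which.max(f0)
  best <- pop0[[best_i]]
  best_fit <- f0[[best_i]]
  traj <- data.frame(round = 0L, scale_id = best$id, fitness = best_fit)
  rounds <- list()
  influence <- list()
  set.seed(as.integer(seed) + 1L)
  pert_seeds <- sample.int(.Machine$integer.max - 1L, length(schedule))
  population <- pop0
  fitness <- f0
  parents <- list()
  for (r in seq_along(schedule)) {
    rd <- schedule[[r]]
    parents[[r]] <- best
    set.seed(pert_seeds[r])
    children <- list()
    meta <- list()
    for (i in seq_len(nrow(rd))) {
      aa <- rd$aa[i]
      deltas <- runif(rd$n[i], rd$lo[i], rd$hi[i])
      for (j in seq_along(deltas)) {
        v <- best$values
        v[aa] <- v[aa] + deltas[j]
        id <- sprintf("evo%d_%s_%03d", r, aa, j)
        ch <- tryCatch(hydro_scale(id, v, category = "evolved"),
                       error = function(e) NULL)  # constant child: skip
        if (is.null(ch)) next
        children[[length(children) + 1L]] <- ch
        meta[[length(meta) + 1L]] <-
          data.frame(id = id, aa = aa, delta = deltas[j])
      }
    }
    meta <- do.call(rbind, meta)
    meta$fitness <- vapply(children, fit1, numeric(1))
    meta$parent_fitness <- best_fit
    if (nrow(meta) && max(meta$fitness) > best_fit) {
      k <- which.max(meta$fitness)
      best <- children[[k]]
      best_fit <- meta$fitness[k]
    }
    traj <- rbind(traj, data.frame(round = r, scale_id = best$id,
                                   fitness = best_fit))
    rounds[[names(schedule)[r] %||% paste0("evo", r)]] <- meta
    if (r <= 2L) {
      top <- meta[order(-meta$fitness), , drop = FALSE]
      top <- top[seq_len(min(100L, nrow(top))), , drop = FALSE]
      influence[[length(influence) + 1L]] <- aggregate(
        cbind(gain = fitness - parent_fitness) ~ aa, data = top, FUN = mean)
    }
    population <- setNames(children, meta$id)
    fitness <- setNames(meta$fitness, meta$id)
  }
  structure(list(value_interval = interval, best_trajectory = traj,
                 best_scale = best, rounds = rounds, parents = parents,
                 influence = influence, population = population,
                 fitness = fitness, rng_seed = as.integer(seed)),
            class = "evolution_state")
}

#' @export
print.evolution_state <- function(x, ...) {
  cat(sprintf("In-silico scale evolution (%d rounds, interval [%.3g, %.3g])\n",
              nrow(x$best_trajectory) - 1L, x$value_interval[1L],
              x$value_interval[2L]))
  print(x$best_trajectory, row.names = FALSE)
  invisible(x)
}

#' Export an evolution run
#'
#' Writes the best-fitness trajectory as TSV and the best scale in the
#' two-column scale dialect.
#'
#' @param state an `evolution_state`.
#' @param trajectory_tsv,scale_file output paths (`NULL` to skip).
#' @return invisibly, the paths.
#' @export
export_evolution <- function(state, trajectory_tsv = NULL, scale_file = NULL) {
  stopifnot(inherits(state, "evolution_state"))
  if (!is.null(trajectory_tsv))
    write.table(state$best_trajectory, trajectory_tsv, sep = "\t",
                quote = FALSE, row.names = FALSE)
  if (!is.null(scale_file)) {
    s <- state$best_scale
    writeLines(c(sprintf("#id: %s", s$id),
                 sprintf("#name: %s", s$name),
                 sprintf("#category: %s", s$category),
                 sprintf("%s\t%.10g", names(s$values), s$values)),
               scale_file)
  }
  invisible(c(trajectory = trajectory_tsv, scale = scale_file))
}
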