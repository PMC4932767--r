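#' Default residue composition profiles for the synthetic generator
#'
#' Sampling probabilities over the 20 amino acids for each segment kind.
#' Transmembrane helices draw from a strongly hydrophobic profile
#' (mass concentrated on L, I, V, F, A, M); transmembrane sheets alternate
#' between that hydrophobic profile (lipid-facing positions) and a polar
#' profile (D, E, K, R, N, Q, S, T; pore-facing positions).  Soluble helix
#' and sheet profiles carry only the mild composition biases seen in
#' globular proteins (helix formers A, E, L, M vs sheet formers V, I, Y,
#' T, F), and coil is a near-uniform background with a small G/P/S/N
#' bias.  All profiles sum to one.
#'
#' @return named list of 20-vectors (`hydrophobic`, `polar`, `tm_helix`,
#'   `s_helix`, `s_sheet`, `coil`), each summing to 1.
#' @export
default_composition_profiles <- function() {
  mk <- function(weights) {
    v <- setNames(rep(1, 20L), AA_ALPHA)
    v[names(weights)] <- weights
    v / sum(v)
  }
  hydrophobic <- setNames(rep(0.2 / 14, 20L), AA_ALPHA)
  hydrophobic[c("L", "I", "V", "F", "A", "M")] <-
    c(0.20, 0.15, 0.15, 0.12, 0.12, 0.06)
  polar <- setNames(rep(0.2 / 12, 20L), AA_ALPHA)
  polar[c("D", "E", "K", "R", "N", "Q", "S", "T")] <- 0.1
  list(hydrophobic = hydrophobic / sum(hydrophobic),
       polar = polar / sum(polar),
       tm_helix = hydrophobic / sum(hydrophobic),
       s_helix = mk(c(A = 1.5, E = 1.4, L = 1.5, M = 1.2, Q = 1.2, K = 1.2)),
       s_sheet = mk(c(V = 1.5, I = 1.4, Y = 1.3, T = 1.2, F = 1.2, W = 1.1)),
       coil = mk(c(G = 1.5, P = 1.5, S = 1.2, N = 1.2, D = 1.1)))
}

SEGMENT_KINDS <- c("tm_helix", "tm_sheet", "s_helix", "s_sheet", "coil")

kind_annotation <- function(kind) {
  switch(kind,
         tm_helix = c(sse = "H", topo = "M"),
         tm_sheet = c(sse = "E", topo = "M"),
         s_helix  = c(sse = "H", topo = "S"),
         s_sheet  = c(sse = "E", topo = "S"),
         coil     = c(sse = "C", topo = "S"),
         stop(sprintf("unknown segment kind '%s'", kind)))
}

kind_pool_label <- function(kind) {
  switch(kind, tm_helix = "tm-helix", tm_sheet = "tm-sheet",
         s_helix = "s-helix", s_sheet = "s-sheet", coil = "random")
}

# Position-dependent sampling profile of a segment kind: transmembrane
# sheets alternate hydrophobic (even offsets, lipid-facing) and polar
# (odd offsets, pore-facing) residues; all other kinds are positionally
# homogeneous.
kind_profile_at <- function(kind, offset, profiles) {
  if (kind == "tm_sheet") {
    if (offset %% 2L == 0L) profiles$hydrophobic else profiles$polar
  } else profiles[[kind]]
}

#' Default segment plan
#'
#' Segment kinds with realistic length bounds: transmembrane helices
#' 18-25 residues (a lipid bilayer crossing), transmembrane strands
#' 10-14, soluble helices 10-20, soluble strands 10-16 and coil linkers
#' 10-20 (the 10-residue floor matches the minimal peptide length used
#' throughout).
#'
#' @return data frame with columns `kind`, `min_len`, `max_len`.
#' @export
default_segment_plan <- function() {
  data.frame(kind = SEGMENT_KINDS,
             min_len = c(18L, 10L, 10L, 10L, 10L),
             max_len = c(25L, 14L, 20L, 16L, 20L))
}

#' Specification for the synthetic protein generator
#'
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @param n_proteins number of proteins to generate.
#' @param segment_plan data frame (`kind`, `min_len`, `max_len`); each
#'   protein concatenates `segments_per_protein` segments drawn uniformly
#'   (with replacement) from its rows, lengths uniform within bounds.
#' @param composition_profiles see [default_composition_profiles]; each
#'   profile must sum to 1 within 1e-9.
#' @param kr_spacer_rate probability that the joint between two
#'   consecutive segments is a tryptic site: the earlier segment's last
#'   residue is replaced by K or R (equiprobable, annotation kept).
#' @param motif_plants optional list of `list(pattern =, kind =, prob =)`
#'   entries: each generated segment of the target kind receives the
#'   pattern (overwriting residues, annotation kept) with the given
#'   probability, at a uniform position.
#' @param segments_per_protein segments per protein (default 5).
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed, n_proteins,
                           segment_plan = default_segment_plan(),
                           composition_profiles = default_composition_profiles(),
                           kr_spacer_rate = 0.9,
                           motif_plants = NULL,
                           segments_per_protein = 5L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n_proteins >= 1L)
  stopifnot(all(c("kind", "min_len", "max_len") %in% names(segment_plan)))
  if (any(!segment_plan$kind %in% SEGMENT_KINDS))
    stop("segment_plan kinds must be among: ", paste(SEGMENT_KINDS, collapse = ", "))
  if (any(segment_plan$min_len > segment_plan$max_len) ||
      any(segment_plan$min_len < 1L))
    stop("infeasible segment plan: need 1 <= min_len <= max_len")
  for (nm in c("hydrophobic", "polar")) {
    pr <- composition_profiles[[nm]]
    if (abs(sum(pr) - 1) > 1e-9)
      stop(sprintf("composition profile '%s' must sum to 1", nm))
  }
  if (kr_spacer_rate < 0 || kr_spacer_rate > 1)
    stop("kr_spacer_rate must be in [0, 1]")
  for (mp in motif_plants) {
    if (mp$prob < 0 || mp$prob > 1) stop("motif planting probability must be in [0, 1]")
    if (!mp$kind %in% SEGMENT_KINDS) stop("motif plant kind unknown")
  }
  structure(list(seed = as.integer(seed), n_proteins = as.integer(n_proteins),
                 segment_plan = segment_plan,
                 composition_profiles = composition_profiles,
                 kr_spacer_rate = kr_spacer_rate,
                 motif_plants = motif_plants,
                 segments_per_protein = as.integer(segments_per_protein)),
            class = "synthetic_spec")
}

sample_segment_seq <- function(kind, len, profiles) {
  vapply(seq_len(len) - 1L, function(off)
    sample(AA_ALPHA, 1L, prob = kind_profile_at(kind, off, profiles)),
    character(1))
}

#' Generate annotated synthetic proteins
#'
#' Each protein is a concatenation of annotated segments drawn from the
#' spec's segment plan; the RNG stream is split deterministically per
#' protein, so generating more proteins never changes earlier ones.  A
#' ground-truth ledger records every segment's coordinates and every
#' planted motif.
#'
#' @param spec a [synthetic_spec].
#' @return list with `proteins` (list of [peptide_record]) and `ledger`
#'   (list of data frames `segments` and `plants`; coordinates are
#'   1-based closed intervals).
#' @export
generate_proteins <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  proto_seeds <- sample.int(.Machine$integer.max - 1L, spec$n_proteins)
  plan <- spec$segment_plan
  profiles <- spec$composition_profiles
  seg_rows <- list()
  plant_rows <- list()
  proteins <- vector("list", spec$n_proteins)
  for (i in seq_len(spec$n_proteins)) {
    set.seed(proto_seeds[i])
    pid <- sprintf("syn%04d", i)
    aa <- character(0); sse <- character(0); topo <- character(0)
    segs <- list()
    for (s in seq_len(spec$segments_per_protein)) {
      row <- plan[sample.int(nrow(plan), 1L), ]
      len <- if (row$min_len == row$max_len) row$min_len else
        sample(row$min_len:row$max_len, 1L)
      ann <- kind_annotation(row$kind)
      from <- length(aa) + 1L
      aa <- c(aa, sample_segment_seq(row$kind, len, profiles))
      sse <- c(sse, rep(ann[["sse"]], len))
      topo <- c(topo, rep(ann[["topo"]], len))
      segs[[s]] <- data.frame(protein = pid, kind = row$kind,
                              start = from, end = length(aa))
      if (s < spec$segments_per_protein &&
          runif(1) < spec$kr_spacer_rate)
        aa[length(aa)] <- sample(c("K", "R"), 1L)
    }
    # motif planting: overwrite residues, keep annotation, record position
    for (mp in spec$motif_plants) {
      k <- nchar(mp$pattern)
      for (sg in segs) {
        if (sg$kind != mp$kind || sg$end - sg$start + 1L < k) next
        if (runif(1) >= mp$prob) next
        pos <- sg$start + sample.int(sg$end - sg$start + 2L - k, 1L) - 1L
        aa[pos:(pos + k - 1L)] <- strsplit(mp$pattern, "")[[1L]]
        plant_rows[[length(plant_rows) + 1L]] <-
          data.frame(protein = pid, pattern = mp$pattern,
                     kind = mp$kind, start = pos, end = pos + k - 1L)
      }
    }
    seg_rows <- c(seg_rows, segs)
    proteins[[i]] <- peptide_record(pid, paste(aa, collapse = ""),
                                    paste(sse, collapse = ""),
                                    paste(topo, collapse = ""))
  }
  list(proteins = proteins,
       ledger = list(
         segments = do.call(rbind, seg_rows),
         plants = if (length(plant_rows)) do.call(rbind, plant_rows) else
           data.frame(protein = character(0), pattern = character(0),
                      kind = character(0), start = integer(0), end = integer(0))))
}

#' Generate a matched pair of peptide pools with controlled separability
#'
#' Draws two pools of standalone annotated peptides whose residue
#' distributions are interpolated between a common mixture and the two
#' kinds' own profiles.  At `separation_strength = 0` both pools sample
#' from the identical position-wise mixture (exchangeable pools, expected
#' separation near zero); at 1 each pool uses its kind's full profile
#' (including the hydrophobic/polar position alternation of transmembrane
#' sheets).
#'
#' @param kind_a,kind_b segment kinds (see [default_segment_plan]).
#' @param n_per_pool peptides per pool; at least 12 so that a
#'   five-dimensional hull (needing >= 6 affinely independent points)
#'   survives envelope stripping.
#' @param separation_strength interpolation weight in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param len_range peptide length bounds (default 14-30).
#' @param profiles composition profiles, see
#'   [default_composition_profiles].
#' @return list with `pool_a`, `pool_b` ([peptide_pool] objects) and a
#'   `ledger` recording the settings.
#' @export
generate_pool_pair <- function(kind_a, kind_b, n_per_pool,
                               separation_strength = 1, seed = 1L,
                               len_range = c(14L, 30L),
                               profiles = default_composition_profiles()) {
  stopifnot(kind_a %in% SEGMENT_KINDS, kind_b %in% SEGMENT_KINDS)
  if (n_per_pool < 12L)
    stop("n_per_pool must be >= 12: a 5-D hull needs at least 6 affinely ",
         "independent points and must survive envelope stripping")
  if (separation_strength < 0 || separation_strength > 1)
    stop("separation_strength must be in [0, 1]")
  set.seed(as.integer(seed))
  s <- separation_strength
  draw_pool <- function(kind, tag) {
    ann <- kind_annotation(kind)
    recs <- lapply(seq_len(n_per_pool), function(i) {
      len <- sample(len_range[1L]:len_range[2L], 1L)
      aa <- vapply(seq_len(len) - 1L, function(off) {
        own <- kind_profile_at(kind, off, profiles)
        mix <- (kind_profile_at(kind_a, off, profiles) +
                kind_profile_at(kind_b, off, profiles)) / 2
        sample(AA_ALPHA, 1L, prob = s * own + (1 - s) * mix)
      }, character(1))
      peptide_record(sprintf("%s_%s%04d", tag, gsub("_", "", kind), i),
                     paste(aa, collapse = ""),
                     strrep(ann[["sse"]], len), strrep(ann[["topo"]], len))
    })
    peptide_pool(kind_pool_label(kind), recs, "structure")
  }
  pool_a <- draw_pool(kind_a, "a")
  pool_b <- draw_pool(kind_b, "b")
  list(pool_a = pool_a, pool_b = pool_b,
       ledger = list(kind_a = kind_a, kind_b = kind_b,
                     n_per_pool = n_per_pool,
                     separation_strength = separation_strength,
                     seed = as.integer(seed), len_range = len_range))
}
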