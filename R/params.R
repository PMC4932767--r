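#' Beta-strand face propensities
#'
#' Positive per-residue propensities for the two faces of a membrane
#' beta-strand: `outward` (lipid-facing) and `inward` (pore-facing).
#' Logarithms are taken downstream, so all entries must be strictly
#' positive.
#'
#' @param outward,inward named numeric 20-vectors over the standard
#'   amino acids, all entries > 0.
#' @return an object of class `ebss_propensities`.
#' @export
ebss_propensities <- function(outward, inward) {
  chk <- function(v, what) {
    if (!all(AA_ALPHA %in% names(v)))
      stop(sprintf("%s propensities must cover all 20 amino acids", what))
    v <- as.numeric(v[AA_ALPHA])
    if (any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("%s propensities must be finite and > 0", what))
    setNames(v, AA_ALPHA)
  }
  structure(list(outward = chk(outward, "outward"),
                 inward = chk(inward, "inward")),
            class = "ebss_propensities")
}

#' Default synthetic beta-strand propensities
#'
#' The published beta-barrel inward/outward frequencies are not bundled;
#' this synthetic stand-in is derived from the bundled Kyte-Doolittle
#' hydropathy values as `outward = exp(+h/4)`, `inward = exp(-h/4)`
#' (normalized to mean 1), which reproduces the qualitative behaviour of
#' a beta-barrel propensity table: hydrophobic residues favour the
#' lipid-facing alternation phase, polar residues the pore-facing one.
#' Published propensity tables can be supplied via
#' [ebss_propensities].
#'
#' @return an `ebss_propensities` object.
#' @export
default_ebss_propensities <- function() {
  kd <- bundled_scales()[["kd"]]$values
  outv <- exp(kd / 4); inv <- exp(-kd / 4)
  ebss_propensities(outv / mean(outv), inv / mean(inv))
}

scale_lookup <- function(window_aa, scale, where = "window") {
  h <- scale$values[window_aa]
  if (anyNA(h))
    stop(sprintf("unknown residue '%s' at %s position %d for scale '%s'",
                 window_aa[which(is.na(h))[1L]], where, which(is.na(h))[1L],
                 scale$id))
  unname(h)
}

#' Average hydrophobicity of a window
#'
#' Mean scale value over the residues, `(1/L) * sum(h)`.
#'
#' @param window amino-acid string (or character vector of residues).
#' @param scale a [hydro_scale].
#' @return a single number.
#' @export
average_hydrophobicity <- function(window, scale) {
  aa <- if (length(window) == 1L) strsplit(window, "")[[1L]] else window
  mean(scale_lookup(aa, scale))
}

#' Hydrophobic moment of a window
#'
#' Length-normalized magnitude of the vector sum of residue
#' hydrophobicities placed at successive angular offsets `delta`:
#' `(1/L) * sqrt((sum h_i sin(i*delta))^2 + (sum h_i cos(i*delta))^2)`
#' with `i = 0..L-1`.  `delta = 100` probes alpha-helical periodicity,
#' `delta = 180` beta-strand alternation.
#'
#' @param window amino-acid string or residue vector.
#' @param scale a [hydro_scale].
#' @param delta angle between successive residues, in degrees.
#' @return a single non-negative number.
#' @export
hydrophobic_moment <- function(window, scale, delta) {
  aa <- if (length(window) == 1L) strsplit(window, "")[[1L]] else window
  h <- scale_lookup(aa, scale)
  th <- (seq_along(h) - 1L) * delta * pi / 180
  sqrt(sum(h * sin(th))^2 + sum(h * cos(th))^2) / length(h)
}

#' Alternating hydrophobicity of a window
#'
#' Length-normalized absolute alternating sum
#' `(1/L) * |sum (-1)^i h_i|`, capturing the polar/apolar face
#' alternation of membrane beta-strands.  Identical to the hydrophobic
#' moment at `delta = 180` degrees.
#'
#' @inheritParams average_hydrophobicity
#' @return a single non-negative number.
#' @export
alternating_hydrophobicity <- function(window, scale) {
  aa <- if (length(window) == 1L) strsplit(window, "")[[1L]] else window
  if (length(aa) < 2L) stop("alternating hydrophobicity needs a window of length >= 2")
  h <- scale_lookup(aa, scale)
  abs(sum(h * c(1, -1)[(seq_along(h) - 1L) %% 2L + 1L])) / length(h)
}

#' Exact beta-strand score (EBSS) of a window
#'
#' Scores the probability that a window of at least 10 residues is a
#' transmembrane beta-strand: residues are assigned alternately to the
#' outward (lipid-facing) and inward (pore-facing) face, and the score is
#' the mean log propensity of each residue on its face, maximized over
#' the two possible phases.
#'
#' @param window amino-acid string or residue vector, length >= 10.
#' @param propensities an [ebss_propensities] object.
#' @return a single number (0 when all propensities are 1).
#' @export
ebss <- function(window, propensities) {
  stopifnot(inherits(propensities, "ebss_propensities"))
  aa <- if (length(window) == 1L) strsplit(window, "")[[1L]] else window
  L <- length(aa)
  if (L < 10L)
    stop("EBSS requires a window of at least 10 amino acids")
  po <- propensities$outward[aa]
  if (anyNA(po))
    stop(sprintf("unknown residue '%s' at window position %d",
                 aa[which(is.na(po))[1L]], which(is.na(po))[1L]))
  lo <- log(unname(po))
  li <- log(unname(propensities$inward[aa]))
  even <- (seq_len(L) - 1L) %% 2L == 0L
  phase0 <- sum(lo[even]) + sum(li[!even])
  phase1 <- sum(li[even]) + sum(lo[!even])
  max(phase0, phase1) / L
}

# All five parameters for every sliding window of a residue vector,
# returned as a (n_windows x 5) matrix in fixed parameter order.
window_parameter_matrix <- function(h, lo, li, window_len) {
  L <- window_len
  n <- length(h)
  W <- n - L + 1L
  idx <- embed(seq_len(n), L)[, L:1, drop = FALSE]   # W x L window indices
  Hw <- matrix(h[idx], nrow = W)
  alt_kernel <- c(1, -1)[(seq_len(L) - 1L) %% 2L + 1L]
  th <- (seq_len(L) - 1L) * 100 * pi / 180
  avg <- rowSums(Hw) / L
  alternating <- abs(Hw %*% alt_kernel) / L
  m_alpha <- sqrt((Hw %*% sin(th))^2 + (Hw %*% cos(th))^2) / L
  m_beta <- alternating                               # moment at 180 degrees
  even <- as.numeric((seq_len(L) - 1L) %% 2L == 0L)
  LOw <- matrix(lo[idx], nrow = W)
  LIw <- matrix(li[idx], nrow = W)
  ph0 <- LOw %*% even + LIw %*% (1 - even)
  ph1 <- LIw %*% even + LOw %*% (1 - even)
  eb <- pmax(ph0, ph1) / L
  cbind(ebss = eb, alternating = alternating, moment_alpha = m_alpha,
        moment_beta = m_beta, average = avg)
}

#' Sliding-window parameter extrema of a peptide
#'
#' Computes the five hydrophobicity parameters (EBSS, alternating
#' hydrophobicity, hydrophobic moment at 100 degrees, hydrophobic moment
#' at 180 degrees, average hydrophobicity) in every sliding window of
#' `window_len` residues (step 1) and records the per-peptide maximum and
#' minimum of each, giving the ten extrema indexed 0-9:
#' 0/1 max/min EBSS, 2/3 max/min alternating, 4/5 max/min moment-alpha,
#' 6/7 max/min moment-beta, 8/9 max/min average hydrophobicity.
#'
#' @param peptide a [peptide_record] (or plain amino-acid string).
#' @param scale a [hydro_scale].
#' @param propensities an [ebss_propensities] object (default
#'   [default_ebss_propensities]).
#' @param window_len sliding-window length (default 10).
#' @return an object of class `parameter_vector`: named numeric of length
#'   10 with attributes `peptide_id` and `scale_id`.
#' @export
window_extrema <- function(peptide, scale,
                           propensities = default_ebss_propensities(),
                           window_len = 10L) {
  seqstr <- if (inherits(peptide, "peptide_record")) peptide$sequence else peptide
  pid <- if (inherits(peptide, "peptide_record")) peptide$id else NA_character_
  aa <- strsplit(seqstr, "")[[1L]]
  if (length(aa) < window_len)
    stop(sprintf("peptide%s of length %d is shorter than the window length %d",
                 if (is.na(pid)) "" else sprintf(" '%s'", pid),
                 length(aa), window_len))
  h <- scale_lookup(aa, scale, where = "peptide")
  lo <- log(propensities$outward[aa])
  li <- log(propensities$inward[aa])
  P <- window_parameter_matrix(h, unname(lo), unname(li), window_len)
  ext <- as.vector(rbind(apply(P, 2L, max), apply(P, 2L, min)))
  names(ext) <- EXTREMA_NAMES
  structure(ext, peptide_id = pid, scale_id = scale$id,
            class = c("parameter_vector", "numeric"))
}

#' Parameter extrema for a whole pool
#'
#' @param pool a [peptide_pool].
#' @inheritParams window_extrema
#' @return numeric matrix (peptides x 10 extrema), rows named by peptide
#'   id, with attribute `scale_id`.
#' @export
pool_extrema <- function(pool, scale,
                         propensities = default_ebss_propensities(),
                         window_len = 10L) {
  stopifnot(inherits(pool, "peptide_pool"))
  M <- t(vapply(pool$records, function(r)
    as.numeric(window_extrema(r, scale, propensities, window_len)),
    numeric(10L)))
  dimnames(M) <- list(vapply(pool$records, function(r) r$id, character(1)),
                      EXTREMA_NAMES)
  attr(M, "scale_id") <- scale$id
  M
}

#' Select a 5-D parameter combination
#'
#' Of the ten per-peptide extrema, a combination mask chooses for each of
#' the five parameters either its maximum or its minimum, yielding a
#' point in five dimensions.  Bit `k` of `combo` (0 = least significant,
#' parameter order EBSS, alternating, moment-alpha, moment-beta, average)
#' selects the maximum when 0 and the minimum when 1; the 32 masks 0-31
#' enumerate all combinations.
#'
#' @param extrema a `parameter_vector`, or a matrix of pool extrema from
#'   [pool_extrema].
#' @param combo integer mask in `0..31`.
#' @return numeric vector of length 5 (or matrix peptides x 5).
#' @export
select_combination <- function(extrema, combo) {
  if (length(combo) != 1L || is.na(combo) || combo < 0 || combo > 31 ||
      combo != floor(combo))
    stop("combo mask must be a single integer in 0..31")
  bits <- bitwAnd(bitwShiftR(as.integer(combo), 0:4), 1L)
  cols <- 2L * (0:4) + bits + 1L          # column in the 10-extrema layout
  if (is.matrix(extrema)) {
    out <- extrema[, cols, drop = FALSE]
    colnames(out) <- PARAM_NAMES
    out
  } else {
    setNames(as.numeric(extrema)[cols], PARAM_NAMES)
  }
}

#' Write a pool's parameter extrema as TSV
#'
#' @param extrema matrix from [pool_extrema].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_extrema <- function(extrema, path) {
  df <- data.frame(peptide_id = rownames(extrema),
                   scale_id = attr(extrema, "scale_id"),
                   as.data.frame(extrema), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
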