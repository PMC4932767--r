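#' Construct an annotated peptide record
#'
#' A peptide (or whole protein) with per-residue secondary-structure
#' annotation over `{H, E, C}` (helix, sheet, coil) and membrane topology
#' over `{M, S}` (membrane, soluble).  All three strings have equal
#' length.
#'
#' @param id record identifier.
#' @param sequence amino-acid string over the 20 standard letters.
#' @param sse secondary-structure string over `H`, `E`, `C`.
#' @param topo topology string over `M`, `S`.
#' @return an object of class `peptide_record`.
#' @export
peptide_record <- function(id, sequence, sse, topo) {
  n <- nchar(sequence)
  if (n < 1L || nchar(sse) != n || nchar(topo) != n)
    stop(sprintf("record '%s': sequence, sse and topo must have equal length >= 1", id))
  if (grepl(sprintf("[^%s]", paste(AA_ALPHA, collapse = "")), sequence))
    stop(sprintf("record '%s': sequence contains non-standard letters", id))
  if (grepl("[^HEC]", sse))
    stop(sprintf("record '%s': sse letters must be H, E or C", id))
  if (grepl("[^MS]", topo))
    stop(sprintf("record '%s': topo letters must be M or S", id))
  structure(list(id = id, sequence = sequence, sse = sse, topo = topo),
            class = "peptide_record")
}

#' @export
print.peptide_record <- function(x, ...) {
  cat(sprintf(">%s (%d aa)\n%s\n%s\n%s\n", x$id, nchar(x$sequence),
              x$sequence, x$sse, x$topo))
  invisible(x)
}

rec_slice <- function(rec, from, to, id = NULL) {
  peptide_record(if (is.null(id)) sprintf("%s_%d_%d", rec$id, from, to) else id,
                 substr(rec$sequence, from, to),
                 substr(rec$sse, from, to),
                 substr(rec$topo, from, to))
}

#' Dissect a protein into uniform secondary-structure segments
#'
#' Maximal runs of one SSE letter become candidate peptides.  A run whose
#' residues are all soluble maps to `s-helix`, `s-sheet` or `random`; a
#' run containing any membrane residue maps to `tm-helix` or `tm-sheet`.
#' Transmembrane runs shorter than 10 residues are extended with flanking
#' residues of the parent sequence (alternating right then left, the other
#' side absorbing the deficit at a sequence end) until they reach length
#' 10; soluble runs shorter than 10 are discarded.  Membrane coil runs
#' have no pool and are dropped.
#'
#' @param protein a [peptide_record].
#' @param min_len minimum emitted peptide length (default 10).
#' @return data frame-free list of `(record, label)` pairs; may be empty.
#' @export
dissect_sse_segments <- function(protein, min_len = 10L) {
  stopifnot(inherits(protein, "peptide_record"))
  n <- nchar(protein$sequence)
  sse <- strsplit(protein$sse, "")[[1L]]
  topo <- strsplit(protein$topo, "")[[1L]]
  runs <- rle(sse)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in seq_along(starts)) {
    from <- starts[k]; to <- ends[k]
    is_tm <- any(topo[from:to] == "M")
    kind <- runs$values[k]
    if (is_tm) {
      if (kind == "C") next                      # no TM-coil pool
      label <- if (kind == "H") "tm-helix" else "tm-sheet"
      # extend short TM runs with flanking parent residues to min_len
      add_right <- TRUE
      while (to - from + 1L < min_len) {
        if (add_right && to < n) to <- to + 1L
        else if (from > 1L) from <- from - 1L
        else if (to < n) to <- to + 1L
        else break
        add_right <- !add_right
      }
      if (to - from + 1L < min_len) next         # whole protein too short
    } else {
      if (to - from + 1L < min_len) next
      label <- switch(kind, H = "s-helix", E = "s-sheet", C = "random")
    }
    out[[length(out) + 1L]] <- list(record = rec_slice(protein, from, to),
                                    label = label)
  }
  out
}

#' In-silico tryptic digest
#'
#' Cleaves after every lysine (K) and arginine (R).  The fragments
#' partition the sequence in order and the annotation strings are sliced
#' in register; no length filtering is applied here.
#'
#' @param protein a [peptide_record].
#' @return list of [peptide_record] fragments.
#' @export
tryptic_digest <- function(protein) {
  stopifnot(inherits(protein, "peptide_record"))
  aa <- strsplit(protein$sequence, "")[[1L]]
  n <- length(aa)
  cuts <- which(aa %in% c("K", "R"))
  cuts <- cuts[cuts < n]
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  lapply(seq_along(starts), function(k)
    rec_slice(protein, starts[k], ends[k],
              id = sprintf("%s_t%d", protein$id, k)))
}

#' Classify a digest fragment by secondary-structure content
#'
#' Implements the digest pool rules: fragments shorter than 10 residues
#' are unclassified (`NA`).  Fragments with any membrane residue are
#' pooled as `krtm-helix`/`krtm-sheet` by the majority SSE among membrane
#' residues (tie: helix); krtm takes precedence over all other labels.
#' Otherwise, if one SSE exceeds the dominance fraction it yields
#' `dc-`(continuous, one gap-free block) or `dd-`(discontinuous) helix,
#' sheet or random; if exactly two SSE letters occur the label is the
#' missing one (`no-helix`, `no-sheet`, `no-random`); fragments with all
#' three SSEs and no dominant one fall into `all`.
#'
#' @param frag a [peptide_record].
#' @param dominance strict dominance fraction (default 0.70: a fragment at
#'   exactly 70 percent is not dominated).
#' @return a pool label, or `NA_character_` for fragments below length 10.
#' @export
classify_fragment <- function(frag, dominance = 0.70) {
  stopifnot(inherits(frag, "peptide_record"))
  n <- nchar(frag$sequence)
  if (n < 10L) return(NA_character_)
  sse <- strsplit(frag$sse, "")[[1L]]
  topo <- strsplit(frag$topo, "")[[1L]]
  if (any(topo == "M")) {
    m_sse <- sse[topo == "M"]
    nh <- sum(m_sse == "H"); ne <- sum(m_sse == "E")
    return(if (nh >= ne) "krtm-helix" else "krtm-sheet")
  }
  frac <- c(H = sum(sse == "H"), E = sum(sse == "E"), C = sum(sse == "C")) / n
  word <- c(H = "helix", E = "sheet", C = "random")
  dom <- names(frac)[frac > dominance]
  if (length(dom) == 1L) {
    runs <- rle(sse)
    contiguous <- sum(runs$values == dom) == 1L
    return(paste0(if (contiguous) "dc-" else "dd-", word[[dom]]))
  }
  present <- names(frac)[frac > 0]
  if (length(present) == 2L) {
    absent <- setdiff(names(frac), present)
    return(paste0("no-", word[[absent]]))
  }
  "all"
}

#' Assemble the canonical peptide pools from annotated proteins
#'
#' Runs both pool-building strategies on every protein: secondary-structure
#' dissection ([dissect_sse_segments]) and in-silico tryptic digestion
#' ([tryptic_digest] followed by [classify_fragment]).  Peptides shorter
#' than `min_len` are dropped and exact duplicate sequences within a pool
#' are removed.
#'
#' @param proteins list of [peptide_record] objects.
#' @param dominance passed to [classify_fragment].
#' @param min_len minimum peptide length (default 10).
#' @return an object of class `peptide_pools`: a named list of pools (each
#'   with `label`, `strategy`, `records`) plus a `summary` data frame
#'   (pool, strategy, n_peptides, mean_length).
#' @export
assemble_pools <- function(proteins, dominance = 0.70, min_len = 10L) {
  if (!length(proteins)) warning("no input proteins: all pools are empty")
  buckets <- setNames(vector("list", length(ALL_POOL_LABELS)), ALL_POOL_LABELS)
  for (p in proteins) {
    for (seg in dissect_sse_segments(p, min_len = min_len))
      buckets[[seg$label]] <- c(buckets[[seg$label]], list(seg$record))
    for (fr in tryptic_digest(p)) {
      if (nchar(fr$sequence) < min_len) next
      lab <- classify_fragment(fr, dominance = dominance)
      if (!is.na(lab))
        buckets[[lab]] <- c(buckets[[lab]], list(fr))
    }
  }
  pools <- lapply(ALL_POOL_LABELS, function(lab) {
    recs <- buckets[[lab]]
    if (length(recs)) {
      seqs <- vapply(recs, function(r) r$sequence, character(1))
      recs <- recs[!duplicated(seqs)]
    }
    peptide_pool(lab, recs,
                 strategy = if (lab %in% STRUCTURE_POOL_LABELS) "structure" else "digest")
  })
  names(pools) <- ALL_POOL_LABELS
  structure(c(pools, list(summary = pool_summary(pools))),
            class = "peptide_pools")
}

#' Construct a peptide pool
#'
#' @param label pool label (one of the 17 canonical labels, or custom).
#' @param records list of [peptide_record] objects.
#' @param strategy `"structure"` or `"digest"`.
#' @return an object of class `peptide_pool`.
#' @export
peptide_pool <- function(label, records, strategy = c("structure", "digest")) {
  strategy <- match.arg(strategy)
  structure(list(label = label, strategy = strategy, records = records),
            class = "peptide_pool")
}

#' @export
print.peptide_pool <- function(x, ...) {
  lens <- vapply(x$records, function(r) nchar(r$sequence), integer(1))
  cat(sprintf("Peptide pool '%s' (%s strategy): %d peptide(s), mean length %.1f\n",
              x$label, x$strategy, length(x$records),
              if (length(lens)) mean(lens) else NA_real_))
  invisible(x)
}

pool_summary <- function(pools) {
  do.call(rbind, lapply(pools, function(p) {
    lens <- vapply(p$records, function(r) nchar(r$sequence), integer(1))
    data.frame(pool = p$label, strategy = p$strategy,
               n_peptides = length(p$records),
               mean_length = if (length(lens)) mean(lens) else NA_real_)
  }))
}

#' @export
print.peptide_pools <- function(x, ...) {
  cat("Peptide pools\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Read annotated proteins
#'
#' Either a FASTA file plus an annotation TSV (columns `id`, `sse`,
#' `topo`), or a single combined TSV with columns `id`, `sequence`,
#' `sse`, `topo`.
#'
#' @param fasta path to a FASTA file, or `NULL` when `tsv` is combined.
#' @param tsv path to the annotation (or combined) TSV.
#' @return list of [peptide_record] objects.
#' @export
read_annotated_fasta <- function(fasta = NULL, tsv) {
  ann <- read.delim(tsv, stringsAsFactors = FALSE)
  if (is.null(fasta)) {
    stopifnot(all(c("id", "sequence", "sse", "topo") %in% names(ann)))
    seqs <- setNames(ann$sequence, ann$id)
  } else {
    stopifnot(all(c("id", "sse", "topo") %in% names(ann)))
    ss <- Biostrings::readAAStringSet(fasta)
    seqs <- setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  }
  lapply(seq_len(nrow(ann)), function(i) {
    id <- ann$id[i]
    if (is.null(seqs[[id]])) stop(sprintf("no sequence for annotated id '%s'", id))
    peptide_record(id, seqs[[id]], ann$sse[i], ann$topo[i])
  })
}

#' Write pools to per-pool FASTA files plus a summary TSV
#'
#' @param pools a `peptide_pools` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the summary TSV path.
#' @export
write_pools <- function(pools, dir) {
  stopifnot(inherits(pools, "peptide_pools"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (lab in ALL_POOL_LABELS) {
    p <- pools[[lab]]
    if (!length(p$records)) next
    ss <- Biostrings::AAStringSet(vapply(p$records, function(r) r$sequence,
                                         character(1)))
    names(ss) <- vapply(p$records, function(r) r$id, character(1))
    Biostrings::writeXStringSet(ss, file.path(dir, paste0(lab, ".fasta")))
  }
  out <- file.path(dir, "pool_summary.tsv")
  write.table(pools$summary, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
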