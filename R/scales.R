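#' Construct a hydrophobicity scale
#'
#' A hydrophobicity scale assigns every one of the 20 standard amino acids
#' a real-valued (dimensionless) hydrophobicity.  Values are stored in
#' fixed alphabetical amino-acid order.  Constant scales are rejected:
#' they carry no information and make the correlation-based dissimilarity
#' undefined.
#'
#' @param id short unique identifier.
#' @param values named numeric vector with exactly the 20 standard
#'   one-letter codes, each finite.
#' @param name free-text description.
#' @param category one of `"experimental"`, `"calculated"`, `"improved"`,
#'   `"inverted"`, `"random"`, `"evolved"`.
#' @return an object of class `hydro_scale`.
#' @export
hydro_scale <- function(id, values, name = id, category = "experimental") {
  category <- match.arg(category,
    c("experimental", "calculated", "improved", "inverted", "random", "evolved"))
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("scale id must be a non-empty string")
  aa <- names(values)
  missing_aa <- setdiff(AA_ALPHA, aa)
  extra <- setdiff(aa, AA_ALPHA)
  if (length(extra))
    stop(sprintf("scale '%s': unknown amino-acid code(s): %s",
                 id, paste(extra, collapse = ", ")))
  if (length(missing_aa))
    stop(sprintf("scale '%s': %d of 20 amino acids present (missing %s)",
                 id, 20L - length(missing_aa), paste(missing_aa, collapse = ", ")))
  v <- as.numeric(values[AA_ALPHA])
  if (anyNA(v) || any(!is.finite(v)))
    stop(sprintf("scale '%s': all 20 values must be finite numbers", id))
  if (length(unique(v)) < 2L)
    stop(sprintf("scale '%s': degenerate (constant) scale rejected", id))
  structure(list(id = id, name = name, category = category,
                 values = setNames(v, AA_ALPHA)),
            class = "hydro_scale")
}

#' @export
print.hydro_scale <- function(x, ...) {
  cat(sprintf("Hydrophobicity scale '%s' (%s)\n  %s\n", x$id, x$category, x$name))
  print(round(x$values, 3))
  invisible(x)
}

is_hydro_scale <- function(x) inherits(x, "hydro_scale")

#' Parse hydrophobicity scale tables
#'
#' Reads one or more scales from either the AAindex flat-file dialect
#' (`H`/`D` lines and an `I` block of 20 values in AAindex residue order,
#' records terminated by `//`) or a plain two-column dialect
#' (`#id:` header lines, then `AA<TAB>value` rows; optional `#name:` and
#' `#category:` metadata lines).
#'
#' @param source path to a file, or a character vector of lines.
#' @param dialect `"aaindex_flat"` or `"two_column"`.
#' @return a named list of [hydro_scale] objects (names = ids).
#' @export
parse_scale_table <- function(source, dialect = c("two_column", "aaindex_flat")) {
  dialect <- match.arg(dialect)
  lines <- if (length(source) == 1L && file.exists(source))
    readLines(source, warn = FALSE) else as.character(source)
  scales <- if (dialect == "two_column")
    parse_two_column(lines) else parse_aaindex_flat(lines)
  ids <- vapply(scales, function(s) s$id, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate scale id(s): %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  setNames(scales, ids)
}

parse_two_column <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  starts <- grep("^#id:", lines)
  if (!length(starts)) stop("two_column dialect: no '#id:' header found")
  bounds <- c(starts, length(lines) + 1L)
  lapply(seq_along(starts), function(k) {
    blk <- lines[bounds[k]:(bounds[k + 1L] - 1L)]
    id <- trimws(sub("^#id:", "", blk[1L]))
    meta <- blk[startsWith(blk, "#")][-1L]
    name <- id
    category <- "experimental"
    for (m in meta) {
      if (startsWith(m, "#name:")) name <- trimws(sub("^#name:", "", m))
      if (startsWith(m, "#category:")) category <- trimws(sub("^#category:", "", m))
    }
    rows <- blk[!startsWith(blk, "#")]
    parts <- strsplit(rows, "[\t ]+")
    aa <- vapply(parts, `[`, character(1), 1L)
    txt <- vapply(parts, `[`, character(1), 2L)
    val <- suppressWarnings(as.numeric(txt))
    if (anyNA(val))
      stop(sprintf("scale '%s': non-numeric value '%s' for amino acid %s",
                   id, txt[which(is.na(val))[1L]], aa[which(is.na(val))[1L]]))
    hydro_scale(id, setNames(val, aa), name = name, category = category)
  })
}

parse_aaindex_flat <- function(lines) {
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "//")))
  recs <- Filter(function(r) any(grepl("^H ", r)), recs)
  if (!length(recs)) stop("aaindex_flat dialect: no 'H ' record found")
  lapply(recs, function(r) {
    id <- trimws(sub("^H ", "", r[grep("^H ", r)[1L]]))
    dline <- grep("^D ", r)
    name <- if (length(dline)) trimws(sub("^D ", "", r[dline[1L]])) else id
    iline <- grep("^I ", r)
    if (!length(iline))
      stop(sprintf("scale '%s': no 'I' value block", id))
    numtxt <- unlist(strsplit(trimws(r[iline[1L] + 1:2]), "[ \t]+"))
    val <- suppressWarnings(as.numeric(numtxt))
    if (length(val) != 20L || anyNA(val))
      stop(sprintf("scale '%s': expected 20 numeric values in the I block", id))
    hydro_scale(id, setNames(val, AA_AAINDEX), name = name)
  })
}

#' Invert a hydrophobicity scale
#'
#' Negates every amino-acid value.  An inverted scale is perfectly
#' anti-correlated with its original (Pearson r = -1), so the two have
#' correlation dissimilarity 0 and always fall into the same cluster.
#'
#' @param s a [hydro_scale].
#' @return the inverted scale, id suffixed `"_inv"`, category `"inverted"`.
#' @export
reverse_scale <- function(s) {
  stopifnot(is_hydro_scale(s))
  id <- if (endsWith(s$id, "_inv")) sub("_inv$", "", s$id) else paste0(s$id, "_inv")
  hydro_scale(id, -s$values, name = paste("inverted:", s$name),
              category = "inverted")
}

#' Min-max normalize a scale to the unit interval
#'
#' Affine map `(x - min) / (max - min)`; the least hydrophobic residue
#' becomes 0, the most hydrophobic 1, and the residue ranking is
#' preserved.
#'
#' @param s a [hydro_scale].
#' @return normalized scale (id suffixed `"_mm"` unless already normalized).
#' @export
minmax_normalize <- function(s) {
  stopifnot(is_hydro_scale(s))
  v <- s$values
  rng <- range(v)
  w <- (v - rng[1L]) / (rng[2L] - rng[1L])
  if (isTRUE(all.equal(unname(v), unname(w)))) return(s)
  hydro_scale(paste0(sub("_mm$", "", s$id), "_mm"), w,
              name = paste("min-max normalized:", s$name),
              category = s$category)
}

#' Correlation dissimilarity between two scales
#'
#' `sqrt(1 - r^2)` with `r` the Pearson correlation of the 20 paired
#' amino-acid values.  The square makes the measure sign-blind: a scale
#' and its inversion (r = -1) have dissimilarity 0, scales carrying
#' unrelated information (r = 0) have dissimilarity 1.
#'
#' @param a,b [hydro_scale] objects.
#' @return a number in `[0, 1]`.
#' @export
scale_dissimilarity <- function(a, b) {
  stopifnot(is_hydro_scale(a), is_hydro_scale(b))
  r <- cor(a$values, b$values)
  v <- max(0, 1 - r^2)
  if (v < 1e-12) v <- 0   # |r| = 1 up to rounding: exactly collinear scales
  sqrt(v)
}

#' Pairwise dissimilarity matrix of a scale set
#'
#' @param scales list of [hydro_scale] objects.
#' @return symmetric matrix with zero diagonal, entries in `[0, 1]`.
#' @export
dissimilarity_matrix <- function(scales) {
  ids <- vapply(scales, function(s) s$id, character(1))
  V <- vapply(scales, function(s) s$values, numeric(20L))
  R <- cor(V)
  V2 <- pmax(1 - R^2, 0)        # pmax keeps the matrix shape of its first arg
  V2[V2 < 1e-12] <- 0           # snap |r| = 1 rounding noise to exact zero
  D <- sqrt(V2)
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  D
}

cluster_letter <- function(i) {
  # a..z, then aa, ab, ... (base-26 with letters)
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]
    s <- ""
    while (n > 0) {
      r <- (n - 1L) %% 26L
      s <- paste0(letters[r + 1L], s)
      n <- (n - 1L) %/% 26L
    }
    out[k] <- s
  }
  out
}

upgma_linkage <- function(D, ids) {
  # Average-linkage agglomeration with deterministic tie-breaking: among
  # equally close pairs, merge the one whose (sorted) representative ids
  # are lexicographically smallest.  Heights are join heights (= half the
  # merge-time average distance), giving an ultrametric tree.
  n <- nrow(D)
  size <- rep(1L, n)
  rep_id <- ids                      # lexicographically smallest member id
  code <- -seq_len(n)                # hclust convention
  active <- seq_len(n)
  W <- D
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- NULL
    bd <- Inf
    for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
      a <- active[i]; b <- active[j]
      dij <- W[a, b]
      if (dij < bd - 1e-15) {
        bd <- dij; best <- c(a, b)
      } else if (abs(dij - bd) <= 1e-15) {
        cand <- sort(c(rep_id[a], rep_id[b]))
        cur <- sort(c(rep_id[best[1L]], rep_id[best[2L]]))
        if (cand[1L] < cur[1L] || (cand[1L] == cur[1L] && cand[2L] < cur[2L]))
          best <- c(a, b)
      }
    }
    a <- best[1L]; b <- best[2L]
    merge[step, ] <- sort(c(code[a], code[b]))
    height[step] <- bd / 2
    # average-linkage update into slot a
    for (k in active) if (k != a && k != b)
      W[a, k] <- W[k, a] <- (size[a] * W[a, k] + size[b] * W[b, k]) /
        (size[a] + size[b])
    size[a] <- size[a] + size[b]
    rep_id[a] <- min(rep_id[a], rep_id[b])
    code[a] <- step
    active <- setdiff(active, b)
  }
  list(merge = merge, height = height)
}

hclust_leaf_order <- function(merge) {
  n <- nrow(merge) + 1L
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1L]), rec(merge[node, 2L]))
  }
  rec(n - 1L)
}

#' UPGMA clustering of hydrophobicity scales
#'
#' Builds an average-linkage (UPGMA) ultrametric tree over the pairwise
#' correlation dissimilarities and cuts it into clusters: two scales share
#' a cluster when their join height is at most `threshold`.  Cluster
#' labels `a`, `b`, ... are assigned in the tree's left-to-right leaf
#' order.
#'
#' @param scales list of at least two [hydro_scale] objects.
#' @param threshold join-height cut in `(0, 1)`; default 0.05.
#' @return an object of class `scale_clustering` with fields `scale_ids`,
#'   `dissimilarity`, `hclust`, `tree` (an [ape::phylo]), `clusters`
#'   (named character vector) and `threshold`.
#' @export
upgma_cluster <- function(scales, threshold = 0.05) {
  if (length(scales) < 2L) stop("need at least two scales to cluster")
  upgma_from_matrix(dissimilarity_matrix(scales), threshold)
}

# UPGMA tree + threshold cut over an arbitrary symmetric dissimilarity
# matrix with unique row names.
upgma_from_matrix <- function(D, threshold = 0.05) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  ids <- rownames(D)
  lk <- upgma_linkage(D, ids)
  hc <- structure(list(merge = lk$merge, height = lk$height,
                       order = hclust_leaf_order(lk$merge), labels = ids,
                       method = "average", dist.method = "sqrt(1-r^2)",
                       call = match.call()),
                  class = "hclust")
  # cut: union leaves over merges whose join height <= threshold
  n <- length(ids)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  members <- c(as.list(seq_len(n)), vector("list", n - 1L))
  for (s in seq_len(n - 1L)) {
    kids <- lk$merge[s, ]
    mem <- unlist(lapply(kids, function(k) if (k < 0) -k else members[[n + k]]))
    members[[n + s]] <- mem
    if (lk$height[s] <= threshold) {
      r <- vapply(mem, find, integer(1))
      parent[r] <- r[1L]
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  # label clusters in leaf order of the tree
  lab <- character(n)
  nxt <- 1L
  seen <- integer(0)
  for (leaf in hc$order) {
    r <- root[leaf]
    if (!r %in% seen) { seen <- c(seen, r); }
  }
  cl_of_root <- setNames(cluster_letter(seq_along(seen)), seen)
  lab <- unname(cl_of_root[as.character(root)])
  structure(list(scale_ids = ids, dissimilarity = D, hclust = hc,
                 tree = ape::as.phylo(hc),
                 clusters = setNames(lab, ids), threshold = threshold),
            class = "scale_clustering")
}

#' @export
print.scale_clustering <- function(x, ...) {
  k <- length(unique(x$clusters))
  cat(sprintf("UPGMA clustering of %d scales at join-height threshold %g: %d cluster(s)\n",
              length(x$scale_ids), x$threshold, k))
  print(x$clusters)
  invisible(x)
}

#' @export
plot.scale_clustering <- function(x, ...) {
  plot(x$hclust, hang = -1, xlab = "", sub = "",
       main = "UPGMA tree of hydrophobicity scales", ...)
  invisible(x)
}

#' Export a scale clustering
#'
#' Writes the ultrametric tree as Newick (branch lengths are join-height
#' differences) and the cluster assignment as a two-column TSV.
#'
#' @param clustering a `scale_clustering`.
#' @param newick,tsv output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
export_clustering <- function(clustering, newick = NULL, tsv = NULL) {
  stopifnot(inherits(clustering, "scale_clustering"))
  if (!is.null(newick))
    ape::write.tree(clustering$tree, file = newick)
  if (!is.null(tsv))
    write.table(data.frame(scale_id = clustering$scale_ids,
                           cluster_label = unname(clustering$clusters)),
                tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(newick = newick, tsv = tsv))
}

#' Amino-acid distance analysis of a scale
#'
#' On the min-max normalized scale, computes the 20 x 20 matrix of
#' absolute value differences and flags residue pairs that are nearly
#' interchangeable (difference below `low`) or span almost the whole
#' scale (difference above `high`).
#'
#' @param s a [hydro_scale].
#' @param low,high flag thresholds on the normalized (0-1) scale.
#' @return list with `matrix` (symmetric, zero diagonal), and data frames
#'   `similar` and `distant` of flagged unordered pairs.
#' @export
aa_difference_matrix <- function(s, low = 0.1, high = 0.9) {
  v <- minmax_normalize(s)$values
  M <- abs(outer(v, v, "-"))
  dimnames(M) <- list(AA_ALPHA, AA_ALPHA)
  ut <- which(upper.tri(M), arr.ind = TRUE)
  pairs <- data.frame(aa1 = AA_ALPHA[ut[, 1L]], aa2 = AA_ALPHA[ut[, 2L]],
                      difference = M[ut])
  list(matrix = M,
       similar = pairs[pairs$difference < low, , drop = FALSE],
       distant = pairs[pairs$difference > high, , drop = FALSE])
}

#' Bundled reference hydrophobicity scales
#'
#' A small set of widely used public scales (Kyte-Doolittle hydropathy,
#' Hopp-Woods hydrophilicity, the Eisenberg consensus scale and the
#' Engelman GES transfer free energies) shipped as plain-text fixtures in
#' the two-column dialect.  Larger scale corpora are user-supplied input.
#'
#' @return named list of [hydro_scale] objects.
#' @export
bundled_scales <- function() {
  path <- system.file("extdata", "bundled_scales.txt", package = "hydrosep",
                      mustWork = TRUE)
  parse_scale_table(path, "two_column")
}
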