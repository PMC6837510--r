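# Pairwise and group-mean p-distances, windowed profiles, site classification.

#' Pairwise p-distance
#'
#' Proportion of differing nucleotides among compared positions, with pairwise
#' deletion: positions where either row carries `N` or `-` are excluded.
#'
#' @param row_a,row_b Equal-length aligned sequences (strings).
#' @return List with `differences`, `sites_compared`, `p`.
#' @examples
#' p_distance("ACGT", "ACGA")$p   # 0.25
#' p_distance("ACGN", "ACTA")$p   # 1/3 (the N column is excluded)
#' @export
p_distance <- function(row_a, row_b) {
  a <- seq_chars(row_a)
  b <- seq_chars(row_b)
  if (length(a) != length(b)) {
    stop("rows have unequal lengths (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  ok <- !(a %in% c("N", "-")) & !(b %in% c("N", "-"))
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites (all positions missing)", call. = FALSE)
  diffs <- sum(a[ok] != b[ok])
  list(differences = diffs, sites_compared = n, p = diffs / n)
}

#' Group mean p-distance
#'
#' Arithmetic mean of per-pair p-distances over all pairs of the selected taxa,
#' each pair with its own pairwise-deletion denominator.
#'
#' @param alignment Named character vector of aligned rows (or character
#'   matrix).
#' @param taxa Taxon names to include (default: all rows).
#' @return List with `p` (mean), `n_pairs`, and the per-pair data frame.
#' @export
group_mean_p <- function(alignment, taxa = NULL) {
  m <- as_aln_matrix(alignment)
  taxa <- taxa %||% rownames(m)
  if (!all(taxa %in% rownames(m))) {
    stop("unknown taxa: ", paste(setdiff(taxa, rownames(m)), collapse = ", "),
         call. = FALSE)
  }
  if (length(taxa) < 2L) stop("need at least 2 taxa", call. = FALSE)
  pairs <- utils::combn(taxa, 2)
  per_pair <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    est <- tryCatch(
      p_distance(paste(m[a, ], collapse = ""), paste(m[b, ], collapse = "")),
      error = function(e) stop("pair (", a, ", ", b, "): ",
                               conditionMessage(e), call. = FALSE))
    data.frame(taxon_a = a, taxon_b = b, p = est$p,
               differences = est$differences,
               sites_compared = est$sites_compared)
  })
  per_pair <- do.call(rbind, per_pair)
  list(p = mean(per_pair$p), n_pairs = nrow(per_pair), pairs = per_pair)
}

#' Sliding-window divergence profile
#'
#' Mean within-group p-distance in windows sliding along the alignment.
#' Consecutive windows share `overlap` bp, so the step is `window - overlap`
#' (500/100 by default, step 400). A final truncated window is emitted iff its
#' length is at least `window / 2`.
#'
#' @param alignment Named character vector of aligned rows (or matrix).
#' @param groups Named list mapping group label to taxon names; default one
#'   group of all rows.
#' @param window Window width, bp.
#' @param overlap Shared bp between consecutive windows (`0 <= overlap <
#'   window`).
#' @return Data frame with `group`, `start` (0-based), `end`, `p`,
#'   `sites_compared` (minimum pairwise denominator within the window).
#' @export
window_profile <- function(alignment, groups = NULL, window = 500L,
                           overlap = 100L) {
  if (overlap >= window || overlap < 0) {
    stop("overlap must satisfy 0 <= overlap < window", call. = FALSE)
  }
  m <- as_aln_matrix(alignment)
  L <- ncol(m)
  if (L < window) stop("alignment shorter than one window", call. = FALSE)
  groups <- groups %||% list(all = rownames(m))
  step <- window - overlap
  starts <- seq(0L, L - 1L, by = step)
  keep <- (pmin(starts + window, L) - starts) >= window / 2 & starts < L
  starts <- starts[keep]
  ends <- pmin(starts + window, L)
  out <- lapply(names(groups), function(gname) {
    taxa <- groups[[gname]]
    do.call(rbind, lapply(seq_along(starts), function(i) {
      sub <- m[taxa, (starts[i] + 1L):ends[i], drop = FALSE]
      gm <- group_mean_p(sub)
      data.frame(group = gname, start = starts[i], end = ends[i],
                 p = gm$p, sites_compared = min(gm$pairs$sites_compared))
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pairwise p-distance matrix
#'
#' Symmetric matrix of pairwise p-distances with a zero diagonal.
#'
#' @param alignment Named character vector of aligned rows (or matrix).
#' @return Numeric matrix with taxon dimnames.
#' @export
pairwise_matrix <- function(alignment) {
  m <- as_aln_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  taxa <- rownames(m)
  rows <- apply(m, 1, paste, collapse = "")
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- p_distance(rows[i], rows[j])$p
    }
  }
  d
}

#' Classify alignment sites
#'
#' Classifies each column as conserved (one state), parsimony-informative
#' (>= 2 states each in >= 2 rows), singleton (exactly one row differs from
#' the single state shared by all others), or other-variable. Columns
#' containing any `-` or `N` are counted as unclassified.
#'
#' @param alignment Named character vector of aligned rows (or matrix), with at
#'   least 4 rows.
#' @return One-row data frame: `total`, `conserved`, `parsimony_informative`,
#'   `singleton`, `other_variable`, `unclassified`.
#' @export
classify_sites <- function(alignment) {
  m <- as_aln_matrix(alignment)
  if (nrow(m) < 4L) {
    stop("need at least 4 rows for parsimony-informativeness", call. = FALSE)
  }
  cls <- apply(m, 2, function(col) {
    if (any(col %in% c("N", "-"))) return("unclassified")
    tab <- table(col)
    if (length(tab) == 1L) return("conserved")
    if (sum(tab >= 2) >= 2) return("parsimony_informative")
    if (length(tab) == 2L && min(tab) == 1L) return("singleton")
    "other_variable"
  })
  lv <- c("conserved", "parsimony_informative", "singleton", "other_variable",
          "unclassified")
  counts <- table(factor(cls, levels = lv))
  data.frame(total = ncol(m),
             conserved = as.integer(counts[["conserved"]]),
             parsimony_informative = as.integer(counts[["parsimony_informative"]]),
             singleton = as.integer(counts[["singleton"]]),
             other_variable = as.integer(counts[["other_variable"]]),
             unclassified = as.integer(counts[["unclassified"]]))
}
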