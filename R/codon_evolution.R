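# Four-fold degenerate site extraction and Nei-Gojobori (1986) dN/dS counting.

#' Extract four-fold degenerate third-position sites
#'
#' A third-codon-position column is extracted iff, in every taxon, the codon is
#' four-fold degenerate at position 3, the first two codon positions are
#' identical across all taxa, and no taxon carries a gap or `N` anywhere in the
#' codon. This is the strict (cross-taxon conserved) definition of putatively
#' neutral sites used for molecular dating.
#'
#' @param pcg_alignment Named character vector of codon-aligned in-frame coding
#'   rows (or matrix). Length must be divisible by 3.
#' @param code Genetic code from [genetic_code()].
#' @return Named character vector: per taxon, the concatenated extracted
#'   third-position bases. Attribute `positions` holds the 0-based alignment
#'   positions extracted.
#' @export
extract_fourfold <- function(pcg_alignment, code = genetic_code(5)) {
  m <- as_aln_matrix(pcg_alignment)
  L <- ncol(m)
  if (L %% 3 != 0) {
    stop("alignment length (", L, ") not divisible by 3", call. = FALSE)
  }
  taxa <- rownames(m)
  keep <- logical(L %/% 3)
  fourfold <- fourfold_codons(code)
  for (ci in seq_len(L %/% 3)) {
    cols <- (3 * ci - 2):(3 * ci)
    block <- m[, cols, drop = FALSE]
    if (any(!(block %in% DNA_BASES))) next
    if (length(unique(block[, 1])) > 1L || length(unique(block[, 2])) > 1L) next
    codons <- paste0(block[, 1], block[, 2], block[, 3])
    if (all(codons %in% fourfold)) keep[ci] <- TRUE
  }
  pos3 <- 3 * which(keep)
  out <- vapply(taxa, function(t) paste(m[t, pos3], collapse = ""), character(1))
  attr(out, "positions") <- pos3 - 1L
  out
}

# Codons with degeneracy 4 at position 3 under `code`.
fourfold_codons <- function(code) {
  codons <- names(code)
  codons[vapply(codons, function(cd) {
    if (code[[cd]] == "*") return(FALSE)
    degeneracy_class(cd, 3, code) == 4L
  }, logical(1))]
}

# Observed synonymous/non-synonymous differences between two codons, averaged
# over all minimal mutational pathways. Pathways passing through stop codons
# are excluded; if every pathway is blocked, all pathways are used (flagged).
codon_path_diffs <- function(ca, cb, code) {
  pos <- which(seq_chars(ca) != seq_chars(cb))
  k <- length(pos)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (k == 1L) list(pos) else {
    if (k == 2L) list(pos, rev(pos)) else {
      list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
           pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
    }
  }
  eval_path <- function(order) {
    cur <- ca
    syn <- 0L; nonsyn <- 0L; blocked <- FALSE
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(cb, p, p)
      if (code[[nxt]] == "*") blocked <- TRUE
      if (code[[nxt]] == code[[cur]]) syn <- syn + 1L else nonsyn <- nonsyn + 1L
      cur <- nxt
    }
    # the endpoint is never a stop here; only intermediates can block
    list(syn = syn, nonsyn = nonsyn, blocked = blocked && code[[cb]] != "*")
  }
  evals <- lapply(perms, eval_path)
  ok <- !vapply(evals, `[[`, logical(1), "blocked")
  if (!any(ok)) ok <- rep(TRUE, length(evals))
  c(syn = mean(vapply(evals[ok], `[[`, integer(1), "syn")),
    nonsyn = mean(vapply(evals[ok], `[[`, integer(1), "nonsyn")))
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Counting-method estimate for one pair of in-frame coding sequences:
#' potential synonymous sites per codon are the per-position fractions of
#' synonymous single-nucleotide changes (averaged between the two sequences,
#' `S + N = 3L`); observed synonymous/non-synonymous differences are averaged
#' over all minimal mutational pathways between differing codons, excluding
#' pathways through stop codons; the Jukes-Cantor correction
#' `d = -(3/4) log(1 - (4/3) p)` maps proportions to distances. Codons
#' containing gaps, `N`, or a stop in either sequence are skipped pairwise.
#' Proportions `p >= 3/4` are flagged saturated and the corresponding distance
#' is `NA`.
#'
#' @param cds_a,cds_b Equal-length in-frame coding sequences.
#' @param code Genetic code from [genetic_code()].
#' @param gene Gene label carried into the result.
#' @return A `dnds_estimate` data frame row: `gene`, `S`, `N`, `Sd`, `Nd`,
#'   `pS`, `pN`, `dS`, `dN`, `omega`, `saturated`, `codons_compared`.
#' @export
ng86_pair <- function(cds_a, cds_b, code = genetic_code(5), gene = "gene") {
  a <- normalize_seq(cds_a)
  b <- normalize_seq(cds_b)
  if (nchar(a) != nchar(b)) {
    stop("sequences have unequal lengths (", nchar(a), " vs ", nchar(b), ")",
         call. = FALSE)
  }
  if (nchar(a) %% 3 != 0) {
    stop("sequence length (", nchar(a), ") not divisible by 3", call. = FALSE)
  }
  starts <- seq(1L, max(nchar(a), 1L), by = 3L)
  if (nchar(a) == 0L) starts <- integer(0)
  ca <- substring(a, starts, starts + 2L)
  cb <- substring(b, starts, starts + 2L)
  synm <- syn_change_matrix(code)
  valid <- function(cd) all(seq_chars(cd) %in% DNA_BASES) && code[[cd]] != "*"
  use <- vapply(ca, valid, logical(1)) & vapply(cb, valid, logical(1))
  ca <- ca[use]; cb <- cb[use]
  Lc <- length(ca)
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_len(Lc)) {
    S <- S + (sum(synm[ca[i], ]) + sum(synm[cb[i], ])) / 2 / 3
    if (ca[i] != cb[i]) {
      d <- codon_path_diffs(ca[i], cb[i], code)
      Sd <- Sd + d[["syn"]]
      Nd <- Nd + d[["nonsyn"]]
    }
  }
  N <- 3 * Lc - S
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  sat <- (!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75)
  jc <- function(p) {
    if (is.na(p) || p >= 0.75) NA_real_ else -0.75 * log(1 - (4 / 3) * p)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  omega <- if (!is.na(dS) && dS > 0 && !is.na(dN)) dN / dS else NA_real_
  out <- data.frame(gene = gene, S = S, N = N, Sd = Sd, Nd = Nd,
                    pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
                    saturated = sat, codons_compared = Lc)
  class(out) <- c("dnds_estimate", class(out))
  out
}

#' Per-gene group dN/dS
#'
#' Group estimate over all sequence pairs in a gene alignment: mean pairwise dN
#' and mean pairwise dS over the non-saturated pairs (saturated pairs are
#' excluded and counted), with `omega` their ratio.
#'
#' @param gene_alignment Named character vector of in-frame coding rows (>= 2
#'   taxa), or matrix.
#' @param code Genetic code from [genetic_code()].
#' @param gene Gene label.
#' @return A `dnds_estimate` row with the group means plus `n_pairs` and
#'   `n_saturated`.
#' @export
gene_dnds <- function(gene_alignment, code = genetic_code(5), gene = "gene") {
  m <- as_aln_matrix(gene_alignment)
  if (nrow(m) < 2L) stop("need at least 2 taxa", call. = FALSE)
  rows <- apply(m, 1, paste, collapse = "")
  pairs <- utils::combn(length(rows), 2)
  ests <- lapply(seq_len(ncol(pairs)), function(i) {
    ng86_pair(rows[pairs[1, i]], rows[pairs[2, i]], code, gene)
  })
  est <- do.call(rbind, ests)
  ok <- !est$saturated & !is.na(est$dS) & !is.na(est$dN)
  if (!any(ok)) {
    stop("all ", nrow(est), " pairs are saturated for gene '", gene,
         "'; no dN/dS estimate possible", call. = FALSE)
  }
  dS <- mean(est$dS[ok])
  dN <- mean(est$dN[ok])
  out <- data.frame(gene = gene,
                    S = mean(est$S[ok]), N = mean(est$N[ok]),
                    Sd = mean(est$Sd[ok]), Nd = mean(est$Nd[ok]),
                    pS = mean(est$pS[ok]), pN = mean(est$pN[ok]),
                    dS = dS, dN = dN,
                    omega = if (dS > 0) dN / dS else NA_real_,
                    saturated = FALSE, codons_compared = est$codons_compared[1],
                    n_pairs = nrow(est), n_saturated = sum(!ok))
  class(out) <- c("dnds_estimate", class(out))
  out
}
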