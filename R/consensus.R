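# Threshold consensus across multiple per-coverage assemblies of one genome.

#' Consensus parameters
#'
#' The representation threshold is the fraction of assembly rows a nucleotide
#' must reach to win a column (0.60 by default, i.e. "mostly represented").
#' Thresholds at or below 0.5 are refused: above 0.5 the winning nucleotide is
#' always unique, so no tie-breaking rule is needed.
#'
#' @param threshold Winning fraction in (0.5, 1].
#' @param min_rows Minimum number of assembly rows (>= 2).
#' @return A `consensus_params` list.
#' @export
consensus_params <- function(threshold = 0.60, min_rows = 2L) {
  if (threshold <= 0.5 || threshold > 1) {
    stop("threshold must be in (0.5, 1]", call. = FALSE)
  }
  if (min_rows < 2L) stop("min_rows must be >= 2", call. = FALSE)
  list(threshold = threshold, min_rows = as.integer(min_rows))
}

#' Call one consensus column
#'
#' Nucleotide fractions are computed over all rows (`N` and `-` count in the
#' denominator but can never win). The nucleotide with fraction >= threshold is
#' the consensus; if none reaches it the column yields `N`; if every row is `N`
#' or `-` the column is dropped.
#'
#' @param symbols Character vector over `{A,C,G,T,N,-}`, one per assembly row.
#' @param params A [consensus_params()].
#' @return One of `"A"`, `"C"`, `"G"`, `"T"`, `"N"`, or `NA` (drop marker).
#' @examples
#' consensus_column(c("A", "A", "G"), consensus_params(0.60))  # "A" (2/3)
#' consensus_column(c("A", "G"), consensus_params(0.60))       # "N"
#' @export
consensus_column <- function(symbols, params = consensus_params()) {
  if (length(symbols) < params$min_rows) {
    stop("fewer than min_rows (", params$min_rows, ") symbols", call. = FALSE)
  }
  if (!all(symbols %in% ALN_ALPHABET)) {
    stop("symbols must be in {A,C,G,T,N,-}", call. = FALSE)
  }
  if (all(symbols %in% c("N", "-"))) return(NA_character_)
  frac <- vapply(DNA_BASES, function(b) mean(symbols == b), numeric(1))
  if (max(frac) >= params$threshold) names(which.max(frac)) else "N"
}

#' Build a threshold consensus from aligned assemblies
#'
#' Applies [consensus_column()] to every column of the assembly alignment, left
#' to right. Gaps can neither win a column nor appear in the consensus;
#' all-gap/N columns are removed, so the consensus is always gap-free.
#'
#' @param assemblies Named character vector of equal-length aligned assembly
#'   sequences (or a character matrix, rows = assemblies).
#' @param params A [consensus_params()].
#' @param id Identifier for the consensus record.
#' @return A `consensus_report` list: `consensus` (named sequence string),
#'   `columns` (per-column data frame with winning symbol, winning fraction and
#'   number of informative rows), and counts `resolved`, `n_columns`
#'   (columns emitted as `N`), `dropped`.
#' @export
build_consensus <- function(assemblies, params = consensus_params(),
                            id = "consensus") {
  m <- as_aln_matrix(assemblies)
  if (nrow(m) < params$min_rows) {
    stop("need at least min_rows (", params$min_rows, ") assemblies",
         call. = FALSE)
  }
  if (!all(m %in% ALN_ALPHABET)) {
    stop("assembly symbols must be in {A,C,G,T,N,-}", call. = FALSE)
  }
  ncol_aln <- ncol(m)
  nrows <- nrow(m)
  counts <- vapply(DNA_BASES, function(b) colSums(m == b), numeric(ncol_aln))
  if (ncol_aln == 1L) counts <- matrix(counts, nrow = 1,
                                       dimnames = list(NULL, DNA_BASES))
  frac <- counts / nrows
  informative <- rowSums(counts)
  best <- max.col(frac, ties.method = "first")
  best_frac <- frac[cbind(seq_len(ncol_aln), best)]
  symbol <- ifelse(informative == 0, NA_character_,
                   ifelse(best_frac >= params$threshold,
                          DNA_BASES[best], "N"))
  kept <- !is.na(symbol)
  consensus <- paste(symbol[kept], collapse = "")
  names(consensus) <- id
  report <- list(
    consensus = consensus,
    columns = data.frame(column = seq_len(ncol_aln),
                         symbol = symbol,
                         winning_fraction = ifelse(informative == 0, NA,
                                                   best_frac),
                         n_informative = as.integer(informative)),
    resolved = sum(kept & symbol != "N", na.rm = TRUE),
    n_columns = sum(kept & symbol == "N", na.rm = TRUE),
    dropped = sum(!kept)
  )
  class(report) <- "consensus_report"
  report
}

#' @export
print.consensus_report <- function(x, ...) {
  cat(sprintf("consensus '%s': %d bp (%d resolved, %d N, %d columns dropped)\n",
              names(x$consensus), nchar(x$consensus),
              x$resolved, x$n_columns, x$dropped))
  invisible(x)
}
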