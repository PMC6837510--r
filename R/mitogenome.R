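#' Annotated mitogenome
#'
#' Bundles one linearized mitogenome sequence with its typed, stranded gene
#' features. Coordinates are 0-based half-open; the genome is stored linearized
#' at the control-region start so no feature wraps the origin.
#'
#' @param sequence Genome sequence (single string over `{A,C,G,T,N}`).
#' @param features Feature data frame with columns `gene`, `kind`
#'   (`PCG`/`tRNA`/`rRNA`/`control`), `strand` (`+`/`-`), `start`, `end`.
#' @param id Genome identifier.
#' @return An object of class `annotated_mitogenome`.
#' @export
annotated_mitogenome <- function(sequence, features, id = "mitogenome") {
  sequence <- normalize_seq(sequence)
  check_alphabet(sequence, SEQ_ALPHABET, id)
  stopifnot(is.data.frame(features),
            all(c("gene", "kind", "strand", "start", "end") %in% names(features)))
  L <- nchar(sequence)
  if (any(features$start < 0L) || any(features$end > L) ||
      any(features$start >= features$end)) {
    stop("feature coordinates out of bounds for genome of length ", L,
         call. = FALSE)
  }
  if (!all(features$kind %in% FEATURE_KINDS)) {
    stop("unknown feature kind", call. = FALSE)
  }
  if (!all(features$strand %in% c("+", "-"))) {
    stop("feature strand must be '+' or '-'", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, features = features),
            class = "annotated_mitogenome")
}

#' @export
print.annotated_mitogenome <- function(x, ...) {
  k <- table(factor(x$features$kind, levels = FEATURE_KINDS))
  cat(sprintf("annotated mitogenome '%s': %d bp, %d features (%d PCG, %d tRNA, %d rRNA, %d control)\n",
              x$id, nchar(x$sequence), nrow(x$features),
              k[["PCG"]], k[["tRNA"]], k[["rRNA"]], k[["control"]]))
  invisible(x)
}

#' Extract one gene sequence, coding-strand oriented
#'
#' Light-strand (`-`) genes are reverse-complemented so PCGs read 5'->3' in
#' frame.
#'
#' @param genome An [annotated_mitogenome()].
#' @param gene Gene name as annotated.
#' @return Single sequence string.
#' @export
extract_gene <- function(genome, gene) {
  i <- which(genome$features$gene == gene)
  if (length(i) != 1L) stop("gene '", gene, "' not annotated exactly once",
                            call. = FALSE)
  f <- genome$features[i, ]
  s <- substr(genome$sequence, f$start + 1L, f$end)
  if (f$strand == "-") s <- reverse_complement(s)
  s
}

#' Extract all protein-coding genes, coding-strand oriented
#'
#' @param genome An [annotated_mitogenome()].
#' @return Named character vector of CDS sequences in annotation order.
#' @export
extract_pcgs <- function(genome) {
  f <- genome$features[genome$features$kind == "PCG", ]
  if (nrow(f) == 0L) stop("genome has no PCG annotations", call. = FALSE)
  out <- vapply(f$gene, function(g) extract_gene(genome, g), character(1))
  names(out) <- f$gene
  out
}
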