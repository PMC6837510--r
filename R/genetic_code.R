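#' Genetic code lookup
#'
#' Returns a genetic code as a named character vector of 64 codons to one-letter
#' amino acids, with stops encoded as `*`. Table 5 is the invertebrate
#' mitochondrial code used throughout mitogenome analyses here (ATA -> Met,
#' TGA -> Trp, AGA/AGG -> Ser; stops TAA and TAG only).
#'
#' @param table_id Genetic code table id: `5` (invertebrate mitochondrial,
#'   default) or `1` (standard).
#' @return Named character vector of length 64.
#' @examples
#' genetic_code(5)[c("ATA", "TGA", "AGA")]
#' @export
genetic_code <- function(table_id = 5) {
  id <- as.character(table_id)
  if (!id %in% c("1", "5")) {
    stop("unsupported genetic code table: ", id, call. = FALSE)
  }
  gc <- Biostrings::getGeneticCode(id)
  out <- as.character(gc)
  names(out) <- names(gc)
  out
}

#' Translate a coding sequence
#'
#' Translates an in-frame DNA coding sequence codon by codon. Stop codons are
#' rendered `*`; codons containing `N` or `-` are rendered `X`.
#'
#' @param cds Coding sequence (length divisible by 3).
#' @param code Genetic code from [genetic_code()].
#' @return Single string of one-letter amino acids.
#' @examples
#' translate_cds("ATAAGATGA", genetic_code(5))  # "MSW" under table 5
#' @export
translate_cds <- function(cds, code = genetic_code(5)) {
  cds <- normalize_seq(cds)
  n <- nchar(cds)
  if (n %% 3 != 0) {
    stop("coding sequence length (", n, ") not divisible by 3", call. = FALSE)
  }
  if (n == 0L) return("")
  starts <- seq(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Codon degeneracy at one position
#'
#' Number of nucleotides at `position` (holding the other two positions fixed)
#' that yield the same amino acid as `codon`. A value of 4 at position 3 marks
#' a four-fold degenerate site, the putatively neutral site class used for
#' molecular dating.
#'
#' @param codon A 3-letter codon over `{A,C,G,T}`.
#' @param position Codon position, 1 to 3.
#' @param code Genetic code from [genetic_code()].
#' @return Integer in 1:4.
#' @examples
#' degeneracy_class("GGA", 3)  # 4: GGN are all glycine
#' degeneracy_class("ATT", 3)  # 2 under table 5 (ATT/ATC Ile; ATA/ATG Met)
#' @export
degeneracy_class <- function(codon, position, code = genetic_code(5)) {
  codon <- normalize_seq(codon)
  if (nchar(codon) != 3L || !all(seq_chars(codon) %in% DNA_BASES)) {
    stop("codon must be 3 characters over {A,C,G,T}: '", codon, "'",
         call. = FALSE)
  }
  if (!position %in% 1:3) stop("position must be 1, 2 or 3", call. = FALSE)
  aa <- code[[codon]]
  variants <- vapply(DNA_BASES, function(b) {
    v <- codon
    substr(v, position, position) <- b
    code[[v]]
  }, character(1))
  sum(variants == aa)
}

# Precompute per-codon counts of synonymous single-nucleotide changes at each
# position (changes to stop codons count as non-synonymous). Used by NG86
# potential-site counting. Returns a 64 x 3 matrix keyed by codon.
syn_change_matrix <- function(code) {
  key <- paste(code, collapse = "")
  cached <- .syn_cache[[key]]
  if (!is.null(cached)) return(cached)
  codons <- names(code)
  m <- matrix(0L, nrow = length(codons), ncol = 3,
              dimnames = list(codons, NULL))
  for (cd in codons) {
    if (code[[cd]] == "*") next
    for (pos in 1:3) {
      cnt <- 0L
      for (b in DNA_BASES) {
        if (b == substr(cd, pos, pos)) next
        v <- cd
        substr(v, pos, pos) <- b
        if (code[[v]] == code[[cd]]) cnt <- cnt + 1L
      }
      m[cd, pos] <- cnt
    }
  }
  .syn_cache[[key]] <- m
  m
}

.syn_cache <- new.env(parent = emptyenv())
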