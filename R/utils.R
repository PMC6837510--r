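# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
SEQ_ALPHABET <- c(DNA_BASES, "N")
ALN_ALPHABET <- c(SEQ_ALPHABET, "-")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N", `-` = "-")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded simulator calls do not disturb
#' the caller's random stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Split a sequence string into single characters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Named character vector of sequences -> character matrix (rows = taxa).
as_aln_matrix <- function(sequences) {
  if (is.matrix(sequences)) {
    if (is.null(rownames(sequences))) {
      rownames(sequences) <- paste0("seq", seq_len(nrow(sequences)))
    }
    return(sequences)
  }
  stopifnot(is.character(sequences))
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1L) {
    stop("alignment rows have unequal lengths: ",
         paste(unique(lens), collapse = ", "), call. = FALSE)
  }
  nm <- names(sequences) %||% paste0("seq", seq_along(sequences))
  m <- do.call(rbind, lapply(sequences, seq_chars))
  rownames(m) <- nm
  m
}

reverse_complement <- function(x) {
  paste(rev(unname(COMPLEMENT[seq_chars(x)])), collapse = "")
}

# Validate characters of one sequence against an alphabet; report the 0-based
# offset of the first offending character.
check_alphabet <- function(seq, alphabet, id = "?") {
  bad <- which(!(seq_chars(seq) %in% alphabet))
  if (length(bad) > 0L) {
    stop(sprintf("sequence '%s': invalid character '%s' at offset %d",
                 id, substr(seq, bad[1], bad[1]), bad[1] - 1L),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Normalize raw input sequence text: upper-case, RNA U -> DNA T.
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}
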