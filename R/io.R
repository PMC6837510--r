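#' Read a FASTA file
#'
#' Reads plain (optionally aligned) FASTA into a named character vector of
#' upper-case sequences. Lower-case input and RNA `U` are normalized to
#' upper-case DNA. Characters outside `{A,C,G,T,N}` (plus `-` when
#' `aligned = TRUE`) raise an error naming the record and 0-based offset.
#'
#' @param path Path to a FASTA file.
#' @param aligned Logical; allow the gap character `-`.
#' @return Named character vector, one element per record, in file order.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path, aligned = FALSE) {
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA format error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    stop("FASTA format error: no records in '", path, "'", call. = FALSE)
  }
  seqs <- normalize_seq(as.character(set))
  ids <- names(set)
  if (any(!nzchar(ids))) stop("FASTA record with empty id", call. = FALSE)
  if (any(!nzchar(seqs))) {
    stop("FASTA record '", ids[which(!nzchar(seqs))[1]], "' has empty sequence",
         call. = FALSE)
  }
  alphabet <- if (aligned) ALN_ALPHABET else SEQ_ALPHABET
  for (i in seq_along(seqs)) check_alphabet(seqs[i], alphabet, ids[i])
  names(seqs) <- ids
  seqs
}

#' Write sequences to FASTA
#'
#' Writes a named character vector as FASTA wrapped at 70 columns.
#' `read_fasta(write_fasta(x))` reproduces `x` exactly.
#'
#' @param sequences Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.character(sequences), length(sequences) > 0L)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("all sequences must be named", call. = FALSE)
  }
  set <- Biostrings::BStringSet(sequences)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

FEATURE_KINDS <- c("PCG", "tRNA", "rRNA", "control")

#' Read a GFF3-style feature table
#'
#' Parses tab-separated GFF3 (1-based inclusive coordinates) into a feature
#' data frame with internal 0-based half-open coordinates. Gene name and kind
#' are taken from the `Name=` and `kind=` attribute keys (falling back to the
#' type column for the kind). Mitochondrial genes are stranded, so strand must
#' be `+` or `-`.
#'
#' @param path Path to a GFF3 file.
#' @return Data frame with columns `gene`, `kind`, `strand`, `start`, `end`
#'   (0-based half-open).
#' @seealso [write_features()]
#' @export
read_features <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("feature table is empty", call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0L) {
    stop("feature table line ", bad[1], " does not have 9 tab-separated columns",
         call. = FALSE)
  }
  parse_attr <- function(attr, key) {
    m <- regmatches(attr, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attr))[[1]]
    if (length(m) == 2L) m[2] else NA_character_
  }
  rows <- lapply(fields, function(f) {
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1)) {
      stop("feature table: non-integer coordinates", call. = FALSE)
    }
    if (end1 < start1) {
      stop(sprintf("feature table: end (%d) < start (%d)", end1, start1),
           call. = FALSE)
    }
    strand <- f[7]
    if (!strand %in% c("+", "-")) {
      stop("feature table: strand must be '+' or '-' (got '", strand,
           "'); mitochondrial genes are stranded", call. = FALSE)
    }
    gene <- parse_attr(f[9], "Name")
    kind <- parse_attr(f[9], "kind")
    if (is.na(kind)) kind <- f[3]
    if (is.na(gene)) stop("feature table: attribute 'Name=' missing", call. = FALSE)
    if (!kind %in% FEATURE_KINDS) {
      stop("feature table: unknown kind '", kind, "' (expected ",
           paste(FEATURE_KINDS, collapse = "/"), ")", call. = FALSE)
    }
    data.frame(gene = gene, kind = kind, strand = strand,
               start = start1 - 1L, end = end1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a feature table as GFF3
#'
#' Converts internal 0-based half-open coordinates back to 1-based inclusive
#' GFF3. The conversion is an exact bijection with [read_features()].
#'
#' @param features Feature data frame (`gene`, `kind`, `strand`, `start`, `end`).
#' @param path Output path.
#' @param seqid Sequence identifier for column 1.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path, seqid = "mitogenome") {
  stopifnot(all(c("gene", "kind", "strand", "start", "end") %in% names(features)))
  lines <- sprintf("%s\tmitoclade\t%s\t%d\t%d\t.\t%s\t.\tName=%s;kind=%s",
                   seqid, features$kind, features$start + 1L, features$end,
                   features$strand, features$gene, features$kind)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a Newick tree
#'
#' Thin wrapper over [ape::read.tree()] adding the validation this pipeline
#' relies on: a parse failure is an error (not `NULL`) and tip labels must be
#' unique.
#'
#' @param path Path to a Newick file.
#' @return An [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  tr <- tryCatch(suppressWarnings(ape::read.tree(path)),
                 error = function(e) NULL)
  if (is.null(tr)) stop("Newick parse error in '", path, "'", call. = FALSE)
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  tr
}

#' Write a Newick tree
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}
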