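# Composition summaries and codon-usage statistics.

#' Genome composition summary
#'
#' Total length, GC and N percentages, and the percentage of the genome covered
#' by each annotated element class. A position covered by features of two
#' classes counts once toward each class; intergenic positions are covered by
#' no gene feature and are not control region. Percentages are reported to two
#' decimals.
#'
#' @param genome An [annotated_mitogenome()].
#' @return Data frame with one row: `total_length`, `gc_percent`, `n_percent`,
#'   `intergenic_percent`, `trna_percent`, `pcg_percent`, `rrna_percent`.
#' @export
composition_summary <- function(genome) {
  stopifnot(inherits(genome, "annotated_mitogenome"))
  if (nrow(genome$features) == 0L) {
    stop("genome has no annotations", call. = FALSE)
  }
  chars <- seq_chars(genome$sequence)
  L <- length(chars)
  class_cover <- function(kind) {
    f <- genome$features[genome$features$kind == kind, ]
    cov <- logical(L)
    for (i in seq_len(nrow(f))) cov[(f$start[i] + 1L):f$end[i]] <- TRUE
    cov
  }
  pcg <- class_cover("PCG")
  trna <- class_cover("tRNA")
  rrna <- class_cover("rRNA")
  ctrl <- class_cover("control")
  intergenic <- !(pcg | trna | rrna | ctrl)
  pct <- function(x) round(100 * sum(x) / L, 2)
  data.frame(total_length = L,
             gc_percent = round(100 * sum(chars %in% c("G", "C")) / L, 2),
             n_percent = round(100 * sum(chars == "N") / L, 2),
             intergenic_percent = pct(intergenic),
             trna_percent = pct(trna),
             pcg_percent = pct(pcg),
             rrna_percent = pct(rrna))
}

#' Base composition over concatenated protein-coding genes
#'
#' PCGs are extracted coding-strand oriented (light-strand genes
#' reverse-complemented) and pooled across all genomes; `N` is excluded from
#' the denominator, so the four percentages sum to 100.
#'
#' @param genomes A single [annotated_mitogenome()] or a list of them.
#' @return Named numeric vector of percentages for A, C, G, T.
#' @export
pcg_base_composition <- function(genomes) {
  if (inherits(genomes, "annotated_mitogenome")) genomes <- list(genomes)
  pooled <- unlist(lapply(genomes, function(g) {
    seq_chars(paste(extract_pcgs(g), collapse = ""))
  }))
  pooled <- pooled[pooled != "N"]
  100 * vapply(DNA_BASES, function(b) mean(pooled == b), numeric(1))
}

# Synonymous families of a genetic code: codons grouped by amino acid,
# stops excluded.
codon_families <- function(code) {
  sense <- names(code)[code != "*"]
  split(sense, code[sense])
}

#' Codon usage, RSCU and usage bias
#'
#' Counts codons per gene and pooled; terminal stop codons are excluded, codons
#' containing `N` or `-` are skipped (and tallied). RSCU is the observed count
#' divided by the family's uniform expectation. The per-gene bias index B
#' weighs each synonymous family's departure from uniform usage by the
#' family's share of the gene's codons; B is 0 iff usage is uniform within
#' every used family and is bounded by 1.
#'
#' @param genes Named character vector of in-frame CDS sequences.
#' @param code Genetic code from [genetic_code()].
#' @return List with `counts` (pooled named codon counts), `per_gene_counts`,
#'   `rscu` (long data frame: gene/pooled, codon, amino acid, count, RSCU),
#'   `bias` (named per-gene B), `top_codons` (pooled codons by decreasing
#'   count), `skipped` (codons containing N or `-`).
#' @export
codon_usage <- function(genes, code = genetic_code(5)) {
  stopifnot(is.character(genes), length(genes) > 0L)
  if (is.null(names(genes))) names(genes) <- paste0("gene", seq_along(genes))
  fams <- codon_families(code)
  all_codons <- names(code)
  skipped <- 0L
  per_gene <- lapply(names(genes), function(g) {
    s <- normalize_seq(genes[[g]])
    n <- nchar(s)
    if (n %% 3 != 0) {
      stop("gene '", g, "' length (", n, ") not divisible by 3", call. = FALSE)
    }
    starts <- seq(1L, n, by = 3L)
    codons <- substring(s, starts, starts + 2L)
    # trim trailing incomplete/terminal stop
    if (length(codons) > 0 && !is.na(code[codons[length(codons)]]) &&
        code[[codons[length(codons)]]] == "*") {
      codons <- codons[-length(codons)]
    }
    clean <- codons[codons %in% all_codons]
    skipped <<- skipped + (length(codons) - length(clean))
    tab <- table(factor(clean, levels = all_codons))
    as.integer(tab)
  })
  names(per_gene) <- names(genes)
  per_gene_counts <- lapply(per_gene, function(x) {
    names(x) <- all_codons
    x
  })
  pooled <- Reduce(`+`, per_gene)
  names(pooled) <- all_codons

  rscu_for <- function(counts) {
    out <- rep(NA_real_, length(all_codons))
    names(out) <- all_codons
    for (fam in fams) {
      tot <- sum(counts[fam])
      k <- length(fam)
      if (tot > 0) out[fam] <- counts[fam] / (tot / k)
    }
    out
  }
  bias_for <- function(counts) {
    total <- sum(counts)
    if (total == 0) return(NA_real_)
    b <- 0
    for (fam in fams) {
      k <- length(fam)
      tot <- sum(counts[fam])
      if (k < 2L || tot == 0) next
      f <- counts[fam] / tot
      b <- b + (tot / total) * sum(abs(f - 1 / k)) / (2 * (1 - 1 / k))
    }
    b
  }
  bias <- vapply(per_gene_counts, bias_for, numeric(1))
  rscu_rows <- lapply(c(list(pooled = pooled), per_gene_counts), rscu_for)
  rscu <- do.call(rbind, lapply(names(rscu_rows), function(g) {
    data.frame(gene = g, codon = all_codons,
               amino_acid = unname(code[all_codons]),
               count = as.integer(c(list(pooled = pooled),
                                    per_gene_counts)[[g]]),
               rscu = unname(rscu_rows[[g]]),
               stringsAsFactors = FALSE)
  }))
  rscu <- rscu[rscu$amino_acid != "*", ]
  rownames(rscu) <- NULL
  sense <- names(pooled)[code[names(pooled)] != "*"]
  top <- sense[order(pooled[sense], decreasing = TRUE)]
  list(counts = pooled, per_gene_counts = per_gene_counts, rscu = rscu,
       bias = bias, top_codons = top, skipped = skipped)
}
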