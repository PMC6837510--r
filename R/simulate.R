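# Seeded simulator: annotated ancestral mitogenomes, evolution along a dated
# tree under per-gene purifying selection, and noisy assembly replicates.

#' Default mitogenome gene architecture
#'
#' 37 genes (13 PCGs, 22 tRNAs, 2 rRNAs) plus one control-region feature, in
#' the gene order and orientation shared by *Drosophila* mitogenomes
#' (23 features on the heavy `+` strand, 14 on the light `-` strand). Lengths
#' are realistic per-gene values summing, with the short intergenic spacers in
#' `gap_after`, to 14892 bp. The control region stands in for the AT-rich
#' regulatory region, truncated as in typical short-read mitogenome assemblies.
#'
#' @return Data frame with columns `gene`, `kind`, `strand`, `length`,
#'   `gap_after` (intergenic spacer following the feature, bp).
#' @export
default_gene_architecture <- function() {
  a <- function(gene, kind, strand, length, gap = 0L) {
    data.frame(gene = gene, kind = kind, strand = strand,
               length = as.integer(length), gap_after = as.integer(gap),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    a("trnI",  "tRNA", "+", 66), a("trnQ", "tRNA", "-", 69),
    a("trnM",  "tRNA", "+", 66), a("ND2",  "PCG",  "+", 1023),
    a("trnW",  "tRNA", "+", 66), a("trnC", "tRNA", "-", 66, 4),
    a("trnY",  "tRNA", "-", 66), a("COI",  "PCG",  "+", 1536),
    a("trnL2", "tRNA", "+", 66), a("COII", "PCG",  "+", 687),
    a("trnK",  "tRNA", "+", 69), a("trnD", "tRNA", "+", 66),
    a("ATP8",  "PCG",  "+", 162), a("ATP6", "PCG", "+", 678),
    a("COIII", "PCG",  "+", 789), a("trnG", "tRNA", "+", 66),
    a("ND3",   "PCG",  "+", 354, 3), a("trnA", "tRNA", "+", 66),
    a("trnR",  "tRNA", "+", 66), a("trnN", "tRNA", "+", 66),
    a("trnS1", "tRNA", "+", 66), a("trnE", "tRNA", "+", 66, 6),
    a("trnF",  "tRNA", "-", 66), a("ND5",  "PCG",  "-", 1719),
    a("trnH",  "tRNA", "-", 66), a("ND4",  "PCG",  "-", 1341),
    a("ND4L",  "PCG",  "-", 291), a("trnT", "tRNA", "+", 66),
    a("trnP",  "tRNA", "-", 66, 3), a("ND6", "PCG", "+", 525),
    a("CytB",  "PCG",  "+", 1137), a("trnS2", "tRNA", "+", 66, 10),
    a("ND1",   "PCG",  "-", 936), a("trnL1", "tRNA", "-", 66),
    a("rrnL",  "rRNA", "-", 1300), a("trnV", "tRNA", "-", 66),
    a("rrnS",  "rRNA", "-", 780),
    a("control_region", "control", "+", 150)
  ))
}

#' Default per-gene dN/dS used by the simulator
#'
#' Purifying-selection strengths for the 13 PCGs, spanning the 0.003-0.060
#' range observed among mitochondrial protein-coding genes in closely related
#' *Drosophila* clades (ATP8 and ND2 the least constrained, COI and ND1 the
#' most).
#'
#' @return Named numeric vector over the 13 PCGs.
#' @export
default_omega <- function() {
  c(ATP6 = 0.005, ATP8 = 0.060, CytB = 0.005, COI = 0.003, COII = 0.005,
    COIII = 0.006, ND1 = 0.003, ND2 = 0.036, ND3 = 0.009, ND4L = 0.008,
    ND4 = 0.011, ND5 = 0.007, ND6 = 0.012)
}

#' Default dated tree for the simulated clade
#'
#' A six-tip ingroup chronogram (two main clades: one with `Dbuz` sister to the
#' two `Dkoe` strains, one with `Dant` sister to the very recent `Dbor`/`Dser`
#' pair) with crown age 2.11 Myr, splits at 1.5, 0.9, 0.31 and 0.05 Myr, and an
#' optional outgroup `Dmoj` diverging 10.63 Myr ago. Branch lengths are in
#' years.
#'
#' @param age_scale Multiplier applied to every age (use < 1 to keep deep
#'   divergences away from distance saturation).
#' @param include_outgroup Include the `Dmoj` outgroup tip.
#' @return An ultrametric [ape::phylo] tree with branch lengths in years.
#' @export
default_chronogram <- function(age_scale = 1, include_outgroup = TRUE) {
  s <- function(x) format(x * age_scale, scientific = FALSE, trim = TRUE)
  ingroup <- sprintf(
    "((Dbuz:%s,(DkoeA:%s,DkoeB:%s):%s):%s,(Dant:%s,(Dbor:%s,Dser:%s):%s):%s)",
    s(1.5e6), s(0.31e6), s(0.31e6), s(1.19e6), s(0.61e6),
    s(0.9e6), s(0.05e6), s(0.05e6), s(0.85e6), s(1.21e6))
  txt <- if (include_outgroup) {
    sprintf("(%s:%s,Dmoj:%s);", ingroup, s(8.52e6), s(10.63e6))
  } else {
    paste0(ingroup, ";")
  }
  ape::read.tree(text = txt)
}

#' Simulation configuration
#'
#' Collects and validates all simulator parameters: a seed, the target genome
#' length and AT richness, the 37-gene architecture, the strict-clock rate, the
#' per-PCG dN/dS used to thin non-synonymous changes, and codon-position rate
#' multipliers.
#'
#' @param seed Integer seed; the simulator is byte-reproducible given the seed.
#' @param genome_length_target Target genome length, bp.
#' @param at_fraction Ancestral A+T fraction in (0, 1).
#' @param architecture Gene architecture table, see
#'   [default_gene_architecture()].
#' @param clock_rate_per_year Neutral substitution rate per site per year.
#' @param omega_per_gene Named vector of per-PCG acceptance probabilities for
#'   amino-acid-changing substitutions, each in `[0, 1]`.
#' @param codon_position_rate_multipliers Length-3 multiplier applied to the
#'   neutral branch divergence at codon positions 1-3 of PCG sites.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length_target = 14900L,
                       at_fraction = 0.765,
                       architecture = default_gene_architecture(),
                       clock_rate_per_year = 6.2e-7,
                       omega_per_gene = default_omega(),
                       codon_position_rate_multipliers = c(1, 1, 1)) {
  stopifnot(is.data.frame(architecture),
            all(c("gene", "kind", "strand", "length", "gap_after") %in%
                  names(architecture)))
  counts <- table(factor(architecture$kind, levels = FEATURE_KINDS))
  if (counts[["PCG"]] != 13L || counts[["tRNA"]] != 22L ||
      counts[["rRNA"]] != 2L || counts[["control"]] != 1L) {
    stop("architecture must have 13 PCG + 22 tRNA + 2 rRNA + 1 control region",
         call. = FALSE)
  }
  genes <- architecture[architecture$kind != "control", ]
  if (sum(genes$strand == "+") != 23L || sum(genes$strand == "-") != 14L) {
    stop("architecture must place 23 genes on '+' and 14 on '-'", call. = FALSE)
  }
  if (any(architecture$length[architecture$kind == "PCG"] %% 3 != 0)) {
    stop("PCG lengths must be divisible by 3", call. = FALSE)
  }
  if (at_fraction <= 0 || at_fraction >= 1) {
    stop("at_fraction must be in (0, 1)", call. = FALSE)
  }
  pcgs <- architecture$gene[architecture$kind == "PCG"]
  if (!all(pcgs %in% names(omega_per_gene))) {
    stop("omega_per_gene must name every PCG", call. = FALSE)
  }
  if (any(omega_per_gene < 0 | omega_per_gene > 1)) {
    stop("omega values must be in [0, 1]", call. = FALSE)
  }
  if (length(codon_position_rate_multipliers) != 3L ||
      any(codon_position_rate_multipliers < 0)) {
    stop("codon_position_rate_multipliers must be 3 non-negative values",
         call. = FALSE)
  }
  total <- sum(architecture$length) + sum(architecture$gap_after)
  if (total > genome_length_target) {
    stop("architecture lengths (", total, " bp) exceed genome_length_target (",
         genome_length_target, " bp)", call. = FALSE)
  }
  if (clock_rate_per_year <= 0) stop("clock rate must be positive", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 genome_length_target = as.integer(genome_length_target),
                 at_fraction = at_fraction,
                 architecture = architecture,
                 clock_rate_per_year = clock_rate_per_year,
                 omega_per_gene = omega_per_gene,
                 codon_position_rate_multipliers = codon_position_rate_multipliers),
            class = "sim_config")
}

# Draw n bases at the configured AT richness (A/T and G/C equiprobable within
# their class).
draw_bases <- function(n, at_fraction) {
  probs <- c(at_fraction / 2, (1 - at_fraction) / 2,
             (1 - at_fraction) / 2, at_fraction / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = probs)
}

# A random stop-free in-frame CDS with ATG start and TAA terminal stop.
draw_cds <- function(n_codons, at_fraction, code) {
  stops <- names(code)[code == "*"]
  body <- character(n_codons - 2L)
  for (i in seq_along(body)) {
    repeat {
      cd <- paste(draw_bases(3L, at_fraction), collapse = "")
      if (!cd %in% stops) break
    }
    body[i] <- cd
  }
  paste(c("ATG", body, "TAA"), collapse = "")
}

#' Build the ancestral annotated mitogenome
#'
#' Generates a genome at the configured AT richness following the 37-gene
#' architecture: every PCG is a stop-free open reading frame under the
#' invertebrate mitochondrial code with a complete terminal stop (light-strand
#' PCGs are generated in coding orientation and reverse-complemented into the
#' genome). Deterministic given `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An [annotated_mitogenome()].
#' @export
build_ancestor <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  code <- genetic_code(5)
  with_seed(config$seed, {
    arch <- config$architecture
    segs <- character(0)
    feats <- vector("list", nrow(arch))
    pos <- 0L
    for (i in seq_len(nrow(arch))) {
      f <- arch[i, ]
      seg <- if (f$kind == "PCG") {
        cds <- draw_cds(f$length %/% 3L, config$at_fraction, code)
        if (f$strand == "-") reverse_complement(cds) else cds
      } else {
        paste(draw_bases(f$length, config$at_fraction), collapse = "")
      }
      segs <- c(segs, seg)
      feats[[i]] <- data.frame(gene = f$gene, kind = f$kind, strand = f$strand,
                               start = pos, end = pos + f$length,
                               stringsAsFactors = FALSE)
      pos <- pos + f$length
      if (f$gap_after > 0L) {
        segs <- c(segs, paste(draw_bases(f$gap_after, config$at_fraction),
                              collapse = ""))
        pos <- pos + f$gap_after
      }
    }
    genome <- annotated_mitogenome(paste(segs, collapse = ""),
                                   do.call(rbind, feats), id = "ancestor")
    L <- nchar(genome$sequence)
    if (abs(L - config$genome_length_target) > 0.01 * config$genome_length_target) {
      stop("generated length ", L, " deviates more than 1% from target",
           call. = FALSE)
    }
    genome
  })
}

# Per-site lookup tables used by the branch evolution engine.
# Integer base coding A=1, C=2, G=3, T=4; complement is 5 - b.
site_tables <- function(genome, config) {
  L <- nchar(genome$sequence)
  base_int <- match(seq_chars(genome$sequence), DNA_BASES)
  pcg_id <- integer(L)      # 0 = not coding, else index into pcg table
  cpos <- integer(L)        # codon position 1..3 (coding frame)
  codon_pos_mat <- matrix(0L, nrow = L, ncol = 3)  # genome positions, coding order
  terminal <- logical(L)
  f <- genome$features[genome$features$kind == "PCG", ]
  omega <- unname(config$omega_per_gene[f$gene])
  for (k in seq_len(nrow(f))) {
    s <- f$start[k]; e <- f$end[k]
    idx <- (s + 1L):e
    if (f$strand[k] == "+") {
      o <- idx - (s + 1L)
      cp <- o %% 3L + 1L
      first <- idx - (cp - 1L)
      codon_pos_mat[idx, ] <- cbind(first, first + 1L, first + 2L)
      term <- o >= (e - s - 3L)
    } else {
      o <- e - idx
      cp <- o %% 3L + 1L
      first_off <- o - (cp - 1L)     # coding offset of codon's first base
      codon_pos_mat[idx, ] <- cbind(e - first_off, e - first_off - 1L,
                                    e - first_off - 2L)
      term <- o >= (e - s - 3L)
    }
    pcg_id[idx] <- k
    cpos[idx] <- cp
    terminal[idx] <- term
  }
  mult <- rep(1, L)
  in_pcg <- pcg_id > 0L
  mult[in_pcg] <- config$codon_position_rate_multipliers[cpos[in_pcg]]
  comp <- logical(L)
  comp[in_pcg] <- f$strand[pcg_id[in_pcg]] == "-"
  code <- genetic_code(5)
  aa_tab <- integer(64)
  for (b1 in 1:4) for (b2 in 1:4) for (b3 in 1:4) {
    cd <- paste0(DNA_BASES[b1], DNA_BASES[b2], DNA_BASES[b3])
    aa <- code[[cd]]
    aa_tab[(b1 - 1L) * 16L + (b2 - 1L) * 4L + b3] <-
      if (aa == "*") 0L else utf8ToInt(aa)
  }
  list(L = L, base_int = base_int, pcg_id = pcg_id, cpos = cpos,
       codon_pos = codon_pos_mat, terminal = terminal, mult = mult,
       comp = comp, omega = omega, aa_tab = aa_tab)
}

# Evolve one branch: single Jukes-Cantor-probability proposal per site, with
# omega-thinning of amino-acid-changing proposals inside PCGs and rejection of
# internal stop codons; the terminal stop may only exchange with another stop.
evolve_branch <- function(seq_int, d_neutral, st) {
  p <- 0.75 * (1 - exp(-(4 / 3) * d_neutral * st$mult))
  hits <- which(stats::runif(st$L) < p)
  n_acc <- 0L
  if (length(hits) == 0L) return(list(seq = seq_int, n = 0L))
  prop <- (seq_int[hits] - 1L + sample.int(3L, length(hits), replace = TRUE)) %% 4L + 1L
  in_pcg <- st$pcg_id[hits] > 0L
  # Non-coding sites: every proposal is accepted.
  if (any(!in_pcg)) {
    seq_int[hits[!in_pcg]] <- prop[!in_pcg]
    n_acc <- n_acc + sum(!in_pcg)
  }
  ph <- hits[in_pcg]
  pp <- prop[in_pcg]
  for (i in seq_along(ph)) {
    g <- ph[i]
    cps <- st$codon_pos[g, ]
    b <- seq_int[cps]
    if (st$comp[g]) b <- 5L - b
    nb <- if (st$comp[g]) 5L - pp[i] else pp[i]
    j <- st$cpos[g]
    old_idx <- (b[1] - 1L) * 16L + (b[2] - 1L) * 4L + b[3]
    b[j] <- nb
    new_idx <- (b[1] - 1L) * 16L + (b[2] - 1L) * 4L + b[3]
    aa_old <- st$aa_tab[old_idx]
    aa_new <- st$aa_tab[new_idx]
    accept <- if (st$terminal[g]) {
      aa_old == 0L && aa_new == 0L
    } else if (aa_new == 0L) {
      FALSE
    } else if (aa_new == aa_old) {
      TRUE
    } else {
      stats::runif(1) < st$omega[st$pcg_id[g]]
    }
    if (accept) {
      seq_int[g] <- pp[i]
      n_acc <- n_acc + 1L
    }
  }
  list(seq = seq_int, n = n_acc)
}

#' Evolve a mitogenome clade along a dated tree
#'
#' Evolves the ancestor along each branch of the chronogram in fixed pre-order.
#' Per branch, each site receives at most one substitution proposal with the
#' Jukes-Cantor net-change probability `p = 3/4 (1 - exp(-4/3 d))`, where `d`
#' is the branch's neutral expected divergence (`clock_rate_per_year` x branch
#' years) times the site's codon-position multiplier. Proposals inside PCGs
#' that change the encoded amino acid are accepted with the gene's omega;
#' silent changes are always accepted; changes creating internal stop codons
#' (or destroying the terminal stop) are rejected. Annotations carry over
#' unchanged. Deterministic given `config$seed`.
#'
#' @param ancestor An [annotated_mitogenome()], typically [build_ancestor()].
#' @param chronogram Rooted [ape::phylo] tree, branch lengths in years, named
#'   tips.
#' @param config A [sim_config()].
#' @return List with `genomes` (named list of [annotated_mitogenome()], one per
#'   tip) and `truth` (chronogram, omega map, seed, realized accepted
#'   substitution counts per branch).
#' @export
evolve_clade <- function(ancestor, chronogram, config) {
  stopifnot(inherits(ancestor, "annotated_mitogenome"),
            inherits(chronogram, "phylo"),
            inherits(config, "sim_config"))
  if (length(chronogram$tip.label) < 2L) {
    stop("chronogram must have at least 2 tips", call. = FALSE)
  }
  if (is.null(chronogram$edge.length) || any(chronogram$edge.length < 0)) {
    stop("chronogram must have non-negative branch lengths in years",
         call. = FALSE)
  }
  st <- site_tables(ancestor, config)
  tr <- ape::reorder.phylo(chronogram, "cladewise")  # parents before children
  ntip <- length(tr$tip.label)
  root <- ntip + 1L
  node_seq <- vector("list", max(tr$edge))
  node_seq[[root]] <- st$base_int
  counts <- integer(nrow(tr$edge))
  with_seed(config$seed, {
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1]
      child <- tr$edge[e, 2]
      d <- config$clock_rate_per_year * tr$edge.length[e]
      res <- evolve_branch(node_seq[[par]], d, st)
      node_seq[[child]] <- res$seq
      counts[e] <- res$n
    }
  })
  genomes <- lapply(seq_len(ntip), function(i) {
    annotated_mitogenome(paste(DNA_BASES[node_seq[[i]]], collapse = ""),
                         ancestor$features, id = tr$tip.label[i])
  })
  names(genomes) <- tr$tip.label
  truth <- list(chronogram = chronogram,
                omega_per_gene = config$omega_per_gene,
                seed = config$seed,
                substitutions = data.frame(parent = tr$edge[, 1],
                                           child = tr$edge[, 2],
                                           count = counts))
  list(genomes = genomes, truth = truth)
}

#' Emit noisy per-coverage assembly replicates
#'
#' Each replicate equals the input genome with independent per-site
#' substitution errors at `error_rate`, and the replicate's masked intervals
#' (emulating low-read-representation regions) replaced by `N`. Deterministic
#' given `seed`.
#'
#' @param genome An [annotated_mitogenome()] or a single sequence string.
#' @param n_replicates Number of replicates (>= 2).
#' @param error_rate Per-site substitution error probability in `[0, 0.05]`.
#' @param mask_intervals List (length `n_replicates`) of two-column matrices of
#'   0-based half-open `[start, end)` intervals, or `NULL` for no masking.
#' @param seed Integer seed.
#' @return Named character vector of replicate sequences.
#' @export
corrupt_assemblies <- function(genome, n_replicates, error_rate = 0.01,
                               mask_intervals = NULL, seed = 1L) {
  seqstr <- if (inherits(genome, "annotated_mitogenome")) genome$sequence else genome
  id <- if (inherits(genome, "annotated_mitogenome")) genome$id else "genome"
  if (n_replicates < 2L) stop("n_replicates must be >= 2", call. = FALSE)
  if (error_rate < 0 || error_rate > 0.05) {
    stop("error_rate must be in [0, 0.05]", call. = FALSE)
  }
  L <- nchar(seqstr)
  if (!is.null(mask_intervals)) {
    stopifnot(length(mask_intervals) == n_replicates)
    for (m in mask_intervals) {
      if (is.null(m)) next
      m <- matrix(as.numeric(m), ncol = 2)
      if (any(m[, 1] < 0) || any(m[, 2] > L) || any(m[, 1] >= m[, 2])) {
        stop("mask interval out of bounds for genome of length ", L,
             call. = FALSE)
      }
    }
  }
  base_int <- match(seq_chars(seqstr), DNA_BASES)  # NA for N
  with_seed(seed, {
    reps <- vapply(seq_len(n_replicates), function(r) {
      b <- base_int
      err <- which(stats::runif(L) < error_rate & !is.na(b))
      if (length(err) > 0L) {
        b[err] <- (b[err] - 1L + sample.int(3L, length(err), replace = TRUE)) %% 4L + 1L
      }
      chars <- DNA_BASES[b]
      chars[is.na(b)] <- "N"
      if (!is.null(mask_intervals) && !is.null(mask_intervals[[r]])) {
        m <- matrix(as.numeric(mask_intervals[[r]]), ncol = 2)
        for (i in seq_len(nrow(m))) {
          chars[(m[i, 1] + 1L):m[i, 2]] <- "N"
        }
      }
      paste(chars, collapse = "")
    }, character(1))
    names(reps) <- sprintf("%s_rep%d", id, seq_len(n_replicates))
    reps
  })
}

#' Write a simulation bundle directory
#'
#' Writes `tips.fasta`, `features.gff3`, `truth.nwk` (branch lengths in Myr)
#' and `truth.tsv` (per-gene omega and per-branch realized substitution
#' counts).
#'
#' @param sim Result of [evolve_clade()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tips <- vapply(sim$genomes, function(g) g$sequence, character(1))
  write_fasta(tips, file.path(dir, "tips.fasta"))
  write_features(sim$genomes[[1]]$features, file.path(dir, "features.gff3"))
  tr <- sim$truth$chronogram
  tr$edge.length <- tr$edge.length / 1e6
  write_newick(tr, file.path(dir, "truth.nwk"))
  om <- sim$truth$omega_per_gene
  tab <- rbind(
    data.frame(record = "omega", name = names(om), value = unname(om)),
    data.frame(record = "seed", name = "seed", value = sim$truth$seed),
    data.frame(record = "substitutions",
               name = paste(sim$truth$substitutions$parent,
                            sim$truth$substitutions$child, sep = "->"),
               value = sim$truth$substitutions$count)
  )
  utils::write.table(tab, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
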