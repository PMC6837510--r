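# Independent brute-force oracles, written position-by-position so they share
# no code path with the package implementations they check.

oracle_p_distance <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  diffs <- 0L
  n <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] %in% c("N", "-") || cb[i] %in% c("N", "-")) next
    n <- n + 1L
    if (ca[i] != cb[i]) diffs <- diffs + 1L
  }
  list(differences = diffs, sites_compared = n,
       p = if (n > 0) diffs / n else NA_real_)
}

oracle_classify_column <- function(col) {
  if (any(col == "N") || any(col == "-")) return("unclassified")
  counts <- sapply(unique(col), function(s) sum(col == s))
  if (length(counts) == 1) return("conserved")
  if (sum(counts >= 2) >= 2) return("parsimony_informative")
  # variable, at most one state with count >= 2
  if (length(counts) == 2 && sort(counts)[1] == 1) return("singleton")
  "other_variable"
}

oracle_degeneracy <- function(codon, position, code) {
  target <- code[[codon]]
  n <- 0L
  for (b in c("A", "C", "G", "T")) {
    v <- codon
    substr(v, position, position) <- b
    if (code[[v]] == target) n <- n + 1L
  }
  n
}

# NG86 oracle: potential sites by explicit 9-mutation enumeration, observed
# differences by recursive pathway enumeration.
oracle_ng86_counts <- function(codons_a, codons_b, code) {
  stop_codons <- names(code)[code == "*"]
  syn_sites_codon <- function(cd) {
    s <- 0
    for (pos in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (b == substr(cd, pos, pos)) next
        v <- cd
        substr(v, pos, pos) <- b
        if (!(v %in% stop_codons) && code[[v]] == code[[cd]]) s <- s + 1 / 3
      }
    }
    s
  }
  paths <- function(cur, target) {
    pos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (length(pos) == 0) {
      return(list(list(syn = 0, nonsyn = 0, blocked = FALSE)))
    }
    out <- list()
    for (p in pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(target, p, p)
      step_syn <- code[[nxt]] == code[[cur]]
      step_blocks <- (nxt %in% stop_codons) && nxt != target
      for (rest in paths(nxt, target)) {
        out[[length(out) + 1]] <- list(
          syn = rest$syn + as.integer(step_syn),
          nonsyn = rest$nonsyn + as.integer(!step_syn),
          blocked = rest$blocked || step_blocks)
      }
    }
    out
  }
  S <- 0; Sd <- 0; Nd <- 0; L <- 0
  for (i in seq_along(codons_a)) {
    ca <- codons_a[i]; cb <- codons_b[i]
    if (ca %in% stop_codons || cb %in% stop_codons) next
    if (grepl("[^ACGT]", ca) || grepl("[^ACGT]", cb)) next
    L <- L + 1
    S <- S + (syn_sites_codon(ca) + syn_sites_codon(cb)) / 2
    if (ca != cb) {
      pw <- paths(ca, cb)
      keep <- Filter(function(x) !x$blocked, pw)
      if (length(keep) == 0) keep <- pw
      Sd <- Sd + mean(sapply(keep, `[[`, "syn"))
      Nd <- Nd + mean(sapply(keep, `[[`, "nonsyn"))
    }
  }
  list(S = S, N = 3 * L - S, Sd = Sd, Nd = Nd, codons = L)
}

random_cds_codons <- function(n_codons, code) {
  sense <- names(code)[code != "*"]
  sample(sense, n_codons, replace = TRUE)
}
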