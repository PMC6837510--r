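# Small, fast simulator configurations used across tests.

# Same 37-gene architecture as the default, scaled down so a clade simulation
# takes milliseconds.
mini_architecture <- function() {
  arch <- default_gene_architecture()
  arch$length[arch$kind == "PCG"] <- 60L
  arch$length[arch$kind == "tRNA"] <- 12L
  arch$length[arch$kind == "rRNA"] <- 60L
  arch$length[arch$kind == "control"] <- 30L
  arch$gap_after <- ifelse(arch$gap_after > 0, 2L, 0L)
  arch
}

mini_config <- function(seed = 1L, ...) {
  sim_config(seed = seed, genome_length_target = 1204L,
             architecture = mini_architecture(), ...)
}

# Two-tip chronogram with both tips at age `years`.
two_tip_tree <- function(years, labels = c("tipA", "tipB")) {
  ape::read.tree(text = sprintf("(%s:%s,%s:%s);", labels[1],
                                format(years, scientific = FALSE),
                                labels[2],
                                format(years, scientific = FALSE)))
}

tip_sequences <- function(sim) {
  vapply(sim$genomes, function(g) g$sequence, character(1))
}

pcg_alignment <- function(sim) {
  vapply(sim$genomes, function(g) paste(extract_pcgs(g), collapse = ""),
         character(1))
}
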