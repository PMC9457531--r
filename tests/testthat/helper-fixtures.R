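# Shared fixture builders; everything is generated in code at test time.

AA20bb <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

aa_sample <- function(n, seed) {
  set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

nt_sample <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A deliberately small scenario so module tests stay fast; the full-size
# defaults are exercised in the acceptance suite.
small_scenario_config <- function(seed = 7L) {
  scenario_config(seed = seed, n_enzymes = 5L, enzyme_length = 120L,
                  enriched_subset = c("1", "2", "3"),
                  isolate_subset = c("1", "2"),
                  genome_length = 6000L, n_isolates = 2L,
                  decoy_orf_length = 80L)
}

# Hand-built presence matrix for set-logic tests (no alignment involved).
toy_presence <- function(present) {
  structure(list(enzymes = rownames(present), genomes = colnames(present),
                 best = NULL, similarity = NULL, identity = NULL,
                 coverage = NULL, present = present, threshold_pct = 30,
                 coverage_min_pct = 50, metric = "similarity"),
            class = "presence_matrix")
}

# One planted-ortholog (or decoy, identity = NA) detection replicate under
# the default presence rule: similarity > 30 and query coverage >= 50,
# evaluated on the maximum-score alignment.
planted_detected <- function(identity, seed, genome_len = 50000L,
                             plen = 300L) {
  enz <- seq_record("q", random_protein(plen, bbrpath:::sub_seed(seed, 1L)),
                    "protein")
  g <- new_genome("g_c1", genome_len, bbrpath:::sub_seed(seed, 2L))
  if (!is.na(identity)) {
    ortho <- mutate_protein(enz$residues, identity,
                            bbrpath:::sub_seed(seed, 3L))
    set.seed(bbrpath:::sub_seed(seed, 4L))
    pos <- sample.int(genome_len - 3L * plen, 1L)
    g <- plant_gene(g, ortho, sample(c("+", "-"), 1L), pos,
                    seed = bbrpath:::sub_seed(seed, 5L))
  }
  hit <- best_hit(enz, list(g$record))
  !is.null(hit) && hit$similarity_pct > 30 && hit$query_coverage_pct >= 50
}

# Direct per-codon translation oracle, independent of the package's
# implementation path (standard code written out via Biostrings).
oracle_translate <- function(nt, frame = 0L, strand = "+") {
  if (strand == "-")
    nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  nt <- substr(nt, frame + 1L, nchar(nt))
  nt <- substr(nt, 1L, 3L * (nchar(nt) %/% 3L))
  if (nchar(nt) == 0L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                     if.fuzzy.codon = "solve"))
}
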