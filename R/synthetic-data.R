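# Synonymous codons per amino acid, derived from the codon table.
.codons_by_aa <- local({
  split(names(.codon_table), .codon_table)
})

# Deterministic sub-seed derivation; keeps every derived seed a valid
# 32-bit integer.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483629)
}

#' Random protein sequence
#' @param length Number of residues.
#' @param seed Integer seed.
#' @return Protein string over the 20 standard amino acids.
#' @export
random_protein <- function(length, seed) {
  set.seed(seed)
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

#' Mutate a protein to a target percent identity
#'
#' Substitutes residues at uniformly chosen distinct positions, each
#' replaced by a uniformly drawn different residue, until the realized
#' identity (exact positional matches) is within 2 points of the target.
#' Uniform (rather than conservative) replacements are used on purpose:
#' low-identity mutants then behave like unrelated sequence under
#' BLOSUM62 scoring, which is what a detection-threshold null requires.
#'
#' @param seq Protein string.
#' @param target_identity_pct Target identity in (0, 100].
#' @param seed Integer seed.
#' @return Mutated protein string of equal length.
#' @export
#' @examples
#' mutate_protein("MKVLANDESTRGHW", 100, 1)  # unchanged
mutate_protein <- function(seq, target_identity_pct, seed) {
  if (target_identity_pct <= 0 || target_identity_pct > 100)
    stop("target identity must be in (0, 100]")
  L <- nchar(seq)
  k <- round(L * (1 - target_identity_pct / 100))
  realized <- 100 * (L - k) / L
  if (abs(realized - target_identity_pct) > 2)
    stop("target identity ", target_identity_pct,
         " unreachable within 2 points at length ", L,
         " (identity granularity ", format(100 / L), " points)")
  if (k == 0L) return(seq)
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(L, k)
  for (p in pos) {
    chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Reverse-translate a protein with uniform synonymous codons
#' @param protein Protein string (20 standard residues).
#' @param seed Integer seed.
#' @return Nucleotide CDS of length `3 * nchar(protein)` (no stop codon
#'   appended).
#' @export
reverse_translate <- function(protein, seed) {
  set.seed(seed)
  chars <- strsplit(protein, "")[[1]]
  if (!all(chars %in% AA20))
    stop("reverse translation needs standard residues only")
  codons <- vapply(chars, function(a) {
    opts <- .codons_by_aa[[a]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  paste(codons, collapse = "")
}

#' Random genome scaffold
#' @param id Contig/genome identifier.
#' @param length Genome length in nucleotides.
#' @param seed Integer seed.
#' @return A `synthetic_genome`: the contig [seq_record] plus a ledger of
#'   planted intervals.
#' @export
new_genome <- function(id, length, seed) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
               collapse = "")
  structure(list(record = seq_record(id, seq, "nucleotide"),
                 planted = data.frame(start = integer(0), end = integer(0),
                                      what = character(0))),
            class = "synthetic_genome")
}

#' Plant a protein-coding gene into a synthetic genome
#'
#' Reverse-translates the protein (seeded synonymous codon choice) and
#' overwrites the genome window starting at `position`; on the `-` strand
#' the reverse complement of the CDS is written, so the protein appears in
#' a minus-strand reading frame. Flanks are untouched and overlaps with
#' previously planted genes are an error.
#'
#' @param genome A `synthetic_genome` from [new_genome()].
#' @param protein Protein string to plant.
#' @param strand `"+"` or `"-"`.
#' @param position 1-based start of the CDS window on the forward strand.
#' @param frame_offset Optional expected frame (0-2); validated against the
#'   frame implied by `position` and `strand`.
#' @param seed Integer seed for codon choice.
#' @param what Label recorded in the planted ledger.
#' @return The updated genome; the new ledger row carries the realized
#'   `strand`, `frame`, `start`, `end`.
#' @export
plant_gene <- function(genome, protein, strand = "+", position,
                       frame_offset = NULL, seed = 1L, what = "gene") {
  stopifnot(inherits(genome, "synthetic_genome"), strand %in% c("+", "-"))
  L <- nchar(genome$record$residues)
  span <- 3L * nchar(protein)
  if (position < 1L || position + span - 1L > L)
    stop("position leaves no room for a ", span, " nt CDS")
  end <- position + span - 1L
  if (any(position <= genome$planted$end & end >= genome$planted$start))
    stop("planted gene would overlap an existing one at position ", position)
  frame <- if (strand == "+") (position - 1L) %% 3L else (L - end) %% 3L
  if (!is.null(frame_offset) && frame != frame_offset)
    stop("position ", position, " on strand ", strand, " implies frame ",
         frame, ", not ", frame_offset)
  cds <- reverse_translate(protein, seed)
  if (strand == "-") cds <- revcomp(cds)
  seq <- genome$record$residues
  substr(seq, position, end) <- cds
  genome$record$residues <- seq
  genome$planted <- rbind(genome$planted,
                          data.frame(start = position, end = end,
                                     what = what, strand = strand,
                                     frame = frame))
  genome
}

# Random non-overlapping planting position.
free_position <- function(genome, span) {
  L <- nchar(genome$record$residues)
  for (try in 1:200) {
    p <- sample.int(L - span + 1L, 1L)
    if (!any(p <= genome$planted$end & p + span - 1L >= genome$planted$start))
      return(p)
  }
  stop("could not find a free planting position (genome too crowded)")
}

#' Scenario configuration for the planted-truth benchmark
#'
#' Defaults mirror the study design this package models: a numbered
#' pathway of 26 enzymes; an uncultivable enriched-genus genome
#' (Methylotenera-like) carrying orthologs of enzymes 1, 2, 3, 9 and 24;
#' eight cultivable non-degrader isolates (five Pseudomonas, two
#' Sphingobacterium, one Agrobacterium) carrying only 1, 2, 3 and 24;
#' orthologs planted at 60% amino-acid identity on random strands/frames of
#' 50 kb genomes salted with decoy ORFs.
#'
#' @param seed Master seed; all randomness derives from it.
#' @param n_enzymes Number of pathway enzymes (labelled `"1"`..).
#' @param enzyme_length Parent protein length (residues).
#' @param enriched_subset,isolate_subset Enzyme labels planted in the
#'   enriched-genus genome and in each isolate.
#' @param planted_identity_pct Target amino-acid identity of planted
#'   orthologs.
#' @param genome_length Genome length (nt).
#' @param n_isolates Number of isolate genomes.
#' @param isolate_genera Genus labels recycled over the isolates.
#' @param decoy_orf_density Decoy ORFs per kb of genome.
#' @param decoy_orf_length Decoy protein length (residues).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(seed = 42L,
                            n_enzymes = 26L,
                            enzyme_length = 300L,
                            enriched_subset = c("1", "2", "3", "9", "24"),
                            isolate_subset = c("1", "2", "3", "24"),
                            planted_identity_pct = 60,
                            genome_length = 50000L,
                            n_isolates = 8L,
                            isolate_genera = c("Pseudomonas",
                                               "Sphingobacterium",
                                               "Pseudomonas",
                                               "Sphingobacterium",
                                               "Agrobacterium",
                                               "Pseudomonas", "Pseudomonas",
                                               "Pseudomonas"),
                            decoy_orf_density = 0.1,
                            decoy_orf_length = 250L) {
  labels <- as.character(seq_len(n_enzymes))
  if (!all(enriched_subset %in% labels) || !all(isolate_subset %in% labels))
    stop("enzyme subsets must be drawn from the pathway labels 1..",
         n_enzymes)
  structure(list(seed = as.integer(seed), n_enzymes = as.integer(n_enzymes),
                 enzyme_length = as.integer(enzyme_length),
                 enriched_subset = enriched_subset,
                 isolate_subset = isolate_subset,
                 planted_identity_pct = planted_identity_pct,
                 genome_length = as.integer(genome_length),
                 n_isolates = as.integer(n_isolates),
                 isolate_genera = rep_len(isolate_genera,
                                          as.integer(n_isolates)),
                 decoy_orf_density = decoy_orf_density,
                 decoy_orf_length = as.integer(decoy_orf_length)),
            class = "scenario_config")
}

plant_set <- function(genome, enzymes, subset, identity_pct, base_seed,
                      truth_rows, genome_id) {
  for (e in subset) {
    parent <- enzymes[[e]]
    sd1 <- sub_seed(base_seed, match(e, names(enzymes)))
    ortho <- mutate_protein(parent$residues, identity_pct, sd1)
    realized <- 100 * mean(strsplit(parent$residues, "")[[1]] ==
                             strsplit(ortho, "")[[1]])
    set.seed(sub_seed(sd1, 7L))
    strand <- sample(c("+", "-"), 1L)
    pos <- free_position(genome, 3L * nchar(ortho))
    genome <- plant_gene(genome, ortho, strand, pos,
                         seed = sub_seed(sd1, 11L),
                         what = paste0("enzyme_", e))
    lr <- genome$planted[nrow(genome$planted), ]
    truth_rows[[length(truth_rows) + 1L]] <- data.frame(
      genome_id = genome_id, enzyme_id = e,
      contig = genome$record$id, strand = lr$strand, frame = lr$frame,
      position = lr$start, realized_identity_pct = realized)
  }
  list(genome = genome, truth = truth_rows)
}

add_decoys <- function(genome, n, length, base_seed) {
  for (d in seq_len(n)) {
    sd <- sub_seed(base_seed, 500L + d)
    prot <- random_protein(length, sd)
    set.seed(sub_seed(sd, 3L))
    strand <- sample(c("+", "-"), 1L)
    pos <- tryCatch(free_position(genome, 3L * length),
                    error = function(e) NA_integer_)
    if (is.na(pos)) next
    genome <- plant_gene(genome, prot, strand, pos,
                         seed = sub_seed(sd, 5L), what = "decoy")
  }
  genome
}

#' Generate the full planted-truth scenario
#'
#' Draws random parent proteins for every pathway enzyme, builds one
#' enriched-genus genome and `n_isolates` isolate genomes, plants the
#' configured enzyme subsets as diverged orthologs (plus decoy ORFs) at
#' random strands/frames, and emits the genome-role table and the ground
#' truth. Fully deterministic under the config's seed.
#'
#' @param config A [scenario_config()].
#' @return A `bbr_scenario`: `enzymes` (named list of protein
#'   [seq_record]s), `genomes` (named list; each a list of contig records),
#'   `roles` (data.frame), `truth` (`planted` data.frame and
#'   `expected_essential`), and the `config`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  labels <- as.character(seq_len(config$n_enzymes))
  enzymes <- stats::setNames(lapply(labels, function(e) {
    seq_record(paste0("enzyme_", e),
               random_protein(config$enzyme_length,
                              sub_seed(config$seed, 1000L + as.integer(e))),
               "protein",
               description = paste("pathway enzyme", e))
  }), labels)

  n_decoys <- round(config$decoy_orf_density * config$genome_length / 1000)
  truth_rows <- list()
  genomes <- list()
  roles <- list()

  build_genome <- function(genome_id, genus, role, subset, gseed) {
    g <- new_genome(paste0(genome_id, "_c1"), config$genome_length, gseed)
    g <- add_decoys(g, n_decoys, config$decoy_orf_length,
                    sub_seed(gseed, 1L))
    res <- plant_set(g, enzymes, subset, config$planted_identity_pct,
                     sub_seed(gseed, 2L), truth_rows, genome_id)
    truth_rows <<- res$truth
    genomes[[genome_id]] <<- list(res$genome$record)
    roles[[length(roles) + 1L]] <<- data.frame(genome_id = genome_id,
                                               genus = genus, role = role)
  }

  build_genome("enriched_Methylotenera", "Methylotenera", "enriched_genus",
               config$enriched_subset, sub_seed(config$seed, 1L))
  for (i in seq_len(config$n_isolates)) {
    build_genome(paste0("isolate_J", i), config$isolate_genera[i],
                 "nondegrader_isolate", config$isolate_subset,
                 sub_seed(config$seed, 1L + i))
  }

  planted <- do.call(rbind, truth_rows)
  rownames(planted) <- NULL
  structure(list(
    enzymes = enzymes, genomes = genomes,
    roles = do.call(rbind, roles),
    truth = list(planted = planted,
                 expected_essential = setdiff(config$enriched_subset,
                                              config$isolate_subset)),
    config = config), class = "bbr_scenario")
}

#' Write a scenario to disk in the pipeline's file dialects
#'
#' Emits `enzymes.faa`, one `genomes/<id>.fna` per genome, `roles.tsv` and
#' `truth.json`.
#'
#' @param scenario A `bbr_scenario`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "bbr_scenario"))
  dir.create(file.path(dir, "genomes"), recursive = TRUE,
             showWarnings = FALSE)
  write_fasta(unname(scenario$enzymes), file.path(dir, "enzymes.faa"))
  for (g in names(scenario$genomes))
    write_fasta(scenario$genomes[[g]],
                file.path(dir, "genomes", paste0(g, ".fna")))
  utils::write.table(scenario$roles, file.path(dir, "roles.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(scenario$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Community time-series configuration
#'
#' Defaults emulate the observed dynamics: samples assayed on days 0, 3,
#' 6, 10 and 14; in degrading samples the focal genus rises from a
#' near-zero baseline to a sharp peak on day 3 and declines while a
#' successor genus rises after day 3; a control genus is enriched in both
#' degrading and stable samples; degradation curves hold ~100 ug/mL
#' through a ~5-day lag, then decay below 10% residual within 2-3 days.
#'
#' @param n_degrading,n_stable Numbers of samples per group.
#' @param depth Sequencing depth (reads per sample per day, >= 100).
#' @param timepoints Amplicon sampling days.
#' @param curve_days Degradation-curve sampling days (daily by default).
#' @param lag_days Lag phase length of degrading curves.
#' @param initial_conc Initial compound concentration (ug/mL).
#' @param noise_sd Multiplicative measurement noise (log scale).
#' @return A `community_config` list.
#' @export
community_config <- function(n_degrading = 3L, n_stable = 3L,
                             depth = 20000L,
                             timepoints = c(0L, 3L, 6L, 10L, 14L),
                             curve_days = 0:14, lag_days = 5L,
                             initial_conc = 100, noise_sd = 0.02) {
  if (depth < 100L) stop("depth below 100 reads makes fractions meaningless")
  structure(as.list(environment()), class = "community_config")
}

# Piecewise templates over timepoints 0, 3, 6, 10, 14 (interpolated for
# other sampling grids).
.community_templates <- function(group) {
  if (group == "degraded")
    list(Methylotenera    = c(0.001, 0.220, 0.090, 0.020, 0.005),
         Novosphingobium  = c(0.001, 0.020, 0.100, 0.160, 0.180),
         Flavobacterium   = c(0.010, 0.200, 0.100, 0.050, 0.030),
         Delftia          = c(0.001, 0.005, 0.030, 0.080, 0.100),
         Sphingopyxis     = c(0.001, 0.004, 0.020, 0.060, 0.080),
         Pseudomonas      = c(0.200, 0.160, 0.140, 0.120, 0.110),
         Stenotrophomonas = c(0.100, 0.080, 0.070, 0.060, 0.055),
         Acinetobacter    = c(0.150, 0.010, 0.001, 0.001, 0.001))
  else
    list(Methylotenera    = c(0.001, 0.001, 0.001, 0.001, 0.001),
         Novosphingobium  = c(0.001, 0.001, 0.001, 0.001, 0.001),
         Flavobacterium   = c(0.010, 0.100, 0.060, 0.030, 0.020),
         Delftia          = c(0.001, 0.001, 0.001, 0.001, 0.001),
         Sphingopyxis     = c(0.001, 0.001, 0.001, 0.001, 0.001),
         Pseudomonas      = c(0.200, 0.180, 0.170, 0.160, 0.150),
         Stenotrophomonas = c(0.100, 0.090, 0.085, 0.080, 0.075),
         Acinetobacter    = c(0.150, 0.150, 0.145, 0.140, 0.140))
}

#' Generate genus-count tables and degradation curves
#'
#' Multinomial read sampling at the configured depth around the group
#' templates (see [community_config()]); an `Other` genus absorbs the
#' remaining probability mass so abundances are complete.
#'
#' @param config A [community_config()].
#' @param seed Integer seed.
#' @return List with `counts` (list of [genus_counts()]) and `curves`
#'   (list of [degradation_curve()]), sample ids `deg_i` / `stable_i`.
#' @export
generate_community_series <- function(config = community_config(),
                                      seed = 42L) {
  stopifnot(inherits(config, "community_config"))
  tp <- config$timepoints
  base5 <- c(0, 3, 6, 10, 14)
  make_sample <- function(sample_id, group, sseed) {
    tmpl <- .community_templates(group)
    probs <- vapply(tmpl, function(v)
      stats::approx(base5, v, xout = pmin(tp, 14), rule = 2)$y,
      numeric(length(tp)))
    probs <- t(probs)  # genus x day
    other <- pmax(0, 1 - colSums(probs))
    probs <- rbind(probs, Other = other)
    set.seed(sseed)
    counts <- apply(probs, 2L, function(p)
      as.integer(stats::rmultinom(1L, config$depth, p)))
    rownames(counts) <- rownames(probs)
    tab <- genus_counts(counts, tp, sample_id)

    days <- config$curve_days
    rel <- if (group == "degraded") {
      decay <- c(0.55, 0.07, 0.015)
      vapply(days, function(d) {
        if (d <= config$lag_days) 1.0
        else if (d - config$lag_days <= length(decay))
          decay[d - config$lag_days]
        else 0.01
      }, 0)
    } else rep(1.0, length(days))
    conc <- config$initial_conc * rel *
      exp(stats::rnorm(length(days), 0, config$noise_sd))
    curve <- degradation_curve(days, pmax(conc, 0), sample_id)
    list(counts = tab, curve = curve)
  }
  ids <- c(paste0("deg_", seq_len(config$n_degrading)),
           paste0("stable_", seq_len(config$n_stable)))
  groups <- rep(c("degraded", "stable"),
                c(config$n_degrading, config$n_stable))
  out <- lapply(seq_along(ids), function(i)
    make_sample(ids[i], groups[i], sub_seed(seed, 2000L + i)))
  list(counts = stats::setNames(lapply(out, `[[`, "counts"), ids),
       curves = stats::setNames(lapply(out, `[[`, "curve"), ids))
}

#' Synthetic methyltransferase homolog family with a planted motif
#'
#' Builds a parent protein carrying exactly one `GCGxG`-matching window,
#' mutates each family member at `mutation_rate` per site outside the
#' motif window, and removes the motif from a `1 - carriage` fraction of
#' members. Members are equal length (substitution-only divergence), so
#' the family aligns without gaps and the motif columns coincide.
#'
#' @param n Family size.
#' @param length Protein length.
#' @param carriage Fraction of members carrying the intact motif.
#' @param motif Concrete motif instance planted (default `"GCGAG"`).
#' @param mutation_rate Per-site substitution probability outside the
#'   motif.
#' @param seed Integer seed.
#' @return List of protein [seq_record]s (`hom1`..`homN`); attribute
#'   `motif_position` gives the planted residue position.
#' @export
make_motif_family <- function(n = 7L, length = 200L, carriage = 1.0,
                              motif = "GCGAG", mutation_rate = 0.2,
                              seed = 42L) {
  stopifnot(n >= 2L, length >= nchar(motif) + 10L)
  pat_re <- "GCG.G"
  parent <- random_protein(length, sub_seed(seed, 1L))
  pos <- as.integer(floor(length / 2))
  substr(parent, pos, pos + nchar(motif) - 1L) <- motif
  # scrub accidental pattern windows elsewhere (deterministically)
  repeat {
    m <- gregexpr(pat_re, parent)[[1]]
    m <- m[m > 0 & m != pos]
    if (length(m) == 0L) break
    w <- m[1L]
    fixed <- c(w, w + 1L, w + 2L, w + 4L)  # non-wildcard positions
    out <- fixed[fixed < pos | fixed > pos + nchar(motif) - 1L][1L]
    substr(parent, out, out) <- "L"
  }
  carriers <- seq_len(n) <= round(carriage * n)
  members <- lapply(seq_len(n), function(i) {
    set.seed(sub_seed(seed, 100L + i))
    chars <- strsplit(parent, "")[[1]]
    protected <- seq.int(pos, pos + nchar(motif) - 1L)
    mut <- which(stats::runif(length) < mutation_rate)
    mut <- setdiff(mut, protected)
    for (p in mut) chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
    if (!carriers[i]) chars[pos] <- "A"  # break the leading G of the motif
    seq_record(paste0("hom", i), paste(chars, collapse = ""), "protein")
  })
  attr(members, "motif_position") <- pos
  members
}

#' @export
print.bbr_scenario <- function(x, ...) {
  cat(sprintf("Synthetic scenario: %d enzymes, %d genomes (%d kb), seed %d\n",
              length(x$enzymes), length(x$genomes),
              round(x$config$genome_length / 1000), x$config$seed))
  cat("  expected essential candidate(s): ",
      paste(x$truth$expected_essential, collapse = ", "), "\n", sep = "")
  invisible(x)
}
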