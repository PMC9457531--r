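# Translate and encode every searchable subject of a genome once, so the
# same frames can be reused across all pathway enzymes.
genome_subjects <- function(genome, matrix) {
  if (inherits(genome, "seq_record")) genome <- list(genome)
  if (length(genome) == 0L) stop("empty genome")
  subjects <- list()
  for (rec in genome) {
    if (rec$alphabet == "nucleotide") {
      for (fr in six_frame_translate(rec)) {
        if (!nzchar(fr$residues)) next
        subjects[[length(subjects) + 1L]] <- list(
          subject_id = fr$contig_id, strand = fr$strand, frame = fr$frame,
          residues = fr$residues,
          encoded = encode_residues(fr$residues, matrix))
      }
    } else {
      subjects[[length(subjects) + 1L]] <- list(
        subject_id = rec$id, strand = NA_character_, frame = NA_integer_,
        residues = rec$residues,
        encoded = encode_residues(rec$residues, matrix))
    }
  }
  if (length(subjects) == 0L)
    stop("genome contains no translatable sequence")
  subjects
}

#' Best local alignment of one enzyme against one genome
#'
#' Nucleotide genomes are searched in all six reading frames of every
#' contig (alignments may span stop codons, which score -4); protein
#' records are searched directly. The hit with the maximum Smith-Waterman
#' score wins; ties are broken by higher similarity, then lexicographic
#' subject id, then strand (`+` before `-`), then frame.
#'
#' @param enzyme A protein [seq_record] (the pathway enzyme query).
#' @param genome List of [seq_record]s (contigs or proteins).
#' @param matrix,gap_open,gap_extend Scoring parameters, see
#'   [smith_waterman()].
#' @param subjects Pre-computed result of the internal subject translation
#'   (used by [build_presence_matrix()] to avoid re-translating).
#' @return A `local_alignment` with `subject_strand`/`subject_frame` set, or
#'   `NULL` when no alignment scores above 0.
#' @export
best_hit <- function(enzyme, genome, matrix = scoring_matrix(),
                     gap_open = 11L, gap_extend = 1L, subjects = NULL) {
  stopifnot(inherits(enzyme, "seq_record"), enzyme$alphabet == "protein")
  if (is.null(subjects)) subjects <- genome_subjects(genome, matrix)
  q <- encode_residues(enzyme$residues, matrix)
  scores <- vapply(subjects, function(s)
    cpp_local_score(q, s$encoded, matrix, as.integer(gap_open),
                    as.integer(gap_extend)), 0L)
  top <- max(scores)
  if (top <= 0L) return(NULL)
  cands <- which(scores == top)
  alns <- lapply(cands, function(k) {
    s <- subjects[[k]]
    raw <- cpp_local_align(q, s$encoded, matrix, as.integer(gap_open),
                           as.integer(gap_extend))
    build_alignment(raw, enzyme$residues, s$residues, matrix,
                    enzyme$id, s$subject_id, s$strand, s$frame)
  })
  if (length(alns) > 1L) {
    ord <- order(-vapply(alns, `[[`, 0, "similarity_pct"),
                 vapply(alns, `[[`, "", "subject_id"),
                 vapply(alns, function(a) a$subject_strand %||% "+", ""),
                 vapply(alns, function(a) a$subject_frame %||% 0L, 0L))
    alns <- alns[ord]
  }
  alns[[1L]]
}

#' Build the enzyme-by-genome presence/absence matrix
#'
#' For every pathway enzyme and genome, records the best local alignment and
#' calls presence when the chosen metric of that alignment exceeds
#' `threshold` (strict, matching the ">30%" rule) and its query coverage is
#' at least `coverage_min`. The coverage floor is a deliberate extension of
#' the bare similarity rule: short chance local hits routinely exceed 30%
#' per-column similarity, and requiring half the query to align suppresses
#' them without costing real orthologs.
#'
#' @param pathway List of protein [seq_record]s (enzymes; ids must be
#'   unique).
#' @param genomes Named list; each element a list of [seq_record]s.
#' @param threshold Presence threshold in percent (default 30, strict `>`).
#' @param metric `"similarity"` (default) or `"identity"`.
#' @param coverage_min Minimum query coverage percent (default 50, `>=`).
#' @param matrix,gap_open,gap_extend Scoring parameters.
#' @return A `presence_matrix`: enzyme x genome matrices `similarity`,
#'   `identity`, `coverage`, logical `present`, the best alignments in
#'   `best`, and the parameters used.
#' @export
build_presence_matrix <- function(pathway, genomes, threshold = 30,
                                  metric = c("similarity", "identity"),
                                  coverage_min = 50,
                                  matrix = scoring_matrix(),
                                  gap_open = 11L, gap_extend = 1L) {
  metric <- match.arg(metric)
  if (length(pathway) == 0L) stop("need at least one pathway enzyme")
  if (length(genomes) == 0L || is.null(names(genomes)) ||
      any(!nzchar(names(genomes))))
    stop("genomes must be a non-empty named list")
  enzyme_ids <- vapply(pathway, `[[`, "", "id")
  if (anyDuplicated(enzyme_ids)) stop("duplicate enzyme ids in pathway")
  genome_ids <- names(genomes)
  dims <- list(enzyme_ids, genome_ids)
  sim <- id <- cov <- matrix(NA_real_, length(pathway), length(genomes),
                             dimnames = dims)
  best <- matrix(list(), length(pathway), length(genomes), dimnames = dims)
  for (g in seq_along(genomes)) {
    subjects <- tryCatch(genome_subjects(genomes[[g]], matrix),
                         error = function(e)
                           stop("genome '", genome_ids[g], "': ",
                                conditionMessage(e), call. = FALSE))
    for (e in seq_along(pathway)) {
      hit <- best_hit(pathway[[e]], genomes[[g]], matrix, gap_open,
                      gap_extend, subjects = subjects)
      if (!is.null(hit)) {
        sim[e, g] <- hit$similarity_pct
        id[e, g] <- hit$identity_pct
        cov[e, g] <- hit$query_coverage_pct
        best[[e, g]] <- hit
      }
    }
  }
  val <- if (metric == "similarity") sim else id
  present <- !is.na(val) & val > threshold & cov >= coverage_min
  structure(list(enzymes = enzyme_ids, genomes = genome_ids, best = best,
                 similarity = sim, identity = id, coverage = cov,
                 present = present, threshold_pct = threshold,
                 coverage_min_pct = coverage_min, metric = metric),
            class = "presence_matrix")
}

#' Re-call presence on an existing matrix with different thresholds
#'
#' @param x A `presence_matrix` with alignment percentages filled.
#' @param threshold,metric,coverage_min See [build_presence_matrix()].
#' @return The matrix with `present` (and parameters) updated.
#' @export
recall_presence <- function(x, threshold = x$threshold_pct,
                            metric = x$metric,
                            coverage_min = x$coverage_min_pct) {
  stopifnot(inherits(x, "presence_matrix"))
  val <- if (metric == "similarity") x$similarity else x$identity
  x$present <- !is.na(val) & val > threshold & x$coverage >= coverage_min
  x$threshold_pct <- threshold
  x$coverage_min_pct <- coverage_min
  x$metric <- metric
  x
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("Presence matrix: %d enzymes x %d genomes (%s > %s%%, coverage >= %s%%)\n",
              length(x$enzymes), length(x$genomes), x$metric,
              format(x$threshold_pct), format(x$coverage_min_pct)))
  print(x$present)
  invisible(x)
}
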