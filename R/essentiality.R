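#' Construct a genome-role table
#'
#' @param genome_id,genus,role Equal-length vectors; `role` one of
#'   `enriched_genus` (genome of a degradation-associated, uncultivable
#'   genus), `nondegrader_isolate` (cultured strain that failed to degrade
#'   the compound) or `other`.
#' @return data.frame of roles.
#' @export
genome_roles <- function(genome_id, genus, role) {
  ok <- c("enriched_genus", "nondegrader_isolate", "other")
  if (!all(role %in% ok))
    stop("role must be one of: ", paste(ok, collapse = ", "))
  if (anyDuplicated(genome_id)) stop("duplicate genome_id in roles")
  data.frame(genome_id = genome_id, genus = genus, role = role)
}

#' Read a genome-role TSV (`genome_id`, `genus`, `role`)
#' @param path TSV file.
#' @return data.frame of roles.
#' @export
read_genome_roles <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "genus", "role")
  if (!all(need %in% colnames(df)))
    stop("roles TSV needs columns ", paste(need, collapse = ", "))
  genome_roles(df$genome_id, df$genus, df$role)
}

#' Classify pathway enzymes by their distribution across genome roles
#'
#' The taxon-restricted essential-enzyme inference: an enzyme present in at
#' least one enriched-genus genome but in no cultivable non-degrader
#' isolate is a candidate essential step -- the step the culturable
#' community cannot supply. Enzymes present in both groups are `shared`,
#' in isolates only `isolate_only`, in neither `absent`. Genomes with role
#' `other` are reported but never affect the classification.
#'
#' @param matrix A `presence_matrix`.
#' @param roles Role table covering every matrix genome (see
#'   [genome_roles()]).
#' @param enriched_rule `"any"` (default): presence in any enriched genome
#'   counts; `"all"`: require presence in every enriched genome.
#' @return An `essentiality_report`: data.frame `enzymes` with
#'   `enzyme_id`, `classification`, `present_in_enriched`,
#'   `present_in_isolates` (comma-joined genome ids), plus the vector of
#'   `essential_candidates`.
#' @export
classify_enzymes <- function(matrix, roles, enriched_rule = c("any", "all")) {
  stopifnot(inherits(matrix, "presence_matrix"))
  enriched_rule <- match.arg(enriched_rule)
  missing <- setdiff(matrix$genomes, roles$genome_id)
  if (length(missing) > 0L)
    stop("no role assigned for genome(s): ", paste(missing, collapse = ", "))
  role_of <- stats::setNames(roles$role, roles$genome_id)[matrix$genomes]
  enriched <- matrix$genomes[role_of == "enriched_genus"]
  isolates <- matrix$genomes[role_of == "nondegrader_isolate"]
  others <- matrix$genomes[role_of == "other"]
  if (length(enriched) == 0L || length(isolates) == 0L)
    stop("need at least one enriched_genus and one nondegrader_isolate genome")
  rows <- lapply(matrix$enzymes, function(e) {
    pe <- enriched[matrix$present[e, enriched]]
    pi <- isolates[matrix$present[e, isolates]]
    in_enr <- if (enriched_rule == "any") length(pe) > 0L
              else length(pe) == length(enriched)
    cls <- if (in_enr && length(pi) == 0L) "essential_candidate"
           else if (in_enr) "shared"
           else if (length(pi) > 0L) "isolate_only"
           else "absent"
    data.frame(enzyme_id = e, classification = cls,
               present_in_enriched = paste(pe, collapse = ","),
               present_in_isolates = paste(pi, collapse = ","),
               present_in_other = paste(others[matrix$present[e, others]],
                                        collapse = ","))
  })
  enzymes <- do.call(rbind, rows)
  rownames(enzymes) <- NULL
  structure(list(
    enzymes = enzymes,
    essential_candidates =
      enzymes$enzyme_id[enzymes$classification == "essential_candidate"],
    enriched_genomes = enriched, isolate_genomes = isolates,
    other_genomes = others, enriched_rule = enriched_rule),
    class = "essentiality_report")
}

#' @export
print.essentiality_report <- function(x, ...) {
  cat(sprintf("Essentiality report (%d enzymes; enriched rule: %s)\n",
              nrow(x$enzymes), x$enriched_rule))
  tab <- table(factor(x$enzymes$classification,
                      c("essential_candidate", "shared", "isolate_only",
                        "absent")))
  for (n in names(tab)) cat(sprintf("  %-20s %d\n", n, tab[[n]]))
  if (length(x$essential_candidates) > 0L)
    cat("  essential candidate(s): ",
        paste(x$essential_candidates, collapse = ", "), "\n", sep = "")
  invisible(x)
}
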