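#' Top-N hits by similarity
#'
#' @param hits Hit data.frame from [read_hit_table()] (needs `subject_id`
#'   and `similarity_pct`).
#' @param n Number of hits to keep (default 500). When fewer are available
#'   all are returned.
#' @return The `n` highest-similarity hits; ties broken by lexicographic
#'   subject id. Idempotent.
#' @export
top_hits <- function(hits, n = 500L) {
  if (n < 1L) stop("n must be >= 1")
  ord <- order(-hits$similarity_pct, hits$subject_id)
  out <- hits[ord[seq_len(min(n, nrow(hits)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  # tiny offset so decimal halves stored just below .5 still round up
  floor(x * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Per-genus counts and percentages of a hit set
#'
#' Percentages are computed on the genus-resolved denominator (hits whose
#' lineage carries a genus), not the full hit count: unresolved hits are
#' reported in `total_hits` but excluded from `genus_resolved_count`.
#' Percentages are rounded half-up to two decimals.
#'
#' @param hits Hit data.frame with a `genus` column (`NA` = unresolved).
#' @return A `genus_distribution`: `total_hits`, `genus_resolved_count`,
#'   and a data.frame `rows` (`genus`, `count`, `pct_of_resolved`) sorted
#'   by decreasing count then genus.
#' @export
#' @examples
#' h <- data.frame(subject_id = paste0("s", 1:4),
#'                 similarity_pct = 90,
#'                 genus = c("A", "B", "C", "D"))
#' genus_fraction(h)$rows$pct_of_resolved  # 25 each
genus_fraction <- function(hits) {
  if (nrow(hits) == 0L) stop("empty hit set")
  resolved <- hits[!is.na(hits$genus), , drop = FALSE]
  if (nrow(resolved) == 0L) stop("no hit has a resolved genus")
  tab <- table(resolved$genus)
  rows <- data.frame(genus = names(tab), count = as.integer(tab))
  rows$pct_of_resolved <- round_half_up(100 * rows$count / nrow(resolved))
  rows <- rows[order(-rows$count, rows$genus), , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(total_hits = nrow(hits),
                 genus_resolved_count = nrow(resolved),
                 rows = rows),
            class = "genus_distribution")
}

#' @export
print.genus_distribution <- function(x, ...) {
  cat(sprintf("Genus distribution: %d hits, %d genus-resolved, %d genera\n",
              x$total_hits, x$genus_resolved_count, nrow(x$rows)))
  print(utils::head(x$rows, 10L))
  invisible(x)
}
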