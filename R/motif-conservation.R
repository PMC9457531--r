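#' Center-star multiple sequence alignment
#'
#' Deterministic progressive MSA: the center is the sequence maximising the
#' summed pairwise global alignment scores against all others (ties broken
#' by id); every other sequence is aligned to the center with
#' [global_align()] and merged under "once a gap, always a gap" (gaps
#' opened in the center propagate to all previously merged rows). Chosen
#' for determinism and testability over progressive profile aligners;
#' adequate for families of full-length homologs.
#'
#' @param seqs List of >= 2 protein [seq_record]s with unique ids.
#' @param matrix,gap_open,gap_extend Scoring parameters.
#' @return An `msa_result`: named character vector `aligned` (equal-length
#'   gapped sequences, input order), numeric `column_conservation`
#'   (modal-residue fraction per column; gaps count in the denominator and
#'   never as the mode), and `center_id`.
#' @export
center_star_msa <- function(seqs, matrix = scoring_matrix(),
                            gap_open = 11L, gap_extend = 1L) {
  if (length(seqs) < 2L) stop("center-star MSA needs at least 2 sequences")
  ids <- vapply(seqs, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  n <- length(seqs)
  # summed pairwise global scores -> center
  total <- numeric(n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    sc <- cpp_global_score(encode_residues(seqs[[i]]$residues, matrix),
                           encode_residues(seqs[[j]]$residues, matrix),
                           matrix, as.integer(gap_open),
                           as.integer(gap_extend))
    total[i] <- total[i] + sc
    total[j] <- total[j] + sc
  }
  center <- order(-total, ids)[1L]

  master <- strsplit(seqs[[center]]$residues, "")[[1]]  # center, gapped
  rows <- list()  # merged non-center rows as character vectors
  row_ids <- character(0)
  # merge in id order so the result is input-order invariant
  for (k in order(ids)) {
    if (k == center) next
    aln <- global_align(paste(master[master != "-"], collapse = ""),
                        seqs[[k]]$residues, matrix, gap_open, gap_extend)
    ac <- strsplit(aln$aligned_query, "")[[1]]    # center with new gaps
    ao <- strsplit(aln$aligned_subject, "")[[1]]  # new sequence
    # map the pairwise center gapping onto the master gapping
    merged_center <- character(0)
    merged_new <- character(0)
    mi <- 1L  # position in master
    pi <- 1L  # position in pairwise alignment
    while (mi <= length(master) || pi <= length(ac)) {
      m_gap <- mi <= length(master) && master[mi] == "-"
      p_gap <- pi <= length(ac) && ac[pi] == "-"
      if (m_gap && !p_gap) {
        merged_center <- c(merged_center, "-")
        merged_new <- c(merged_new, "-")
        mi <- mi + 1L
      } else if (p_gap) {
        merged_center <- c(merged_center, "-")
        merged_new <- c(merged_new, ao[pi])
        rows <- lapply(rows, append, "-", after = length(merged_center) - 1L)
        pi <- pi + 1L
      } else {
        merged_center <- c(merged_center, master[mi])
        merged_new <- c(merged_new, ao[pi])
        mi <- mi + 1L
        pi <- pi + 1L
      }
    }
    master <- merged_center
    rows <- lapply(rows, function(r)
      if (length(r) < length(master))
        c(r, rep("-", length(master) - length(r))) else r)
    rows[[length(rows) + 1L]] <- merged_new
    row_ids <- c(row_ids, ids[k])
  }
  aligned <- stats::setNames(c(list(master), rows),
                             c(ids[center], row_ids))
  aligned <- vapply(aligned, paste, "", collapse = "")
  aligned <- aligned[ids]  # restore input order
  structure(list(aligned = aligned,
                 column_conservation = column_conservation(aligned),
                 center_id = ids[center]),
            class = "msa_result")
}

#' Per-column conservation of an alignment
#'
#' Fraction of sequences carrying the modal (most frequent non-gap) residue
#' in each column; gaps count in the denominator, so gappy columns score
#' low.
#'
#' @param aligned Named character vector of equal-length gapped sequences.
#' @return Numeric vector in \[0, 1\], one value per column.
#' @export
column_conservation <- function(aligned) {
  mat <- do.call(rbind, strsplit(aligned, ""))
  apply(mat, 2L, function(col) {
    res <- col[col != "-"]
    if (length(res) == 0L) return(0)
    max(table(res)) / length(col)
  })
}

parse_motif <- function(pattern) {
  if (!nzchar(pattern)) stop("empty motif pattern")
  chars <- strsplit(toupper(pattern), "")[[1]]
  if (!all(chars %in% c(LETTERS)))
    stop("motif pattern may contain only residue letters and the 'x' wildcard")
  chars
}

#' Scan an alignment for a conserved sequence motif
#'
#' Slides the pattern over alignment columns. A sequence matches a window
#' when it is gap-free there and every fixed pattern letter equals its
#' residue (`x`/`X` matches any residue). A window is a hit when at least
#' `min_conservation` of the sequences match. On a single-sequence
#' alignment this reduces to plain wildcard substring search.
#'
#' @param msa An `msa_result` (or named character vector of gapped
#'   sequences).
#' @param pattern Motif such as `"GCGxG"`; letters plus the `x` wildcard.
#' @param min_conservation Minimum matching-sequence fraction (default
#'   0.8).
#' @return data.frame with one row per hit: `pattern`, `column_start`,
#'   `match_fraction`, and `matched` (comma-joined `id=substring` for
#'   matching sequences).
#' @export
#' @examples
#' msa <- list(aligned = c(a = "MGCGAGK", b = "MGCGAGK"))
#' scan_motif(msa, "GCGxG")
scan_motif <- function(msa, pattern, min_conservation = 0.8) {
  aligned <- if (is.list(msa)) msa$aligned else msa
  pat <- parse_motif(pattern)
  L <- length(pat)
  mat <- do.call(rbind, strsplit(aligned, ""))
  ids <- names(aligned)
  width <- ncol(mat)
  hits <- list()
  if (width >= L) for (start in seq_len(width - L + 1L)) {
    win <- mat[, start:(start + L - 1L), drop = FALSE]
    match_ok <- apply(win, 1L, function(row) {
      if (any(row == "-")) return(FALSE)
      all(pat == "X" | row == pat)
    })
    frac <- mean(match_ok)
    if (frac >= min_conservation) {
      matched <- paste(sprintf("%s=%s", ids[match_ok],
                               apply(win[match_ok, , drop = FALSE], 1L,
                                     paste, collapse = "")),
                       collapse = ",")
      hits[[length(hits) + 1L]] <- data.frame(
        pattern = pattern, column_start = start, match_fraction = frac,
        matched = matched)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(pattern = character(0), column_start = integer(0),
                      match_fraction = numeric(0), matched = character(0)))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Recover ungapped input sequences from an MSA
#' @param msa An `msa_result`.
#' @return Named character vector of de-gapped sequences.
#' @export
degap_msa <- function(msa) {
  vapply(msa$aligned, gsub, "", pattern = "-", replacement = "",
         fixed = TRUE)
}

#' @export
print.msa_result <- function(x, ...) {
  cat(sprintf("MSA of %d sequences, %d columns (center: %s)\n",
              length(x$aligned), nchar(x$aligned[[1L]]), x$center_id))
  invisible(x)
}
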