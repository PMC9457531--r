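#' @useDynLib bbrpath, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.bbr_env <- new.env(parent = emptyenv())

# Standard genetic code (identical to the bacterial/plastid table 11 for
# internal codons; start-codon differences are irrelevant here because no ORF
# calling is performed). Codons containing N translate to 'X'.
.codon_table <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  # 4x4x4 in TCAG order, first base slowest when built this way; rebuild
  # explicitly to keep the mapping auditable.
  codons <- character(64)
  aas <- character(64)
  k <- 1L
  aa_string <- paste0(
    "FFLLSSSSYY**CC*W", # TTT..TGG
    "LLLLPPPPHHQQRRRR", # CTT..CGG
    "IIIMTTTTNNKKSSRR", # ATT..AGG
    "VVVVAAAADDEEGGGG"  # GTT..GGG
  )
  aa <- strsplit(aa_string, "")[[1]]
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    codons[k] <- paste0(b1, b2, b3)
    k <- k + 1L
  }
  stats::setNames(aa, codons)
})

#' Default protein scoring matrix
#'
#' BLOSUM62 with the ambiguity/stop characters `X` and `*` rescored to -4
#' against everything (including themselves). Frame-translated genome
#' subjects contain stop codons and `X` residues; the flat -4 keeps them from
#' ever contributing positive ("similar") alignment columns.
#'
#' @param name Matrix name available in `Biostrings` (default `"BLOSUM62"`).
#' @return Integer matrix with residue-labelled dimnames.
#' @export
#' @examples
#' m <- scoring_matrix()
#' m["G", "G"]; m["X", "X"]
scoring_matrix <- function(name = "BLOSUM62") {
  key <- paste0("mat_", name)
  if (!is.null(.bbr_env[[key]])) return(.bbr_env[[key]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- e[[name]]
  storage.mode(m) <- "integer"
  for (bad in intersect(c("X", "*"), rownames(m))) {
    m[bad, ] <- -4L
    m[, bad] <- -4L
  }
  .bbr_env[[key]] <- m
  m
}

#' Read a substitution matrix in NCBI plain-text format
#'
#' Parses the square whitespace-delimited layout used by NCBI matrix files
#' (`#` comment lines, one header row of residue letters, one labelled row
#' per residue).
#'
#' @param path File path.
#' @return Integer matrix with dimnames.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a scoring matrix: ", path)
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1L]), "\\s+")
  m <- matrix(NA_integer_, length(rows), length(header),
              dimnames = list(vapply(rows, `[`, "", 1L), header))
  for (i in seq_along(rows)) {
    v <- suppressWarnings(as.integer(rows[[i]][-1L]))
    if (anyNA(v) || length(v) != length(header))
      stop("malformed matrix row for residue ", rows[[i]][1L])
    m[i, ] <- v
  }
  if (!identical(rownames(m), colnames(m)))
    stop("scoring matrix must be square with matching residue labels")
  m
}

# Encode residues as 0-based indices into the scoring matrix alphabet.
encode_residues <- function(seq, mat) {
  idx <- match(strsplit(seq, "")[[1]], rownames(mat))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop("residue not covered by scoring matrix at position ", bad, ": ",
         substr(seq, bad, bad))
  }
  idx - 1L
}

#' Reverse-complement a nucleotide string
#' @param nt Nucleotide string (A/C/G/T/N).
#' @return Reverse-complemented string.
#' @export
revcomp <- function(nt) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(nt, "")[[1]]), collapse = ""))
}

#' Translate one reading frame of a nucleotide sequence
#'
#' Direct codon-table translation (bacterial code). Stop codons are rendered
#' as `*`; any codon containing `N` becomes `X`. Trailing bases that do not
#' complete a codon are dropped, so the protein length is
#' `floor((nchar(nt) - frame) / 3)`.
#'
#' @param nt Nucleotide string.
#' @param frame Frame offset 0, 1 or 2.
#' @param strand `"+"` or `"-"`; `"-"` reverse-complements first.
#' @return Protein string (possibly empty).
#' @export
#' @examples
#' translate_frame("ATGGCGTAA")            # "MA*"
#' translate_frame("TTACGCCAT", strand = "-")
translate_frame <- function(nt, frame = 0L, strand = "+") {
  stopifnot(frame %in% 0:2, strand %in% c("+", "-"))
  if (strand == "-") nt <- revcomp(nt)
  len <- nchar(nt)
  if (len - frame < 3L) return("")
  starts <- seq.int(frame + 1L, len - 2L, by = 3L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(.codon_table[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

#' Six-frame translation of a contig
#'
#' @param record A nucleotide [seq_record] (or plain string).
#' @return List of 6 frame translations, each a list with `contig_id`,
#'   `strand`, `frame`, `residues`; frames shorter than one codon are kept
#'   with empty residues (and noted via a message for sub-codon contigs).
#' @export
six_frame_translate <- function(record) {
  if (is.character(record)) record <- seq_record("contig", record, "nucleotide")
  stopifnot(inherits(record, "seq_record"), record$alphabet == "nucleotide")
  if (nchar(record$residues) < 3L)
    message("contig ", record$id, " shorter than one codon; no usable frames")
  out <- vector("list", 6L)
  k <- 1L
  for (strand in c("+", "-")) for (frame in 0:2) {
    out[[k]] <- list(contig_id = record$id, strand = strand, frame = frame,
                     residues = translate_frame(record$residues, frame, strand))
    k <- k + 1L
  }
  out
}

align_pcts <- function(ops, qchars, schars, mat) {
  ncols <- length(ops)
  if (ncols == 0L)
    return(list(identity = 0, similarity = 0, columns = 0L))
  qi <- qchars
  si <- schars
  diag <- ops == 0L
  ident <- diag & qi == si
  pos <- diag & !ident &
    mat[cbind(match(qi, rownames(mat)), match(si, colnames(mat)))] > 0
  pos[is.na(pos)] <- FALSE
  list(identity = 100 * sum(ident) / ncols,
       similarity = 100 * (sum(ident) + sum(pos)) / ncols,
       columns = ncols)
}

build_alignment <- function(raw, query, subject, mat, query_id, subject_id,
                            strand = NA_character_, frame = NA_integer_) {
  ops <- raw$ops
  qres <- strsplit(query, "")[[1]]
  sres <- strsplit(subject, "")[[1]]
  aligned_q <- character(length(ops))
  aligned_s <- character(length(ops))
  qi <- raw$q_start
  sj <- raw$s_start
  for (k in seq_along(ops)) {
    if (ops[k] == 0L) {
      aligned_q[k] <- qres[qi]; aligned_s[k] <- sres[sj]
      qi <- qi + 1L; sj <- sj + 1L
    } else if (ops[k] == 1L) {
      aligned_q[k] <- qres[qi]; aligned_s[k] <- "-"
      qi <- qi + 1L
    } else {
      aligned_q[k] <- "-"; aligned_s[k] <- sres[sj]
      sj <- sj + 1L
    }
  }
  pct <- align_pcts(ops, aligned_q, aligned_s, mat)
  cov <- if (raw$score > 0)
    100 * (raw$q_end - raw$q_start + 1) / nchar(query) else 0
  structure(list(
    query_id = query_id, subject_id = subject_id,
    subject_strand = strand, subject_frame = frame,
    query_start = raw$q_start, query_end = raw$q_end,
    subject_start = raw$s_start, subject_end = raw$s_end,
    score = raw$score,
    aligned_query = paste(aligned_q, collapse = ""),
    aligned_subject = paste(aligned_s, collapse = ""),
    identity_pct = pct$identity,
    similarity_pct = pct$similarity,
    query_coverage_pct = cov,
    query_length = nchar(query)
  ), class = "local_alignment")
}

#' Smith-Waterman local protein alignment with affine gaps
#'
#' Optimal local alignment under Gotoh's affine-gap recurrence. A gap of
#' length k costs `gap_open + k * gap_extend` (BLASTP defaults 11/1).
#' Percentage identity counts identical columns over all aligned columns
#' (gaps included in the denominator); percentage similarity additionally
#' counts positive-scoring substitution columns. Tie-breaking is
#' deterministic: among equal-scoring end cells the smallest
#' (subject_end, query_end) wins, and the traceback prefers diagonal, then
#' up (gap in subject), then left.
#'
#' @param query,subject Protein strings or protein [seq_record]s; non-empty.
#' @param matrix Substitution matrix (default [scoring_matrix()]).
#' @param gap_open,gap_extend Affine gap parameters.
#' @param query_id,subject_id Identifiers carried into the result.
#' @return A `local_alignment` with score, 1-based inclusive coordinates,
#'   gapped strings and identity/similarity/coverage percentages.
#' @export
#' @examples
#' aln <- smith_waterman("MKVLA", "XXXMKVLAXXX")
#' aln$query_coverage_pct  # 100
smith_waterman <- function(query, subject, matrix = scoring_matrix(),
                           gap_open = 11L, gap_extend = 1L,
                           query_id = "query", subject_id = "subject") {
  if (inherits(query, "seq_record")) { query_id <- query$id; query <- query$residues }
  if (inherits(subject, "seq_record")) { subject_id <- subject$id; subject <- subject$residues }
  if (!nzchar(query) || !nzchar(subject))
    stop("smith_waterman requires non-empty sequences")
  q <- encode_residues(query, matrix)
  s <- encode_residues(subject, matrix)
  raw <- cpp_local_align(q, s, matrix, as.integer(gap_open),
                         as.integer(gap_extend))
  build_alignment(raw, query, subject, matrix, query_id, subject_id)
}

#' Global (Needleman-Wunsch) protein alignment with affine gaps
#'
#' Same scoring model and tie-breaking as [smith_waterman()], but end-to-end;
#' used by the center-star multiple aligner.
#'
#' @inheritParams smith_waterman
#' @return List with `score`, `aligned_query`, `aligned_subject`.
#' @export
global_align <- function(query, subject, matrix = scoring_matrix(),
                         gap_open = 11L, gap_extend = 1L) {
  if (inherits(query, "seq_record")) query <- query$residues
  if (inherits(subject, "seq_record")) subject <- subject$residues
  if (!nzchar(query) || !nzchar(subject))
    stop("global_align requires non-empty sequences")
  q <- encode_residues(query, matrix)
  s <- encode_residues(subject, matrix)
  raw <- cpp_global_align(q, s, matrix, as.integer(gap_open),
                          as.integer(gap_extend))
  qres <- strsplit(query, "")[[1]]
  sres <- strsplit(subject, "")[[1]]
  ops <- raw$ops
  aq <- character(length(ops)); as_ <- character(length(ops))
  qi <- 1L; sj <- 1L
  for (k in seq_along(ops)) {
    if (ops[k] == 0L) { aq[k] <- qres[qi]; as_[k] <- sres[sj]; qi <- qi + 1L; sj <- sj + 1L }
    else if (ops[k] == 1L) { aq[k] <- qres[qi]; as_[k] <- "-"; qi <- qi + 1L }
    else { aq[k] <- "-"; as_[k] <- sres[sj]; sj <- sj + 1L }
  }
  list(score = raw$score,
       aligned_query = paste(aq, collapse = ""),
       aligned_subject = paste(as_, collapse = ""))
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf("Local alignment %s vs %s%s\n", x$query_id, x$subject_id,
              if (!is.na(x$subject_strand))
                sprintf(" (strand %s frame %d)", x$subject_strand, x$subject_frame)
              else ""))
  cat(sprintf("  score %d | identity %.1f%% | similarity %.1f%% | coverage %.1f%%\n",
              x$score, x$identity_pct, x$similarity_pct, x$query_coverage_pct))
  if (x$score > 0)
    cat(sprintf("  query %d-%d, subject %d-%d\n",
                x$query_start, x$query_end, x$subject_start, x$subject_end))
  invisible(x)
}
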