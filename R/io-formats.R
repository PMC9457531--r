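AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct a sequence record
#'
#' @param id First whitespace-delimited token of the FASTA header.
#' @param residues Residue string (stored uppercase).
#' @param alphabet `"nucleotide"` or `"protein"`.
#' @param description Remainder of the header line.
#' @return A `seq_record`.
#' @export
seq_record <- function(id, residues, alphabet = c("protein", "nucleotide"),
                       description = "") {
  alphabet <- match.arg(alphabet)
  residues <- toupper(residues)
  validate_residues(residues, alphabet, id)
  structure(list(id = id, description = description, residues = residues,
                 alphabet = alphabet), class = "seq_record")
}

validate_residues <- function(residues, alphabet, id) {
  if (!nzchar(residues))
    stop("record '", id, "' has empty residues")
  allowed <- if (alphabet == "nucleotide") "ACGTN"
             else paste(c(AA20, "X"), collapse = "")
  bad <- regexpr(sprintf("[^%s]", allowed), residues)
  if (bad > 0)
    stop("record '", id, "': invalid ", alphabet, " residue '",
         substr(residues, bad, bad), "' at position ", bad)
  invisible(TRUE)
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<%s record '%s'> %d residues\n", x$alphabet, x$id,
              nchar(x$residues)))
  invisible(x)
}

#' Read a FASTA file with strict validation
#'
#' IDs are the first whitespace token of the header and must be unique.
#' Residues are uppercased; `*` stop characters in protein records are
#' stripped with a warning; residues outside the declared alphabet
#' (nucleotide: ACGTN; protein: 20 amino acids plus X) raise an error naming
#' the record and position.
#'
#' @param path FASTA file.
#' @param alphabet `"protein"` or `"nucleotide"`.
#' @return List of [seq_record]s in file order.
#' @export
read_fasta <- function(path, alphabet = c("protein", "nucleotide")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1L])
  res <- unname(toupper(as.character(set)))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    r <- res[i]
    if (alphabet == "protein" && grepl("*", r, fixed = TRUE)) {
      warning("stripping '*' stop characters from record '", ids[i], "'")
      r <- gsub("*", "", r, fixed = TRUE)
    }
    out[[i]] <- seq_record(ids[i], r, alphabet, desc[i])
  }
  out
}

#' Write sequence records as FASTA
#'
#' @param records Non-empty list of [seq_record]s.
#' @param path Output path.
#' @param width Line-wrap width (default 60).
#' @return `path`, invisibly. Round-trips through [read_fasta()].
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  if (length(records) == 0L) stop("refusing to write an empty FASTA file")
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "residues"))
  names(set) <- vapply(records, function(r)
    if (nzchar(r$description)) paste(r$id, r$description) else r$id, "")
  Biostrings::writeXStringSet(set, path, width = as.integer(width))
  invisible(path)
}

#' Read a genus-count table
#'
#' TSV with a `genus` column and one `d<day>` column per timepoint, e.g.
#' `genus  d0  d3  d6`. Counts must be non-negative integers and days
#' strictly increasing.
#'
#' @param path TSV file.
#' @param sample_id Sample identifier (default: file name without extension).
#' @return A `genus_counts` object: `sample_id`, `days`, and a genus x day
#'   integer `counts` matrix.
#' @export
read_genus_counts <- function(path, sample_id = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!identical(colnames(df)[1L], "genus"))
    stop("first column must be 'genus': ", path)
  daycols <- colnames(df)[-1L]
  if (!all(grepl("^d[0-9]+$", daycols)))
    stop("timepoint columns must be named d<day>: ", path)
  days <- as.integer(sub("^d", "", daycols))
  genus_counts(counts = as.matrix(df[, -1L, drop = FALSE]) |>
                 `rownames<-`(df$genus),
               days = days,
               sample_id = sample_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct/validate a genus-count table
#' @param counts Genus x day matrix of non-negative integers.
#' @param days Strictly increasing integer day numbers, one per column.
#' @param sample_id Sample identifier.
#' @return A `genus_counts` object.
#' @export
genus_counts <- function(counts, days, sample_id) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (length(days) < 1L || ncol(counts) != length(days))
    stop("need one count column per timepoint")
  if (any(diff(days) <= 0)) stop("day numbers must be strictly increasing")
  if (anyNA(counts) || any(counts < 0))
    stop("counts must be non-negative integers")
  structure(list(sample_id = sample_id, days = as.integer(days),
                 counts = counts), class = "genus_counts")
}

#' Write a genus-count table
#' @param x A `genus_counts` object.
#' @param path Output TSV path.
#' @export
write_genus_counts <- function(x, path) {
  df <- data.frame(genus = rownames(x$counts), x$counts,
                   check.names = FALSE)
  colnames(df)[-1L] <- paste0("d", x$days)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a degradation curve
#'
#' TSV with columns `day` and `conc_ug_per_ml`. Days must be strictly
#' increasing starting at 0; concentrations non-negative.
#'
#' @param path TSV file.
#' @param sample_id Sample identifier (default from file name).
#' @return A `degradation_curve`: `sample_id`, `days`, `concentration`.
#' @export
read_degradation_curve <- function(path, sample_id = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("day", "conc_ug_per_ml") %in% colnames(df)))
    stop("degradation TSV needs columns day, conc_ug_per_ml: ", path)
  degradation_curve(df$day, df$conc_ug_per_ml,
                    sample_id %||% sub("\\.[^.]*$", "", basename(path)))
}

#' Construct/validate a degradation curve
#' @param days Strictly increasing days, first must be 0.
#' @param concentration Concentrations in ug/mL, non-negative.
#' @param sample_id Sample identifier.
#' @return A `degradation_curve` object.
#' @export
degradation_curve <- function(days, concentration, sample_id = "sample") {
  if (length(days) != length(concentration) || length(days) < 1L)
    stop("days and concentration must have equal positive length")
  if (days[1L] != 0) stop("first day must be 0")
  if (any(diff(days) <= 0)) stop("days must be strictly increasing")
  if (anyNA(concentration) || any(concentration < 0))
    stop("concentrations must be non-negative")
  structure(list(sample_id = sample_id, days = as.integer(days),
                 concentration = as.numeric(concentration)),
            class = "degradation_curve")
}

#' Write a degradation curve
#' @param x A `degradation_curve`.
#' @param path Output TSV path.
#' @export
write_degradation_curve <- function(x, path) {
  utils::write.table(
    data.frame(day = x$days, conc_ug_per_ml = x$concentration),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the genus from a rank-prefixed taxonomy lineage
#'
#' Greengenes/SILVA dialect: semicolon-delimited fields with `g__<Genus>`
#' marking the genus rank. A lineage without a non-empty `g__` field yields
#' `NA` (genus unresolved).
#'
#' @param lineage Character vector of lineage strings.
#' @return Character vector of genera, `NA` where unresolved.
#' @export
#' @examples
#' genus_from_lineage("k__Bacteria;g__Methylotenera;s__x")
genus_from_lineage <- function(lineage) {
  vapply(lineage, function(l) {
    fields <- trimws(strsplit(l, ";", fixed = TRUE)[[1]])
    g <- fields[startsWith(fields, "g__")]
    g <- sub("^g__", "", g)
    g <- g[nzchar(g)]
    if (length(g) >= 1L) g[[1L]] else NA_character_
  }, "", USE.NAMES = FALSE)
}

#' Read a homology hit table
#'
#' TSV with columns `subject_id`, `similarity_pct`, `lineage`. Similarities
#' must lie in \[0, 100\]. Rows whose lineage lacks a `g__` genus field are
#' kept with genus `NA` and a warning, so both denominators (all hits,
#' genus-resolved hits) stay explicit downstream.
#'
#' @param path TSV file.
#' @return data.frame with `subject_id`, `similarity_pct`, `lineage`,
#'   `genus`.
#' @export
read_hit_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "similarity_pct", "lineage")
  if (!all(need %in% colnames(df)))
    stop("hit TSV needs columns ", paste(need, collapse = ", "), ": ", path)
  if (anyNA(df$similarity_pct) || any(df$similarity_pct < 0 |
                                      df$similarity_pct > 100))
    stop("similarity_pct must lie in [0, 100]")
  df$genus <- genus_from_lineage(df$lineage)
  if (anyNA(df$genus))
    warning(sum(is.na(df$genus)), " hit(s) with unresolved genus retained")
  df[, c("subject_id", "similarity_pct", "lineage", "genus")]
}

#' Write a presence/absence matrix as TSV
#'
#' One row per enzyme (`enzyme_id` first), one column per genome holding
#' `best_similarity|present_flag` (e.g. `73.42|1`); absent cells are `NA|0`.
#'
#' @param x A `presence_matrix` from [build_presence_matrix()].
#' @param path Output TSV path.
#' @export
write_presence_matrix <- function(x, path) {
  stopifnot(inherits(x, "presence_matrix"))
  cells <- matrix(sprintf("%s|%d",
                          ifelse(is.na(x$similarity), "NA",
                                 sprintf("%.4f", x$similarity)),
                          as.integer(x$present)),
                  nrow = nrow(x$present), dimnames = dimnames(x$present))
  df <- data.frame(enzyme_id = rownames(cells), cells, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a presence/absence matrix TSV
#'
#' Inverse of [write_presence_matrix()] for the serialised fields (best
#' similarity and presence flag; individual alignments are not stored).
#'
#' @param path TSV file.
#' @return A `presence_matrix` with `similarity` and `present` filled.
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!identical(colnames(df)[1L], "enzyme_id"))
    stop("first column must be 'enzyme_id': ", path)
  df$enzyme_id <- as.character(df$enzyme_id)
  genomes <- colnames(df)[-1L]
  parts <- lapply(df[-1L], function(col) strsplit(col, "|", fixed = TRUE))
  sim <- matrix(NA_real_, nrow(df), length(genomes),
                dimnames = list(df$enzyme_id, genomes))
  pres <- matrix(NA, nrow(df), length(genomes),
                 dimnames = list(df$enzyme_id, genomes))
  for (j in seq_along(genomes)) {
    p <- parts[[j]]
    sim[, j] <- suppressWarnings(as.numeric(vapply(p, `[`, "", 1L)))
    pres[, j] <- vapply(p, `[`, "", 2L) == "1"
  }
  structure(list(enzymes = df$enzyme_id, genomes = genomes,
                 best = NULL, similarity = sim, identity = NULL,
                 coverage = NULL, present = pres,
                 threshold_pct = NA_real_, coverage_min_pct = NA_real_,
                 metric = NA_character_),
            class = "presence_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
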