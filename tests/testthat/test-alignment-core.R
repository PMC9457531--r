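test_that("frame translation follows the bacterial code with X for N-codons", {
  expect_equal(translate_frame("ATGGCGTAA", 0, "+"), "MA*")
  expect_equal(translate_frame("TTACGCCAT", 0, "-"), "MA*")
  expect_equal(translate_frame("ATNGCG", 0, "+"), "XA")
  expect_equal(translate_frame("AT", 0, "+"), "")
})

test_that("six-frame translation matches an independent codon oracle", {
  rec <- seq_record("c1", nt_sample(9, 5), "nucleotide")
  frames <- six_frame_translate(rec)
  expect_length(frames, 6L)
  expect_equal(vapply(frames, function(f) nchar(f$residues), 0L),
               rep(c(3L, 2L, 2L), 2L))

  # palindromic contig: + and - translations coincide frame by frame
  pal <- seq_record("pal", "ACGCGT", "nucleotide")
  pf <- six_frame_translate(pal)
  expect_equal(pf[[1]]$residues, pf[[4]]$residues)
  expect_equal(pf[[2]]$residues, pf[[5]]$residues)

  # random 300-nt contig, all six frames vs the oracle
  contig <- nt_sample(300, 99)
  for (strand in c("+", "-")) for (frame in 0:2)
    expect_equal(translate_frame(contig, frame, strand),
                 oracle_translate(contig, frame, strand),
                 info = paste(strand, frame))
})

test_that("self-alignment scores the matrix diagonal at full coverage", {
  m <- scoring_matrix()
  a <- smith_waterman("MKVLA", "MKVLA")
  expect_equal(a$score, sum(diag(m[strsplit("MKVLA", "")[[1]],
                                   strsplit("MKVLA", "")[[1]]])))
  expect_equal(a$identity_pct, 100)
  expect_equal(a$similarity_pct, 100)
  expect_equal(a$query_coverage_pct, 100)
})

test_that("exact substring hits report coverage and subject coordinates", {
  a <- smith_waterman("MKVLA", "XXXMKVLAXXX")
  expect_equal(a$query_coverage_pct, 100)
  expect_equal(a$subject_start, 4L)
  expect_equal(a$subject_end, 8L)
  expect_equal(a$aligned_subject, "MKVLA")
})

test_that("empty sequences are rejected", {
  expect_error(smith_waterman("", "MKV"), "non-empty")
  expect_error(global_align("MKV", ""), "non-empty")
})

test_that("DP score equals the brute-force enumeration oracle", {
  m <- scoring_matrix()
  set.seed(101)
  for (i in 1:60) {
    q <- aa_sample(sample(1:12, 1), 2000 + i)
    s <- aa_sample(sample(1:12, 1), 3000 + i)
    qe <- bbrpath:::encode_residues(q, m)
    se <- bbrpath:::encode_residues(s, m)
    expect_equal(bbrpath:::cpp_local_score(qe, se, m, 11L, 1L),
                 bbrpath:::cpp_bruteforce_local_score(qe, se, m, 11L, 1L),
                 info = paste(q, s))
  }
})

test_that("local scores agree with Biostrings pairwiseAlignment", {
  m <- scoring_matrix()
  for (i in 1:25) {
    q <- aa_sample(sample(20:80, 1), 4000 + i)
    s <- aa_sample(sample(20:80, 1), 5000 + i)
    ours <- smith_waterman(q, s, matrix = m)$score
    ref <- Biostrings::pairwiseAlignment(
      q, s, type = "local", substitutionMatrix = m,
      gapOpening = 11, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(ours, as.integer(ref), info = i)
  }
})

test_that("score is symmetric, monotone in subject extension, never negative", {
  m <- scoring_matrix()
  for (i in 1:20) {
    q <- aa_sample(sample(3:15, 1), 6000 + i)
    s <- aa_sample(sample(3:15, 1), 7000 + i)
    sq <- smith_waterman(q, s)$score
    expect_identical(sq, smith_waterman(s, q)$score)
    expect_gte(sq, 0L)
    expect_gte(smith_waterman(q, paste0(s, aa_sample(6, 8000 + i)))$score, sq)
  }
})

test_that("identity never exceeds similarity and both stay within bounds", {
  set.seed(33)
  for (i in 1:15) {
    a <- smith_waterman(aa_sample(40, 9000 + i),
                        aa_sample(60, 9500 + i))
    expect_lte(a$identity_pct, a$similarity_pct)
    expect_lte(a$similarity_pct, 100)
    expect_gte(a$identity_pct, 0)
  }
})

test_that("stops and X score -4 and cannot create positive columns", {
  m <- scoring_matrix()
  expect_true(all(m["X", ] == -4L))
  expect_true(all(m["*", ] == -4L))
  # a stop inside the subject splits an otherwise perfect match
  q <- "MKVLAMKVLA"
  a <- smith_waterman(q, "MKVLA*MKVLA", matrix = m)
  expect_lt(a$score, smith_waterman(q, q, matrix = m)$score)
})

test_that("NCBI-format scoring matrices parse and round-trip BLOSUM62", {
  m <- scoring_matrix()
  f <- withr::local_tempfile(fileext = ".txt")
  lines <- c("# test matrix",
             paste(c("", colnames(m)), collapse = " "),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], m[i, ]), collapse = " "), ""))
  writeLines(lines, f)
  expect_equal(read_score_matrix(f), m)
  writeLines(c("A C", "A 1"), f)
  expect_error(read_score_matrix(f), "malformed")
})
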