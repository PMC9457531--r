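roles5 <- genome_roles(
  c("M", "J1", "J2"),
  c("Methylotenera", "Pseudomonas", "Sphingobacterium"),
  c("enriched_genus", "nondegrader_isolate", "nondegrader_isolate"))

pattern_matrix <- function(enriched, isolates,
                           enzymes = c("1", "2", "3", "9", "24")) {
  p <- matrix(FALSE, length(enzymes), 3,
              dimnames = list(enzymes, c("M", "J1", "J2")))
  p[enriched, "M"] <- TRUE
  p[isolates, c("J1", "J2")] <- TRUE
  toy_presence(p)
}

test_that("an enzyme present only in the enriched genome is the candidate", {
  m <- pattern_matrix(enriched = c("1", "2", "3", "9", "24"),
                      isolates = c("1", "2", "3", "24"))
  rep <- classify_enzymes(m, roles5)
  expect_equal(rep$essential_candidates, "9")
  expect_equal(rep$enzymes$classification,
               c("shared", "shared", "shared", "essential_candidate",
                 "shared"))
})

test_that("uniform presence or absence yields no candidates", {
  all_in <- pattern_matrix(enriched = c("1", "2", "3", "9", "24"),
                           isolates = c("1", "2", "3", "9", "24"))
  expect_length(classify_enzymes(all_in, roles5)$essential_candidates, 0L)
  none <- pattern_matrix(enriched = character(0), isolates = character(0))
  rep <- classify_enzymes(none, roles5)
  expect_true(all(rep$enzymes$classification == "absent"))
})

test_that("classifications partition the enzymes", {
  m <- pattern_matrix(enriched = c("1", "9"), isolates = c("2", "9"))
  rep <- classify_enzymes(m, roles5)
  expect_setequal(rep$enzymes$classification[match(c("1", "2", "9", "3"),
                                                   rep$enzymes$enzyme_id)],
                  c("essential_candidate", "isolate_only", "shared",
                    "absent"))
  expect_equal(nrow(rep$enzymes), 5L)
})

test_that("adding isolate evidence only removes candidates", {
  p <- matrix(FALSE, 2, 2, dimnames = list(c("a", "b"), c("M", "J1")))
  p["a", ] <- c(TRUE, FALSE)
  p["b", "M"] <- TRUE
  roles2 <- genome_roles(c("M", "J1"), c("g1", "g2"),
                         c("enriched_genus", "nondegrader_isolate"))
  before <- classify_enzymes(toy_presence(p), roles2)$essential_candidates
  # new isolate carrying enzyme a
  p2 <- cbind(p, J9 = c(TRUE, FALSE))
  roles3 <- rbind(roles2, data.frame(genome_id = "J9", genus = "g3",
                                     role = "nondegrader_isolate"))
  after <- classify_enzymes(toy_presence(p2), roles3)$essential_candidates
  expect_true(all(after %in% before))
  expect_false("a" %in% after)
  expect_true("b" %in% after)
})

test_that("the report ignores genome column order and 'other' genomes", {
  m <- pattern_matrix(enriched = c("9"), isolates = c("1"))
  perm <- m
  perm$present <- perm$present[, c(2, 3, 1)]
  perm$genomes <- colnames(perm$present)
  expect_equal(classify_enzymes(m, roles5)$enzymes,
               classify_enzymes(perm, roles5)$enzymes)

  # an 'other' genome containing everything changes nothing
  p <- cbind(m$present, X = TRUE)
  rolesx <- rbind(roles5, data.frame(genome_id = "X", genus = "gx",
                                     role = "other"))
  expect_equal(classify_enzymes(toy_presence(p), rolesx)$enzymes$classification,
               classify_enzymes(m, roles5)$enzymes$classification)
})

test_that("missing roles and missing groups are errors", {
  m <- pattern_matrix(enriched = "9", isolates = "1")
  expect_error(classify_enzymes(m, roles5[1:2, ]), "no role")
  only_enr <- genome_roles(c("M", "J1", "J2"), c("a", "b", "c"),
                           rep("enriched_genus", 3))
  expect_error(classify_enzymes(m, only_enr), "at least one")
})

test_that("the 'all' enriched rule demands presence in every enriched genome", {
  p <- matrix(c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE), 2, 3,
              dimnames = list(c("a", "b"), c("M1", "M2", "J1")))
  roles <- genome_roles(c("M1", "M2", "J1"), c("g", "g", "h"),
                        c("enriched_genus", "enriched_genus",
                          "nondegrader_isolate"))
  any_rep <- classify_enzymes(toy_presence(p), roles, "any")
  all_rep <- classify_enzymes(toy_presence(p), roles, "all")
  expect_setequal(any_rep$essential_candidates, c("a", "b"))
  expect_equal(all_rep$essential_candidates, "a")
})
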