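test_that("mutate_protein hits its identity target exactly", {
  p <- aa_sample(200, 61)
  expect_identical(mutate_protein(p, 100, 1), p)

  m <- mutate_protein(p, 60, 7)
  realized <- 100 * mean(strsplit(p, "")[[1]] == strsplit(m, "")[[1]])
  expect_true(realized >= 58 && realized <= 62)
  expect_equal(nchar(m), 200L)

  # identity granularity on short sequences: 5% is unreachable at length 10
  expect_error(mutate_protein(aa_sample(10, 62), 5, 1), "unreachable")
  expect_error(mutate_protein(p, 0, 1), "\\(0, 100\\]")
})

test_that("mutations are deterministic per seed and differ across seeds", {
  p <- aa_sample(100, 63)
  expect_identical(mutate_protein(p, 50, 3), mutate_protein(p, 50, 3))
  expect_false(identical(mutate_protein(p, 50, 3), mutate_protein(p, 50, 4)))
})

test_that("planted genes reappear verbatim in the stated strand and frame", {
  prot <- aa_sample(60, 71)
  for (strand in c("+", "-")) for (pos in c(101, 102, 103)) {
    g <- plant_gene(new_genome("c1", 1000, 72), prot, strand, pos, seed = 73)
    led <- g$planted[1L, ]
    frames <- six_frame_translate(g$record)
    holds <- vapply(frames, function(f)
      grepl(prot, f$residues, fixed = TRUE), TRUE)
    expect_equal(sum(holds), 1L, info = paste(strand, pos))
    hit <- frames[[which(holds)]]
    expect_equal(hit$strand, led$strand)
    expect_equal(hit$frame, led$frame)
  }
})

test_that("minus-strand plants are invisible on the plus strand", {
  prot <- aa_sample(60, 74)
  g <- plant_gene(new_genome("c1", 1000, 75), prot, "-", 301, seed = 76)
  plus <- six_frame_translate(g$record)[1:3]
  expect_false(any(vapply(plus, function(f)
    grepl(prot, f$residues, fixed = TRUE), TRUE)))
})

test_that("synonymous codon choice varies with seed, translation does not", {
  prot <- aa_sample(50, 77)
  c1 <- reverse_translate(prot, 1)
  c2 <- reverse_translate(prot, 2)
  expect_false(identical(c1, c2))
  expect_equal(translate_frame(c1), prot)
  expect_equal(translate_frame(c2), prot)
})

test_that("plant_gene enforces bounds, frame consistency and non-overlap", {
  prot <- aa_sample(30, 78)
  g <- new_genome("c1", 500, 79)
  expect_error(plant_gene(g, prot, "+", 450, seed = 1), "no room")
  expect_error(plant_gene(g, prot, "+", 101, frame_offset = 2L, seed = 1),
               "implies frame")
  g <- plant_gene(g, prot, "+", 101, seed = 1)
  expect_error(plant_gene(g, prot, "+", 150, seed = 1), "overlap")
})

test_that("scenario generation is deterministic and matches its truth", {
  cfg <- small_scenario_config(seed = 11L)
  s1 <- generate_scenario(cfg)
  s2 <- generate_scenario(cfg)
  expect_identical(s1$genomes, s2$genomes)
  expect_identical(s1$truth, s2$truth)

  expect_equal(s1$truth$expected_essential, "3")
  expect_equal(sort(unique(s1$truth$planted$genome_id)),
               sort(names(s1$genomes)))
  # realized identities honour the +/- 2 point contract
  expect_true(all(abs(s1$truth$planted$realized_identity_pct -
                        cfg$planted_identity_pct) <= 2))
  # generated sequences pass the io validators by construction
  for (g in s1$genomes)
    expect_silent(validated <- seq_record(g[[1]]$id, g[[1]]$residues,
                                          "nucleotide"))
  expect_error(scenario_config(enriched_subset = "99"), "labels")
})

test_that("scenario files round-trip through the io layer", {
  dir <- withr::local_tempdir()
  scn <- generate_scenario(small_scenario_config(seed = 13L))
  write_scenario(scn, dir)
  enz <- read_fasta(file.path(dir, "enzymes.faa"), "protein")
  expect_equal(vapply(enz, `[[`, "", "residues"),
               vapply(unname(scn$enzymes), `[[`, "", "residues"))
  roles <- read_genome_roles(file.path(dir, "roles.tsv"))
  expect_equal(roles, scn$roles)
  g1 <- read_fasta(file.path(dir, "genomes",
                             paste0(roles$genome_id[1], ".fna")),
                   "nucleotide")
  expect_equal(g1[[1]]$residues, scn$genomes[[roles$genome_id[1]]][[1]]$residues)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$expected_essential, scn$truth$expected_essential)
})

test_that("community series are deterministic with the documented dynamics", {
  cfg <- community_config(depth = 5000L)
  a <- generate_community_series(cfg, seed = 5)
  b <- generate_community_series(cfg, seed = 5)
  expect_identical(a, b)
  expect_error(community_config(depth = 50L), "depth")

  for (id in names(a$counts)) {
    tab <- a$counts[[id]]
    lab <- classify_degradation(a$curves[[id]])
    series <- relative_abundance(tab, lab$label)
    expect_true(all(abs(colSums(series$abundance) - 1) < 1e-9))
    if (startsWith(id, "deg")) {
      expect_equal(lab$label, "degraded")
      expect_equal(series$days[which.max(series$abundance["Methylotenera", ])],
                   3L)
    } else {
      expect_equal(lab$label, "stable")
    }
  }
})

test_that("equal enriched and isolate subsets leave no candidate downstream", {
  cfg <- scenario_config(seed = 17L, n_enzymes = 4L, enzyme_length = 120L,
                         enriched_subset = c("1", "2"),
                         isolate_subset = c("1", "2"),
                         genome_length = 6000L, n_isolates = 2L,
                         decoy_orf_length = 80L)
  res <- scenario_essentiality(generate_scenario(cfg))
  expect_length(res$report$essential_candidates, 0L)
})
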