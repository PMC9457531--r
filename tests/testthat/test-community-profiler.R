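test_that("relative abundance normalises per day and flags zero totals", {
  tab <- genus_counts(matrix(c(50L, 50L), 2, 1,
                            dimnames = list(c("A", "B"), NULL)),
                     days = 0L, sample_id = "s")
  expect_equal(unname(relative_abundance(tab)$abundance[, 1L]), c(0.5, 0.5))

  tab2 <- genus_counts(matrix(c(3L, 1L), 2, 1,
                             dimnames = list(c("A", "B"), NULL)), 0L, "s")
  expect_equal(unname(relative_abundance(tab2)$abundance[, 1L]),
               c(0.75, 0.25))

  solo <- genus_counts(matrix(c(5L, 7L, 2L), 1, 3,
                             dimnames = list("A", NULL)), c(0L, 3L, 6L), "s")
  expect_equal(unname(relative_abundance(solo)$abundance[1L, ]), c(1, 1, 1))

  zero <- genus_counts(matrix(c(1L, 0L), 1, 2, dimnames = list("A", NULL)),
                       c(0L, 3L), "s")
  expect_error(relative_abundance(zero), "day 3")
})

test_that("degradation classification finds residual fraction and onset", {
  cv <- degradation_curve(0:8, c(100, 100, 100, 100, 100, 95, 40, 2, 1))
  got <- classify_degradation(cv)
  expect_equal(got$label, "degraded")
  expect_equal(got$onset_day, 6L)

  stable <- degradation_curve(0:14, rep(100, 15))
  expect_equal(classify_degradation(stable)$label, "stable")

  expect_equal(classify_degradation(degradation_curve(0:1, c(100, 9)))$label,
               "degraded")
  # boundary: exactly 10% residual counts as degraded
  expect_equal(classify_degradation(degradation_curve(0:1, c(100, 10)))$label,
               "degraded")
  expect_equal(classify_degradation(degradation_curve(0:1, c(100, 11)))$label,
               "stable")
  expect_error(classify_degradation(degradation_curve(0:1, c(0, 0))),
               "positive")
})

test_that("degradation classification is scale invariant", {
  base <- c(100, 100, 98, 60, 8, 2)
  for (c_ in c(0.01, 1, 37.5)) {
    cv <- degradation_curve(0:5, base * c_)
    expect_equal(classify_degradation(cv)$label, "degraded")
    expect_equal(classify_degradation(cv)$onset_day, 3L)
  }
})

make_series <- function(sample_id, label, rows, days = c(0L, 3L, 6L, 10L, 14L),
                        depth = 10000L) {
  counts <- do.call(rbind, lapply(rows, function(f) as.integer(round(f * depth))))
  rownames(counts) <- names(rows)
  counts <- rbind(counts,
                  Other = as.integer(depth - colSums(counts)))
  relative_abundance(genus_counts(counts, days, sample_id), label)
}

test_that("enrichment calls isolate degradation-associated genera", {
  deg_rows <- list(Focal = c(0.0001, 0.20, 0.05, 0.02, 0.01),
                   Both = c(0.01, 0.15, 0.08, 0.05, 0.03),
                   Flat = c(0.10, 0.10, 0.10, 0.10, 0.10))
  sta_rows <- list(Focal = c(0.0001, 0.0001, 0.0001, 0.0001, 0.0001),
                   Both = c(0.01, 0.12, 0.06, 0.04, 0.02),
                   Flat = c(0.10, 0.10, 0.10, 0.10, 0.10))
  series <- list(make_series("d1", "degraded", deg_rows),
                 make_series("d2", "degraded", deg_rows),
                 make_series("s1", "stable", sta_rows))
  calls <- call_enriched_genera(series)
  focal <- calls[calls$genus == "Focal", ]
  expect_true(focal$degradation_associated)
  expect_equal(focal$peak_day, 3L)
  both <- calls[calls$genus == "Both", ]
  expect_true(both$enriched_in_degraders)
  expect_true(both$enriched_in_nondegraders)
  expect_false(both$degradation_associated)
  expect_false(calls[calls$genus == "Flat", "degradation_associated"])
})

test_that("enrichment requires the rule to hold in every group sample", {
  hot <- list(Focal = c(0.001, 0.25, 0.05, 0.02, 0.01))
  cold <- list(Focal = c(0.001, 0.002, 0.001, 0.001, 0.001))
  series <- list(make_series("d1", "degraded", hot),
                 make_series("d2", "degraded", cold),  # no enrichment here
                 make_series("s1", "stable", cold))
  calls <- call_enriched_genera(series)
  expect_false(calls[calls$genus == "Focal", "enriched_in_degraders"])
})

test_that("enrichment calls are invariant to sample order and need both groups", {
  deg_rows <- list(Focal = c(0.001, 0.20, 0.05, 0.02, 0.01))
  sta_rows <- list(Focal = rep(0.001, 5))
  s <- list(make_series("d1", "degraded", deg_rows),
            make_series("s1", "stable", sta_rows),
            make_series("d2", "degraded", deg_rows))
  expect_equal(call_enriched_genera(s), call_enriched_genera(rev(s)))
  expect_error(call_enriched_genera(s[1]), "at least one")
  expect_error(
    call_enriched_genera(list(make_series("d1", NA_character_, deg_rows))),
    "degradation_label")
})

test_that("genera missing from one sample count as zero there", {
  a <- make_series("d1", "degraded",
                   list(Focal = c(0.001, 0.2, 0.05, 0.02, 0.01)))
  b <- make_series("d2", "degraded",
                   list(OtherGenus = c(0.05, 0.05, 0.05, 0.05, 0.05)))
  s1 <- make_series("s1", "stable", list(Focal = rep(0.001, 5)))
  calls <- call_enriched_genera(list(a, b, s1))
  # Focal absent (zero) in d2, so peak 0 < min_peak there: not enriched
  expect_false(calls[calls$genus == "Focal", "enriched_in_degraders"])
})
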