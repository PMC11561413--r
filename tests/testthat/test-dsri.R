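means <- spar_trial_means()

test_that("IDSRI is the drought/control ratio of cell means", {
  expect_equal(idsri(means, "DKC-6581", "PH"), 22.00 / 37.50)
  expect_equal(idsri(means, "DKC-6581", "RSR"), 0.36 / 0.11)
  eq <- trait_mean_table(
    data.frame(hybrid = "H1", treatment = c("D", "C"), trait = "PH",
               mean = c(4, 4)),
    design = design_spec("H1"))
  expect_equal(idsri(eq, "H1", "PH"), 1)
  z <- trait_mean_table(
    data.frame(hybrid = "H1", treatment = c("D", "C"), trait = "PH",
               mean = c(4, 0)),
    design = design_spec("H1"))
  expect_error(idsri(z, "H1", "PH"), "PH.*H1")
})

test_that("CDSRI equals the brute-force sum of 21 recomputed ratios", {
  design <- attr(means, "design")
  panel <- attr(means, "panel")
  members <- panel$code[panel$cdsri_member]
  expect_length(members, 21L)
  for (h in design$hybrids) {
    oracle <- sum(vapply(members, function(tc)
      mean_value(means, h, "D", tc) / mean_value(means, h, "C", tc),
      numeric(1)))
    expect_equal(as.numeric(cdsri(means, h)), oracle, tolerance = 1e-12)
  }
  # the recomputed magnitude for DKC-6581
  expect_equal(as.numeric(cdsri(means, "DKC-6581")), 15.53, tolerance = 0.001)
})

test_that("all-unity ratios sum to the trait count", {
  flat <- trait_mean_table(
    expand.grid(hybrid = "H1", treatment = c("D", "C"),
                trait = trait_panel()$code, stringsAsFactors = FALSE) |>
      transform(mean = 5),
    design = design_spec("H1"))
  expect_equal(as.numeric(cdsri(flat, "H1")), 21)
  expect_equal(attr(cdsri(flat, "H1"), "n_traits"), 21L)
})

test_that("subset scoring reports its own trait count", {
  one <- cdsri(means, "DKC-6581", traits = "PH")
  expect_equal(as.numeric(one), idsri(means, "DKC-6581", "PH"))
  expect_equal(attr(one, "n_traits"), 1L)
  # a missing member trait is a hard error, not silent renormalisation
  sub <- trait_mean_table(as.data.frame(means)[means$trait != "Phot", ])
  expect_error(cdsri(sub, "DKC-6581"), "Phot")
})

test_that("equal-width binning of the reported scores yields the published groups", {
  cl <- classify_cdsri(reported_cdsri_scores())
  grp <- split(names(cl$class), cl$class)
  expect_setequal(grp$tolerant, c("DKC-6581", "N61X-3110"))
  expect_setequal(grp$moderate, c("P-1498", "DKC-6697"))
  expect_setequal(grp$sensitive, c("P-1319", "N59B-311A"))
  expect_equal(unname(cl$width), rep((28.32 - 25.21) / 3, 3))
})

test_that("classification boundary and degenerate conventions hold", {
  cl <- classify_cdsri(c(a = 1, b = 2, c = 3))
  expect_equal(as.character(cl$class), c("sensitive", "moderate", "tolerant"))
  # a score exactly on an interior edge joins the upper bin
  edge <- classify_cdsri(c(a = 0, b = 1, c = 3))  # edges at 1 and 2
  expect_equal(as.character(edge$class[["b"]]), "moderate")
  expect_error(classify_cdsri(c(a = 2, b = 2, c = 2)), "degenerate")
  expect_error(classify_cdsri(c(a = 1, b = 2)), "at least 3")
})

test_that("classification is invariant to input order and affine shifts", {
  s <- reported_cdsri_scores()
  perm <- classify_cdsri(s[sample(length(s))])
  expect_equal(perm$class[names(s)], classify_cdsri(s)$class)
  sh <- classify_cdsri(s + 100)
  expect_equal(sh$class, classify_cdsri(s)$class)
  expect_equal(sh$bounds, classify_cdsri(s)$bounds + 100)
})

test_that("raising one hybrid's score never lowers its class", {
  s <- reported_cdsri_scores()
  for (h in names(s)) {
    for (bump in c(0.5, 1.5, 3)) {
      s2 <- s; s2[h] <- s2[h] + bump
      expect_gte(as.integer(classify_cdsri(s2)$class[h]),
                 as.integer(classify_cdsri(s)$class[h]))
    }
  }
})

test_that("hybrid ranking is descending with alphabetical tie-break", {
  r <- rank_hybrids(reported_cdsri_scores())
  expect_equal(r$hybrid[1], "DKC-6581")
  expect_equal(r$hybrid[6], "P-1319")
  expect_false(any(r$tied))
  tied <- rank_hybrids(c(B = 2, A = 2, C = 1))
  expect_equal(tied$hybrid, c("A", "B", "C"))
  expect_equal(tied$rank, c(1L, 1L, 3L))
  expect_equal(tied$tied, c(TRUE, TRUE, FALSE))
})

test_that("the dsri fit bundles ratios, scores, classes and predictions", {
  fit <- dsri(means)
  expect_s3_class(fit, "dsri")
  expect_equal(dim(fit$idsri), c(6L, 21L))
  expect_equal(coef(fit), fit$cdsri)
  expect_equal(unname(coef(fit)["DKC-6581"]),
               as.numeric(cdsri(means, "DKC-6581")))
  # fitted bounds classify new scores consistently
  expect_equal(predict(fit), fit$classification$class)
  top <- predict(fit, newscores = c(x = max(fit$cdsri)))
  expect_equal(as.character(top), "tolerant")
  # replicate-level input collapses first and agrees with the mean route
  obs <- simulate_trial(means, cv = 0, seed = 2)
  expect_equal(coef(dsri(obs)), coef(fit), tolerance = 1e-12)
  expect_output(print(fit), "21 traits")
  expect_output(print(summary(fit)), "IDSRI")
})
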