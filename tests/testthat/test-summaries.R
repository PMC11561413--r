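means <- spar_trial_means()

test_that("treatment means match the published narration", {
  expect_equal(treatment_mean(means, "Phot", "C"), 38.18, tolerance = 0.005)
  expect_equal(treatment_mean(means, "PH", "D"), 22.04, tolerance = 0.005)
  # alias labels address the same treatment
  expect_equal(treatment_mean(means, "PH", "T1"),
               treatment_mean(means, "PH", "D"))
  # single-hybrid table: the treatment mean is that hybrid's value
  one <- trait_mean_table(
    data.frame(hybrid = "H1", treatment = c("D", "C"), trait = "PH",
               mean = c(3, 7)),
    design = design_spec("H1"))
  expect_equal(treatment_mean(one, "PH", "D"), 3)
})

test_that("overall percent changes reproduce the published percentages", {
  expect_equal(percent_change(means, "Phot"), 57.96, tolerance = 0.01)
  expect_equal(percent_change(means, "Fv/Fm"), 29.67, tolerance = 0.01)
  expect_equal(percent_change(means, "TRL"), 27.98, tolerance = 0.02)
  expect_equal(percent_change(means, "LRL", direction = "increase"),
               10.50, tolerance = 0.05)
})

test_that("per-hybrid percent changes and absolute reductions match", {
  expect_equal(percent_change(means, "LA", hybrid = "P-1498"),
               76.88, tolerance = 0.02)
  expect_equal(percent_change(means, "LA", hybrid = "N59B-311A"),
               66.32, tolerance = 0.02)
  expect_equal(absolute_reduction(means, "PH", "DKC-6697"), 17.5)
  expect_equal(absolute_reduction(means, "LN", "P-1498"), 1.25)
})

test_that("decline and increase are exact negatives (antisymmetry)", {
  for (tc in c("PH", "RSR", "LRL", "ETR")) {
    expect_equal(percent_change(means, tc, direction = "decline"),
                 -percent_change(means, tc, direction = "increase"))
    expect_equal(percent_change(means, tc, "DKC-6581", "decline"),
                 -percent_change(means, tc, "DKC-6581", "increase"))
  }
})

test_that("percent change is invariant to rescaling a trait", {
  scaled <- as.data.frame(means)
  k <- 3.7
  scaled$mean[scaled$trait == "LA"] <- k * scaled$mean[scaled$trait == "LA"]
  scaled <- trait_mean_table(scaled)
  expect_equal(percent_change(scaled, "LA"), percent_change(means, "LA"))
  expect_equal(percent_change(scaled, "LA", hybrid = "P-1319"),
               percent_change(means, "LA", hybrid = "P-1319"))
})

test_that("overall change from hybrid means equals the grand-cell-mean form", {
  design <- attr(means, "design")
  for (tc in c("PH", "NRT", "RSR")) {
    mc <- mean(vapply(design$hybrids,
                      function(h) mean_value(means, h, "C", tc), numeric(1)))
    md <- mean(vapply(design$hybrids,
                      function(h) mean_value(means, h, "D", tc), numeric(1)))
    expect_equal(percent_change(means, tc), 100 * (mc - md) / mc)
  }
})

test_that("extreme responders match the published argmax/argmin", {
  nrt <- extreme_responders(means, "NRT")
  expect_equal(nrt$max$hybrid, "P-1498")
  expect_equal(nrt$min$hybrid, "DKC-6697")
  expect_equal(nrt$min$value, 27.80, tolerance = 0.01)
  nrf <- extreme_responders(means, "NRF")
  expect_equal(nrf$min$hybrid, "P-1498")
  expect_equal(nrf$min$value, 23.38, tolerance = 0.01)
  nrc <- extreme_responders(means, "NRC")
  expect_equal(nrc$max$hybrid, "DKC-6581")
  expect_equal(nrc$max$value, 54.15, tolerance = 0.01)
})

test_that("ties in responder ranking are reported as lists", {
  two <- trait_mean_table(
    data.frame(hybrid = rep(c("H1", "H2"), each = 2),
               treatment = rep(c("D", "C"), 2), trait = "PH",
               mean = c(5, 10, 6, 12)),
    design = design_spec(c("H1", "H2")))
  ex <- extreme_responders(two, "PH")
  expect_equal(sort(ex$max$hybrid), c("H1", "H2"))  # both 50%
  expect_equal(ex$max$value, c(50, 50))
})

test_that("zero control mean raises an undefined-ratio error", {
  z <- trait_mean_table(
    data.frame(hybrid = "H1", treatment = c("D", "C"), trait = "PH",
               mean = c(5, 0)),
    design = design_spec("H1"))
  expect_error(percent_change(z, "PH"), "zero")
})

test_that("stress summary covers every trait at overall and hybrid scope", {
  s <- stress_summary(means)
  expect_equal(nrow(s), 22L * 7L)  # overall + 6 hybrids per trait
  phot <- s[s$trait == "Phot" & s$scope == "overall", ]
  expect_equal(phot$pct_decline, 57.96, tolerance = 0.01)
  expect_equal(s$mean_C - s$mean_D, s$abs_reduction)
})
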