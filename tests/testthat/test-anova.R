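test_that("degrees of freedom follow the balanced RCBD partition", {
  obs <- simulate_trial(cv = 0.1, seed = 1)
  a <- rcbd_anova(obs, "PH")
  expect_equal(a$df, c(3L, 1L, 5L, 5L, 33L, 47L))
  expect_equal(a$source[a$df == 33L], "error")
  expect_equal(sum(a$df[1:5]), a$df[6])
})

test_that("sums of squares match the direct-summation oracle on toy data", {
  obs <- toy_obs()
  a <- rcbd_anova(obs, "PH")
  o <- ss_by_definition(obs, "PH")
  expect_equal(a$ss[a$source == "block"], o$block, tolerance = 1e-10)
  expect_equal(a$ss[a$source == "treatment"], o$treatment, tolerance = 1e-10)
  expect_equal(a$ss[a$source == "hybrid"], o$hybrid, tolerance = 1e-10)
  expect_equal(a$ss[a$source == "treatment:hybrid"], o$interaction,
               tolerance = 1e-10)
  expect_equal(a$ss[a$source == "total"], o$total, tolerance = 1e-10)
})

test_that("the whole table agrees with aov() as an independent cross-check", {
  obs <- simulate_trial(cv = 0.15, seed = 9)
  for (tc in c("Phot", "LA", "RSR")) {
    mine <- rcbd_anova(obs, tc)
    d <- as.data.frame(obs[obs$trait == tc, ])
    d$block <- factor(d$replicate)
    ref <- summary(aov(value ~ block + treatment * hybrid, data = d))[[1]]
    expect_equal(mine$ss[1:5], unname(ref[["Sum Sq"]]), tolerance = 1e-8)
    expect_equal(mine$f[1:4], unname(ref[["F value"]][1:4]),
                 tolerance = 1e-8)
    expect_equal(mine$p[1:4], unname(ref[["Pr(>F)"]][1:4]), tolerance = 1e-8)
  }
})

test_that("SS partition is conserved on random balanced inputs", {
  for (s in 1:10) {
    obs <- simulate_trial(cv = runif(1, 0.02, 0.4), seed = 100 + s,
                          n_replicates = sample(2:5, 1))
    a <- rcbd_anova(obs, sample(trait_panel()$code, 1))
    expect_equal(sum(a$ss[1:5]), a$ss[6],
                 tolerance = 1e-8 * max(a$ss[6], 1))
    expect_true(all(a$ss >= -1e-8))
  }
})

test_that("treatment F equals the squared paired t in the two-level limit", {
  set.seed(4)
  df <- data.frame(hybrid = "H1",
                   treatment = rep(c("D", "C"), each = 6),
                   replicate = rep(1:6, 2), trait = "PH",
                   value = c(rnorm(6, 10), rnorm(6, 12)))
  obs <- observation_table(df, design = design_spec("H1", n_replicates = 6))
  a <- rcbd_anova(obs, "PH")
  tt <- t.test(df$value[df$treatment == "D"], df$value[df$treatment == "C"],
               paired = TRUE)
  expect_equal(a$f[a$source == "treatment"], unname(tt$statistic)^2,
               tolerance = 1e-10)
  expect_equal(a$p[a$source == "treatment"], tt$p.value, tolerance = 1e-10)
})

test_that("noise-free data with distinct cell means gives zero error SS", {
  obs <- simulate_trial(cv = 0, seed = 1)
  a <- rcbd_anova(obs, "Phot")
  expect_equal(a$ss[a$source == "error"], 0, tolerance = 1e-6)
  expect_true(is.infinite(a$f[a$source == "treatment"]) ||
                a$f[a$source == "treatment"] > 1e10)
})

test_that("unbalanced data is rejected", {
  obs <- simulate_trial(cv = 0.1, seed = 2)
  broken <- as.data.frame(obs)[-1, ]
  attr_panel <- attr(obs, "panel"); attr_design <- attr(obs, "design")
  broken <- structure(broken, panel = attr_panel, design = attr_design,
                      class = class(obs))
  expect_error(rcbd_anova(broken, "PH"), "unbalanced")
})

test_that("star codes apply strict thresholds, most significant first", {
  expect_equal(star_code(c(0.0005, 0.005, 0.03, 0.05, 0.2)),
               c("***", "**", "*", "NS", "NS"))
  expect_equal(star_code(c(0.001, 0.01)), c("**", "*"))  # strict boundaries
  expect_error(star_code(1.5))
})

test_that("protected LSD computes the textbook threshold and letters", {
  # LSD = t(0.975, 33) * sqrt(2 * 4 / 8) = t(0.975, 33) * 1
  expect_equal(qt(0.975, 33) * sqrt(2 * 4 / 8), 2.0345, tolerance = 1e-4)

  obs <- simulate_trial(cv = 0.08, seed = 21)
  a <- rcbd_anova(obs, "Phot")
  l <- fisher_lsd(a, obs, "hybrid")
  expect_false(l$skipped)
  expect_equal(l$lsd,
               qt(0.975, 33) * sqrt(2 * attr(a, "mse") / 8),
               tolerance = 1e-12)
  g <- l$groups
  # two levels share a letter iff their difference is within the LSD
  for (i in seq_len(nrow(g))) for (j in seq_len(nrow(g))) {
    share <- any(strsplit(g$letters[i], "")[[1]] %in%
                   strsplit(g$letters[j], "")[[1]])
    expect_equal(share, abs(g$mean[i] - g$mean[j]) <= l$lsd,
                 info = paste(g$level[i], g$level[j]))
  }
})

test_that("LSD is skipped when the omnibus test is not significant", {
  # no hybrid effect: every hybrid shares the same cell means
  df <- expand.grid(hybrid = c("H1", "H2", "H3"), treatment = c("D", "C"),
                    replicate = 1:4, trait = "PH",
                    stringsAsFactors = FALSE)
  set.seed(12)
  df$value <- ifelse(df$treatment == "D", 10, 20) + rnorm(nrow(df), 0, 3)
  obs <- observation_table(df, design = design_spec(c("H1", "H2", "H3")))
  a <- rcbd_anova(obs, "PH")
  expect_gte(a$p[a$source == "hybrid"], 0.05)
  l <- fisher_lsd(a, obs, "hybrid")
  expect_true(l$skipped)
  expect_null(l$groups)
  # identical level means all share one letter
  flat <- simulate_trial(cv = 0, seed = 1)
  af <- rcbd_anova(flat, "Phot")
  lf <- fisher_lsd(af, flat, "hybrid")
  if (!lf$skipped) expect_true(all(nchar(lf$groups$letters) >= 1))
})
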