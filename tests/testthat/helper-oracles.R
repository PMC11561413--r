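# Shared fixtures and independent oracles used across the suite.

# small two-hybrid, two-treatment, two-block toy trial with hand-set values
toy_design <- function() {
  design_spec(hybrids = c("H1", "H2"), treatments = c("D", "C"),
              n_replicates = 2L, control = "C")
}

toy_obs <- function(values = NULL) {
  grid <- expand.grid(trait = "PH", replicate = 1:2, treatment = c("D", "C"),
                      hybrid = c("H1", "H2"), stringsAsFactors = FALSE)
  grid <- grid[c("hybrid", "treatment", "replicate", "trait")]
  grid$value <- if (is.null(values)) c(10, 12, 20, 22, 14, 15, 30, 31)
                else values
  observation_table(grid, design = toy_design())
}

# brute-force RCBD sums of squares straight from the definitions:
# squared deviations of group means from the grand mean, times group size
ss_by_definition <- function(obs, trait) {
  d <- obs[obs$trait == trait, ]
  g <- mean(d$value)
  dev2 <- function(f) {
    m <- tapply(d$value, f, mean)
    n <- tapply(d$value, f, length)
    sum(n * (m - g)^2)
  }
  cellf <- interaction(d$treatment, d$hybrid, drop = TRUE)
  ss_cells <- dev2(cellf)
  list(
    block = dev2(d$replicate),
    treatment = dev2(d$treatment),
    hybrid = dev2(d$hybrid),
    interaction = ss_cells - dev2(d$treatment) - dev2(d$hybrid),
    total = sum((d$value - g)^2)
  )
}

# naive Pearson correlation: covariance over product of standard deviations
cor_naive <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# replicate-level matrix (units x traits) for one treatment, aligned like
# pearson_matrix does internally
trait_matrix <- function(obs, treatment, traits) {
  d <- obs[obs$treatment == treatment, ]
  units <- sort(unique(paste(d$hybrid, d$replicate, sep = "\r")))
  sapply(traits, function(tc) {
    sub <- d[d$trait == tc, ]
    v <- setNames(sub$value, paste(sub$hybrid, sub$replicate, sep = "\r"))
    unname(v[units])
  })
}
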