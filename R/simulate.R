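#' Simulate a replicate-level screening trial with known cell means
#'
#' Generates an observation table with the statistical structure of the SPAR
#' experiment: for every (hybrid, treatment, replicate, trait) one value drawn
#' around the corresponding cell mean. Under the default \code{"normal_cv"}
#' noise model values are Normal(mean, cv * |mean|); under \code{"normal_sd"}
#' a fixed standard deviation \code{sd} is used for every cell. Traits
#' declared nonnegative are truncated at zero by rejection (re-drawing), so
#' the distribution stays continuous with no point mass at zero.
#'
#' The defaults emulate the bundled reference trial: its trait-mean table as
#' the truth, 4 replicates, and a within-cell coefficient of variation of
#' 0.10 — a typical replicate-level CV for controlled-environment phenotyping;
#' the source trial published no within-cell variance.
#'
#' Row order is deterministic (hybrid x treatment x replicate, traits in
#' panel order) and a single RNG stream is seeded once, so the output is
#' fully reproducible from \code{seed}.
#'
#' @param means a \code{"trait_means"} table supplying the true cell means;
#'   defaults to [spar_trial_means()].
#' @param cv coefficient of variation, a single number >= 0 or a named vector
#'   keyed by trait code (global default applied where unnamed).
#' @param n_replicates replicates per cell.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @param noise \code{"normal_cv"} or \code{"normal_sd"}.
#' @param sd fixed standard deviation for \code{noise = "normal_sd"}.
#' @param truncate_nonnegative redraw negative values for nonnegative traits.
#' @return A validated \code{"spar_obs"} observation table with
#'   \code{nrow = hybrids * treatments * n_replicates * traits}.
#' @examples
#' obs <- simulate_trial(cv = 0.1, seed = 7)
#' nrow(obs)  # 6 * 2 * 4 * 22 = 1056
#' @export
simulate_trial <- function(means = spar_trial_means(), cv = 0.10,
                           n_replicates = 4L, seed = NULL,
                           noise = c("normal_cv", "normal_sd"), sd = NULL,
                           truncate_nonnegative = TRUE) {
  stopifnot(inherits(means, "trait_means"))
  noise <- match.arg(noise)
  if (any(cv < 0)) stop("cv must be >= 0", call. = FALSE)
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L)
    stop("n_replicates must be a positive integer", call. = FALSE)
  if (noise == "normal_sd" && (is.null(sd) || any(sd < 0)))
    stop("noise = 'normal_sd' needs sd >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))

  panel <- attr(means, "panel")
  design <- attr(means, "design")
  design$n_replicates <- n_replicates
  traits <- panel$code[panel$code %in% unique(means$trait)]
  nn <- panel$code[panel$nonnegative]

  # scalar cv applies globally; a named vector overrides per trait, with any
  # unnamed element (or 0.10) as the fallback for traits not listed
  if (is.null(names(cv))) {
    cvs <- stats::setNames(rep(cv[1L], length(traits)), traits)
  } else {
    fallback <- if (any(names(cv) == "")) cv[names(cv) == ""][1L] else 0.10
    cvs <- stats::setNames(rep(fallback, length(traits)), traits)
    keyed <- names(cv) != ""
    cvs[resolve_traits(names(cv)[keyed], panel)] <- cv[keyed]
  }

  grid <- expand.grid(trait = traits, replicate = seq_len(n_replicates),
                      treatment = design$treatments, hybrid = design$hybrids,
                      stringsAsFactors = FALSE)
  grid <- grid[c("hybrid", "treatment", "replicate", "trait")]
  mu <- vapply(seq_len(nrow(grid)), function(i)
    mean_value(means, grid$hybrid[i], grid$treatment[i], grid$trait[i]),
    numeric(1L))
  sig <- if (noise == "normal_cv") cvs[grid$trait] * abs(mu)
         else rep(sd[1L], nrow(grid))
  val <- stats::rnorm(nrow(grid), mu, sig)
  if (truncate_nonnegative) {
    redo <- which(val < 0 & grid$trait %in% nn)
    guard <- 0L
    while (length(redo) > 0L && guard < 1000L) {
      val[redo] <- stats::rnorm(length(redo), mu[redo], sig[redo])
      redo <- redo[val[redo] < 0]
      guard <- guard + 1L
    }
    if (length(redo) > 0L) val[redo] <- abs(val[redo])  # pathological cv
  }
  grid$value <- val
  observation_table(grid, panel = panel, design = design)
}

#' Randomized chamber layout for a screening trial
#'
#' Assigns hybrids to numbered column positions so that each hybrid occupies
#' exactly \code{n_replicates} positions in every treatment, as in the
#' 48-column SPAR layout (6 hybrids x 2 treatments x 4 replicates). Positions
#' are blocked by treatment and the within-treatment assignment is a uniform
#' random permutation, reproducible from \code{seed}.
#'
#' @param design a [design_spec()].
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return Data frame with columns \code{position}, \code{treatment},
#'   \code{hybrid}.
#' @examples
#' layout <- randomize_layout(spar_design(), seed = 1)
#' nrow(layout)  # 48
#' @export
randomize_layout <- function(design = spar_design(), seed = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  per_trt <- length(design$hybrids) * design$n_replicates
  out <- do.call(rbind, lapply(seq_along(design$treatments), function(k) {
    data.frame(
      position = (k - 1L) * per_trt + seq_len(per_trt),
      treatment = design$treatments[k],
      hybrid = sample(rep(design$hybrids, design$n_replicates)),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
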