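#' Significance star codes
#'
#' Maps p-values to the conventional star codes using strict inequalities:
#' \code{***} for p < 0.001, \code{**} for p < 0.01, \code{*} for p < 0.05,
#' \code{NS} otherwise (so p = 0.05 exactly is NS).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Character vector of star codes.
#' @examples
#' star_code(c(5e-4, 0.03, 0.05))  # "***" "*" "NS"
#' @export
star_code <- function(p) {
  stopifnot(is.numeric(p), all(is.na(p) | (p >= 0 & p <= 1)))
  out <- ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
         ifelse(p < 0.05, "*", "NS")))
  out[is.na(p)] <- NA_character_
  out
}

#' Two-factor randomized-complete-block ANOVA for one trait
#'
#' Partitions the total sum of squares of a balanced two-factor RCBD —
#' replicate as the block, treatment and hybrid as crossed factors — using
#' the explicit textbook formulas (totals squared over their cell sizes,
#' minus the correction factor). For the reference layout (4 blocks, 2
#' treatments, 6 hybrids, N = 48) the degrees of freedom are 3 / 1 / 5 / 5 /
#' 33 / 47 for block / treatment / hybrid / interaction / error / total.
#' F ratios use the error mean square; p-values come from the upper tail of
#' the F distribution. With zero residual variation (e.g. noise-free
#' synthetic data) F is reported as \code{Inf}.
#'
#' @param obs a \code{"spar_obs"} observation table; must be balanced (every
#'   hybrid x treatment cell observed once per block).
#' @param trait trait code to analyse (aliases accepted).
#' @return An object of class \code{"rcbd_anova"}: a data frame with columns
#'   \code{source}, \code{df}, \code{ss}, \code{ms}, \code{f}, \code{p},
#'   \code{stars}, with the trait and design sizes as attributes.
#' @examples
#' obs <- simulate_trial(cv = 0.1, seed = 7)
#' rcbd_anova(obs, "Phot")
#' @export
rcbd_anova <- function(obs, trait) {
  stopifnot(inherits(obs, "spar_obs"))
  trait <- resolve_traits(trait, attr(obs, "panel"))
  d <- obs[obs$trait == trait, , drop = FALSE]
  if (nrow(d) == 0L) stop("no observations for trait ", trait, call. = FALSE)

  blocks <- sort(unique(d$replicate))
  trts <- unique(d$treatment)
  hybs <- unique(d$hybrid)
  r <- length(blocks); t <- length(trts); h <- length(hybs)
  counts <- table(d$hybrid, d$treatment, d$replicate)
  if (any(counts != 1L))
    stop("unbalanced data for trait ", trait,
         ": every hybrid x treatment cell must appear exactly once per block",
         call. = FALSE)
  N <- r * t * h
  df_err <- (N - 1L) - (r - 1L) - (t - 1L) - (h - 1L) - (t - 1L) * (h - 1L)
  if (df_err <= 0L)
    stop("zero error degrees of freedom; need more blocks", call. = FALSE)

  y <- d$value
  CF <- sum(y)^2 / N
  ss_total <- sum(y^2) - CF
  ss_block <- sum(tapply(y, d$replicate, sum)^2) / (t * h) - CF
  ss_trt   <- sum(tapply(y, d$treatment, sum)^2) / (r * h) - CF
  ss_hyb   <- sum(tapply(y, d$hybrid, sum)^2) / (r * t) - CF
  cells    <- tapply(y, interaction(d$treatment, d$hybrid, drop = TRUE), sum)
  ss_int   <- sum(cells^2) / r - CF - ss_trt - ss_hyb
  ss_err   <- ss_total - ss_block - ss_trt - ss_hyb - ss_int
  ss_err   <- max(ss_err, 0)  # guard tiny negative round-off

  src <- c("block", "treatment", "hybrid", "treatment:hybrid", "error",
           "total")
  ss <- c(ss_block, ss_trt, ss_hyb, ss_int, ss_err, ss_total)
  df <- c(r - 1L, t - 1L, h - 1L, (t - 1L) * (h - 1L), df_err, N - 1L)
  ms <- ss / df
  mse <- ms[5L]
  f <- c(ms[1:4] / mse, NA, NA)
  p <- c(stats::pf(f[1:4], df[1:4], df_err, lower.tail = FALSE), NA, NA)
  p[1:4][is.nan(f[1:4])] <- NA  # 0/0: no variation at all
  tab <- data.frame(source = src, df = df, ss = ss, ms = ms, f = f, p = p,
                    stars = c(star_code(p[1:4]), NA, NA),
                    stringsAsFactors = FALSE)
  structure(tab, trait = trait, sizes = c(blocks = r, treatments = t,
                                          hybrids = h),
            mse = mse, df_error = df_err,
            class = c("rcbd_anova", "data.frame"))
}

#' @export
print.rcbd_anova <- function(x, digits = 4L, ...) {
  cat("RCBD ANOVA:", attr(x, "trait"), "\n")
  y <- as.data.frame(x)
  y$ss <- signif(y$ss, digits); y$ms <- signif(y$ms, digits)
  y$f <- signif(y$f, digits)
  y$p <- format.pval(y$p, digits = 3L, na.form = "")
  y$f[is.na(x$f)] <- NA
  y$stars[is.na(y$stars)] <- ""
  print(y, row.names = FALSE)
  invisible(x)
}

#' Fisher's protected LSD mean separation
#'
#' Computes the least significant difference for one factor of a fitted RCBD
#' ANOVA, \code{LSD = t(1 - alpha/2, df_error) * sqrt(2 * MS_error / n)} with
#' n the number of observations per factor level, and assigns grouping
#' letters to the sorted level means. Protection: if the factor's omnibus
#' F-test is not significant at \code{alpha} the separation is skipped and no
#' letters are produced. Two levels share a letter if and only if their mean
#' difference does not exceed the LSD.
#'
#' @param anova a \code{"rcbd_anova"} object.
#' @param obs the observation table the ANOVA was fitted to.
#' @param factor \code{"hybrid"} or \code{"treatment"}.
#' @param alpha significance level (default 0.05).
#' @return An object of class \code{"lsd"}: list with \code{trait},
#'   \code{factor}, \code{alpha}, \code{lsd} (trait units), \code{skipped}
#'   (TRUE when the omnibus test failed), and \code{groups} (data frame of
#'   level, mean, letters, sorted by descending mean).
#' @export
fisher_lsd <- function(anova, obs, factor = c("hybrid", "treatment"),
                       alpha = 0.05) {
  stopifnot(inherits(anova, "rcbd_anova"), inherits(obs, "spar_obs"))
  factor <- match.arg(factor)
  trait <- attr(anova, "trait")
  d <- obs[obs$trait == trait, , drop = FALSE]
  lev_means <- sort(tapply(d$value, d[[factor]], mean), decreasing = TRUE)
  n_per <- nrow(d) / length(lev_means)
  df_err <- attr(anova, "df_error")
  lsd <- stats::qt(1 - alpha / 2, df_err) *
    sqrt(2 * attr(anova, "mse") / n_per)

  p_fac <- anova$p[anova$source == factor]
  if (is.na(p_fac) || p_fac >= alpha) {
    return(structure(list(trait = trait, factor = factor, alpha = alpha,
                          lsd = lsd, skipped = TRUE, groups = NULL),
                     class = "lsd"))
  }
  # maximal windows of sorted means with range <= LSD; one letter per window
  m <- as.numeric(lev_means); k <- length(m)
  windows <- list()
  for (i in seq_len(k)) {
    j <- max(which(m[i] - m <= lsd))          # furthest level still within LSD
    windows[[i]] <- c(i, j)
  }
  windows <- unique(windows)
  keep <- vapply(seq_along(windows), function(a)
    !any(vapply(seq_along(windows), function(b)
      a != b && windows[[b]][1L] <= windows[[a]][1L] &&
        windows[[b]][2L] >= windows[[a]][2L], logical(1L))), logical(1L))
  windows <- windows[keep]
  letters_out <- character(k)
  for (w in seq_along(windows)) {
    rng <- windows[[w]]
    idx <- rng[1L]:rng[2L]
    letters_out[idx] <- paste0(letters_out[idx], letters[w])
  }
  groups <- data.frame(level = names(lev_means), mean = m,
                       letters = letters_out, row.names = NULL,
                       stringsAsFactors = FALSE)
  structure(list(trait = trait, factor = factor, alpha = alpha, lsd = lsd,
                 skipped = FALSE, groups = groups), class = "lsd")
}

#' @export
print.lsd <- function(x, digits = 4L, ...) {
  cat(sprintf("Fisher's protected LSD: %s by %s (alpha = %s)\n",
              x$trait, x$factor, format(x$alpha)))
  cat("  LSD =", signif(x$lsd, digits), "\n")
  if (x$skipped) {
    cat("  omnibus F-test not significant; mean separation skipped\n")
  } else {
    g <- x$groups; g$mean <- signif(g$mean, digits)
    print(g, row.names = FALSE)
  }
  invisible(x)
}
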