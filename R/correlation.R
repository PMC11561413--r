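#' Within-treatment Pearson correlation matrix with significance tiers
#'
#' Correlates every trait pair across the replicate-level observations of one
#' treatment (observations aligned by hybrid and replicate, so for the
#' reference design n = 6 x 4 = 24 per pair). Two-sided p-values use
#' \code{t = r * sqrt(n - 2) / sqrt(1 - r^2)} on n - 2 degrees of freedom.
#' The star legend follows the agronomic trait-correlation convention used
#' with these tables: \code{*} for p < 0.01 and \code{**} for p < 0.001
#' (note: deliberately different from the ANOVA star codes), \code{NS}
#' otherwise. A zero-variance trait yields NA (undefined), never 0.
#'
#' @param obs a \code{"spar_obs"} observation table.
#' @param treatment treatment label to subset (aliases accepted).
#' @param traits trait codes to include; default all traits present, in
#'   panel order.
#' @return An object of class \code{"cor_matrix"}: list with \code{treatment},
#'   \code{traits}, \code{r}, \code{p}, \code{stars} (matrices), \code{n} and
#'   \code{legend}.
#' @examples
#' obs <- simulate_trial(cv = 0.1, seed = 7)
#' cm <- pearson_matrix(obs, "D")
#' cm$r["Phot", "PH"]
#' @export
pearson_matrix <- function(obs, treatment, traits = NULL) {
  stopifnot(inherits(obs, "spar_obs"))
  design <- attr(obs, "design")
  panel <- attr(obs, "panel")
  treatment <- resolve_treatments(treatment, design)
  d <- obs[obs$treatment == treatment, , drop = FALSE]
  if (is.null(traits)) traits <- panel$code[panel$code %in% unique(d$trait)]
  else traits <- resolve_traits(traits, panel)

  key <- paste(d$hybrid, d$replicate, sep = "\r")
  units <- sort(unique(key))
  X <- sapply(traits, function(tc) {
    sub <- d[d$trait == tc, , drop = FALSE]
    v <- stats::setNames(sub$value, paste(sub$hybrid, sub$replicate,
                                          sep = "\r"))
    unname(v[units])
  })
  X <- matrix(X, nrow = length(units), dimnames = list(NULL, traits))
  if (anyNA(X))
    stop("incomplete observations within treatment ", treatment, call. = FALSE)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)

  sds <- apply(X, 2L, stats::sd)
  r <- suppressWarnings(stats::cor(X))
  r[sds == 0, ] <- NA; r[, sds == 0] <- NA
  diag(r)[sds > 0] <- 1
  rr <- pmin(pmax(r, -1), 1)
  tstat <- rr * sqrt(n - 2) / sqrt(pmax(1 - rr^2, 0))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA
  stars <- matrix(ifelse(p < 0.001, "**", ifelse(p < 0.01, "*", "NS")),
                  nrow = nrow(p), dimnames = dimnames(p))
  stars[is.na(p)] <- NA
  structure(list(treatment = treatment, traits = traits, r = r, p = p,
                 stars = stars, n = n,
                 legend = c("*" = "p < 0.01", "**" = "p < 0.001")),
            class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, digits = 3L, max_traits = 8L, ...) {
  cat(sprintf("Pearson correlations within treatment %s (n = %d)\n",
              x$treatment, x$n))
  k <- min(length(x$traits), max_traits)
  show <- x$traits[seq_len(k)]
  m <- matrix(sprintf("%s%s", format(round(x$r[show, show], digits)),
                      ifelse(is.na(x$stars[show, show]), "",
                             ifelse(x$stars[show, show] == "NS", "",
                                    x$stars[show, show]))),
              nrow = k, dimnames = list(show, show))
  print(m, quote = FALSE)
  if (k < length(x$traits))
    cat("... (", length(x$traits) - k, " more traits)\n", sep = "")
  cat("legend: * p < 0.01, ** p < 0.001\n")
  invisible(x)
}

#' Combine drought and control correlation matrices into one table
#'
#' The conventional compact display: drought-treatment correlations above the
#' diagonal, control correlations below, 1.000 on the diagonal, star suffixes
#' appended to each entry.
#'
#' @param corr_drought,corr_control \code{"cor_matrix"} objects over the same
#'   trait list.
#' @param digits digits for the formatted coefficients.
#' @return A character matrix (traits x traits) of formatted entries.
#' @export
combined_matrix_report <- function(corr_drought, corr_control, digits = 3L) {
  stopifnot(inherits(corr_drought, "cor_matrix"),
            inherits(corr_control, "cor_matrix"))
  if (!identical(corr_drought$traits, corr_control$traits))
    stop("the two matrices cover different trait lists", call. = FALSE)
  traits <- corr_drought$traits
  fmt <- function(r, s) ifelse(is.na(r), "NA",
    paste0(formatC(r, digits = digits, format = "f"),
           ifelse(is.na(s) | s == "NS", "", s)))
  out <- matrix("", length(traits), length(traits),
                dimnames = list(traits, traits))
  up <- upper.tri(out); lo <- lower.tri(out)
  out[up] <- fmt(corr_drought$r, corr_drought$stars)[up]
  out[lo] <- fmt(corr_control$r, corr_control$stars)[lo]
  diag(out) <- formatC(1, digits = digits, format = "f")
  out
}
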