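#' Individual drought stress response index (IDSRI)
#'
#' The IDSRI of a trait for one hybrid is the ratio of its mean under drought
#' to its mean under control, \code{drought / control}. The direction is the
#' same for every trait — including traits that increase under drought such
#' as RSR, LRL and RD — so a larger ratio always contributes more to the
#' cumulative index.
#'
#' @param means a \code{"trait_means"} table.
#' @param hybrid hybrid name.
#' @param trait trait code (aliases accepted).
#' @return A single unitless ratio.
#' @examples
#' round(idsri(spar_trial_means(), "DKC-6581", "PH"), 4)  # 0.5867
#' @export
idsri <- function(means, hybrid, trait) {
  stopifnot(inherits(means, "trait_means"))
  design <- attr(means, "design")
  ctrl <- design$control
  drgt <- setdiff(design$treatments, ctrl)[1L]
  den <- mean_value(means, hybrid, ctrl, trait)
  if (den == 0)
    stop(sprintf("control mean is zero for trait %s, hybrid %s; IDSRI undefined",
                 trait, hybrid), call. = FALSE)
  mean_value(means, hybrid, drgt, trait) / den
}

#' Cumulative drought stress response index (CDSRI)
#'
#' The CDSRI of a hybrid is the plain sum of its IDSRI ratios over a fixed
#' trait panel — by default the 21 member traits of [trait_panel()] (all
#' measured traits except ETR). Higher CDSRI means the hybrid retained more
#' of its control-condition phenotype under drought, i.e. is more tolerant.
#' A missing member trait is an error, never silently dropped: CDSRI
#' magnitudes are only comparable at a fixed trait count. Pass \code{traits}
#' to score an explicit subset.
#'
#' @param means a \code{"trait_means"} table.
#' @param hybrid hybrid name.
#' @param traits trait codes to sum over; default the CDSRI members of the
#'   panel attached to \code{means}.
#' @return A single number; \code{attr(., "n_traits")} records how many
#'   ratios were summed.
#' @examples
#' round(cdsri(spar_trial_means(), "DKC-6581"), 2)  # 15.53
#' @export
cdsri <- function(means, hybrid, traits = NULL) {
  stopifnot(inherits(means, "trait_means"))
  panel <- attr(means, "panel")
  if (is.null(traits)) traits <- panel$code[panel$cdsri_member]
  else traits <- resolve_traits(traits, panel)
  missing <- setdiff(traits, unique(means$trait))
  if (length(missing) > 0L)
    stop("CDSRI member trait(s) absent from the table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  r <- vapply(traits, function(tc) idsri(means, hybrid, tc), numeric(1L))
  structure(sum(r), n_traits = length(traits))
}

#' Classify CDSRI scores into three tolerance groups
#'
#' Splits the observed score range \code{[min, max]} into three equal-width
#' bins and labels them, in increasing CDSRI, \code{sensitive},
#' \code{moderate} and \code{tolerant}. The lower two bins are half-open
#' \code{[lo, hi)} and the top bin is closed, so a score exactly on an
#' interior edge goes to the upper bin.
#'
#' @param scores named numeric vector of CDSRI scores (>= 3 hybrids,
#'   \code{max > min}), or pre-computed bounds via \code{breaks}.
#' @param breaks optional numeric vector of 4 increasing edges to use instead
#'   of the observed-range rule (\code{method = "fixed"}).
#' @return A list of class \code{"cdsri_class"}: \code{class} (named factor
#'   with levels sensitive < moderate < tolerant), \code{bounds} (3 x 2
#'   matrix of bin edges), \code{method}, \code{width}.
#' @examples
#' classify_cdsri(reported_cdsri_scores())$class
#' @export
classify_cdsri <- function(scores, breaks = NULL) {
  stopifnot(is.numeric(scores), !is.null(names(scores)), !anyNA(scores))
  labels <- c("sensitive", "moderate", "tolerant")
  if (is.null(breaks)) {
    if (length(scores) < 3L)
      stop("need at least 3 scores for the observed-range rule", call. = FALSE)
    lo <- min(scores); hi <- max(scores)
    if (hi <= lo)
      stop("degenerate score range: all CDSRI scores equal", call. = FALSE)
    breaks <- seq(lo, hi, length.out = 4L)
    method <- "equal_width_observed"
  } else {
    stopifnot(is.numeric(breaks), length(breaks) == 4L, !is.unsorted(breaks))
    method <- "fixed"
  }
  width <- diff(breaks)
  # interior edges belong to the upper bin; the top bin is closed above
  idx <- findInterval(scores, breaks, rightmost.closed = TRUE,
                      left.open = FALSE)
  idx <- pmin(pmax(idx, 1L), 3L)
  cls <- factor(labels[idx], levels = labels, ordered = TRUE)
  names(cls) <- names(scores)
  bounds <- cbind(lower = breaks[1:3], upper = breaks[2:4])
  rownames(bounds) <- labels
  structure(list(class = cls, bounds = bounds, method = method,
                 width = width), class = "cdsri_class")
}

#' @export
print.cdsri_class <- function(x, digits = 3L, ...) {
  cat("CDSRI classification (", x$method, ")\n", sep = "")
  b <- round(x$bounds, digits)
  for (g in rev(rownames(b))) {
    memb <- names(x$class)[x$class == g]
    cat(sprintf("  %-9s [%s, %s%s  %s\n", g, b[g, 1L], b[g, 2L],
                if (g == "tolerant") "]:" else "):",
                if (length(memb)) paste(memb, collapse = ", ") else "-"))
  }
  invisible(x)
}

#' Rank hybrids by CDSRI
#'
#' @param scores named numeric vector of CDSRI scores.
#' @return Data frame sorted by descending score (ties broken alphabetically
#'   by hybrid name) with columns \code{hybrid}, \code{cdsri}, \code{rank}
#'   and \code{tied}.
#' @export
rank_hybrids <- function(scores) {
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  ord <- order(-scores, names(scores))
  out <- data.frame(hybrid = names(scores)[ord], cdsri = unname(scores[ord]),
                    stringsAsFactors = FALSE)
  out$rank <- rank(-out$cdsri, ties.method = "min")
  out$tied <- duplicated(out$cdsri) | duplicated(out$cdsri, fromLast = TRUE)
  out
}

#' CDSRI scores reported for the bundled reference trial
#'
#' The cumulative index values reported alongside the bundled six-hybrid
#' trial. Note that these published magnitudes (25.21-28.32) are not
#' reproducible from the bundled trait-mean table: recomputing the index from
#' the printed means gives roughly 15-18 (see [reference_analysis()]'s
#' discrepancy report). They are retained verbatim because the three-group
#' classification is defined on them.
#'
#' @return Named numeric vector of 6 scores.
#' @export
reported_cdsri_scores <- function() {
  c("P-1319" = 25.21, "N59B-311A" = 25.34, "DKC-6697" = 26.85,
    "P-1498" = 26.89, "N61X-3110" = 28.02, "DKC-6581" = 28.32)
}

#' Fit drought stress response indices to a screening trial
#'
#' The central model-fitting function of the package. Takes either
#' replicate-level observations (collapsed to cell means first) or a
#' trait-mean table, computes every hybrid's individual stress response
#' ratios (IDSRI = drought mean / control mean, per trait), sums them over
#' the member panel into the cumulative index (CDSRI), and classifies the
#' hybrids into sensitive / moderate / tolerant groups by equal-width
#' three-way binning of the observed CDSRI range.
#'
#' @param x a \code{"spar_obs"} observation table or a \code{"trait_means"}
#'   table.
#' @param traits trait codes to sum over; default the panel's CDSRI members.
#' @param breaks optional fixed classification edges, see [classify_cdsri()].
#' @return An object of class \code{"dsri"}: a list with \code{idsri}
#'   (hybrids x traits ratio matrix), \code{cdsri} (named vector),
#'   \code{classification} (a \code{"cdsri_class"}), \code{n_traits},
#'   \code{means}, \code{design} and \code{call}. Supports \code{print},
#'   \code{summary}, \code{coef} (the CDSRI scores), \code{predict}
#'   (classify new scores with the fitted bounds) and \code{plot}.
#' @examples
#' fit <- dsri(spar_trial_means())
#' coef(fit)
#' summary(fit)
#' @export
dsri <- function(x, traits = NULL, breaks = NULL) {
  cl <- match.call()
  means <- if (inherits(x, "spar_obs")) collapse_to_means(x)
           else if (inherits(x, "trait_means")) x
           else stop("x must be an observation table or a trait-mean table",
                     call. = FALSE)
  panel <- attr(means, "panel")
  design <- attr(means, "design")
  if (is.null(traits)) traits <- panel$code[panel$cdsri_member]
  else traits <- resolve_traits(traits, panel)
  missing <- setdiff(traits, unique(means$trait))
  if (length(missing) > 0L)
    stop("CDSRI member trait(s) absent from the data: ",
         paste(missing, collapse = ", "), call. = FALSE)

  ratios <- sapply(traits, function(tc)
    vapply(design$hybrids, function(h) idsri(means, h, tc), numeric(1L)))
  ratios <- matrix(ratios, nrow = length(design$hybrids),
                   dimnames = list(design$hybrids, traits))
  scores <- rowSums(ratios)
  classification <- classify_cdsri(scores, breaks = breaks)
  structure(list(idsri = ratios, cdsri = scores,
                 classification = classification,
                 n_traits = length(traits), means = means, design = design,
                 call = cl),
            class = "dsri")
}

#' @export
print.dsri <- function(x, digits = 2L, ...) {
  cat("Drought stress response indices (", x$n_traits,
      " traits summed)\n\n", sep = "")
  r <- rank_hybrids(x$cdsri)
  r$class <- as.character(x$classification$class[r$hybrid])
  r$cdsri <- round(r$cdsri, digits)
  print(r[c("hybrid", "cdsri", "rank", "class")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.dsri <- function(object, ...) {
  structure(list(fit = object), class = "summary.dsri")
}

#' @export
print.summary.dsri <- function(x, digits = 3L, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("\nIDSRI ratios (drought / control):\n")
  print(round(t(f$idsri), digits))
  cat("\n")
  print(f$classification, digits = digits)
  invisible(x)
}

#' @export
coef.dsri <- function(object, ...) object$cdsri

#' Classify new CDSRI scores with a fitted binning
#'
#' @param object a fitted \code{"dsri"} object.
#' @param newscores named numeric vector of CDSRI scores; default the fitted
#'   scores.
#' @param ... unused.
#' @return Named ordered factor of class labels.
#' @export
predict.dsri <- function(object, newscores = NULL, ...) {
  if (is.null(newscores)) return(object$classification$class)
  b <- object$classification$bounds
  classify_cdsri(newscores, breaks = c(b[, 1L], b[3L, 2L]))$class
}

#' @export
plot.dsri <- function(x, ...) {
  cls <- x$classification
  r <- rank_hybrids(x$cdsri)
  cols <- c(sensitive = "#d95f02", moderate = "#7570b3",
            tolerant = "#1b9e77")
  graphics::barplot(rev(r$cdsri), names.arg = rev(r$hybrid), horiz = TRUE,
                    las = 1, xlab = "CDSRI",
                    col = cols[as.character(cls$class[rev(r$hybrid)])], ...)
  graphics::abline(v = cls$bounds[2:3, 1L], lty = 2, col = "grey40")
  invisible(x)
}
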