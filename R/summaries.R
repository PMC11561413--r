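#' Treatment-level trait mean across hybrids
#'
#' Unweighted arithmetic mean of the per-hybrid cell means for one trait in
#' one treatment.
#'
#' @param means a \code{"trait_means"} table.
#' @param trait trait code (aliases accepted).
#' @param treatment treatment label (aliases \code{T1}/\code{T2} accepted).
#' @return A single number in trait units.
#' @examples
#' round(treatment_mean(spar_trial_means(), "Phot", "C"), 2)  # 38.18
#' @export
treatment_mean <- function(means, trait, treatment) {
  stopifnot(inherits(means, "trait_means"))
  design <- attr(means, "design")
  vals <- vapply(design$hybrids,
                 function(h) mean_value(means, h, treatment, trait),
                 numeric(1L))
  mean(vals)
}

#' Percent stress response of a trait
#'
#' Percent change of a trait from control (C) to drought (D), on the scale
#' the field reports: \code{decline = 100 * (C - D) / C} and
#' \code{increase = 100 * (D - C) / C}; the two are exact negatives. With
#' \code{hybrid = NULL} the change of the across-hybrid treatment means is
#' returned (equivalently, of the grand cell means in a balanced trial);
#' otherwise the change for one hybrid. All arithmetic is on unrounded means;
#' round only for display.
#'
#' @param means a \code{"trait_means"} table.
#' @param trait trait code.
#' @param hybrid one hybrid name, or \code{NULL} for the overall response.
#' @param direction \code{"decline"} or \code{"increase"}.
#' @return A single number (percent).
#' @examples
#' means <- spar_trial_means()
#' round(percent_change(means, "Phot"), 2)                  # 57.96
#' round(percent_change(means, "LRL", direction = "increase"), 2)
#' @export
percent_change <- function(means, trait, hybrid = NULL,
                           direction = c("decline", "increase")) {
  direction <- match.arg(direction)
  stopifnot(inherits(means, "trait_means"))
  design <- attr(means, "design")
  ctrl <- design$control
  drgt <- setdiff(design$treatments, ctrl)[1L]
  if (is.null(hybrid)) {
    mc <- treatment_mean(means, trait, ctrl)
    md <- treatment_mean(means, trait, drgt)
  } else {
    mc <- mean_value(means, hybrid, ctrl, trait)
    md <- mean_value(means, hybrid, drgt, trait)
  }
  if (mc == 0)
    stop("control mean is zero for trait ", trait,
         "; percent change undefined", call. = FALSE)
  pct <- 100 * (mc - md) / mc
  if (direction == "increase") -pct else pct
}

#' Absolute trait reduction under drought
#'
#' Control-minus-drought difference of cell means, in trait units.
#'
#' @inheritParams percent_change
#' @return A single number in trait units.
#' @examples
#' absolute_reduction(spar_trial_means(), "PH", "DKC-6697")  # 17.5
#' @export
absolute_reduction <- function(means, trait, hybrid = NULL) {
  stopifnot(inherits(means, "trait_means"))
  design <- attr(means, "design")
  ctrl <- design$control
  drgt <- setdiff(design$treatments, ctrl)[1L]
  if (is.null(hybrid))
    return(treatment_mean(means, trait, ctrl) -
             treatment_mean(means, trait, drgt))
  mean_value(means, hybrid, ctrl, trait) -
    mean_value(means, hybrid, drgt, trait)
}

#' Most and least responsive hybrids for a trait
#'
#' Ranks hybrids by their percent stress response for one trait and returns
#' the extremes; exact ties are returned as multi-row data frames.
#'
#' @inheritParams percent_change
#' @return A list with elements \code{max} and \code{min}, each a data frame
#'   of \code{hybrid} and \code{value} (percent), plus \code{direction}.
#' @examples
#' extreme_responders(spar_trial_means(), "NRT")$min$hybrid  # DKC-6697
#' @export
extreme_responders <- function(means, trait,
                               direction = c("decline", "increase")) {
  direction <- match.arg(direction)
  stopifnot(inherits(means, "trait_means"))
  design <- attr(means, "design")
  if (length(design$hybrids) < 2L)
    stop("need at least 2 hybrids to rank responders", call. = FALSE)
  pct <- vapply(design$hybrids, function(h)
    percent_change(means, trait, hybrid = h, direction = direction),
    numeric(1L))
  pick <- function(v) data.frame(hybrid = names(pct)[pct == v], value = v,
                                 row.names = NULL, stringsAsFactors = FALSE)
  list(max = pick(max(pct)), min = pick(min(pct)), direction = direction)
}

#' Full stress-response summary table
#'
#' One row per trait and scope (overall plus each hybrid): control mean,
#' drought mean, percent decline and absolute reduction. This is the table
#' behind every narrated percent statement of a screening trial's results.
#'
#' @param means a \code{"trait_means"} table.
#' @param traits trait codes to include; default all traits in the table.
#' @return Data frame with columns \code{trait}, \code{scope},
#'   \code{mean_C}, \code{mean_D}, \code{pct_decline}, \code{abs_reduction}.
#' @export
stress_summary <- function(means, traits = NULL) {
  stopifnot(inherits(means, "trait_means"))
  design <- attr(means, "design")
  ctrl <- design$control
  drgt <- setdiff(design$treatments, ctrl)[1L]
  if (is.null(traits)) {
    panel <- attr(means, "panel")
    traits <- panel$code[panel$code %in% unique(means$trait)]
  } else traits <- resolve_traits(traits, attr(means, "panel"))
  rows <- lapply(traits, function(tc) {
    scopes <- c("overall", design$hybrids)
    do.call(rbind, lapply(scopes, function(sc) {
      h <- if (sc == "overall") NULL else sc
      mc <- if (is.null(h)) treatment_mean(means, tc, ctrl)
            else mean_value(means, h, ctrl, tc)
      md <- if (is.null(h)) treatment_mean(means, tc, drgt)
            else mean_value(means, h, drgt, tc)
      data.frame(trait = tc, scope = sc, mean_C = mc, mean_D = md,
                 pct_decline = if (mc == 0) NA_real_ else 100 * (mc - md) / mc,
                 abs_reduction = mc - md, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
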