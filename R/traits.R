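#' The default morpho-physiological trait panel
#'
#' Returns the 22-trait panel measured in the six-hybrid maize SPAR screening
#' trial bundled with the package: developmental traits (plant height, leaf
#' area, dry weights, ...), root-architecture traits from scanned root images
#' (total root length, tips, forks, crossings, ...), and physiological traits
#' (SPAD chlorophyll, Fv/Fm, net photosynthetic rate, electron transport
#' rate). Exactly 21 of the 22 traits enter the cumulative drought stress
#' response index (CDSRI); ETR is measured and summarised but is not a CDSRI
#' member.
#'
#' @return A data frame of class \code{"trait_panel"} with columns
#'   \code{code}, \code{label}, \code{units}, \code{category} (one of
#'   \code{"developmental"}, \code{"root"}, \code{"physiological"}),
#'   \code{cdsri_member} and \code{nonnegative}.
#' @seealso [resolve_traits()] for the accepted input aliases
#'   (\code{RL} for \code{TRL}, \code{ARD} for \code{RD}, \code{RS} for
#'   \code{RSR}, \code{"Fv/Fm"} for \code{FvFm}).
#' @examples
#' panel <- trait_panel()
#' sum(panel$cdsri_member)  # 21
#' @export
trait_panel <- function() {
  p <- data.frame(
    code = c("PH", "LN", "LA", "LDW", "SDW", "SHDW", "RDW", "RSR", "TDW",
             "RSA", "RD", "TRL", "RV", "NRT", "NRF", "NRC", "LRL", "RN",
             "SPAD", "Phot", "FvFm", "ETR"),
    label = c("plant height", "leaf number", "leaf area", "leaf dry weight",
              "stem dry weight (with leaves)", "shoot dry weight",
              "root dry weight", "root-to-shoot dry weight ratio",
              "total dry weight", "root surface area", "average root diameter",
              "total root length", "root volume", "number of root tips",
              "number of root forks", "number of root crossings",
              "longest root length", "number of roots",
              "SPAD chlorophyll index", "net photosynthetic rate",
              "maximal PSII quantum yield (Fv/Fm)", "electron transport rate"),
    units = c("cm plant-1", "no. plant-1", "cm2 plant-1", "g plant-1",
              "g plant-1", "g plant-1", "g plant-1", "unitless", "g plant-1",
              "cm2 plant-1", "mm plant-1", "cm plant-1", "cm3 plant-1",
              "no. plant-1", "no. plant-1", "no. plant-1", "cm plant-1",
              "no. plant-1", "unitless", "umol m-2 s-1", "unitless",
              "umol m-2 s-1"),
    category = c("developmental", "developmental", "developmental",
                 "developmental", "developmental", "developmental",
                 "root", "root", "developmental",
                 "root", "root", "root", "root", "root", "root", "root",
                 "root", "root",
                 "physiological", "physiological", "physiological",
                 "physiological"),
    stringsAsFactors = FALSE
  )
  # every measured trait enters the cumulative index except ETR
  p$cdsri_member <- p$code != "ETR"
  p$nonnegative <- TRUE
  class(p) <- c("trait_panel", "data.frame")
  p
}

# input aliases: alternative symbols accepted for the same quantity
.trait_aliases <- c(
  "RL"    = "TRL",   # total root length
  "ARD"   = "RD",    # average root diameter
  "RS"    = "RSR",   # root-to-shoot ratio
  "Fv/Fm" = "FvFm",
  "FV/FM" = "FvFm"
)

#' Resolve trait codes against a panel
#'
#' Maps user-supplied trait codes (including accepted aliases such as
#' \code{RL}, \code{ARD}, \code{RS} and \code{"Fv/Fm"}) to the canonical codes
#' of a panel, erroring on codes that resolve to nothing.
#'
#' @param codes character vector of trait codes or aliases.
#' @param panel a trait panel, see [trait_panel()].
#' @return Character vector of canonical codes, same length as \code{codes}.
#' @export
resolve_traits <- function(codes, panel = trait_panel()) {
  stopifnot(is.character(codes))
  out <- ifelse(codes %in% names(.trait_aliases),
                unname(.trait_aliases[codes]), codes)
  bad <- unique(codes[!(out %in% panel$code)])
  if (length(bad) > 0L)
    stop("unknown trait code(s): ", paste(bad, collapse = ", "), call. = FALSE)
  out
}

# treatment aliases: T1 = drought, T2 = irrigated control
.treatment_aliases <- c("T1" = "D", "T2" = "C")

resolve_treatments <- function(labels, design) {
  out <- ifelse(labels %in% names(.treatment_aliases),
                unname(.treatment_aliases[labels]), labels)
  bad <- unique(labels[!(out %in% design$treatments)])
  if (length(bad) > 0L)
    stop("unknown treatment label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  out
}

#' Experimental design specification
#'
#' Describes the layout of a two-treatment screening trial: the genotype
#' entries, the treatment labels, the replicate count, and which treatment is
#' the control (the denominator of all stress-response ratios).
#'
#' @param hybrids ordered character vector of genotype names. Defaults to the
#'   six maize hybrids of the bundled reference trial.
#' @param treatments ordered character vector of treatment labels; the default
#'   \code{c("D", "C")} encodes drought and irrigated control. \code{"T1"} and
#'   \code{"T2"} are accepted as aliases for \code{"D"} and \code{"C"} on
#'   input.
#' @param n_replicates positive integer, replications per hybrid x treatment
#'   cell (the replicate plays the block role in the RCBD analysis).
#' @param control treatment label used as the ratio denominator.
#' @return A list of class \code{"design_spec"}.
#' @examples
#' spar_design()
#' @export
design_spec <- function(hybrids, treatments = c("D", "C"),
                        n_replicates = 4L, control = "C") {
  stopifnot(is.character(hybrids), length(hybrids) >= 1L,
            !anyDuplicated(hybrids),
            is.character(treatments), length(treatments) >= 1L,
            !anyDuplicated(treatments))
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1L)
    stop("n_replicates must be a positive integer", call. = FALSE)
  if (control %in% names(.treatment_aliases))
    control <- unname(.treatment_aliases[control])
  if (!control %in% treatments)
    stop("control label ", sQuote(control), " is not among the treatments",
         call. = FALSE)
  structure(list(hybrids = hybrids, treatments = treatments,
                 n_replicates = n_replicates, control = control),
            class = "design_spec")
}

#' @rdname design_spec
#' @export
spar_design <- function() {
  design_spec(hybrids = c("P-1498", "P-1319", "DKC-6581", "DKC-6697",
                          "N61X-3110", "N59B-311A"))
}

#' @export
print.design_spec <- function(x, ...) {
  cat("Design:", length(x$hybrids), "hybrids x", length(x$treatments),
      "treatments x", x$n_replicates, "replicates\n")
  cat("  hybrids:   ", paste(x$hybrids, collapse = ", "), "\n")
  cat("  treatments:", paste(x$treatments, collapse = ", "),
      sprintf("(control = %s)\n", x$control))
  invisible(x)
}
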