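#' Construct and validate a replicate-level observation table
#'
#' The long-format container for raw trial data: one row per
#' (hybrid, treatment, replicate, trait) with a numeric value. Validation
#' enforces unique keys, label resolution against the panel and design, and
#' non-negativity for traits declared nonnegative.
#'
#' @param df data frame with columns \code{hybrid}, \code{treatment},
#'   \code{replicate}, \code{trait}, \code{value}.
#' @param panel trait panel, see [trait_panel()].
#' @param design design specification, see [design_spec()].
#' @return The validated data frame, class \code{"spar_obs"}, with the panel
#'   and design attached as attributes; trait and treatment aliases are
#'   rewritten to canonical codes.
#' @export
observation_table <- function(df, panel = trait_panel(),
                              design = spar_design()) {
  need <- c("hybrid", "treatment", "replicate", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)[need]
  df$hybrid <- as.character(df$hybrid)
  df$treatment <- as.character(df$treatment)
  df$trait <- as.character(df$trait)

  if (!is.numeric(df$value)) {
    suppressWarnings(v <- as.numeric(df$value))
    if (anyNA(v) && !anyNA(df$value))
      stop("non-numeric value(s) at row(s): ",
           paste(utils::head(which(is.na(v)), 5L), collapse = ", "),
           call. = FALSE)
    df$value <- v
  }
  if (anyNA(df$value))
    stop("missing value(s) at row(s): ",
         paste(utils::head(which(is.na(df$value)), 5L), collapse = ", "),
         call. = FALSE)

  bad_h <- !(df$hybrid %in% design$hybrids)
  if (any(bad_h))
    stop("unknown hybrid label(s) ",
         paste(unique(df$hybrid[bad_h]), collapse = ", "),
         " at row(s): ", paste(utils::head(which(bad_h), 5L), collapse = ", "),
         call. = FALSE)
  df$treatment <- resolve_treatments(df$treatment, design)
  df$trait <- resolve_traits(df$trait, panel)

  key <- paste(df$hybrid, df$treatment, df$replicate, df$trait, sep = "\r")
  if (anyDuplicated(key)) {
    d <- df[duplicated(key), , drop = FALSE][1L, ]
    stop(sprintf("duplicate key (%s, %s, %s, %s)",
                 d$hybrid, d$treatment, d$replicate, d$trait), call. = FALSE)
  }

  nn <- panel$code[panel$nonnegative]
  neg <- df$trait %in% nn & df$value < 0
  if (any(neg))
    stop("negative value for nonnegative trait(s) ",
         paste(unique(df$trait[neg]), collapse = ", "),
         " at row(s): ", paste(utils::head(which(neg), 5L), collapse = ", "),
         call. = FALSE)

  rownames(df) <- NULL
  structure(df, panel = panel, design = design,
            class = c("spar_obs", "data.frame"))
}

#' Read and write observation CSV files
#'
#' Long-format CSV interchange for replicate-level observations: columns
#' \code{hybrid,treatment,replicate,trait,value}, comma-separated, UTF-8,
#' \code{"."} decimal, header required. [write_observations()] followed by
#' [read_observations()] round-trips the table exactly.
#'
#' @param path file path.
#' @param panel,design see [observation_table()].
#' @return [read_observations()] returns a validated \code{"spar_obs"} table.
#' @export
read_observations <- function(path, panel = trait_panel(),
                              design = spar_design()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(value = "character"))
  observation_table(df, panel = panel, design = design)
}

#' @rdname read_observations
#' @param obs an observation table.
#' @export
write_observations <- function(obs, path) {
  out <- as.data.frame(obs)
  # 17 significant digits: doubles survive the text round-trip exactly
  out$value <- sprintf("%.17g", out$value)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a per-cell trait-mean table
#'
#' The treatment-level container: one row per (hybrid, treatment, trait) with
#' the cell mean and optionally its standard error and replicate count. Every
#' trait present must be complete over hybrids x treatments; a missing cell is
#' a load-time error, never silently absent.
#'
#' @param df data frame with columns \code{hybrid}, \code{treatment},
#'   \code{trait}, \code{mean} and optionally \code{se}, \code{n}.
#' @param panel,design see [observation_table()].
#' @return Data frame of class \code{"trait_means"} with attributes
#'   \code{panel} and \code{design}.
#' @export
trait_mean_table <- function(df, panel = trait_panel(),
                             design = spar_design()) {
  need <- c("hybrid", "treatment", "trait", "mean")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df <- as.data.frame(df)
  df$hybrid <- as.character(df$hybrid)
  df$treatment <- resolve_treatments(as.character(df$treatment), design)
  df$trait <- resolve_traits(as.character(df$trait), panel)
  if (!all(df$hybrid %in% design$hybrids))
    stop("unknown hybrid label(s): ",
         paste(setdiff(unique(df$hybrid), design$hybrids), collapse = ", "),
         call. = FALSE)
  stopifnot(is.numeric(df$mean))
  if (!"se" %in% names(df)) df$se <- NA_real_
  if (!"n" %in% names(df)) df$n <- NA_integer_
  if (any(!is.na(df$se) & df$se < 0))
    stop("negative standard error(s)", call. = FALSE)

  key <- paste(df$hybrid, df$treatment, df$trait, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (hybrid, treatment, trait) cell(s)", call. = FALSE)
  # completeness: every trait present must cover all hybrids x treatments
  want <- expand.grid(hybrid = design$hybrids, treatment = design$treatments,
                      trait = unique(df$trait), stringsAsFactors = FALSE)
  wkey <- paste(want$hybrid, want$treatment, want$trait, sep = "\r")
  absent <- setdiff(wkey, key)
  if (length(absent) > 0L)
    stop("incomplete trait-mean table: ", length(absent),
         " missing cell(s), e.g. (",
         gsub("\r", ", ", absent[1L], fixed = TRUE), ")", call. = FALSE)

  df <- df[c("hybrid", "treatment", "trait", "mean", "se", "n")]
  rownames(df) <- NULL
  structure(df, panel = panel, design = design,
            class = c("trait_means", "data.frame"))
}

#' Collapse replicate-level observations to cell means
#'
#' Computes, for every (hybrid, treatment, trait) cell, the arithmetic mean,
#' the standard error of the mean (sample standard deviation with the n-1
#' denominator, divided by sqrt(n)) and the replicate count n. Cells with a
#' single replicate get an undefined (NA) standard error.
#'
#' @param obs an observation table, see [observation_table()].
#' @return A \code{"trait_means"} table, see [trait_mean_table()].
#' @examples
#' obs <- simulate_trial(cv = 0, seed = 1)
#' means <- collapse_to_means(obs)
#' @export
collapse_to_means <- function(obs) {
  stopifnot(inherits(obs, "spar_obs"), nrow(obs) > 0L)
  f <- interaction(obs$hybrid, obs$treatment, obs$trait, sep = "\r",
                   drop = TRUE)
  m <- tapply(obs$value, f, mean)
  s <- tapply(obs$value, f, stats::sd)  # NA when n = 1
  n <- tapply(obs$value, f, length)
  parts <- do.call(rbind, strsplit(names(m), "\r", fixed = TRUE))
  out <- data.frame(hybrid = parts[, 1L], treatment = parts[, 2L],
                    trait = parts[, 3L], mean = as.numeric(m),
                    se = as.numeric(s) / sqrt(as.numeric(n)),
                    n = as.integer(n), stringsAsFactors = FALSE)
  trait_mean_table(out, panel = attr(obs, "panel"),
                   design = attr(obs, "design"))
}

#' Look up one cell of a trait-mean table
#'
#' @param means a \code{"trait_means"} table.
#' @param hybrid,treatment,trait cell coordinates (aliases accepted).
#' @return The cell mean, a single number.
#' @export
mean_value <- function(means, hybrid, treatment, trait) {
  stopifnot(inherits(means, "trait_means"))
  design <- attr(means, "design")
  treatment <- resolve_treatments(treatment, design)
  trait <- resolve_traits(trait, attr(means, "panel"))
  i <- means$hybrid == hybrid & means$treatment == treatment &
    means$trait == trait
  if (sum(i) != 1L)
    stop(sprintf("no cell (%s, %s, %s) in trait-mean table",
                 hybrid, treatment, trait), call. = FALSE)
  means$mean[i]
}

# frozen sum of the 264 reference cell means; guards the packaged fixture
# against value corruption
.SPAR_MEANS_CHECKSUM <- 1191268.57

#' The bundled six-hybrid maize SPAR trial trait means
#'
#' Loads the package's built-in reference dataset: per-cell trait means for
#' six maize hybrids (P-1498, P-1319, DKC-6581, DKC-6697, N61X-3110,
#' N59B-311A) grown under drought (D) and irrigated control (C) in a
#' soil-plant-atmosphere-research chamber trial, measured at 28 days after
#' sowing over the full 22-trait panel. These treatment-level means are the
#' worked-example input for the whole pipeline; replicate-level data were not
#' published, so the table carries means only (no standard errors).
#'
#' @return A \code{"trait_means"} table with 264 cells
#'   (6 hybrids x 2 treatments x 22 traits).
#' @examples
#' means <- spar_trial_means()
#' mean_value(means, "DKC-6581", "D", "Phot")  # 18.2
#' @export
spar_trial_means <- function() {
  path <- system.file("extdata", "spar_trial_means.csv",
                      package = "sparscreen", mustWork = TRUE)
  means <- read_trait_means(path)
  tot <- sum(means$mean)
  if (abs(tot - .SPAR_MEANS_CHECKSUM) > 1e-6)
    stop("bundled trait-mean fixture failed its integrity check (value sum ",
         format(tot, digits = 12), " != ",
         format(.SPAR_MEANS_CHECKSUM, digits = 12), ")", call. = FALSE)
  means
}

#' Read and write wide trait-mean CSV files
#'
#' Wide interchange format: one row per trait, one column per hybrid x
#' treatment cell named \code{<hybrid>_<treatment>}.
#'
#' @param path file path.
#' @param panel,design see [observation_table()].
#' @return [read_trait_means()] returns a \code{"trait_means"} table.
#' @export
read_trait_means <- function(path, panel = trait_panel(),
                             design = spar_design()) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(w)[1L] != "trait")
    stop("wide trait-mean CSV must have 'trait' as its first column",
         call. = FALSE)
  cells <- names(w)[-1L]
  parts <- regmatches(cells, regexpr("_[^_]+$", cells))
  hybs <- substr(cells, 1L, nchar(cells) - nchar(parts))
  trts <- substring(parts, 2L)
  long <- data.frame(
    hybrid = rep(hybs, each = nrow(w)),
    treatment = rep(trts, each = nrow(w)),
    trait = rep(w$trait, times = length(cells)),
    mean = as.numeric(unlist(w[-1L], use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  trait_mean_table(long, panel = panel, design = design)
}

#' @rdname read_trait_means
#' @param means a \code{"trait_means"} table.
#' @export
write_trait_means <- function(means, path) {
  stopifnot(inherits(means, "trait_means"))
  traits <- unique(means$trait)
  design <- attr(means, "design")
  wide <- data.frame(trait = traits, stringsAsFactors = FALSE)
  for (h in design$hybrids) for (tr in design$treatments) {
    col <- vapply(traits, function(tc) mean_value(means, h, tr, tc),
                  numeric(1L))
    wide[[paste0(h, "_", tr)]] <- unname(col)
  }
  utils::write.csv(wide, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
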