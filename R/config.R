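#' Analysis configuration for a Delphi consultation
#'
#' Bundles the scoring scale, dispersion conventions, display rounding and the
#' quality-gate thresholds used throughout the pipeline. Defaults follow common
#' Delphi practice for indicator-system construction: importance scored on an
#' integer 0--10 scale with 10 as the full score, sample (n-1) standard
#' deviations, a 70% response-rate gate, Cr >= 0.7 as acceptable authority and
#' Kendall's W gates at 0.4 ("coordination is fair") and 0.5 ("consultation can
#' close").
#'
#' @param scale_min,scale_max Integer bounds of the importance scale.
#' @param full_score Score counted as "full marks" for the full-score
#'   frequency Kj; defaults to `scale_max`.
#' @param sd_denominator `"n_minus_1"` for the sample standard deviation or
#'   `"n"` for the population form. Applies to both the per-indicator
#'   dispersion and the cross-indicator boundary computation.
#' @param boundary_grouping `"global"` computes screening boundaries across all
#'   active indicators jointly; `"per_tier"` computes them within each tier.
#' @param rounding Named list of display digits per statistic (half-up).
#' @param thresholds Named list of quality gates; see Details.
#' @param judgment_matrix 3 x 4 matrix of judgment-basis impact coefficients
#'   (rows: band `low`/`mid`/`high`; columns: the four bases). Defaults to the
#'   conventional self-assessment table (see [judgment_basis_matrix()]).
#' @param drop_incomplete Drop experts with missing scores before Kendall's W
#'   (the default); if `FALSE`, incomplete matrices raise an error.
#' @param permutation_test If `TRUE`, [kendall_w()] adds a permutation p-value
#'   (`n_perm` resamples) alongside the chi-square approximation.
#' @param n_perm Number of permutation resamples.
#'
#' @details `thresholds` understands: `response_rate_good` (percent, default
#'   70), `cr_acceptable` (default 0.7), `w_fair` (0.4), `w_complete` (0.5),
#'   and the authority band cutoffs `cr_band_lo` (0.5) / `cr_band_hi` (0.75).
#'
#' @return An object of class `panel_config`.
#' @seealso [read_panel_config()] to load the same fields from YAML.
#' @export
panel_config <- function(scale_min = 0L, scale_max = 10L,
                         full_score = scale_max,
                         sd_denominator = c("n_minus_1", "n"),
                         boundary_grouping = c("global", "per_tier"),
                         rounding = NULL,
                         thresholds = NULL,
                         judgment_matrix = judgment_basis_matrix(),
                         drop_incomplete = TRUE,
                         permutation_test = FALSE,
                         n_perm = 999L) {
  sd_denominator <- match.arg(sd_denominator)
  boundary_grouping <- match.arg(boundary_grouping)
  if (!is.numeric(scale_min) || !is.numeric(scale_max) || scale_min >= scale_max)
    stop("`scale_min` must be strictly less than `scale_max`", call. = FALSE)
  if (full_score < scale_min || full_score > scale_max)
    stop("`full_score` must lie within the score scale", call. = FALSE)
  def_round <- list(Mj = 2L, sd = 2L, Vj = 2L, Kj = 2L, Cs = 3L, Ca = 3L, Cr = 3L)
  def_thr <- list(response_rate_good = 70, cr_acceptable = 0.7,
                  w_fair = 0.4, w_complete = 0.5,
                  cr_band_lo = 0.5, cr_band_hi = 0.75)
  rounding <- utils::modifyList(def_round, as.list(rounding %||% list()))
  thresholds <- utils::modifyList(def_thr, as.list(thresholds %||% list()))
  validate_judgment_matrix(judgment_matrix)
  structure(list(
    scale_min = as.integer(scale_min), scale_max = as.integer(scale_max),
    full_score = as.integer(full_score),
    sd_denominator = sd_denominator,
    boundary_grouping = boundary_grouping,
    rounding = rounding, thresholds = thresholds,
    judgment_matrix = judgment_matrix,
    drop_incomplete = isTRUE(drop_incomplete),
    permutation_test = isTRUE(permutation_test),
    n_perm = as.integer(n_perm)
  ), class = "panel_config")
}

#' @export
print.panel_config <- function(x, ...) {
  cat("Delphi panel configuration\n")
  cat(sprintf("  importance scale: %d-%d (full score %d)\n",
              x$scale_min, x$scale_max, x$full_score))
  cat(sprintf("  sd denominator: %s; boundary grouping: %s\n",
              x$sd_denominator, x$boundary_grouping))
  cat(sprintf("  gates: response >= %g%%, Cr >= %g, W > %g / %g\n",
              x$thresholds$response_rate_good, x$thresholds$cr_acceptable,
              x$thresholds$w_fair, x$thresholds$w_complete))
  invisible(x)
}

#' Load a `panel_config` from a YAML file
#'
#' Reads the fields written by the analysis's `config.yaml` layout; missing
#' fields keep the [panel_config()] defaults.
#'
#' @param path Path to a YAML file.
#' @return A `panel_config` object.
#' @export
read_panel_config <- function(path) {
  y <- yaml::read_yaml(path)
  panel_config(
    scale_min = y$scale_min %||% 0L,
    scale_max = y$scale_max %||% 10L,
    full_score = y$full_score %||% (y$scale_max %||% 10L),
    sd_denominator = y$sd_denominator %||% "n_minus_1",
    boundary_grouping = y$boundary_grouping %||% "global",
    rounding = y$rounding,
    thresholds = y$thresholds
  )
}

#' Judgment-basis impact coefficients
#'
#' The conventional 3 x 4 table used to convert an expert's self-rated
#' judgment bases into a judgment coefficient Ca: rows are the self-rating
#' band (`low` = 0--1, `mid` = 2--3, `high` = 4--5), columns the four bases
#' (practical experience, theoretical analysis, understanding of peers,
#' insight). Ca for one expert is the sum of one entry per column, so the row
#' sums give the extremes: all-high sums to 1, all-mid to 0.8, all-low to 0.6.
#'
#' @return A numeric matrix with rownames `low`, `mid`, `high` and colnames
#'   `practical`, `theoretical`, `peers`, `insight`.
#' @export
judgment_basis_matrix <- function() {
  m <- rbind(low  = c(0.3, 0.1, 0.1, 0.1),
             mid  = c(0.4, 0.2, 0.1, 0.1),
             high = c(0.5, 0.3, 0.1, 0.1))
  colnames(m) <- c("practical", "theoretical", "peers", "insight")
  m
}

validate_judgment_matrix <- function(m) {
  if (!is.matrix(m) || !identical(dim(m), c(3L, 4L)))
    stop("judgment matrix must be 3 bands x 4 bases", call. = FALSE)
  if (!all(rownames(m) == c("low", "mid", "high")))
    stop("judgment matrix rows must be named low, mid, high", call. = FALSE)
  if (any(m < 0) || any(m > 1) || any(rowSums(m) <= 0) || any(rowSums(m) > 1))
    stop("judgment matrix entries must be in [0,1] with row sums in (0,1]",
         call. = FALSE)
  invisible(m)
}

#' Familiarity self-rating coefficients
#'
#' The six-point familiarity ladder mapped to its coefficient: very familiar =
#' 1, familiar = 0.8, relatively familiar = 0.6, generally familiar = 0.4, not
#' very familiar = 0.2, unfamiliar = 0.
#'
#' @return A named numeric vector, most to least familiar.
#' @export
familiarity_levels <- function() {
  c(very_familiar = 1, familiar = 0.8, relatively_familiar = 0.6,
    generally_familiar = 0.4, not_very_familiar = 0.2, unfamiliar = 0)
}

# Half-up decimal rounding (R's round() is round-half-even). Used for all
# display values so tables match conventional half-up formatting.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
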