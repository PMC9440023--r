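#' Mean importance score of an indicator
#'
#' The arithmetic mean of the importance scores given by the experts who
#' scored the indicator.
#'
#' @param scores Numeric scores (NAs, i.e. skipped experts, are dropped).
#' @return The mean, or an error if nobody scored the indicator.
#' @export
mean_importance <- function(scores) {
  scores <- scores[!is.na(scores)]
  if (!length(scores))
    stop("no scores: indicator has no respondents", call. = FALSE)
  mean(scores)
}

#' Full-score frequency Kj
#'
#' The fraction of respondents who awarded the maximum possible score. Kj is
#' a supplementary concentration measure: the larger it is, the more experts
#' consider the indicator maximally important.
#'
#' @param scores Numeric scores (NAs dropped).
#' @param full_score The score counted as full marks.
#' @return A proportion in \[0, 1\] (multiply by 100 for the percent form).
#' @examples
#' full_score_frequency(c(rep(10, 5), rep(9, 8)), 10)  # 5/13
#' @export
full_score_frequency <- function(scores, full_score) {
  scores <- scores[!is.na(scores)]
  if (!length(scores))
    stop("no scores: indicator has no respondents", call. = FALSE)
  sum(scores == full_score) / length(scores)
}

#' Coefficient of variation Vj
#'
#' Dispersion relative to the mean, `sd / mean`; the smaller Vj, the higher
#' the convergence of opinions on the indicator.
#'
#' @param Mj Mean importance (> 0).
#' @param sd Standard deviation (>= 0).
#' @return `sd / Mj`. A zero mean (possible when the scale starts at 0) is an
#'   error: the ratio is undefined there.
#' @export
coefficient_of_variation <- function(Mj, sd) {
  stopifnot(is.numeric(Mj), is.numeric(sd))
  if (any(sd < 0)) stop("standard deviation must be >= 0", call. = FALSE)
  if (any(Mj <= 0))
    stop("coefficient of variation undefined for mean <= 0", call. = FALSE)
  sd / Mj
}

# standard deviation under the configured denominator
sd_scores <- function(scores, denominator = c("n_minus_1", "n")) {
  denominator <- match.arg(denominator)
  scores <- scores[!is.na(scores)]
  n <- length(scores)
  if (n < 2) return(0)
  s <- stats::sd(scores)
  if (denominator == "n") s * sqrt((n - 1) / n) else s
}

#' Per-indicator consensus statistics table
#'
#' Computes, for every scored indicator, the concentration statistics (mean
#' Mj, standard deviation, coefficient of variation Vj, full-score frequency
#' Kj) and the authority coefficients (Cs, Ca, Cr), one row per indicator --
#' the layout of a Delphi round's published indicator table.
#'
#' @param responses A [response_set()].
#' @param config A [panel_config()]; sets the full score and the sd
#'   denominator.
#' @param hierarchy Optional [indicator_hierarchy()]. When given, only active
#'   indicators are tabulated, rows are ordered by hierarchy position, and a
#'   `tier` column is attached.
#' @return Data frame with columns `indicator_id`, `m`, `Mj`, `sd`, `Vj`,
#'   `Kj` (proportion), `Cs`, `Ca`, `Cr` (and `tier` when a hierarchy is
#'   given). Values are unrounded; see [write_stats_table()] for display
#'   rounding.
#' @export
stats_table <- function(responses, config = panel_config(), hierarchy = NULL) {
  stopifnot(inherits(responses, "response_set"))
  d <- responses$data[!is.na(responses$data$score), , drop = FALSE]
  if (!is.null(hierarchy)) {
    act <- active_nodes(hierarchy)$id
    d <- d[d$indicator_id %in% act, , drop = FALSE]
  }
  if (!nrow(d))
    stop("no scored indicators in the response set", call. = FALSE)
  ids <- sort(unique(d$indicator_id))
  g <- factor(d$indicator_id, levels = ids)
  mj <- as.numeric(tapply(d$score, g, mean))
  sdj <- as.numeric(tapply(d$score, g, sd_scores,
                           denominator = config$sd_denominator))
  kj <- as.numeric(tapply(d$score, g,
                          function(s) mean(s == config$full_score)))
  out <- data.frame(
    indicator_id = ids,
    m = as.integer(tabulate(g, nbins = length(ids))),
    Mj = mj, sd = sdj,
    Vj = ifelse(mj > 0, sdj / mj, NA_real_),
    Kj = kj, stringsAsFactors = FALSE
  )
  if (any(mj <= 0))
    warning("coefficient of variation undefined (mean <= 0) for: ",
            paste(ids[mj <= 0], collapse = ", "), call. = FALSE)
  auth <- authority_per_indicator(responses, config$judgment_matrix)
  out <- merge(out, auth[c("indicator_id", "Cs", "Ca", "Cr")],
               by = "indicator_id", sort = FALSE)
  if (!is.null(hierarchy)) {
    out <- out[hierarchy_order(hierarchy, out$indicator_id), , drop = FALSE]
    out$tier <- hierarchy$nodes$tier[match(out$indicator_id,
                                           hierarchy$nodes$id)]
  }
  rownames(out) <- NULL
  out
}

#' Write a statistics table to CSV with display rounding
#'
#' Writes one row per indicator with columns `indicator,Mj,sd,Vj,Kj,Cs,Ca,Cr`,
#' Kj as a percent, all values rounded half-up to the digits configured in
#' `config$rounding`.
#'
#' @param stats A [stats_table()] result (columns beyond the written set are
#'   ignored).
#' @param path Output CSV path.
#' @param config A [panel_config()] supplying the rounding digits.
#' @return The path, invisibly.
#' @export
write_stats_table <- function(stats, path, config = panel_config()) {
  r <- config$rounding
  out <- data.frame(
    indicator = stats$indicator_id,
    Mj = round_half_up(stats$Mj, r$Mj),
    sd = round_half_up(stats$sd, r$sd),
    Vj = round_half_up(stats$Vj, r$Vj),
    Kj = round_half_up(100 * stats$Kj, r$Kj),
    Cs = round_half_up(stats$Cs, r$Cs),
    Ca = round_half_up(stats$Ca, r$Ca),
    Cr = round_half_up(stats$Cr, r$Cr),
    stringsAsFactors = FALSE
  )
  if (!nrow(stats))
    out <- out[0, , drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a written statistics table back
#'
#' @param path CSV path produced by [write_stats_table()].
#' @return Data frame with `indicator`, `Mj`, `sd`, `Vj`, `Kj` (percent),
#'   `Cs`, `Ca`, `Cr`.
#' @export
read_stats_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
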