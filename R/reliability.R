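#' Expert engagement: questionnaire recovery rate
#'
#' The positive coefficient of a Delphi round is the percentage of distributed
#' questionnaires that came back; a rate of 70% or more is conventionally read
#' as good engagement.
#'
#' @param distributed Questionnaires sent (>= 1).
#' @param returned Questionnaires recovered (0 <= returned <= distributed).
#' @param threshold Percent threshold for the quality flag (default 70).
#' @return A list with `rate` (percent), `good` (logical flag), `distributed`
#'   and `returned`.
#' @examples
#' response_rate(15, 13)$rate  # 86.67 at 2 dp
#' @export
response_rate <- function(distributed, returned, threshold = 70) {
  if (!is.numeric(distributed) || distributed < 1)
    stop("`distributed` must be a positive count", call. = FALSE)
  if (returned < 0 || returned > distributed)
    stop("`returned` must be between 0 and `distributed`", call. = FALSE)
  rate <- 100 * returned / distributed
  list(rate = rate, good = rate >= threshold,
       distributed = as.integer(distributed), returned = as.integer(returned))
}

#' Familiarity coefficient Cs for one rating level
#'
#' Maps the six-point familiarity self-rating to its coefficient (see
#' [familiarity_levels()]). Vectorised.
#'
#' @param level Character vector of level names.
#' @return Numeric coefficients in \[0, 1\].
#' @export
familiarity_coefficient <- function(level) {
  map <- familiarity_levels()
  bad <- setdiff(unique(level), names(map))
  if (length(bad))
    stop("unknown familiarity level: ", paste(bad, collapse = ", "),
         call. = FALSE)
  unname(map[level])
}

#' Judgment coefficient Ca for one expert and indicator
#'
#' Sums, over the four judgment bases, the impact coefficient selected by the
#' expert's self-rated band on that basis. With the default matrix an expert
#' rating every basis `high` gets Ca = 1, every basis `mid` 0.8, every basis
#' `low` 0.6. Vectorised over parallel band vectors.
#'
#' @param practical,theoretical,peers,insight Band names (`low`, `mid`,
#'   `high`), one per basis.
#' @param matrix The 3 x 4 impact-coefficient matrix
#'   (default [judgment_basis_matrix()]).
#' @return Numeric Ca values in \[0, 1\].
#' @export
judgment_coefficient <- function(practical, theoretical, peers, insight,
                                 matrix = judgment_basis_matrix()) {
  validate_judgment_matrix(matrix)
  bands <- list(practical, theoretical, peers, insight)
  bad <- setdiff(unique(unlist(bands)), rownames(matrix))
  if (length(bad))
    stop("unknown judgment band: ", paste(bad, collapse = ", "),
         call. = FALSE)
  out <- 0
  for (k in seq_len(4))
    out <- out + matrix[cbind(bands[[k]], colnames(matrix)[k])]
  unname(out)
}

#' Per-indicator authority coefficients
#'
#' For each scored indicator, Cs is the mean familiarity coefficient over its
#' respondents, Ca the mean judgment coefficient, and the authority
#' coefficient Cr = (Ca + Cs) / 2. Indicators with no respondents are excluded
#' with a warning.
#'
#' @param responses A [response_set()].
#' @param matrix Judgment-basis impact matrix.
#' @return Data frame with columns `indicator_id`, `m` (respondents), `Cs`,
#'   `Ca`, `Cr`, one row per indicator with at least one respondent.
#' @export
authority_per_indicator <- function(responses,
                                    matrix = judgment_basis_matrix()) {
  stopifnot(inherits(responses, "response_set"))
  d <- responses$data[!is.na(responses$data$score), , drop = FALSE]
  empty <- setdiff(unique(responses$data$indicator_id), unique(d$indicator_id))
  if (length(empty))
    warning("indicator(s) with no respondents excluded: ",
            paste(empty, collapse = ", "), call. = FALSE)
  cs_i <- familiarity_coefficient(d$familiarity)
  ca_i <- judgment_coefficient(d$jb_practical, d$jb_theoretical,
                               d$jb_peers, d$jb_insight, matrix)
  ids <- sort(unique(d$indicator_id))
  g <- factor(d$indicator_id, levels = ids)
  out <- data.frame(
    indicator_id = ids,
    m = as.integer(tabulate(g, nbins = length(ids))),
    Cs = as.numeric(tapply(cs_i, g, mean)),
    Ca = as.numeric(tapply(ca_i, g, mean)),
    stringsAsFactors = FALSE
  )
  out$Cr <- (out$Ca + out$Cs) / 2
  rownames(out) <- NULL
  out
}

#' Count indicators by authority band
#'
#' Partitions per-indicator authority coefficients into strictly-above-high,
#' between (inclusive), and strictly-below-low bands.
#'
#' @param cr Numeric vector of per-indicator Cr values (or a data frame with a
#'   `Cr` column).
#' @param cutoffs Length-2 numeric `c(lo, hi)`, default `c(0.5, 0.75)`.
#' @return Named integer vector `c(above=, between=, below=)`; the three
#'   counts always sum to `length(cr)`.
#' @export
authority_band_counts <- function(cr, cutoffs = c(0.5, 0.75)) {
  if (is.data.frame(cr)) cr <- cr$Cr
  stopifnot(is.numeric(cr), length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  c(above = sum(cr > cutoffs[2]),
    between = sum(cr >= cutoffs[1] & cr <= cutoffs[2]),
    below = sum(cr < cutoffs[1]))
}
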