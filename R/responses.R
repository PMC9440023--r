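#' A round of expert questionnaire responses
#'
#' Holds the long-format response table for one consultation round: one row
#' per (expert, indicator) with the importance score, the familiarity
#' self-rating level and the four judgment-basis bands. A missing score means
#' the expert skipped that indicator; per-indicator respondent counts are
#' computed from non-missing scores.
#'
#' @param data Data frame with columns `expert_id`, `indicator_id`, `score`,
#'   `familiarity` (one of [familiarity_levels()] names), and the four band
#'   columns `jb_practical`, `jb_theoretical`, `jb_peers`, `jb_insight`
#'   (`low`, `mid` or `high`).
#' @param round Round number (integer >= 1).
#' @param distributed Number of questionnaires sent out; defaults to the
#'   number of distinct responding experts.
#' @param config A [panel_config()] providing the score scale.
#' @param hierarchy Optional [indicator_hierarchy()]; if given, indicator ids
#'   must be active nodes of it.
#' @return An object of class `response_set`.
#' @export
response_set <- function(data, round = 1L, distributed = NULL,
                         config = panel_config(), hierarchy = NULL) {
  stopifnot(is.data.frame(data))
  need <- c("expert_id", "indicator_id", "score", "familiarity",
            "jb_practical", "jb_theoretical", "jb_peers", "jb_insight")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("response table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  data$expert_id <- as.character(data$expert_id)
  data$indicator_id <- as.character(data$indicator_id)
  data$score <- suppressWarnings(as.numeric(data$score))

  dup <- duplicated(data[c("expert_id", "indicator_id")])
  if (any(dup)) {
    d1 <- data[which(dup)[1], ]
    stop(sprintf("duplicate response: expert '%s', indicator '%s'",
                 d1$expert_id, d1$indicator_id), call. = FALSE)
  }
  sc <- data$score
  bad <- which(!is.na(sc) &
                 (sc < config$scale_min | sc > config$scale_max | sc != round(sc)))
  if (length(bad)) {
    b <- data[bad[1], ]
    stop(sprintf(
      "score out of scale: expert '%s', indicator '%s', value %s (scale %d-%d)",
      b$expert_id, b$indicator_id, format(b$score),
      config$scale_min, config$scale_max), call. = FALSE)
  }
  bad_fam <- setdiff(unique(data$familiarity), names(familiarity_levels()))
  if (length(bad_fam))
    stop("unknown familiarity level: ", paste(bad_fam, collapse = ", "),
         call. = FALSE)
  for (col in c("jb_practical", "jb_theoretical", "jb_peers", "jb_insight")) {
    bad_b <- setdiff(unique(data[[col]]), c("low", "mid", "high"))
    if (length(bad_b))
      stop(sprintf("unknown %s band: %s", col, paste(bad_b, collapse = ", ")),
           call. = FALSE)
  }
  if (!is.null(hierarchy)) {
    act <- active_nodes(hierarchy)$id
    unk <- which(!(data$indicator_id %in% act))
    if (length(unk)) {
      u <- data[unk[1], ]
      stop(sprintf(
        "unknown or inactive indicator '%s' (expert '%s', row %d)",
        u$indicator_id, u$expert_id, unk[1]), call. = FALSE)
    }
  }
  returned <- length(unique(data$expert_id))
  distributed <- as.integer(distributed %||% returned)
  if (returned > distributed)
    stop("more responding experts than questionnaires distributed",
         call. = FALSE)
  structure(list(round = as.integer(round), distributed = distributed,
                 returned = returned, data = data),
            class = "response_set")
}

#' Read a round of responses from CSV
#'
#' The long format mirrors the questionnaire: columns `round`, `expert_id`,
#' `indicator_id`, `score`, `familiarity`, `jb_practical`, `jb_theoretical`,
#' `jb_peers`, `jb_insight`. Empty scores are allowed (expert skipped the
#' indicator). Validation errors name the offending expert, indicator and
#' value.
#'
#' @param path CSV file path.
#' @param config A [panel_config()].
#' @param hierarchy Optional hierarchy to validate indicator ids against.
#' @param distributed Questionnaires distributed; defaults to the number of
#'   distinct experts in the file.
#' @param round Round number; defaults to the file's `round` column if
#'   present, else 1.
#' @return A `response_set`.
#' @export
read_responses <- function(path, config = panel_config(), hierarchy = NULL,
                           distributed = NULL, round = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(round)) round <- if ("round" %in% names(d)) d$round[1] else 1L
  d$round <- NULL
  response_set(d, round = round, distributed = distributed,
               config = config, hierarchy = hierarchy)
}

#' Write a round of responses to CSV
#'
#' @param responses A `response_set`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_responses <- function(responses, path) {
  stopifnot(inherits(responses, "response_set"))
  d <- cbind(round = responses$round, responses$data)
  utils::write.csv(d, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @export
print.response_set <- function(x, ...) {
  cat(sprintf(
    "Delphi responses, round %d: %d/%d questionnaires returned, %d indicators scored\n",
    x$round, x$returned, x$distributed,
    length(unique(x$data$indicator_id[!is.na(x$data$score)]))))
  invisible(x)
}

#' Expert-by-indicator score matrix
#'
#' Pivots a long-format response set into the matrix Kendall's W works on:
#' experts in rows, indicators in columns, `NA` where an expert skipped an
#' indicator.
#'
#' @param responses A [response_set()].
#' @param indicator_ids Optional column subset/order; defaults to all scored
#'   indicators in lexicographic order.
#' @return A numeric matrix with expert ids as rownames.
#' @export
score_matrix <- function(responses, indicator_ids = NULL) {
  d <- responses$data
  experts <- sort(unique(d$expert_id))
  inds <- indicator_ids %||% sort(unique(d$indicator_id))
  m <- matrix(NA_real_, length(experts), length(inds),
              dimnames = list(experts, inds))
  keep <- d$indicator_id %in% inds
  m[cbind(match(d$expert_id[keep], experts),
          match(d$indicator_id[keep], inds))] <- d$score[keep]
  m
}
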