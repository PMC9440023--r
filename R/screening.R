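#' Boundary values for indicator screening
#'
#' Computes the retention thresholds from the cross-indicator distribution of
#' the three concentration statistics: for the mean importance Mj and the
#' full-score frequency Kj the boundary is `mean - sd` and indicators are kept
#' strictly above it; for the coefficient of variation Vj the boundary is
#' `mean + sd` and indicators are kept strictly below it. Means and sds are
#' taken across the indicators of the grouping (global by default, per tier
#' optionally), with the sd denominator from the configuration.
#'
#' @param stats A [stats_table()] result.
#' @param config A [panel_config()]; `boundary_grouping` selects global or
#'   per-tier boundaries (per-tier needs a `tier` column on `stats`).
#' @return Data frame of class `boundary_values` with columns `criterion`
#'   (`Mj`, `Kj`, `Vj`), `group`, `center`, `spread`, `boundary`, `direction`
#'   (`retain_above` / `retain_below`). Groups with fewer than 2 indicators
#'   get `NA` boundaries with a warning (screening is skipped there).
#' @export
boundary_values <- function(stats, config = panel_config()) {
  stopifnot(is.data.frame(stats))
  per_tier <- config$boundary_grouping == "per_tier"
  if (per_tier && is.null(stats$tier))
    stop("per-tier boundaries need a `tier` column on the stats table",
         call. = FALSE)
  groups <- if (per_tier) split(stats, stats$tier) else list(global = stats)
  rows <- lapply(names(groups), function(gname) {
    g <- groups[[gname]]
    if (nrow(g) < 2) {
      warning(sprintf(
        "boundary group '%s' has fewer than 2 indicators; screening skipped",
        gname), call. = FALSE)
      center <- spread <- rep(NA_real_, 3)
    } else {
      center <- c(mean(g$Mj), mean(g$Kj), mean(g$Vj))
      spread <- vapply(list(g$Mj, g$Kj, g$Vj), sd_scores,
                       numeric(1), denominator = config$sd_denominator)
    }
    data.frame(criterion = c("Mj", "Kj", "Vj"), group = gname,
               center = center, spread = spread,
               boundary = center + c(-1, -1, 1) * spread,
               direction = c("retain_above", "retain_above", "retain_below"),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows),
            class = c("boundary_values", "data.frame"))
}

#' Screen indicators against boundary values
#'
#' Applies the three boundary criteria with strict comparisons: an indicator
#' fails Mj (or Kj) when its value is less than or equal to the boundary, and
#' fails Vj when its value is greater than or equal to the boundary.
#' Disposition follows the count of failed criteria: none failed = retain,
#' one or two = review (expert discussion), all three = delete.
#'
#' @param stats A [stats_table()] result.
#' @param boundaries A [boundary_values()] result (or `NULL` to compute
#'   global boundaries from `stats` with `config`).
#' @param config A [panel_config()] (used only when `boundaries` is `NULL`).
#' @return Data frame of class `screening_decisions`: `indicator_id`,
#'   `Mj_fail`, `Kj_fail`, `Vj_fail`, `n_failed`, `disposition` (`retain` /
#'   `review` / `delete`), `final_action` (`NA` until [apply_review()]).
#'   Indicators in a degenerate boundary group get `NA` failures and
#'   disposition `review`.
#' @export
screen_indicators <- function(stats, boundaries = NULL,
                              config = panel_config()) {
  if (is.null(boundaries)) boundaries <- boundary_values(stats, config)
  per_tier <- !all(boundaries$group == "global")
  key <- if (per_tier) as.character(stats$tier) else rep("global", nrow(stats))
  bnd <- function(crit, grp) {
    b <- boundaries$boundary[boundaries$criterion == crit &
                               boundaries$group == grp]
    if (length(b) != 1) NA_real_ else b
  }
  mj_b <- vapply(key, bnd, numeric(1), crit = "Mj")
  kj_b <- vapply(key, bnd, numeric(1), crit = "Kj")
  vj_b <- vapply(key, bnd, numeric(1), crit = "Vj")
  out <- data.frame(
    indicator_id = stats$indicator_id,
    Mj_fail = stats$Mj <= mj_b,
    Kj_fail = stats$Kj <= kj_b,
    Vj_fail = stats$Vj >= vj_b,
    stringsAsFactors = FALSE
  )
  out$n_failed <- rowSums(out[c("Mj_fail", "Kj_fail", "Vj_fail")])
  out$disposition <- ifelse(is.na(out$n_failed), "review",
                            ifelse(out$n_failed == 0, "retain",
                                   ifelse(out$n_failed == 3, "delete",
                                          "review")))
  out$final_action <- NA_character_
  rownames(out) <- NULL
  structure(out, class = c("screening_decisions", "data.frame"))
}

#' Read a structured edit log from CSV
#'
#' Columns: `round`, `action` (`delete`, `add`, `rename`, `move`, `keep`),
#' `indicator_id`, `label`, `tier`, `parent_id`, `note`.
#'
#' @param path CSV file path.
#' @return Data frame of edits.
#' @export
read_edits <- function(path) {
  e <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("round", "action", "indicator_id")
  miss <- setdiff(need, names(e))
  if (length(miss))
    stop("edit log is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(e$action), c("delete", "add", "rename", "move", "keep"))
  if (length(bad))
    stop("unknown edit action: ", paste(bad, collapse = ", "), call. = FALSE)
  e
}

#' Resolve screening dispositions with the expert edit log
#'
#' The statistical screen only proposes: deletions are automatic only for
#' indicators failing all three criteria, while review items (one or two
#' failures) need an explicit expert decision. This step folds the edit log
#' into the decisions: a `delete` edit finalises deletion, `rename`/`move`
#' finalise as modified, `keep` as kept. Expert edits may also override a
#' retained or review disposition in either direction; such rows are flagged
#' `expert-override` in the audit column, since panels can and do delete
#' statistically acceptable indicators on substantive grounds.
#'
#' @param decisions A [screen_indicators()] result.
#' @param edits An edit-log data frame ([read_edits()]); `add` rows are
#'   ignored here (they act on the hierarchy, not on existing indicators).
#' @param unresolved What to do with review items without an edit entry:
#'   `"error"` (default, lists them) or `"keep"` (panel reviewed and kept by
#'   default -- the convention when the log only records changes).
#' @param hierarchy Optional [indicator_hierarchy()]. Edits that reference a
#'   hierarchy node that was never scored (e.g. a secondary grouping) are
#'   structural and skipped here; without a hierarchy, any edit id absent
#'   from the decisions is an error.
#' @return The decisions with `final_action` filled (`kept` / `deleted` /
#'   `modified`) and an `audit` column.
#' @export
apply_review <- function(decisions, edits,
                         unresolved = c("error", "keep"),
                         hierarchy = NULL) {
  unresolved <- match.arg(unresolved)
  stopifnot(inherits(decisions, "screening_decisions"))
  ed <- edits[edits$action != "add", , drop = FALSE]
  unknown <- setdiff(ed$indicator_id, decisions$indicator_id)
  if (!is.null(hierarchy))
    unknown <- setdiff(unknown, hierarchy$nodes$id)
  if (length(unknown))
    stop("edit log references unknown indicator(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  ed <- ed[ed$indicator_id %in% decisions$indicator_id, , drop = FALSE]
  act_map <- c(delete = "deleted", rename = "modified", move = "modified",
               keep = "kept")
  d <- decisions
  d$audit <- ""
  d$final_action <- ifelse(d$disposition == "delete", "deleted",
                           ifelse(d$disposition == "retain", "kept",
                                  NA_character_))
  for (i in seq_len(nrow(ed))) {
    j <- which(d$indicator_id == ed$indicator_id[i])
    new <- unname(act_map[ed$action[i]])
    if (d$disposition[j] != "review" &&
        !identical(d$final_action[j], new))
      d$audit[j] <- "expert-override"
    d$final_action[j] <- new
  }
  open <- d$indicator_id[is.na(d$final_action)]
  if (length(open)) {
    if (unresolved == "error")
      stop("unresolved review item(s): ", paste(open, collapse = ", "),
           call. = FALSE)
    d$final_action[is.na(d$final_action)] <- "kept"
  }
  d
}

#' Write screening decisions to CSV
#'
#' @param decisions A [screen_indicators()] (optionally [apply_review()]ed)
#'   result.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_screening <- function(decisions, path) {
  utils::write.csv(as.data.frame(decisions), path, row.names = FALSE, na = "")
  invisible(path)
}
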