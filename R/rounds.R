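#' Run one Delphi consultation round
#'
#' Executes the full per-round pipeline in order: engagement (response rate),
#' authority (Cs, Ca, Cr), concentration (Mj, sd, Vj, Kj), coordination
#' (Kendall's W with chi-square test) and boundary-value screening. This is
#' the package's central entry point; the returned object carries every
#' intermediate table plus a round summary and has `print`, `summary` and
#' `plot` methods.
#'
#' @param responses A [response_set()] for the round.
#' @param hierarchy Optional [indicator_hierarchy()]; restricts statistics to
#'   active indicators, orders outputs by hierarchy position and enables
#'   tier counts and per-tier boundaries.
#' @param config A [panel_config()].
#' @param edits Optional edit log ([read_edits()]) recording the panel's
#'   review of this round; when given, [apply_review()] resolves the
#'   dispositions (unresolved review items are kept, since the log records
#'   changes only).
#' @return An object of class `delphi_round` with components `round`,
#'   `engagement`, `stats`, `boundaries`, `decisions`, `concordance`,
#'   `summary`, `config`, `hierarchy`.
#' @examples
#' panel <- generate_panel(panel_sim_config(seed = 42))
#' r1 <- delphi_round(panel$rounds[[1]], panel$hierarchy)
#' r1
#' @export
delphi_round <- function(responses, hierarchy = NULL,
                         config = panel_config(), edits = NULL) {
  stopifnot(inherits(responses, "response_set"))
  if (!nrow(responses$data) || all(is.na(responses$data$score)))
    stop("empty response set: no scores to analyse", call. = FALSE)
  engagement <- response_rate(responses$distributed, responses$returned,
                              config$thresholds$response_rate_good)
  stats <- stats_table(responses, config, hierarchy)
  concord <- coordination_report(responses, config, hierarchy)
  bounds <- boundary_values(stats, config)
  decisions <- screen_indicators(stats, bounds, config)
  if (!is.null(edits))
    decisions <- apply_review(decisions, edits, unresolved = "keep",
                              hierarchy = hierarchy)
  bands <- authority_band_counts(
    stats$Cr, c(config$thresholds$cr_band_lo, config$thresholds$cr_band_hi))
  summary <- list(
    round = responses$round,
    distributed = engagement$distributed,
    returned = engagement$returned,
    response_rate = engagement$rate,
    response_good = engagement$good,
    panel_cr = mean(stats$Cr),
    authority_bands = as.list(bands),
    concordance = list(W = concord$W, chi2 = concord$chi2, df = concord$df,
                       p_value = concord$p_value, flags = concord$flags),
    tier_counts = if (!is.null(hierarchy)) as.list(tier_counts(hierarchy)),
    decision_counts = as.list(table(factor(
      decisions$disposition, levels = c("retain", "review", "delete"))))
  )
  structure(list(round = responses$round, engagement = engagement,
                 stats = stats, boundaries = bounds, decisions = decisions,
                 concordance = concord, summary = summary,
                 config = config, hierarchy = hierarchy),
            class = "delphi_round")
}

#' @export
print.delphi_round <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Delphi round %d: %d/%d returned (%.2f%%%s)\n",
              s$round, s$returned, s$distributed, s$response_rate,
              if (s$response_good) ", good" else ""))
  cat(sprintf("  %d indicators; panel Cr %.3f; bands >%.2f/mid/<%.2f = %d/%d/%d\n",
              nrow(x$stats), s$panel_cr,
              x$config$thresholds$cr_band_hi, x$config$thresholds$cr_band_lo,
              s$authority_bands$above, s$authority_bands$between,
              s$authority_bands$below))
  cat(sprintf("  Kendall's W %.3f (chi2 %.1f, df %d, p %s)\n",
              s$concordance$W, s$concordance$chi2, s$concordance$df,
              if (s$concordance$p_value < 0.001) "< 0.001"
              else sprintf("= %.3f", s$concordance$p_value)))
  dc <- s$decision_counts
  cat(sprintf("  screening: %d retain, %d review, %d delete\n",
              dc$retain, dc$review, dc$delete))
  invisible(x)
}

#' @export
summary.delphi_round <- function(object, ...) {
  print(object)
  cat("\nBoundary values:\n")
  print(as.data.frame(object$boundaries), row.names = FALSE)
  inv <- object$decisions[object$decisions$disposition != "retain", ]
  if (nrow(inv)) {
    cat("\nIndicators flagged by the screen:\n")
    print(inv[c("indicator_id", "Mj_fail", "Kj_fail", "Vj_fail",
                "disposition")], row.names = FALSE)
  }
  invisible(object)
}

#' Plot a round's concentration statistics against its boundaries
#'
#' Scatter of Vj against Mj for every indicator, with the global boundary
#' lines; indicators outside the retained region sit left of the Mj line or
#' above the Vj line.
#'
#' @param x A `delphi_round`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.delphi_round <- function(x, ...) {
  s <- x$stats
  fail <- x$decisions$disposition != "retain"
  graphics::plot(s$Mj, s$Vj, pch = ifelse(fail, 17, 16),
                 col = ifelse(fail, "firebrick", "grey30"),
                 xlab = "mean importance Mj",
                 ylab = "coefficient of variation Vj",
                 main = sprintf("Round %d boundary screen", x$round), ...)
  b <- x$boundaries
  gb <- b[b$group == b$group[1], ]
  graphics::abline(v = gb$boundary[gb$criterion == "Mj"], lty = 2)
  graphics::abline(h = gb$boundary[gb$criterion == "Vj"], lty = 2)
  invisible(x)
}

#' Advance the hierarchy to the next round
#'
#' Applies a structured edit log to the hierarchy: `delete` marks nodes
#' deleted (a parent may only be deleted when none of its children stay
#' active), `add` inserts a node with `origin_round` stamped to the new
#' round, `rename` rewrites the label (status `renamed`), `move` re-parents a
#' node, `keep` is a no-op recorded for audit. Replaying the same log on the
#' same hierarchy reproduces the result exactly.
#'
#' @param hierarchy An [indicator_hierarchy()].
#' @param edits Edit-log data frame ([read_edits()]); needs `action`,
#'   `indicator_id` and, for `add`, `label`, `tier`, `parent_id`.
#' @param decisions Optional reviewed [screen_indicators()] decisions; any
#'   unresolved review item (no `final_action`) is an error.
#' @return A new `indicator_hierarchy` with `round` incremented and status
#'   bookkeeping preserved for audit.
#' @export
advance_hierarchy <- function(hierarchy, edits, decisions = NULL) {
  stopifnot(inherits(hierarchy, "indicator_hierarchy"))
  if (!is.null(decisions)) {
    open <- decisions$indicator_id[is.na(decisions$final_action)]
    if (length(open))
      stop("unresolved review item(s): ", paste(open, collapse = ", "),
           call. = FALSE)
  }
  nodes <- hierarchy$nodes
  new_round <- hierarchy$round + 1L
  # previous-round bookkeeping statuses revert to plain active
  nodes$status[nodes$status %in% c("added", "renamed")] <- "active"
  for (i in seq_len(nrow(edits))) {
    e <- edits[i, ]
    if (e$action == "add") {
      if (e$indicator_id %in% nodes$id)
        stop("cannot add '", e$indicator_id, "': id already exists",
             call. = FALSE)
      nodes <- rbind(nodes, data.frame(
        id = e$indicator_id, label = e$label, tier = as.integer(e$tier),
        parent_id = e$parent_id, status = "added",
        origin_round = new_round, stringsAsFactors = FALSE))
      next
    }
    j <- match(e$indicator_id, nodes$id)
    if (is.na(j))
      stop("edit references unknown indicator '", e$indicator_id, "'",
           call. = FALSE)
    if (e$action == "delete") nodes$status[j] <- "deleted"
    else if (e$action == "rename") {
      nodes$label[j] <- e$label
      nodes$status[j] <- "renamed"
    } else if (e$action == "move") nodes$parent_id[j] <- e$parent_id
  }
  kept <- nodes$status != "deleted"
  par <- nodes$parent_id[kept]
  bad_par <- !is.na(par) & !(par %in% nodes$id[kept])
  if (any(bad_par))
    stop("active node(s) left under a deleted parent: ",
         paste(nodes$id[kept][bad_par], collapse = ", "), call. = FALSE)
  indicator_hierarchy(nodes, round = new_round)
}

#' Consolidated report over completed rounds
#'
#' Collects the per-round summaries and the final hierarchy's tier counts
#' into one report; optionally writes `summary.json` plus the per-round
#' `stats_roundN.csv` and `screening_roundN.csv` files, fixed ordering and
#' rounding throughout so reruns are byte-identical.
#'
#' @param rounds List of `delphi_round` objects (>= 1), in order.
#' @param final_hierarchy Optional hierarchy after the last round's edits.
#' @param dir Optional output directory (created if needed).
#' @return A list of class `delphi_report` with `rounds` (summaries) and
#'   `final_tier_counts`; invisibly when writing.
#' @export
final_report <- function(rounds, final_hierarchy = NULL, dir = NULL) {
  stopifnot(length(rounds) >= 1,
            all(vapply(rounds, inherits, logical(1), "delphi_round")))
  rep <- structure(list(
    rounds = lapply(rounds, `[[`, "summary"),
    final_tier_counts = if (!is.null(final_hierarchy))
      as.list(tier_counts(final_hierarchy))
  ), class = "delphi_report")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(rep), file.path(dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    for (r in rounds) {
      write_stats_table(r$stats,
                        file.path(dir, sprintf("stats_round%d.csv", r$round)),
                        r$config)
      write_screening(r$decisions,
                      file.path(dir, sprintf("screening_round%d.csv", r$round)))
    }
    return(invisible(rep))
  }
  rep
}

#' @export
print.delphi_report <- function(x, ...) {
  cat(sprintf("Delphi consultation report: %d round(s)\n", length(x$rounds)))
  for (s in x$rounds) {
    cat(sprintf(
      "  round %d: response %.2f%%, W %.3f (%s), retain/review/delete %d/%d/%d\n",
      s$round, s$response_rate, s$concordance$W,
      if (s$concordance$flags$complete) "can close" else "continue",
      s$decision_counts$retain, s$decision_counts$review,
      s$decision_counts$delete))
  }
  if (!is.null(x$final_tier_counts))
    cat(sprintf("  final index system: %d primary / %d secondary / %d tertiary\n",
                x$final_tier_counts$primary, x$final_tier_counts$secondary,
                x$final_tier_counts$tertiary))
  invisible(x)
}
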