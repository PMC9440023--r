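#' Three-tier indicator hierarchy
#'
#' Constructs and validates the indicator hierarchy used in indicator-system
#' Delphi studies: tier 1 (primary) groups tier 2 (secondary) groups tier 3
#' (tertiary). A tertiary node may attach directly to a primary node when no
#' secondary grouping exists (e.g. the burn-site items).
#'
#' @param nodes A data frame with columns `id`, `label`, `tier` (1, 2 or 3),
#'   `parent_id` (empty/`NA` only for tier 1), and optionally `status`
#'   (`active`, `deleted`, `added`, `renamed`; default `active`) and
#'   `origin_round` (default 0).
#' @param round Consultation round this hierarchy feeds (integer >= 0).
#' @return An object of class `indicator_hierarchy`: the validated node table
#'   plus the round number.
#' @examples
#' h <- indicator_hierarchy(data.frame(
#'   id = c("a", "a1"), label = c("A", "A1"), tier = c(1, 3),
#'   parent_id = c(NA, "a")))
#' tier_counts(h)
#' @export
indicator_hierarchy <- function(nodes, round = 0L) {
  stopifnot(is.data.frame(nodes))
  need <- c("id", "label", "tier", "parent_id")
  miss <- setdiff(need, names(nodes))
  if (length(miss))
    stop("hierarchy is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  nodes$id <- as.character(nodes$id)
  nodes$label <- as.character(nodes$label)
  nodes$tier <- as.integer(nodes$tier)
  nodes$parent_id <- as.character(nodes$parent_id)
  nodes$parent_id[!nzchar(nodes$parent_id) | is.na(nodes$parent_id)] <- NA_character_
  if (is.null(nodes$status)) nodes$status <- "active"
  if (is.null(nodes$origin_round)) nodes$origin_round <- 0L
  nodes$origin_round <- as.integer(nodes$origin_round)

  if (anyDuplicated(nodes$id))
    stop("duplicate indicator ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
         call. = FALSE)
  if (!all(nodes$tier %in% 1:3))
    stop("tier must be 1, 2 or 3", call. = FALSE)
  bad_status <- setdiff(unique(nodes$status),
                        c("active", "deleted", "added", "renamed"))
  if (length(bad_status))
    stop("unknown status value: ", paste(bad_status, collapse = ", "),
         call. = FALSE)
  if (any(nodes$tier == 1L & !is.na(nodes$parent_id)))
    stop("tier-1 nodes must not have a parent", call. = FALSE)
  if (any(nodes$tier > 1L & is.na(nodes$parent_id)))
    stop("non-root node without parent: ",
         paste(nodes$id[nodes$tier > 1L & is.na(nodes$parent_id)],
               collapse = ", "), call. = FALSE)
  has_par <- !is.na(nodes$parent_id)
  idx <- match(nodes$parent_id[has_par], nodes$id)
  if (anyNA(idx))
    stop("orphan parent reference: ",
         paste(unique(nodes$parent_id[has_par][is.na(idx)]), collapse = ", "),
         call. = FALSE)
  # parent must sit strictly above its child; this also rules out cycles,
  # since tiers strictly decrease along any parent chain
  if (any(nodes$tier[has_par] <= nodes$tier[idx]))
    stop("tier inversion: parent tier must be smaller than child tier for ",
         paste(nodes$id[has_par][nodes$tier[has_par] <= nodes$tier[idx]],
               collapse = ", "), call. = FALSE)

  structure(list(nodes = nodes, round = as.integer(round)),
            class = "indicator_hierarchy")
}

#' Read an indicator hierarchy from CSV
#'
#' Expects columns `id,label,tier,parent_id` and optionally
#' `status,origin_round`. Malformed files (duplicate ids, orphan parents, tier
#' inversions) raise a load error naming the offending rows.
#'
#' @param path CSV file path.
#' @param round Round number to stamp on the hierarchy.
#' @return An `indicator_hierarchy`.
#' @export
read_hierarchy <- function(path, round = 0L) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  indicator_hierarchy(d, round = round)
}

#' Write an indicator hierarchy to CSV
#'
#' @param hierarchy An `indicator_hierarchy`.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_hierarchy <- function(hierarchy, path) {
  stopifnot(inherits(hierarchy, "indicator_hierarchy"))
  utils::write.csv(hierarchy$nodes, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Active nodes of a hierarchy
#'
#' Nodes are active unless deleted; freshly added or renamed nodes are scored
#' like any other.
#'
#' @param hierarchy An `indicator_hierarchy`.
#' @param tier Optional tier filter.
#' @return The active subset of the node table.
#' @export
active_nodes <- function(hierarchy, tier = NULL) {
  stopifnot(inherits(hierarchy, "indicator_hierarchy"))
  n <- hierarchy$nodes[hierarchy$nodes$status != "deleted", , drop = FALSE]
  if (!is.null(tier)) n <- n[n$tier %in% tier, , drop = FALSE]
  n
}

#' Count indicators by tier
#'
#' @param hierarchy An `indicator_hierarchy`.
#' @param active_only Count only non-deleted nodes (default).
#' @return Named integer vector `c(primary=, secondary=, tertiary=)`.
#' @export
tier_counts <- function(hierarchy, active_only = TRUE) {
  n <- if (active_only) active_nodes(hierarchy) else hierarchy$nodes
  out <- vapply(1:3, function(t) sum(n$tier == t), integer(1))
  names(out) <- c("primary", "secondary", "tertiary")
  out
}

#' @export
print.indicator_hierarchy <- function(x, ...) {
  tc <- tier_counts(x)
  cat(sprintf(
    "Indicator hierarchy (round %d): %d primary / %d secondary / %d tertiary active\n",
    x$round, tc[1], tc[2], tc[3]))
  del <- sum(x$nodes$status == "deleted")
  if (del) cat(sprintf("  (%d deleted nodes retained for audit)\n", del))
  invisible(x)
}

# ordering key: hierarchy position (stable table order of the node list),
# used so outputs group indicators as the source tables do
hierarchy_order <- function(hierarchy, ids) {
  pos <- match(ids, hierarchy$nodes$id)
  order(ifelse(is.na(pos), .Machine$integer.max, pos), ids)
}
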