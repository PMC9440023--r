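#' Rank one expert's scores across indicators
#'
#' Converts raw importance scores to ranks with the convention that the most
#' important indicator gets rank 1; tied scores share the average of the ranks
#' they span, so every rank vector sums to n(n+1)/2. Kendall's W is invariant
#' to the ascending/descending choice; fixing it keeps intermediate output
#' reproducible.
#'
#' @param scores Numeric vector of one expert's scores over >= 2 indicators.
#' @return Rank vector of the same length.
#' @examples
#' rank_scores(c(9, 7, 7, 3))  # 1, 2.5, 2.5, 4
#' @export
rank_scores <- function(scores) {
  if (length(scores) < 2)
    stop("ranking needs at least 2 scored indicators", call. = FALSE)
  if (anyNA(scores))
    stop("cannot rank scores with missing values", call. = FALSE)
  rank(-scores, ties.method = "average")
}

#' Kendall's coefficient of concordance W, tie-corrected
#'
#' Measures agreement among m experts each ranking the same n indicators.
#' With rank sums \eqn{R_j} and \eqn{S = \sum_j (R_j - \bar R)^2}, the
#' tie-corrected coefficient is
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m \sum_i T_i},}
#' where \eqn{T_i = \sum_g (t_g^3 - t_g)} sums over the tie groups of expert
#' i's scores. Significance uses the chi-square approximation
#' \eqn{\chi^2 = m (n - 1) W} on n - 1 degrees of freedom. W > 0.4 is read as
#' fair coordination and W > 0.5 as sufficient to close the consultation.
#'
#' @param scores Numeric matrix, experts in rows, indicators in columns.
#'   Experts with any missing score are dropped with a warning when
#'   `config$drop_incomplete` is `TRUE` (the default), otherwise missingness
#'   is an error.
#' @param config A [panel_config()]; supplies the flag thresholds and the
#'   optional permutation test.
#' @return An object of class `concordance`: list with `W`, `chi2`, `df`,
#'   `p_value`, `n_experts`, `n_items`, `tie_correction_total`, `flags`
#'   (`fair`, `complete`), and `p_perm` when the permutation test is on.
#' @examples
#' m <- rbind(e1 = c(5, 4, 3, 2, 1), e2 = c(5, 4, 3, 2, 1))
#' kendall_w(m)$W  # 1: identical rankings
#' @export
kendall_w <- function(scores, config = panel_config()) {
  stopifnot(is.matrix(scores))
  if (anyNA(scores)) {
    if (!config$drop_incomplete)
      stop("score matrix has missing values", call. = FALSE)
    drop <- apply(scores, 1, anyNA)
    warning(sprintf("dropping %d expert(s) with incomplete scores", sum(drop)),
            call. = FALSE)
    scores <- scores[!drop, , drop = FALSE]
  }
  m <- nrow(scores); n <- ncol(scores)
  if (m < 2) stop("Kendall's W needs at least 2 complete experts", call. = FALSE)
  if (n < 2) stop("Kendall's W needs at least 2 indicators", call. = FALSE)
  if (n < 3)
    warning("chi-square approximation is unreliable for fewer than 3 indicators",
            call. = FALSE)
  ranks <- t(apply(scores, 1, rank_scores))
  R <- colSums(ranks)
  S <- sum((R - mean(R))^2)
  Ti <- apply(scores, 1, function(x) {
    t <- table(x)
    sum(t^3 - t)
  })
  denom <- m^2 * (n^3 - n) - m * sum(Ti)
  W <- if (denom > 0) 12 * S / denom else 0
  chi2 <- m * (n - 1) * W
  p <- stats::pchisq(chi2, df = n - 1, lower.tail = FALSE)
  out <- structure(list(
    W = W, chi2 = chi2, df = n - 1L, p_value = p,
    n_experts = m, n_items = n, tie_correction_total = sum(Ti),
    flags = list(fair = W > config$thresholds$w_fair,
                 complete = W > config$thresholds$w_complete)
  ), class = "concordance")
  if (config$permutation_test) {
    obs <- W
    perm <- replicate(config$n_perm, {
      shuf <- t(apply(scores, 1, sample))
      r <- t(apply(shuf, 1, rank_scores))
      Rp <- colSums(r)
      Sp <- sum((Rp - mean(Rp))^2)
      if (denom > 0) 12 * Sp / denom else 0
    })
    out$p_perm <- (1 + sum(perm >= obs)) / (config$n_perm + 1)
  }
  out
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf(
    "Kendall's W = %.3f (%d experts, %d indicators)\n  chi2 = %.2f, df = %d, p %s\n",
    x$W, x$n_experts, x$n_items, x$chi2, x$df,
    if (x$p_value < 0.001) "< 0.001" else sprintf("= %.3f", x$p_value)))
  cat(sprintf("  coordination: %s; consultation %s be closed on this gate\n",
              if (x$flags$fair) "fair (W > 0.4)" else "weak (W <= 0.4)",
              if (x$flags$complete) "can" else "cannot"))
  if (!is.null(x$p_perm)) cat(sprintf("  permutation p = %.4f\n", x$p_perm))
  invisible(x)
}

#' Coordination report for one round
#'
#' Builds the expert-by-indicator score matrix over the active indicators and
#' applies [kendall_w()]. A single active indicator cannot carry a ranking and
#' is a clean error.
#'
#' @param responses A [response_set()].
#' @param config A [panel_config()].
#' @param hierarchy Optional hierarchy restricting and ordering the columns.
#' @return A `concordance` object.
#' @export
coordination_report <- function(responses, config = panel_config(),
                                hierarchy = NULL) {
  stopifnot(inherits(responses, "response_set"))
  ids <- sort(unique(responses$data$indicator_id))
  if (!is.null(hierarchy)) ids <- ids[ids %in% active_nodes(hierarchy)$id]
  if (length(ids) < 2)
    stop("coordination needs at least 2 active scored indicators",
         call. = FALSE)
  kendall_w(score_matrix(responses, ids), config = config)
}
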