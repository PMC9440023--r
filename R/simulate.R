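#' Configuration for a synthetic expert panel
#'
#' Describes the panel and response-generating process used by
#' [generate_panel()]: a hierarchy (or tier counts to build one), a true
#' importance value per tertiary indicator, Gaussian scoring noise, a round-2
#' dropout count, and the marginal distributions of the familiarity and
#' judgment self-ratings. Defaults emulate a two-round consultation of 15
#' experts scoring an 8/16/54 three-tier indicator system on a 0--10 scale
#' with 2 experts lost in round 2.
#'
#' @param n_experts Panel size (default 15).
#' @param tier_counts Integer vector `c(primary, secondary, tertiary)` used to
#'   build a synthetic hierarchy when `hierarchy` is `NULL`.
#' @param hierarchy Optional [indicator_hierarchy()] to score instead.
#' @param mu True importance per tertiary indicator, on the score scale;
#'   default evenly spaced over \[2, 10\] so indicators are distinctly
#'   ordered. Recycled/validated against the number of active tertiary nodes.
#' @param sigma Standard deviation of the Gaussian scoring noise (>= 0);
#'   default 2, a typical per-expert spread on a 0--10 importance scale.
#' @param dropout Number of experts who do not return the round-2
#'   questionnaire (default 2, i.e. a 13/15 = 86.67% round-2 response rate).
#' @param familiarity_probs Probabilities over the six familiarity levels,
#'   most to least familiar.
#' @param judgment_probs Probabilities over the `low`/`mid`/`high`
#'   judgment-basis bands (shared by the four bases).
#' @param full_score_affinity Probability bonus of scoring exactly full when
#'   the true importance is within 2 points of the top of the scale (default
#'   0, off). Pure rounded-Gaussian noise under-produces full marks at high
#'   `mu`; this knob restores them when full-score-frequency behaviour is
#'   under study.
#' @param noise `"gaussian"` (rounded and clipped to the scale) or
#'   `"binomial"` (score ~ Binomial(scale_max, mu/scale_max); integer-valued
#'   and tie-heavy, useful for exercising the tie correction in Kendall's W).
#' @param scale_min,scale_max,full_score Score scale (defaults 0/10/10).
#' @param seed Integer seed; mandatory, every draw is derived from it.
#' @return An object of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_experts = 15L,
                             tier_counts = c(8L, 16L, 54L),
                             hierarchy = NULL, mu = NULL, sigma = 2,
                             dropout = 2L,
                             familiarity_probs = c(0.20, 0.30, 0.25,
                                                   0.15, 0.07, 0.03),
                             judgment_probs = c(low = 0.15, mid = 0.35,
                                                high = 0.50),
                             full_score_affinity = 0,
                             noise = c("gaussian", "binomial"),
                             scale_min = 0L, scale_max = 10L,
                             full_score = scale_max, seed) {
  noise <- match.arg(noise)
  if (missing(seed) || is.null(seed))
    stop("`seed` is mandatory: synthetic panels must be reproducible",
         call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  if (dropout >= n_experts)
    stop("`dropout` must be smaller than the panel size", call. = FALSE)
  if (!is.null(mu) && (any(mu < scale_min) || any(mu > scale_max)))
    stop("`mu` must lie within the score scale", call. = FALSE)
  if (length(familiarity_probs) != 6 || any(familiarity_probs < 0))
    stop("`familiarity_probs` must be 6 non-negative weights", call. = FALSE)
  if (length(judgment_probs) != 3 || any(judgment_probs < 0))
    stop("`judgment_probs` must be 3 non-negative weights", call. = FALSE)
  structure(list(
    n_experts = as.integer(n_experts), tier_counts = as.integer(tier_counts),
    hierarchy = hierarchy, mu = mu, sigma = sigma,
    dropout = as.integer(dropout),
    familiarity_probs = familiarity_probs / sum(familiarity_probs),
    judgment_probs = judgment_probs / sum(judgment_probs),
    full_score_affinity = full_score_affinity, noise = noise,
    scale_min = as.integer(scale_min), scale_max = as.integer(scale_max),
    full_score = as.integer(full_score), seed = as.integer(seed)
  ), class = "panel_sim_config")
}

#' A 15-expert panel profile
#'
#' A fixed panel of 15 experts constructed to match the marginal composition
#' typical of a burn-model consultation: 7 clinical-medicine and 8
#' animal-research experts; 5 with under 15 years of experience, 8 with
#' 15--30 and 2 with over 30; 10 associate professors and 5 professors. The
#' two experts marked absent in round 2 are clinical-medicine experts with
#' 15--30 years (one of each title), so the round-2 marginals are 5/8,
#' 5/6/2 and 9/4. The per-expert assignment is a construction -- only the
#' marginals are externally given.
#'
#' @return Data frame with `expert_id`, `field`, `experience`, `title`,
#'   `round1`, `round2` (participation flags).
#' @export
default_expert_profiles <- function() {
  data.frame(
    expert_id = sprintf("e%02d", 1:15),
    field = c(rep("clinical_medicine", 7), rep("animal_research", 8)),
    experience = c("lt15", "lt15", "b15_30", "b15_30", "b15_30", "b15_30",
                   "gt30", "lt15", "lt15", "lt15", "b15_30", "b15_30",
                   "b15_30", "b15_30", "gt30"),
    title = c("associate_professor", "associate_professor", "professor",
              "associate_professor", "professor", "associate_professor",
              "professor", "associate_professor", "associate_professor",
              "associate_professor", "professor", "associate_professor",
              "associate_professor", "associate_professor", "professor"),
    round1 = TRUE,
    round2 = c(TRUE, TRUE, FALSE, FALSE, rep(TRUE, 11)),
    stringsAsFactors = FALSE
  )
}

# synthetic three-tier hierarchy with the requested tier counts; secondary
# nodes are spread round-robin over primaries, tertiary over secondaries
# (or directly over primaries when there are no secondaries)
synthetic_hierarchy <- function(tier_counts) {
  n1 <- tier_counts[1]; n2 <- tier_counts[2]; n3 <- tier_counts[3]
  stopifnot(n1 >= 1, n3 >= 1)
  p <- data.frame(id = sprintf("P%02d", seq_len(n1)),
                  label = sprintf("Primary %d", seq_len(n1)),
                  tier = 1L, parent_id = NA_character_,
                  stringsAsFactors = FALSE)
  s <- if (n2 > 0) data.frame(
    id = sprintf("S%02d", seq_len(n2)),
    label = sprintf("Secondary %d", seq_len(n2)),
    tier = 2L, parent_id = p$id[((seq_len(n2) - 1) %% n1) + 1],
    stringsAsFactors = FALSE)
  parents3 <- if (n2 > 0) s$id[((seq_len(n3) - 1) %% n2) + 1]
              else p$id[((seq_len(n3) - 1) %% n1) + 1]
  t3 <- data.frame(id = sprintf("T%02d", seq_len(n3)),
                   label = sprintf("Tertiary %d", seq_len(n3)),
                   tier = 3L, parent_id = parents3,
                   stringsAsFactors = FALSE)
  indicator_hierarchy(rbind(p, s, t3), round = 1L)
}

#' Generate a synthetic two-round Delphi panel
#'
#' Simulates the full data a two-round consultation produces: expert
#' profiles, a three-tier hierarchy, and per-round response sets. Each
#' expert's score for indicator j is `clip(round(mu_j + e), scale)` with
#' `e ~ Normal(0, sigma)`, independent across experts and indicators (or a
#' binomial draw under the tie-heavy alternative); familiarity levels and
#' judgment bands are drawn from the configured marginals. Round 2 drops the
#' configured number of experts and redraws scores around the same truth.
#' The same seed always reproduces the same panel.
#'
#' @param config A [panel_sim_config()].
#' @return An object of class `delphi_panel`: list with `profiles`,
#'   `hierarchy`, `mu` (named by tertiary indicator id), `rounds` (list of
#'   two [response_set()]s) and `config`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  set.seed(config$seed)
  hier <- config$hierarchy %||% synthetic_hierarchy(config$tier_counts)
  items <- active_nodes(hier, tier = 3L)$id
  n_items <- length(items)
  mu <- config$mu %||% seq(2, 10, length.out = n_items)
  if (length(mu) != n_items)
    stop("`mu` must have one value per active tertiary indicator",
         call. = FALSE)
  names(mu) <- items

  if (config$n_experts == 15L) {
    profiles <- default_expert_profiles()
    if (config$dropout != 2L) {
      profiles$round2 <- TRUE
      if (config$dropout > 0)
        profiles$round2[sample(config$n_experts, config$dropout)] <- FALSE
    }
  } else {
    profiles <- data.frame(
      expert_id = sprintf("e%02d", seq_len(config$n_experts)),
      field = rep(c("clinical_medicine", "animal_research"),
                  length.out = config$n_experts),
      experience = rep(c("lt15", "b15_30", "gt30"),
                       length.out = config$n_experts),
      title = rep(c("associate_professor", "professor"),
                  length.out = config$n_experts),
      round1 = TRUE, round2 = TRUE, stringsAsFactors = FALSE)
    if (config$dropout > 0)
      profiles$round2[sample(config$n_experts, config$dropout)] <- FALSE
  }

  draw_round <- function(experts, round) {
    ne <- length(experts)
    grid <- expand.grid(expert_id = experts, indicator_id = items,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu_g <- mu[grid$indicator_id]
    score <- if (config$noise == "gaussian") {
      raw <- round(mu_g + stats::rnorm(nrow(grid), 0, config$sigma))
      pmin(pmax(raw, config$scale_min), config$scale_max)
    } else {
      stats::rbinom(nrow(grid), config$scale_max, mu_g / config$scale_max) +
        config$scale_min * 0
    }
    if (config$full_score_affinity > 0) {
      bonus <- config$full_score_affinity *
        pmax(0, (mu_g - (config$scale_max - 2)) / 2)
      hit <- stats::runif(nrow(grid)) < bonus
      score[hit] <- config$full_score
    }
    fam <- sample(names(familiarity_levels()), nrow(grid), replace = TRUE,
                  prob = config$familiarity_probs)
    jb <- replicate(4, sample(c("low", "mid", "high"), nrow(grid),
                              replace = TRUE, prob = config$judgment_probs))
    d <- data.frame(expert_id = grid$expert_id,
                    indicator_id = grid$indicator_id,
                    score = as.numeric(score), familiarity = fam,
                    jb_practical = jb[, 1], jb_theoretical = jb[, 2],
                    jb_peers = jb[, 3], jb_insight = jb[, 4],
                    stringsAsFactors = FALSE)
    response_set(d, round = round, distributed = config$n_experts,
                 config = panel_config(config$scale_min, config$scale_max,
                                       config$full_score))
  }

  r1 <- draw_round(profiles$expert_id[profiles$round1], 1L)
  r2 <- draw_round(profiles$expert_id[profiles$round2], 2L)
  structure(list(profiles = profiles, hierarchy = hier, mu = mu,
                 rounds = list(r1, r2), config = config),
            class = "delphi_panel")
}

#' @export
print.delphi_panel <- function(x, ...) {
  tc <- tier_counts(x$hierarchy)
  cat(sprintf(
    "Synthetic Delphi panel: %d experts, %d/%d/%d indicators, sigma %.1f, seed %d\n",
    x$config$n_experts, tc[1], tc[2], tc[3], x$config$sigma, x$config$seed))
  cat(sprintf("  round 2 returns %d/%d questionnaires\n",
              x$rounds[[2]]$returned, x$rounds[[2]]$distributed))
  invisible(x)
}

#' Write a synthetic panel to pipeline-compatible CSV files
#'
#' @param panel A [generate_panel()] result.
#' @param dir Output directory (created if needed): `hierarchy.csv`,
#'   `responses_round1.csv`, `responses_round2.csv`, `profiles.csv`,
#'   `true_importance.csv`.
#' @return The directory, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "delphi_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_hierarchy(panel$hierarchy, file.path(dir, "hierarchy.csv"))
  write_responses(panel$rounds[[1]], file.path(dir, "responses_round1.csv"))
  write_responses(panel$rounds[[2]], file.path(dir, "responses_round2.csv"))
  utils::write.csv(panel$profiles, file.path(dir, "profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(indicator_id = names(panel$mu),
                              mu = as.numeric(panel$mu)),
                   file.path(dir, "true_importance.csv"), row.names = FALSE)
  invisible(dir)
}

#' Check how well the pipeline recovers a panel's planted truth
#'
#' Compares the round-1 mean importance estimates against the true `mu` the
#' panel was generated from: maximum and mean absolute error, the Spearman
#' rank correlation between estimated and true importance, and -- when a set
#' of deliberately low-importance indicators is named -- the fraction of them
#' caught by the mean-importance screening criterion and by the overall
#' screen.
#'
#' @param panel A [generate_panel()] result.
#' @param stats Optional precomputed [stats_table()] for round 1.
#' @param low_ids Optional ids of indicators planted with low `mu`.
#' @return List with `max_abs_err`, `mean_abs_err`, `rank_cor`, `n_items`,
#'   and (when `low_ids` is given) `planted` with `mj_fail_rate` and
#'   `flagged_rate`.
#' @export
recovery_check <- function(panel, stats = NULL, low_ids = NULL) {
  stopifnot(inherits(panel, "delphi_panel"))
  cfg <- panel_config(panel$config$scale_min, panel$config$scale_max,
                      panel$config$full_score)
  if (is.null(stats))
    stats <- stats_table(panel$rounds[[1]], cfg, panel$hierarchy)
  mu <- panel$mu[stats$indicator_id]
  err <- stats$Mj - mu
  out <- list(max_abs_err = max(abs(err)), mean_abs_err = mean(abs(err)),
              rank_cor = stats::cor(stats$Mj, mu, method = "spearman"),
              n_items = nrow(stats))
  if (!is.null(low_ids)) {
    dec <- screen_indicators(stats, config = cfg)
    sel <- dec$indicator_id %in% low_ids
    out$planted <- list(
      ids = low_ids,
      mj_fail_rate = mean(dec$Mj_fail[sel]),
      flagged_rate = mean(dec$disposition[sel] != "retain"))
  }
  out
}
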