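test_that("simulation configuration validates its inputs", {
  expect_error(panel_sim_config(), "seed")
  expect_error(panel_sim_config(sigma = -1, seed = 1), "sigma")
  expect_error(panel_sim_config(dropout = 15, seed = 1), "smaller than the panel")
  expect_error(panel_sim_config(mu = c(3, 12), seed = 1), "within the score scale")
})

test_that("a noiseless panel reproduces the truth exactly", {
  mu <- rep(c(2, 4, 6, 8, 10), 3)  # integer truths: rounding cannot move them
  cfg <- panel_sim_config(seed = 77, sigma = 0, tier_counts = c(3, 5, 15),
                          mu = mu)
  panel <- generate_panel(cfg)
  st <- stats_table(panel$rounds[[1]], hierarchy = panel$hierarchy)
  expect_equal(st$Mj, unname(panel$mu[st$indicator_id]))
  rc <- recovery_check(panel)
  expect_equal(rc$max_abs_err, 0)
  expect_equal(rc$rank_cor, 1)
  w <- kendall_w(score_matrix(panel$rounds[[1]]))
  expect_equal(w$W, 1)
})

test_that("the same seed reproduces the panel; different seeds differ", {
  a <- generate_panel(panel_sim_config(seed = 101, tier_counts = c(2, 4, 10)))
  b <- generate_panel(panel_sim_config(seed = 101, tier_counts = c(2, 4, 10)))
  expect_identical(a$rounds[[1]]$data, b$rounds[[1]]$data)
  expect_identical(a$rounds[[2]]$data, b$rounds[[2]]$data)
  c_ <- generate_panel(panel_sim_config(seed = 102, tier_counts = c(2, 4, 10)))
  expect_false(identical(a$rounds[[1]]$data$score, c_$rounds[[1]]$data$score))
})

test_that("default dropout mirrors a 13-of-15 second round", {
  panel <- generate_panel(panel_sim_config(seed = 6, tier_counts = c(2, 4, 10)))
  rr <- response_rate(panel$rounds[[2]]$distributed, panel$rounds[[2]]$returned)
  expect_equal(round(rr$rate, 2), 86.67)
  expect_true(rr$good)
})

test_that("the fixed 15-expert profile matches the published panel marginals", {
  p <- default_expert_profiles()
  expect_equal(sum(p$field == "clinical_medicine"), 7)
  expect_equal(sum(p$field == "animal_research"), 8)
  expect_equal(unname(table(p$experience)[c("lt15", "b15_30", "gt30")]),
               c(5L, 8L, 2L), ignore_attr = TRUE)
  expect_equal(sum(p$title == "associate_professor"), 10)
  r2 <- p[p$round2, ]
  expect_equal(nrow(r2), 13)
  expect_equal(sum(r2$field == "clinical_medicine"), 5)
  expect_equal(unname(table(r2$experience)[c("lt15", "b15_30", "gt30")]),
               c(5L, 6L, 2L), ignore_attr = TRUE)
  expect_equal(sum(r2$title == "professor"), 4)
})

test_that("generated self-rating marginals match the configured distributions", {
  cfg <- panel_sim_config(seed = 55)
  panel <- generate_panel(cfg)
  d <- panel$rounds[[1]]$data
  n <- nrow(d)  # 15 x 54 draws
  fam_freq <- table(factor(d$familiarity,
                           levels = names(familiarity_levels()))) / n
  tol <- 4 * sqrt(cfg$familiarity_probs * (1 - cfg$familiarity_probs) / n)
  expect_true(all(abs(as.numeric(fam_freq) - cfg$familiarity_probs) < tol))
  jb_freq <- table(factor(d$jb_practical,
                          levels = c("low", "mid", "high"))) / n
  tolj <- 4 * sqrt(cfg$judgment_probs * (1 - cfg$judgment_probs) / n)
  expect_true(all(abs(as.numeric(jb_freq) - cfg$judgment_probs) < tolj))
})

test_that("the binomial noise alternative produces in-scale tie-heavy integers", {
  panel <- generate_panel(panel_sim_config(seed = 19, noise = "binomial",
                                           tier_counts = c(2, 4, 10)))
  s <- panel$rounds[[1]]$data$score
  expect_true(all(s >= 0 & s <= 10 & s == round(s)))
  res <- kendall_w(score_matrix(panel$rounds[[1]]))
  expect_gt(res$tie_correction_total, 0)
})

test_that("full-score affinity boosts top marks only near the top of the scale", {
  lo <- generate_panel(panel_sim_config(seed = 23, full_score_affinity = 0,
                                        tier_counts = c(2, 4, 10),
                                        mu = rep(9.5, 10)))
  hi <- generate_panel(panel_sim_config(seed = 23, full_score_affinity = 0.8,
                                        tier_counts = c(2, 4, 10),
                                        mu = rep(9.5, 10)))
  full_rate <- function(p) mean(p$rounds[[1]]$data$score == 10)
  expect_gt(full_rate(hi), full_rate(lo))
  far <- generate_panel(panel_sim_config(seed = 23, full_score_affinity = 0.8,
                                         tier_counts = c(2, 4, 10),
                                         mu = rep(4, 10)))
  far0 <- generate_panel(panel_sim_config(seed = 23, full_score_affinity = 0,
                                          tier_counts = c(2, 4, 10),
                                          mu = rep(4, 10)))
  expect_equal(far$rounds[[1]]$data$score, far0$rounds[[1]]$data$score)
})

test_that("recovery reporting flags planted low-importance indicators", {
  mu <- c(seq(6, 9, length.out = 12), rep(2, 3))
  cfg <- panel_sim_config(seed = 37, sigma = 1, tier_counts = c(3, 5, 15),
                          mu = mu)
  panel <- generate_panel(cfg)
  low_ids <- names(panel$mu)[panel$mu == 2]
  rc <- recovery_check(panel, low_ids = low_ids)
  expect_equal(rc$planted$mj_fail_rate, 1)
  expect_gt(rc$rank_cor, 0.5)
})

test_that("panels written to disk feed straight back into the pipeline", {
  panel <- generate_panel(panel_sim_config(seed = 61, tier_counts = c(2, 4, 10)))
  d <- withr::local_tempdir()
  write_panel(panel, d)
  h <- read_hierarchy(file.path(d, "hierarchy.csv"), round = 1)
  r1 <- read_responses(file.path(d, "responses_round1.csv"),
                       hierarchy = h, distributed = 15)
  res <- delphi_round(r1, h)
  expect_equal(res$summary$response_rate, 100)
  expect_equal(nrow(res$stats), 10)
})
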