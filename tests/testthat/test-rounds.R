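test_that("a full round runs the stages in order and summarises them", {
  panel <- generate_panel(panel_sim_config(seed = 42))
  r1 <- delphi_round(panel$rounds[[1]], panel$hierarchy)
  expect_s3_class(r1, "delphi_round")
  expect_equal(r1$summary$response_rate, 100)
  expect_true(r1$summary$response_good)
  expect_equal(nrow(r1$stats), 54)
  expect_equal(sum(unlist(r1$summary$decision_counts)), 54)
  expect_equal(sum(unlist(r1$summary$authority_bands)), 54)
  expect_equal(r1$summary$panel_cr, mean(r1$stats$Cr))

  r2 <- delphi_round(panel$rounds[[2]], panel$hierarchy)
  expect_equal(round(r2$summary$response_rate, 2), 86.67)
  expect_equal(r2$engagement$returned, 13L)
})

test_that("an empty response set fails cleanly before any statistic", {
  d <- data.frame(expert_id = character(), indicator_id = character(),
                  score = numeric(), familiarity = character(),
                  jb_practical = character(), jb_theoretical = character(),
                  jb_peers = character(), jb_insight = character(),
                  stringsAsFactors = FALSE)
  expect_error(delphi_round(response_set(d)), "empty response set")
})

test_that("the edit log advances the hierarchy with exact bookkeeping", {
  h1 <- burn_example_hierarchy()
  expect_equal(unname(tier_counts(h1)), c(8L, 16L, 54L))
  h2 <- advance_hierarchy(h1, burn_example_edits())
  expect_equal(unname(tier_counts(h2)), c(8L, 14L, 46L))
  expect_equal(h2$round, 2L)

  # additions carry their origin round; renames keep the id, change the label
  n2 <- h2$nodes
  expect_equal(n2$origin_round[n2$id == "ionizing_radiation"], 2L)
  expect_equal(n2$status[n2$id == "ionizing_radiation"], "added")
  expect_equal(n2$label[n2$id == "wound_color"], "Wound was pale")
  expect_equal(n2$parent_id[n2$id == "env_disinfection"],
               "infection_prevention")

  # tier counts after = before - deletions + additions
  e <- burn_example_edits()
  expect_equal(sum(tier_counts(h2)),
               sum(tier_counts(h1)) - sum(e$action == "delete") +
                 sum(e$action == "add"))

  # replaying the same log reproduces the hierarchy exactly
  h2b <- advance_hierarchy(h1, burn_example_edits())
  expect_identical(h2b$nodes, h2$nodes)

  # a no-op log changes nothing but the round number
  h_same <- advance_hierarchy(h1, burn_example_edits()[0, ])
  expect_identical(h_same$nodes, h1$nodes)

  # deleting a parent while a child stays active is rejected
  bad <- data.frame(round = 1, action = "delete",
                    indicator_id = "general_anesthesia", label = "",
                    tier = 2, parent_id = "", note = "")
  expect_error(advance_hierarchy(h1, bad), "deleted parent")
})

test_that("unresolved review blocks hierarchy advancement", {
  st <- data.frame(indicator_id = c("a", "b", "c", "d"), m = 15L,
                   Mj = c(8, 8.1, 7.9, 8.0), sd = 0.5,
                   Vj = c(0.10, 0.11, 0.09, 0.60),
                   Kj = c(0.5, 0.52, 0.48, 0.50), Cs = 0.8, Ca = 0.9)
  dec <- screen_indicators(st)  # "d" fails Vj only -> review, unresolved
  expect_true(any(dec$disposition == "review"))
  h <- indicator_hierarchy(data.frame(
    id = c("p", "a", "b", "c", "d"), label = c("P", "A", "B", "C", "D"),
    tier = c(1, 3, 3, 3, 3), parent_id = c(NA, "p", "p", "p", "p")))
  expect_error(advance_hierarchy(h, burn_example_edits()[0, ],
                                 decisions = dec),
               "unresolved review")
})

test_that("the consolidated report covers every round and the final system", {
  panel <- generate_panel(panel_sim_config(seed = 13, tier_counts = c(3, 6, 16)))
  cfg <- panel_config()
  r1 <- delphi_round(panel$rounds[[1]], panel$hierarchy, cfg)
  r2 <- delphi_round(panel$rounds[[2]], panel$hierarchy, cfg)
  rep2 <- final_report(list(r1, r2), panel$hierarchy)
  expect_length(rep2$rounds, 2)
  expect_named(rep2$rounds[[1]]$concordance$flags, c("fair", "complete"))
  expect_equal(rep2$final_tier_counts$tertiary, 16)

  rep1 <- final_report(list(r1))
  expect_length(rep1$rounds, 1)
  expect_null(rep1$final_tier_counts)

  # rerunning the writer yields byte-identical output files
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  final_report(list(r1, r2), panel$hierarchy, dir = d1)
  final_report(list(r1, r2), panel$hierarchy, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_setequal(list.files(d1),
                  c("summary.json", "stats_round1.csv", "stats_round2.csv",
                    "screening_round1.csv", "screening_round2.csv"))
})

test_that("the reference round-2 table ranks the back highest among burn sites", {
  s2 <- burn_example_stats(2)
  sites <- s2[s2$primary_id == "burn_sites", ]
  expect_equal(sites$indicator_id[which.max(sites$Mj)], "back")
  expect_equal(max(sites$Mj), 9.15)
})
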