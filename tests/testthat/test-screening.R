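make_stats <- function(Mj, Kj = NULL, Vj = NULL, ids = NULL) {
  n <- length(Mj)
  structure(data.frame(
    indicator_id = ids %||% sprintf("i%02d", seq_len(n)),
    m = 15L, Mj = Mj, sd = Vj %||% rep(0.5, n),
    Vj = Vj %||% rep(0.1, n), Kj = Kj %||% rep(0.5, n),
    Cs = 0.8, Ca = 0.9, stringsAsFactors = FALSE), class = "data.frame")
}

test_that("boundary values follow mean - sd (Mj, Kj) and mean + sd (Vj)", {
  st <- make_stats(Mj = c(9, 6, 3))
  b <- boundary_values(st)
  mj <- b[b$criterion == "Mj", ]
  expect_equal(mj$center, 6)
  expect_equal(mj$spread, 3)
  expect_equal(mj$boundary, 3)
  expect_equal(mj$direction, "retain_above")

  dec <- screen_indicators(st, b)
  # only the indicator sitting exactly at the boundary fails (not strictly above)
  expect_equal(dec$Mj_fail, c(FALSE, FALSE, TRUE))

  st2 <- make_stats(Mj = c(7, 7, 7), Vj = c(0.1, 0.2, 0.6))
  b2 <- boundary_values(st2)
  vj <- b2[b2$criterion == "Vj", ]
  expect_equal(vj$boundary, 0.3 + sd(c(0.1, 0.2, 0.6)))
  expect_equal(vj$direction, "retain_below")
  dec2 <- screen_indicators(st2, b2)
  expect_equal(dec2$Vj_fail, c(FALSE, FALSE, TRUE))
})

test_that("identical statistics are a degenerate screen: boundaries touch every value", {
  st <- make_stats(Mj = rep(6, 4), Kj = rep(0.4, 4), Vj = rep(0.2, 4))
  dec <- screen_indicators(st)
  # strict comparisons put a value exactly at its boundary on the failing side
  expect_true(all(dec$Mj_fail) && all(dec$Kj_fail) && all(dec$Vj_fail))
  expect_true(all(dec$disposition == "delete"))
})

test_that("dispositions follow the failed-criteria count", {
  # one indicator placed far worse on all three criteria
  st <- make_stats(Mj = c(8, 8.5, 7.5, 8.2, 2),
                   Kj = c(0.6, 0.5, 0.55, 0.65, 0.01),
                   Vj = c(0.10, 0.12, 0.11, 0.09, 0.90))
  dec <- screen_indicators(st)
  expect_equal(dec$disposition[5], "delete")
  expect_true(all(dec$disposition[1:4] == "retain"))

  # failing Vj alone is review, never automatic deletion
  st2 <- make_stats(Mj = c(8, 8.1, 7.9, 8.0),
                    Kj = c(0.5, 0.52, 0.48, 0.50),
                    Vj = c(0.10, 0.11, 0.09, 0.60))
  dec2 <- screen_indicators(st2)
  expect_equal(dec2$disposition[4], "review")
  expect_equal(dec2$Vj_fail[4], TRUE)
  expect_false(dec2$Mj_fail[4])

  # the strictly best indicator in a non-degenerate group cannot fail
  st3 <- make_stats(Mj = c(9, 6, 5), Kj = c(0.9, 0.3, 0.2),
                    Vj = c(0.05, 0.4, 0.5))
  dec3 <- screen_indicators(st3)
  expect_equal(dec3$disposition[1], "retain")
})

test_that("screening partitions indicators and respects dominance", {
  set.seed(17)
  for (rep in 1:50) {
    st <- random_stats_table(sample(5:25, 1))
    dec <- screen_indicators(st)
    expect_true(all(dec$disposition %in% c("retain", "review", "delete")))
    expect_equal(dec$disposition == "retain", dec$n_failed == 0)
    expect_equal(dec$disposition == "delete", dec$n_failed == 3)
    # dominance: scoring at least as well on every criterion never adds failures
    for (pair in list(sample(nrow(st), 2))) {
      a <- pair[1]; b <- pair[2]
      if (st$Mj[a] >= st$Mj[b] && st$Kj[a] >= st$Kj[b] &&
          st$Vj[a] <= st$Vj[b]) {
        expect_true(all(!dec$Mj_fail[a] | dec$Mj_fail[b]))
        expect_true(all(!dec$Kj_fail[a] | dec$Kj_fail[b]))
        expect_true(all(!dec$Vj_fail[a] | dec$Vj_fail[b]))
      }
    }
  }
})

test_that("screening is scale-equivariant", {
  set.seed(5)
  st <- random_stats_table(12)
  dec <- screen_indicators(st)
  k <- 3.7
  st_scaled <- st
  st_scaled$Mj <- st$Mj * k
  st_scaled$sd <- st$sd * k
  # Vj and Kj are scale-free, Mj boundaries shift proportionally
  dec_scaled <- screen_indicators(st_scaled)
  expect_equal(dec_scaled$Mj_fail, dec$Mj_fail)
  expect_equal(dec_scaled$disposition, dec$disposition)
  b <- boundary_values(st); bs <- boundary_values(st_scaled)
  expect_equal(bs$boundary[bs$criterion == "Mj"],
               k * b$boundary[b$criterion == "Mj"])
})

test_that("single-indicator groups skip screening with a warning", {
  st <- make_stats(Mj = 7)
  expect_warning(b <- boundary_values(st), "fewer than 2")
  expect_true(all(is.na(b$boundary)))
  dec <- suppressWarnings(screen_indicators(st))
  expect_equal(dec$disposition, "review")
})

test_that("expert review resolves dispositions through the edit log", {
  st <- make_stats(Mj = c(8, 8.2, 7.9, 7.8, 2),
                   Kj = c(0.6, 0.62, 0.58, 0.55, 0.01),
                   Vj = c(0.10, 0.11, 0.12, 0.60, 0.65),
                   ids = c("good1", "good2", "good3", "border", "bad"))
  dec <- screen_indicators(st)
  expect_equal(dec$disposition,
               c("retain", "retain", "retain", "review", "delete"))

  # unresolved review item errors by name
  expect_error(apply_review(dec, data.frame(round = 1, action = "keep",
                                            indicator_id = "good1")),
               "unresolved review item.*border")

  edits <- data.frame(round = 1, action = c("keep", "delete"),
                      indicator_id = c("border", "good2"))
  fin <- apply_review(dec, edits)
  expect_equal(fin$final_action,
               c("kept", "deleted", "kept", "kept", "deleted"))
  # deleting a statistically retained indicator is allowed but audited
  expect_equal(fin$audit, c("", "expert-override", "", "", ""))

  # deletion is automatic only for the all-three-failed disposition
  expect_equal(fin$final_action[fin$disposition == "delete"], "deleted")

  expect_error(apply_review(dec, data.frame(round = 1, action = "delete",
                                            indicator_id = "ghost")),
               "unknown indicator")

  # an empty edit log leaves a review-free table unchanged
  dec0 <- screen_indicators(make_stats(Mj = c(7.9, 8.0, 8.4),
                                       Kj = c(0.45, 0.5, 0.6),
                                       Vj = c(0.10, 0.18, 0.20)))
  expect_true(all(dec0$disposition == "retain"))
  fin0 <- apply_review(dec0, data.frame(round = integer(), action = character(),
                                        indicator_id = character()))
  expect_true(all(fin0$final_action == "kept"))
})

test_that("the edit-log reader validates actions", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines("round,action,indicator_id\n1,explode,x", f)
  expect_error(read_edits(f), "unknown edit action")
  e <- burn_example_edits()
  expect_equal(nrow(e), 14)
  expect_equal(sum(e$action == "delete"), 11)
})
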