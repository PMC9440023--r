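#' Bundled reference tables from a two-round burn-model consultation
#'
#' The package ships the transcribed per-indicator summary tables of a
#' published two-round Delphi consultation that built a rat third-degree-burn
#' model indicator system: 54 tertiary indicators in round 1 and 46 in round
#' 2, each with the printed mean importance `Mj`, standard deviation `sd`,
#' coefficient of variation `Vj`, full-score frequency `Kj` (percent),
#' familiarity `Cs`, judgment `Ca` and authority `Cr` columns, plus the
#' hierarchy ids linking every row to its secondary and primary indicator.
#'
#' Two transcription caveats carried over from the printed source: the
#' round-1 `Kj` column visibly duplicates the `Mj` column (a typesetting
#' fault -- never use it as a full-score frequency), and the round-2
#' "Subcutaneous injury" `Kj` of 28.46 is not k/13 for any integer k (most
#' plausibly a misprint of 38.46). Both are shipped exactly as printed.
#'
#' @param round 1 or 2.
#' @return Data frame with columns `indicator_id`, `label`, `secondary_id`,
#'   `primary_id`, `Mj`, `sd`, `Vj`, `Kj`, `Cs`, `Ca`, `Cr`.
#' @examples
#' s1 <- burn_example_stats(1)
#' authority_band_counts((s1$Cs + s1$Ca) / 2)
#' @export
burn_example_stats <- function(round = 1) {
  stopifnot(round %in% 1:2)
  f <- system.file("extdata", sprintf("burn_round%d_stats.csv", round),
                   package = "delphiScreen", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}

#' Bundled round-1 indicator hierarchy of the burn-model consultation
#'
#' The three-tier index system entering round 1: 8 primary, 16 secondary and
#' 54 tertiary indicators. Burn-site and induction-temperature tertiary
#' indicators attach directly to their primary indicator (no secondary
#' grouping exists there).
#'
#' @return An [indicator_hierarchy()].
#' @export
burn_example_hierarchy <- function() {
  f <- system.file("extdata", "burn_round1_hierarchy.csv",
                   package = "delphiScreen", mustWork = TRUE)
  read_hierarchy(f, round = 1L)
}

#' Bundled round-1 edit log of the burn-model consultation
#'
#' The structured record of the panel's review after round 1: 2 secondary and
#' 9 tertiary deletions, the addition of ionizing radiation as a new
#' induction method, one rename (the wound-colour criterion reworded to
#' "wound was pale") and one re-parenting. Replayed on the round-1 hierarchy
#' it yields the final 8/14/46 index system.
#'
#' @return Edit-log data frame (see [read_edits()]).
#' @export
burn_example_edits <- function() {
  f <- system.file("extdata", "burn_round1_edits.csv",
                    package = "delphiScreen", mustWork = TRUE)
  read_edits(f)
}

#' Bundled example configuration file
#'
#' @return A [panel_config()] loaded from the shipped `config.yaml`.
#' @export
burn_example_config <- function() {
  f <- system.file("extdata", "config.yaml",
                   package = "delphiScreen", mustWork = TRUE)
  read_panel_config(f)
}
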