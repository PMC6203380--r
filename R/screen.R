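#' Quality-filter RNAi lines
#'
#' Removes hairpin lines with insufficient targeting specificity: lines are
#' kept when the S19 specificity score is at least `s19_min` AND the number
#' of CAN repeats is at most `can_max` (both boundaries inclusive; the
#' exclusion rule drops lines with S19 < 0.8 and/or more than six CAN
#' repeats). Row order is preserved.
#'
#' @param lines Data frame with at least `s19_score` and `can_repeats`.
#' @param s19_min Minimum S19 score kept (default 0.8).
#' @param can_max Maximum CAN repeat count kept (default 6).
#' @return The kept rows, as a tibble.
#' @export
#' @examples
#' filter_rnai_quality(tibble::tibble(s19_score = c(0.8, 0.79), can_repeats = c(6, 0)))
filter_rnai_quality <- function(lines, s19_min = 0.8, can_max = 6) {
  stopifnot(is.finite(s19_min), is.finite(can_max))
  dplyr::filter(as_tibble(lines),
                .data$s19_score >= s19_min, .data$can_repeats <= can_max)
}

#' Pupariation Z-score
#'
#' The primary-screen statistic: (control mean pupariation - test
#' pupariation) / control SD. The assay records percent larval progeny, so
#' by default the test value is converted to percent pupariation as
#' 100 - percent larvae before differencing; pass `input = "pupariation"`
#' when the value is already a pupariation percentage.
#'
#' @param pct_test Percent larvae (default) or percent pupariation for the
#'   test cross; vectorized.
#' @param control A [new_control_stats()] row (percent-pupariation scale).
#' @param input Either `"larvae"` (convert as 100 - x) or `"pupariation"`.
#' @return Numeric Z-score(s); large positive values mean pupariation far
#'   below control.
#' @export
#' @examples
#' pupariation_zscore(66.64, new_control_stats(98.8, 5)) # 13.088
pupariation_zscore <- function(pct_test, control, input = c("larvae", "pupariation")) {
  input <- match.arg(input)
  if (control$sd_pupariation <= 0) abort("control SD must be positive")
  pup <- if (input == "larvae") 100 - pct_test else pct_test
  (control$mean_pupariation - pup) / control$sd_pupariation
}

#' Call primary screen hits
#'
#' A line is a larval-arrest hit when its day-8 pupariation Z-score strictly
#' exceeds `z_cutoff`; an invasion hit when it shows mouth-hook invasion or
#' ectopic GFP foci; and a primary hit when either holds. Day-12 counts are
#' carried for reporting but not used for calling.
#'
#' @param records Quality-filtered screen table (one row per line) with
#'   `pct_larvae_day8`, `mouthhook_invasion`, `ectopic_foci`.
#' @param control A [new_control_stats()] row.
#' @param z_cutoff Z threshold (default 1.65, strict).
#' @return The input tibble with added columns `z`, `larval_arrest_hit`,
#'   `invasion_hit`, `is_hit`.
#' @export
call_primary_hits <- function(records, control, z_cutoff = 1.65) {
  records <- as_tibble(records)
  dplyr::mutate(
    records,
    z = pupariation_zscore(.data$pct_larvae_day8, control),
    larval_arrest_hit = .data$z > z_cutoff,
    invasion_hit = .data$mouthhook_invasion | .data$ectopic_foci,
    is_hit = .data$larval_arrest_hit | .data$invasion_hit
  )
}

#' Aggregate secondary-screen scores per gene
#'
#' Secondary validation scores each RNAi line for rough-eye phenotype
#' enhancement on a 0-3 scale; a gene is validated when the arithmetic mean
#' over its lines reaches `cutoff` (inclusive).
#'
#' @param scores Data frame with columns `fly_gene` and `score` (one row per
#'   line; scores in \[0, 3\]).
#' @param cutoff Validation threshold on the per-gene mean (default 0.75).
#' @return Tibble with `fly_gene`, `n_lines`, `mean_score`, `validated`.
#'   Genes whose scores are all missing are excluded with a warning.
#' @export
#' @examples
#' validate_secondary(tibble::tibble(fly_gene = "g", score = c(1, 0.5)))
validate_secondary <- function(scores, cutoff = 0.75) {
  scores <- as_tibble(scores)
  if (any(scores$score < 0 | scores$score > 3, na.rm = TRUE)) {
    abort("secondary scores must lie in [0, 3]")
  }
  out <- scores |>
    dplyr::group_by(.data$fly_gene) |>
    dplyr::summarise(n_lines = sum(!is.na(.data$score)),
                     mean_score = mean(.data$score, na.rm = TRUE),
                     .groups = "drop")
  empty <- out$n_lines == 0
  if (any(empty)) {
    warn(sprintf("excluding %d gene(s) with no usable secondary scores: %s",
                 sum(empty), toString(head(out$fly_gene[empty], 5))))
    out <- out[!empty, ]
  }
  dplyr::mutate(out, validated = .data$mean_score >= cutoff)
}
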