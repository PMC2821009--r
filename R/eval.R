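# Evaluation of site-prediction criteria against "known" functional or
# associated variants.
#
# The packaged annotation table records, for 27 missense variants of
# ANGPTL4, where each rare variant fell in the triglyceride phenotype
# distribution (High / Middle / Low), the biological assay outcome, the
# PolyPhen score and prediction, and the maximum physicochemical-change
# category from radical-substitution scoring.  The six low-tail variants
# with a functional assay result plus the two scan-significant common
# variants form the "known" positive set; the two high-tail variants that
# were assayed and showed no functional effect are held out of the 2x2
# tables and reported separately; the remaining 17 are negatives.

#' Packaged missense-variant annotations
#'
#' @param path optional path to a CSV with the same schema; defaults to the
#'   packaged table.
#' @return tibble of variant annotations with a `known_status` column
#'   (`functional_or_significant`, `tested_not_functional`,
#'   `middle_or_notsig`).
#' @export
read_variant_annotations <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "angptl4_missense_variants.csv", package = "phyloscan")
  }
  ann <- readr::read_csv(path,
    col_types = readr::cols(
      variant = readr::col_character(),
      codon_site = readr::col_integer(),
      distribution_class = readr::col_character(),
      assay = readr::col_character(),
      polyphen_score = readr::col_double(),
      polyphen_prediction = readr::col_character(),
      treesaap_category = readr::col_character(),
      treesaap_properties = readr::col_character()
    )
  )
  bad_pp <- setdiff(ann$polyphen_prediction, c("benign", "possibly damaging", "probably damaging"))
  if (length(bad_pp)) abort(paste0("unknown PolyPhen prediction: ", paste(bad_pp, collapse = ", ")))
  bad_ts <- setdiff(ann$treesaap_category, c("none", "6-7", "8"))
  if (length(bad_ts)) abort(paste0("unknown category: ", paste(bad_ts, collapse = ", ")))
  ann %>% mutate(known_status = case_when(
    .data$distribution_class %in% c("Low", "Significant") ~ "functional_or_significant",
    .data$distribution_class == "High" ~ "tested_not_functional",
    TRUE ~ "middle_or_notsig"
  ))
}

#' Site-prediction criteria
#'
#' The seven criteria compared: PolyPhen (possibly or probably damaging),
#' Strict PolyPhen (probably damaging only), TreeSAAP (category 6 or above),
#' Strict TreeSAAP (category 8 only), their conjunctions, and the strict
#' disjunction.
#'
#' @return named list of predicate functions over an annotation tibble.
#' @export
variant_criteria <- function() {
  pp <- function(a) a$polyphen_prediction %in% c("possibly damaging", "probably damaging")
  spp <- function(a) a$polyphen_prediction == "probably damaging"
  ts <- function(a) a$treesaap_category %in% c("6-7", "8")
  sts <- function(a) a$treesaap_category == "8"
  list(
    "PolyPhen" = pp,
    "TreeSAAP" = ts,
    "Strict PolyPhen" = spp,
    "Strict TreeSAAP" = sts,
    "PolyPhen & TreeSAAP" = function(a) pp(a) & ts(a),
    "Strict PolyPhen & Strict TreeSAAP" = function(a) spp(a) & sts(a),
    "Strict PolyPhen OR Strict TreeSAAP" = function(a) spp(a) | sts(a)
  )
}

#' Apply one criterion to the annotations
#'
#' @param annotations tibble from [read_variant_annotations()].
#' @param criterion criterion name (see [variant_criteria()]).
#' @return `annotations` with a logical `predicted_significant` column.
#' @export
classify_variants <- function(annotations, criterion) {
  crit <- variant_criteria()[[criterion]]
  if (is.null(crit)) abort(paste0("unknown criterion: ", criterion))
  annotations %>% mutate(predicted_significant = crit(annotations))
}

#' 2x2 table of predictions against known status
#'
#' Columns are the known classes (functional-or-significant vs
#' middle-or-not-significant); rows are predicted significant / not.  The
#' assayed-nonfunctional high-tail variants are excluded from the table and
#' counted separately.
#'
#' @param classified output of [classify_variants()].
#' @return list with `table` (2x2 integer matrix), `high_tail_flagged` and
#'   `high_tail_total` counts.
#' @export
build_2x2 <- function(classified) {
  stopifnot("predicted_significant" %in% names(classified))
  core <- classified %>% filter(.data$known_status != "tested_not_functional")
  ht <- classified %>% filter(.data$known_status == "tested_not_functional")
  tab <- matrix(
    c(
      sum(core$predicted_significant & core$known_status == "functional_or_significant"),
      sum(!core$predicted_significant & core$known_status == "functional_or_significant"),
      sum(core$predicted_significant & core$known_status == "middle_or_notsig"),
      sum(!core$predicted_significant & core$known_status == "middle_or_notsig")
    ),
    nrow = 2,
    dimnames = list(
      prediction = c("significant", "not_significant"),
      known = c("functional_or_significant", "middle_or_notsig")
    )
  )
  list(
    table = tab,
    high_tail_flagged = sum(ht$predicted_significant),
    high_tail_total = nrow(ht)
  )
}

#' Two-tailed Fisher exact test of a 2x2 table
#'
#' Exact hypergeometric test with the point-probability two-tailed rule
#' (all tables with fixed margins whose probability does not exceed the
#' observed table's are summed).
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @return the two-tailed p-value.
#' @export
fisher_exact_two_tailed <- function(table) {
  if (all(table == 0)) {
    warn("all-zero table; p = 1")
    return(1)
  }
  fisher.test(table)$p.value
}

#' Conditional-MLE odds ratio with exact confidence interval
#'
#' The odds ratio maximising the noncentral hypergeometric likelihood of the
#' table with fixed margins, with the exact tail-inversion confidence
#' interval; the convention reported alongside Fisher's exact test.  Zero
#' margin cells yield infinite or zero bounds, reported explicitly.
#'
#' @param table 2x2 matrix of nonnegative integer counts.
#' @param conf_level confidence level, default 0.95.
#' @return tibble: estimate, conf_low, conf_high.
#' @export
conditional_odds_ratio <- function(table, conf_level = 0.95) {
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(tibble(estimate = NA_real_, conf_low = NA_real_, conf_high = NA_real_))
  }
  ft <- fisher.test(table, conf.level = conf_level)
  tibble(
    estimate = unname(ft$estimate),
    conf_low = ft$conf.int[1], conf_high = ft$conf.int[2]
  )
}

#' Evaluate all site-prediction criteria
#'
#' Builds the 2x2 table of every criterion against the known variant
#' classes and reports the exact test, conditional odds ratio with exact
#' 95 percent CI, and sensitivity / specificity with their complements
#' (alpha = false-positive rate, beta = false-negative rate).
#'
#' @param annotations tibble from [read_variant_annotations()].
#' @param conf_level confidence level for the odds-ratio interval.
#' @return tibble, one row per criterion.
#' @export
evaluate_predictors <- function(annotations = read_variant_annotations(),
                                conf_level = 0.95) {
  purrr::imap(variant_criteria(), function(f, nm) {
    cls <- classify_variants(annotations, nm)
    b <- build_2x2(cls)
    tab <- b$table
    or <- conditional_odds_ratio(tab, conf_level)
    sens <- tab[1, 1] / sum(tab[, 1])
    spec <- tab[2, 2] / sum(tab[, 2])
    tibble(
      criterion = nm,
      functional_flagged = tab[1, 1], functional_missed = tab[2, 1],
      nonfunctional_flagged = tab[1, 2], nonfunctional_unflagged = tab[2, 2],
      high_tail_flagged = b$high_tail_flagged,
      p_value = fisher_exact_two_tailed(tab),
      odds_ratio = or$estimate,
      ci_lower = or$conf_low, ci_upper = or$conf_high,
      sensitivity = sens, specificity = spec,
      alpha = 1 - spec, beta = 1 - sens
    )
  }) %>% bind_rows()
}
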