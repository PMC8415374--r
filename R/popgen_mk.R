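#' Join selection-test results with polymorphism counts
#'
#' @param results a `selection_test_result` tibble (needs `enhancer_id`,
#'   `n_substitutions`, `positive_call`).
#' @param snp_table counts-granularity `snp_table` (`enhancer_id`, `n_snps`).
#' @return Tibble of divergence/polymorphism records: `enhancer_id,
#'   n_substitutions, n_polymorphisms, positive_call`.
#' @export
div_poly_records <- function(results, snp_table) {
  stopifnot(all(c("enhancer_id", "n_snps") %in% names(snp_table)))
  merged <- dplyr::inner_join(
    as_tibble(results)[, c("enhancer_id", "n_substitutions", "positive_call")],
    as_tibble(snp_table), by = "enhancer_id")
  tibble(enhancer_id = merged$enhancer_id,
         n_substitutions = merged$n_substitutions,
         n_polymorphisms = merged$n_snps,
         positive_call = merged$positive_call)
}

#' Pooled substitution/polymorphism table by positive-selection status
#'
#' @param records tibble from [div_poly_records()].
#' @return List: `table` (2 x 2 integer matrix, rows positive/nonpositive,
#'   columns substitutions/polymorphisms) and `ratios` (per-group
#'   substitutions-to-polymorphisms ratio, NA when a group has zero
#'   polymorphisms).
#' @export
mk_tabulate <- function(records) {
  if (!any(records$positive_call) || !any(!records$positive_call))
    stop("need at least one record in each group (positive and nonpositive)")
  pos <- records[records$positive_call, ]
  non <- records[!records$positive_call, ]
  tab <- matrix(c(sum(pos$n_substitutions), sum(pos$n_polymorphisms),
                  sum(non$n_substitutions), sum(non$n_polymorphisms)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("positive", "nonpositive"),
                                c("substitutions", "polymorphisms")))
  ratio <- function(m) if (m[2] == 0) NA_real_ else unname(m[1] / m[2])
  list(table = tab,
       ratios = c(positive = ratio(tab[1, ]), nonpositive = ratio(tab[2, ])))
}

#' Fisher exact test for an excess of fixed differences
#'
#' Two-sided Fisher exact test of the pooled 2 x 2 substitution/polymorphism
#' table, with the sample odds ratio (ad/bc).
#'
#' @param table 2 x 2 nonnegative integer matrix (rows groups, columns
#'   substitutions/polymorphisms).
#' @return List: `odds_ratio` (NA on zero denominator), `p_value`,
#'   `zero_margin` flag (p = 1 by convention for zero-margin tables).
#' @export
mk_excess_test <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  orr <- if (table[1, 2] * table[2, 1] == 0) NA_real_ else
    (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(odds_ratio = orr, p_value = 1, zero_margin = TRUE))
  list(odds_ratio = orr, p_value = fisher.test(table)$p.value,
       zero_margin = FALSE)
}

#' Per-stage substitution/polymorphism excess summary
#'
#' @param results `selection_test_result` with a `stage` column or a
#'   matching `stages` tibble (`enhancer_id`, `stage`).
#' @param snp_table counts-granularity `snp_table`.
#' @param stages optional tibble mapping enhancer ids to stages.
#' @return Tibble: per stage, pooled counts by group, ratios, odds ratio and
#'   Fisher p.
#' @export
mk_by_stage <- function(results, snp_table, stages = NULL) {
  res <- as_tibble(results)
  if (!is.null(stages))
    res <- dplyr::inner_join(res, stages, by = "enhancer_id")
  stopifnot("stage" %in% names(res))
  rows <- lapply(split(res, res$stage), function(sub) {
    rec <- div_poly_records(sub, snp_table)
    if (!any(rec$positive_call) || !any(!rec$positive_call)) {
      return(tibble(stage = sub$stage[1], subs_pos = NA_integer_,
                    poly_pos = NA_integer_, subs_non = NA_integer_,
                    poly_non = NA_integer_, ratio_pos = NA_real_,
                    ratio_non = NA_real_, odds_ratio = NA_real_,
                    p_value = NA_real_))
    }
    tb <- mk_tabulate(rec)
    ex <- mk_excess_test(tb$table)
    tibble(stage = sub$stage[1],
           subs_pos = tb$table[1, 1], poly_pos = tb$table[1, 2],
           subs_non = tb$table[2, 1], poly_non = tb$table[2, 2],
           ratio_pos = tb$ratios["positive"], ratio_non = tb$ratios["nonpositive"],
           odds_ratio = ex$odds_ratio, p_value = ex$p_value)
  })
  dplyr::bind_rows(rows)
}
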