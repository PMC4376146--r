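# Scoring predicted links against a reference standard: confusion counts,
# test characteristics, and the multi-strategy comparison report with ROC
# operating points.

#' Confusion counts of a link table against a reference standard
#'
#' In the default `per_child` convention each child contributes exactly one
#' cell: a child with a reference mother is a TP when linked to exactly that
#' mother and otherwise an FN (including when linked to the wrong person);
#' a child without a reference mother is an FP when any link is emitted and
#' otherwise a TN. This is the convention under which the marginals of a
#' published strategy table add up (TP+FN = children with a mother, TN+FP =
#' children without). The `strict` convention additionally counts a
#' wrong-person link for a with-mother child as one FP on top of the FN, the
#' usual epidemiological reading; its four cells then sum to more than the
#' cohort size whenever wrong-person links occur.
#'
#' @param links Link tibble from [link_cohort()].
#' @param reference Reference tibble from [read_reference()] or
#'   [simulate_population()].
#' @param mode `"per_child"` (default) or `"strict"`.
#' @return One-row tibble `tp`, `fp`, `tn`, `fn` with attribute `"mode"`.
#' @export
confusion <- function(links, reference, mode = c("per_child", "strict")) {
  mode <- match.arg(mode)
  if (!setequal(links$child_id, reference$child_id) ||
    nrow(links) != nrow(reference)) {
    abort("links and reference must cover the same set of children",
      class = "fairlink_data_error"
    )
  }
  ref <- reference$mother_id[match(links$child_id, reference$child_id)]
  has_ref <- !is.na(ref)
  linked <- !is.na(links$mother_id)
  correct <- has_ref & linked & links$mother_id == ref

  tp <- sum(correct)
  fn <- sum(has_ref) - tp
  tn <- sum(!has_ref & !linked)
  fp <- sum(!has_ref & linked)
  if (mode == "strict") {
    fp <- fp + sum(has_ref & linked & !correct)
  }
  out <- tibble(tp = tp, fp = fp, tn = tn, fn = fn)
  attr(out, "mode") <- mode
  out
}

#' Test characteristics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive predictive
#' value `tp/(tp+fp)` and negative predictive value `tn/(tn+fn)`. A metric
#' whose denominator is zero is undefined and reported as `NA`, never 0.
#' Percentages are rounded half away from zero at the requested precision
#' (`"one_decimal"`, `"whole_percent"`, or `"none"` for unrounded).
#'
#' @param counts One-row tibble (or named list) with `tp`, `fp`, `tn`, `fn`.
#' @param rounding Percentage rendering precision.
#' @return Tibble with one row per metric: `metric`, `numerator`,
#'   `denominator`, `estimate` (proportion in \[0, 1\] or `NA`), `percent`,
#'   and `label` (printed style, e.g. `"264/270 (97.8)"`).
#' @examples
#' test_characteristics(tibble::tibble(tp = 264, fp = 6, tn = 93, fn = 137))
#' @export
test_characteristics <- function(counts,
                                 rounding = c(
                                   "one_decimal", "whole_percent",
                                   "none"
                                 )) {
  rounding <- match.arg(rounding)
  out <- tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv"),
    numerator = c(counts$tp, counts$tn, counts$tp, counts$tn),
    denominator = c(
      counts$tp + counts$fn, counts$tn + counts$fp,
      counts$tp + counts$fp, counts$tn + counts$fn
    )
  )
  out$estimate <- ifelse(out$denominator > 0,
    out$numerator / out$denominator, NA_real_
  )
  out$percent <- switch(rounding,
    none = 100 * out$estimate,
    one_decimal = round_half_away(100 * out$estimate, 1),
    whole_percent = round_half_away(100 * out$estimate, 0)
  )
  out$label <- ifelse(is.na(out$estimate), "NA",
    sprintf(
      "%d/%d (%s)", out$numerator, out$denominator,
      format(out$percent,
        trim = TRUE,
        nsmall = if (rounding == "one_decimal") 1 else 0
      )
    )
  )
  out
}

#' Compare match strategies against a reference standard
#'
#' Runs [link_cohort()] once per strategy, scores each against the reference
#' standard, and collects confusion counts, the four test characteristics
#' (with table-style percentage renderings: one decimal for sensitivity,
#' PPV and NPV; whole percent for specificity) and the ROC operating point
#' (1 - specificity, sensitivity) per strategy. When a simulator annotation
#' table is supplied the report also carries per-stratum sensitivity and
#' specificity by generative flag (safety-net insurance, phone churn,
#' multi-unit address, stepmother presence), which is how the mechanism of
#' each failure mode is inspected.
#'
#' @param patients Patient tibble.
#' @param cohort Character vector of child ids.
#' @param reference Reference standard covering the cohort.
#' @param strategies List of [match_strategy()] objects (default: the six
#'   study strategies).
#' @param params A [classifier_params()].
#' @param rules A [normalization_rules()].
#' @param annotations Optional per-child annotation tibble from
#'   [simulate_population()].
#' @param mode Confusion counting convention, see [confusion()].
#' @return A `fair_comparison` object with fields `results` (per-strategy
#'   counts and metrics), `roc` (operating points), `strata` (or `NULL`),
#'   and `links` (named list of per-strategy link tables). Supports
#'   [tidy()], [glance()], [autoplot()] and `print()`.
#' @export
compare_strategies <- function(patients, cohort, reference,
                               strategies = study_strategies(),
                               params,
                               rules = normalization_rules(),
                               annotations = NULL,
                               mode = c("per_child", "strict")) {
  mode <- match.arg(mode)
  if (length(strategies) == 0) {
    abort("need at least one strategy", class = "fairlink_config_error")
  }
  ref <- reference[reference$child_id %in% cohort, , drop = FALSE]

  links <- lapply(strategies, function(s) {
    link_cohort(patients, cohort, s, params, rules)
  })
  names(links) <- vapply(strategies, `[[`, character(1), "name")

  rows <- purrr::imap(links, function(lk, nm) {
    cc <- confusion(lk, ref, mode)
    tc <- test_characteristics(cc, rounding = "none")
    est <- stats::setNames(tc$estimate, tc$metric)
    tibble(
      strategy = nm,
      tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
      sensitivity = est[["sensitivity"]],
      specificity = est[["specificity"]],
      ppv = est[["ppv"]],
      npv = est[["npv"]],
      sensitivity_pct = round_half_away(100 * est[["sensitivity"]], 1),
      specificity_pct = round_half_away(100 * est[["specificity"]], 0),
      ppv_pct = round_half_away(100 * est[["ppv"]], 1),
      npv_pct = round_half_away(100 * est[["npv"]], 1)
    )
  })
  results <- dplyr::bind_rows(rows)

  roc <- tibble(
    strategy = results$strategy,
    fpr = 1 - results$specificity,
    tpr = results$sensitivity
  )

  strata <- NULL
  if (!is.null(annotations)) {
    flags <- intersect(
      c(
        "safety_net", "family_plan", "phone_churned", "multi_unit",
        "stepmother"
      ),
      names(annotations)
    )
    strata <- purrr::map_dfr(names(links), function(nm) {
      purrr::map_dfr(flags, function(fl) {
        purrr::map_dfr(c(FALSE, TRUE), function(lv) {
          ids <- annotations$child_id[annotations[[fl]] == lv]
          ids <- intersect(ids, cohort)
          if (length(ids) == 0) {
            return(tibble())
          }
          cc <- confusion(
            links[[nm]][links[[nm]]$child_id %in% ids, , drop = FALSE],
            ref[ref$child_id %in% ids, , drop = FALSE],
            mode
          )
          tc <- test_characteristics(cc, rounding = "none")
          tibble(
            strategy = nm, stratum = fl, level = lv,
            n = length(ids), tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
            sensitivity = tc$estimate[tc$metric == "sensitivity"],
            specificity = tc$estimate[tc$metric == "specificity"]
          )
        })
      })
    })
  }

  structure(
    list(
      results = results, roc = roc, strata = strata, links = links,
      n_children = length(cohort),
      prevalence = mean(!is.na(ref$mother_id)),
      mode = mode
    ),
    class = "fair_comparison"
  )
}

#' @export
print.fair_comparison <- function(x, ...) {
  cat(sprintf(
    "<fair_comparison> %d strategies on %d children (prevalence %.1f%%, %s mode)\n",
    nrow(x$results), x$n_children, 100 * x$prevalence, x$mode
  ))
  print(x$results[, c(
    "strategy", "tp", "fp", "tn", "fn",
    "sensitivity_pct", "specificity_pct", "ppv_pct", "npv_pct"
  )])
  invisible(x)
}

#' Tidy a strategy comparison
#'
#' @param x A `fair_comparison` object.
#' @param ... Unused.
#' @return The per-strategy results tibble (counts, proportions and
#'   table-style percentages).
#' @method tidy fair_comparison
#' @export
tidy.fair_comparison <- function(x, ...) {
  x$results
}

#' One-row summary of a strategy comparison
#'
#' @inheritParams tidy.fair_comparison
#' @return One-row tibble with cohort size, reference prevalence, counting
#'   mode, number of strategies, and the strategy with the largest Youden
#'   index (sensitivity + specificity - 1).
#' @method glance fair_comparison
#' @export
glance.fair_comparison <- function(x, ...) {
  youden <- x$results$sensitivity + x$results$specificity - 1
  tibble(
    n_children = x$n_children,
    prevalence = x$prevalence,
    mode = x$mode,
    n_strategies = nrow(x$results),
    best_youden_strategy = x$results$strategy[which.max(youden)],
    best_youden = max(youden, na.rm = TRUE)
  )
}

#' ROC operating points of a strategy comparison
#'
#' The deterministic strategies are not threshold-ordered, so this is a
#' scatter of one operating point per strategy in (1 - specificity,
#' sensitivity) space; no curve is interpolated and no AUC is defined.
#'
#' @param object A `fair_comparison` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fair_comparison
#' @export
autoplot.fair_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object$roc,
    ggplot2::aes(x = .data$fpr, y = .data$tpr, label = .data$strategy)
  ) +
    ggplot2::geom_abline(
      slope = 1, intercept = 0,
      linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = "Operating points of the match strategies"
    ) +
    ggplot2::theme_minimal()
}

#' Render a comparison as a printed-style characteristics table
#'
#' One row per strategy with `n (%)` renderings: sensitivity and specificity
#' as `numerator (percent)`, PPV and NPV as `num/den (percent)`.
#'
#' @param comparison A `fair_comparison` object.
#' @return Tibble of formatted strings.
#' @export
characteristics_table <- function(comparison) {
  r <- comparison$results
  fmt1 <- function(p) format(p, trim = TRUE, nsmall = 1)
  tibble(
    strategy = r$strategy,
    sensitivity = sprintf("%d (%s)", r$tp, fmt1(r$sensitivity_pct)),
    specificity = sprintf(
      "%d (%s)", r$tn,
      format(r$specificity_pct, trim = TRUE)
    ),
    ppv = sprintf("%d/%d (%s)", r$tp, r$tp + r$fp, fmt1(r$ppv_pct)),
    npv = sprintf("%d/%d (%s)", r$tn, r$tn + r$fn, fmt1(r$npv_pct))
  )
}
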