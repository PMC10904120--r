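## ---------------------------------------------------------------------------
## Population analysis: subgroup summaries, direct standardization to a
## reference population, and deprivation-gradient gaps.
## ---------------------------------------------------------------------------

#' Age bands at entry
#'
#' Default 5-year bands from 40 to 70 (`"40-44"` ... `"65-69"`), open-ended
#' `"70+"` above and `"<40"` below.
#'
#' @param age numeric ages.
#' @param breaks lower band edges (default `seq(40, 70, 5)`).
#' @return character band labels.
#' @export
age_band <- function(age, breaks = seq(40, 70, 5)) {
  lo <- breaks[-length(breaks)]
  hi <- breaks[-1] - 1
  labels <- c(paste0("<", breaks[1]), sprintf("%d-%d", lo, hi),
              paste0(breaks[length(breaks)], "+"))
  labels[1 + findInterval(age, breaks)]
}

#' Summarize simulation results by category
#'
#' Per-category means of remaining life years and QALYs (10-year, 20-year,
#' lifetime) over persons and replicates, with counts. Categories must
#' partition the cohort: every person maps to exactly one category.
#'
#' @param summary a `sim_summary` from [run_microsimulation()].
#' @param cohort the cohort that produced it.
#' @param by character vector of grouping dimensions: any of `"sex"`,
#'   `"age_band"`, `"quintile"`, `"cvd_history"`, or a cohort column name;
#'   alternatively a factor/vector of length n via `categories`.
#' @param categories optional explicit category assignment (one non-missing
#'   value per person); overrides `by`.
#' @return data frame with grouping columns, `n`, and mean outcome columns.
#' @export
summarize_by_category <- function(summary, cohort,
                                  by = c("sex", "age_band", "quintile"),
                                  categories = NULL) {
  p <- summary$person
  stopifnot(nrow(p) == nrow(cohort))
  if (!is.null(categories)) {
    if (length(categories) != nrow(cohort) || anyNA(categories)) {
      cvd_error("cvd_partition_error",
                "categories must assign every person to exactly one category")
    }
    cat_df <- data.frame(category = as.character(categories))
  } else {
    cols <- lapply(by, function(b) {
      switch(b,
             age_band = age_band(cohort$age_entry),
             quintile = cohort$townsend_quintile,
             cvd_history = ifelse(has_cvd_history(cohort), "cvd", "no_cvd"),
             {
               if (is.null(cohort[[b]])) {
                 cvd_error("cvd_partition_error",
                           paste0("unknown category dimension: ", b))
               }
               cohort[[b]]
             })
    })
    cat_df <- stats::setNames(as.data.frame(cols), by)
    if (anyNA(cat_df)) {
      cvd_error("cvd_partition_error", "missing category value")
    }
  }
  key <- interaction(cat_df, drop = TRUE, sep = "\r")
  meas <- c("life_years", "qalys", "life_years_10y", "qalys_10y",
            "life_years_20y", "qalys_20y")
  out <- do.call(rbind, lapply(split(seq_len(nrow(p)), key), function(ix) {
    cbind(cat_df[ix[1], , drop = FALSE], n = length(ix),
          as.data.frame(lapply(p[ix, meas], mean)))
  }))
  rownames(out) <- NULL
  out
}

#' Directly standardize category means to a reference population
#'
#' Weighted average of sex x age band x quintile cell means with normalized
#' reference weights, collapsible to any margin (e.g. per quintile across sex
#' and age). A positive-weight reference cell with no estimate is an error
#' unless `missing_policy = "drop"`, which drops the cell and renormalizes
#' (logged in attribute `dropped_cells`).
#'
#' @param category_means output of [summarize_by_category()] with grouping
#'   columns `sex`, `age_band`, `quintile`.
#' @param reference a [reference_population()].
#' @param margin columns to retain (default `"quintile"`); empty character
#'   vector collapses to a single standardized value.
#' @param measures outcome columns to standardize.
#' @param missing_policy `"error"` (default) or `"drop"`.
#' @return data frame of standardized means by the margin.
#' @export
standardize_means <- function(category_means, reference,
                              margin = "quintile",
                              measures = c("life_years", "qalys",
                                           "life_years_10y", "qalys_10y",
                                           "life_years_20y", "qalys_20y"),
                              missing_policy = c("error", "drop")) {
  missing_policy <- match.arg(missing_policy)
  need <- c("sex", "age_band", "quintile")
  if (!all(need %in% names(category_means))) {
    cvd_error("cvd_config_error",
              "category means must be grouped by sex, age_band and quintile")
  }
  measures <- intersect(measures, names(category_means))
  ref <- as.data.frame(reference)
  ref <- ref[ref$weight > 0, , drop = FALSE]
  m <- merge(ref, category_means,
             by.x = c("sex", "age_band", "quintile"),
             by.y = c("sex", "age_band", "quintile"), all.x = TRUE)
  unmatched <- is.na(m[[measures[1]]])
  dropped <- m[unmatched, c("sex", "age_band", "quintile")]
  if (any(unmatched)) {
    if (missing_policy == "error") {
      cvd_error("cvd_missing_cell_error",
                sprintf("%d positive-weight reference cell(s) have no estimate (e.g. %s/%s/q%s); use missing_policy='drop' to renormalize",
                        sum(unmatched), dropped$sex[1], dropped$age_band[1],
                        dropped$quintile[1]))
    }
    m <- m[!unmatched, , drop = FALSE]
  }
  key <- if (length(margin)) {
    interaction(m[margin], drop = TRUE, sep = "\r")
  } else {
    factor(rep("all", nrow(m)))
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(m)), key), function(ix) {
    w <- m$weight[ix] / sum(m$weight[ix])
    cbind(if (length(margin)) m[ix[1], margin, drop = FALSE] else
            data.frame(margin = "all"),
          as.data.frame(lapply(m[ix, measures, drop = FALSE],
                               function(v) sum(w * v))))
  }))
  rownames(out) <- NULL
  attr(out, "dropped_cells") <- dropped
  out
}

#' Deprivation-gradient gap
#'
#' Signed gap between the least and most deprived quintiles (quintile 1 minus
#' quintile 5) in standardized means, for each measure; all five quintiles
#' must be present.
#'
#' @param standardized output of [standardize_means()] with a `quintile`
#'   column (optionally further stratified by other margin columns).
#' @param measures outcome columns.
#' @return data frame of gaps (one row per stratum of the non-quintile
#'   margins, or a single row).
#' @export
gradient_gap <- function(standardized,
                         measures = intersect(c("life_years", "qalys",
                                                "life_years_10y", "qalys_10y",
                                                "life_years_20y", "qalys_20y"),
                                              names(standardized))) {
  if (!"quintile" %in% names(standardized)) {
    cvd_error("cvd_config_error", "standardized means must include quintile")
  }
  strata_cols <- setdiff(names(standardized), c("quintile", measures))
  key <- if (length(strata_cols)) {
    interaction(standardized[strata_cols], drop = TRUE, sep = "\r")
  } else {
    factor(rep("all", nrow(standardized)))
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(standardized)), key),
                               function(ix) {
    s <- standardized[ix, , drop = FALSE]
    if (!all(1:5 %in% s$quintile)) {
      cvd_error("cvd_config_error", "all five quintiles must be present")
    }
    q1 <- s[s$quintile == 1, measures, drop = FALSE]
    q5 <- s[s$quintile == 5, measures, drop = FALSE]
    gaps <- stats::setNames(as.data.frame(as.list(unlist(q1) - unlist(q5))),
                            paste0(measures, "_gap"))
    if (length(strata_cols)) cbind(s[1, strata_cols, drop = FALSE], gaps)
    else gaps
  }))
  rownames(out) <- NULL
  out
}
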