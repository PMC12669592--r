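# Item preparation: reverse coding, composite scores, the missingness
# threshold information-score trade-off, complete-case filtering,
# zero-variance removal and standardisation.

#' Reverse-code flagged items
#'
#' Maps each reverse-flagged item `x` to `scale_min + scale_max - x` so that
#' higher values point in the construct direction; missing values stay
#' missing, unflagged items are untouched. Applying the operation twice
#' returns the original dataset.
#'
#' @param ds An [item_dataset()].
#' @return The dataset with flagged items reflected (flags retained in the
#'   metadata so the operation remains an involution).
#' @export
reverse_code <- function(ds) {
  stopifnot(inherits(ds, "item_dataset"))
  meta <- ds$item_meta
  flagged <- which(meta$reverse)
  if (length(flagged) == 0) return(ds)
  bad <- flagged[is.na(meta$scale_min[flagged]) | is.na(meta$scale_max[flagged])]
  if (length(bad)) {
    stop_npdim("reverse-flagged items without scale bounds: ",
               paste(meta$item[bad], collapse = ", "))
  }
  items <- ds$items
  for (j in flagged) {
    items[, j] <- meta$scale_min[j] + meta$scale_max[j] - items[, j]
  }
  item_dataset(items, meta, ds$covariates)
}

#' Per-scale composite scores
#'
#' Sums item responses within each scale. In strict mode (the default) a
#' participant's total is missing whenever any constituent item is missing;
#' composites are reporting conveniences and take no part in factor analysis.
#'
#' @param ds An [item_dataset()] (reverse coding should already be applied).
#' @param scale_map Named list `scale -> character vector of items`; defaults
#'   to the questionnaire blocks in the item metadata.
#' @param strict Propagate missingness (default `TRUE`); otherwise sum over
#'   observed items.
#' @return Data.frame `participant_id` plus one total column per scale.
#' @export
composite_scores <- function(ds, scale_map = NULL, strict = TRUE) {
  stopifnot(inherits(ds, "item_dataset"))
  if (is.null(scale_map)) {
    scale_map <- split(ds$item_meta$item, ds$item_meta$block)
  }
  empties <- names(scale_map)[lengths(scale_map) == 0]
  if (length(empties)) {
    stop_npdim("empty scales in scale_map: ", paste(empties, collapse = ", "))
  }
  out <- data.frame(participant_id = ds$covariates$participant_id)
  for (s in names(scale_map)) {
    vars <- scale_map[[s]]
    miss <- setdiff(vars, colnames(ds$items))
    if (length(miss)) {
      stop_npdim("scale '", s, "' refers to unknown items: ",
                 paste(miss, collapse = ", "))
    }
    m <- ds$items[, vars, drop = FALSE]
    out[[s]] <- rowSums(m, na.rm = !strict)
    if (!strict) {
      all_na <- rowSums(!is.na(m)) == 0
      out[[s]][all_na] <- NA_real_
    }
  }
  out
}

#' Missingness-threshold information-score trade-off
#'
#' For each candidate threshold `t` (a minimum number of non-missing
#' observations per variable), keeps the variables observed at least `t`
#' times, counts the complete cases `n(t)` over the kept variables, and
#' scores the operating point as `info(t) = v(t) * n(t) / max(n)` — the
#' number of retained variables multiplied by the sample size normalised
#' across thresholds. The selected threshold maximises the information
#' score; ties prefer more retained variables, then the smaller threshold.
#'
#' @param ds An [item_dataset()].
#' @param grid Numeric vector of candidate thresholds. Values in (0, 1) are
#'   read as fractions of the row count and converted to absolute counts.
#' @return Object of class `tradeoff_result`: data.frame `grid` (threshold,
#'   n_vars, complete_case_n, info_score, selected), `selected` threshold,
#'   `retained_vars` at the selected threshold.
#' @export
threshold_tradeoff <- function(ds, grid) {
  stopifnot(inherits(ds, "item_dataset"))
  if (length(grid) == 0) stop_npdim("grid must be non-empty")
  n <- nrow(ds$items)
  thresholds <- ifelse(grid > 0 & grid < 1, ceiling(grid * n), grid)
  thresholds <- as.numeric(thresholds)
  nonmiss <- colSums(!is.na(ds$items))
  rows <- lapply(thresholds, function(t) {
    keep <- nonmiss >= t
    v <- sum(keep)
    cc <- if (v == 0) 0L else
      sum(rowSums(is.na(ds$items[, keep, drop = FALSE])) == 0)
    list(threshold = t, n_vars = v, complete_case_n = cc,
         vars = colnames(ds$items)[keep])
  })
  tab <- data.frame(threshold = vapply(rows, `[[`, 0, "threshold"),
                    n_vars = vapply(rows, `[[`, 0, "n_vars"),
                    complete_case_n = vapply(rows, `[[`, 0, "complete_case_n"))
  if (all(tab$n_vars == 0)) {
    stop_npdim("every threshold in the grid drops all variables ",
               "(max non-missing count is ", max(nonmiss), ")")
  }
  max_n <- max(tab$complete_case_n)
  tab$info_score <- if (max_n > 0) tab$n_vars * tab$complete_case_n / max_n
                    else rep(0, nrow(tab))
  # argmax with deterministic tie-breaks: more variables, then smaller t
  ord <- order(-tab$info_score, -tab$n_vars, tab$threshold)
  sel <- ord[1]
  tab$selected <- seq_len(nrow(tab)) == sel
  structure(list(grid = tab, selected = tab$threshold[sel],
                 retained_vars = rows[[sel]]$vars,
                 complete_case_n = tab$complete_case_n[sel]),
            class = "tradeoff_result")
}

#' @export
print.tradeoff_result <- function(x, ...) {
  cat("<tradeoff_result> selected threshold:", x$selected,
      "->", length(x$retained_vars), "variables,",
      x$complete_case_n, "complete cases\n")
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' Complete-case filtering and zero-variance removal
#'
#' `complete_case_filter()` drops participants with any missing value among
#' `vars` and restricts the item table to those variables.
#' `drop_zero_variance()` then removes items with zero sample variance.
#' Both emit a removal log attribute (`attr(, "removal_log")`) and reject
#' datasets that would end up empty; applying the pair twice equals once.
#'
#' @param ds An [item_dataset()].
#' @param vars Variables to require complete (default: all items).
#' @return The filtered dataset.
#' @export
complete_case_filter <- function(ds, vars = colnames(ds$items)) {
  stopifnot(inherits(ds, "item_dataset"))
  unknown <- setdiff(vars, colnames(ds$items))
  if (length(unknown)) {
    stop_npdim("unknown variables: ", paste(unknown, collapse = ", "))
  }
  sub <- subset_item_dataset(ds, vars = vars)
  keep <- rowSums(is.na(sub$items)) == 0
  if (!any(keep)) stop_npdim("complete-case filter removes every participant")
  out <- subset_item_dataset(sub, rows = which(keep))
  attr(out, "removal_log") <- list(op = "complete_case_filter",
                                   rows_dropped = sum(!keep),
                                   vars_kept = vars)
  out
}

#' @rdname complete_case_filter
#' @export
drop_zero_variance <- function(ds) {
  stopifnot(inherits(ds, "item_dataset"))
  v <- apply(ds$items, 2, stats::var, na.rm = TRUE)
  zero <- !is.na(v) & v == 0
  if (!any(zero)) {
    attr(ds, "removal_log") <- list(op = "drop_zero_variance",
                                    vars_dropped = character(0))
    return(ds)
  }
  if (all(zero)) stop_npdim("all variables have zero variance")
  out <- subset_item_dataset(ds, vars = colnames(ds$items)[!zero])
  attr(out, "removal_log") <- list(op = "drop_zero_variance",
                                   vars_dropped = colnames(ds$items)[zero])
  out
}

#' Standardise item columns
#'
#' Z-scores each column, either against its own mean/SD or against supplied
#' reference statistics (e.g. the control group's, so cross-group mean
#' differences survive into projected factor scores).
#'
#' @param x Numeric matrix or [item_dataset()] (its `items` are used).
#' @param reference_stats Optional list with `mean` and `sd` named per column.
#' @return List with `z` (matrix) and `stats` (the means/SDs used).
#' @export
standardize_items <- function(x, reference_stats = NULL) {
  if (inherits(x, "item_dataset")) x <- x$items
  x <- as.matrix(x)
  if (is.null(reference_stats)) {
    mu <- colMeans(x, na.rm = TRUE)
    sd <- apply(x, 2, stats::sd, na.rm = TRUE)
  } else {
    mu <- reference_stats$mean[colnames(x)]
    sd <- reference_stats$sd[colnames(x)]
    if (anyNA(mu) || anyNA(sd)) {
      stop_npdim("reference_stats missing entries for some columns")
    }
  }
  if (any(sd <= 0 | !is.finite(sd))) {
    stop_npdim("zero or non-finite SD in columns: ",
               paste(colnames(x)[sd <= 0 | !is.finite(sd)], collapse = ", "),
               " (drop zero-variance items first)")
  }
  z <- sweep(sweep(x, 2, mu, "-"), 2, sd, "/")
  list(z = z, stats = list(mean = mu, sd = sd))
}

#' Standard item-preparation chain
#'
#' Convenience wrapper running reverse coding, the missingness trade-off
#' (optional), complete-case filtering, zero-variance removal and
#' standardisation in the pipeline order, for a single group.
#'
#' @param ds An [item_dataset()].
#' @param grid Optional threshold grid for [threshold_tradeoff()]; `NULL`
#'   keeps all items and just requires complete cases.
#' @param reference_stats Optional standardisation reference (see
#'   [standardize_items()]).
#' @return List with `dataset` (filtered [item_dataset()]), `z` (standardised
#'   matrix), `stats`, `tradeoff` (or `NULL`).
#' @export
prepare_items <- function(ds, grid = NULL, reference_stats = NULL) {
  ds <- reverse_code(ds)
  tr <- NULL
  vars <- colnames(ds$items)
  if (!is.null(grid)) {
    tr <- threshold_tradeoff(ds, grid)
    vars <- tr$retained_vars
  }
  ds <- complete_case_filter(ds, vars)
  ds <- drop_zero_variance(ds)
  st <- standardize_items(ds, reference_stats)
  list(dataset = ds, z = st$z, stats = st$stats, tradeoff = tr)
}
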