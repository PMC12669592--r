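#' Participant-by-item questionnaire dataset
#'
#' The universal input container of the pipeline: an ordinal item response
#' table, per-item metadata (questionnaire block, scale range, reverse-coding
#' flag) and participant covariates. Item values must lie within the declared
#' scale range or be missing; covariates carry one row per participant, aligned
#' with the item table.
#'
#' @param items Numeric matrix or data.frame, participants x items. Integer
#'   ordinal responses (missing allowed). Continuous values are accepted when
#'   the item metadata declares no scale bounds (e.g. undigitised synthetic
#'   items).
#' @param item_meta Data.frame with columns `item`, `block`, `scale_min`,
#'   `scale_max`, `reverse` (logical). `scale_min`/`scale_max` may be `NA` for
#'   continuous items.
#' @param covariates Data.frame with at least `participant_id` and `group`;
#'   typically also `age`, `gender`, `education`, `centre`, genotype carrier
#'   flags and `age_at_diagnosis`.
#' @return An object of class `item_dataset` with elements `items` (numeric
#'   matrix), `item_meta` and `covariates`.
#' @export
item_dataset <- function(items, item_meta, covariates) {
  items <- as.matrix(items)
  storage.mode(items) <- "double"
  if (is.null(colnames(items))) {
    colnames(items) <- item_meta$item
  }
  need_meta <- c("item", "block", "scale_min", "scale_max", "reverse")
  if (!all(need_meta %in% names(item_meta))) {
    stop_npdim("item_meta must have columns: ", paste(need_meta, collapse = ", "))
  }
  if (!identical(colnames(items), as.character(item_meta$item))) {
    stop_npdim("items columns must match item_meta$item (same order)")
  }
  if (!all(c("participant_id", "group") %in% names(covariates))) {
    stop_npdim("covariates must contain participant_id and group")
  }
  if (nrow(covariates) != nrow(items)) {
    stop_npdim("covariates and items must have one aligned row per participant")
  }
  if (anyDuplicated(covariates$participant_id)) {
    stop_npdim("duplicate participant_id in covariates")
  }
  # range check only where bounds are declared
  for (j in seq_len(ncol(items))) {
    lo <- item_meta$scale_min[j]; hi <- item_meta$scale_max[j]
    if (!is.na(lo) && !is.na(hi)) {
      v <- items[, j]
      bad <- !is.na(v) & (v < lo | v > hi)
      if (any(bad)) {
        stop_npdim("item '", item_meta$item[j], "' has values outside [",
                   lo, ", ", hi, "]")
      }
    }
  }
  structure(list(items = items, item_meta = item_meta, covariates = covariates),
            class = "item_dataset")
}

#' @export
print.item_dataset <- function(x, ...) {
  cat("<item_dataset> ", nrow(x$items), " participants x ", ncol(x$items),
      " items (", length(unique(x$item_meta$block)), " blocks)\n", sep = "")
  cat("  groups: ", paste(names(table(x$covariates$group)), "=",
                          as.integer(table(x$covariates$group)),
                          collapse = ", "), "\n", sep = "")
  miss <- mean(is.na(x$items))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.item_dataset <- function(x) dim(x$items)

#' Subset an item dataset
#'
#' Restricts an [item_dataset()] to chosen participants (rows) and/or items
#' (columns), keeping the item metadata and covariates aligned.
#'
#' @param ds An [item_dataset()].
#' @param rows Integer or logical row index (participants); `NULL` keeps all.
#' @param vars Character vector of item names; `NULL` keeps all.
#' @return The subsetted `item_dataset`.
#' @export
subset_item_dataset <- function(ds, rows = NULL, vars = NULL) {
  items <- ds$items
  meta <- ds$item_meta
  cov <- ds$covariates
  if (!is.null(vars)) {
    idx <- match(vars, colnames(items))
    if (anyNA(idx)) stop_npdim("unknown items: ",
                               paste(vars[is.na(idx)], collapse = ", "))
    items <- items[, idx, drop = FALSE]
    meta <- meta[idx, , drop = FALSE]
  }
  if (!is.null(rows)) {
    items <- items[rows, , drop = FALSE]
    cov <- cov[rows, , drop = FALSE]
  }
  item_dataset(items, meta, cov)
}

#' Write / read an item dataset as tab-delimited text
#'
#' Serialises the three tables (`items` joined with `participant_id`,
#' `item_meta`, `covariates`) under a common file stem:
#' `<stem>_items.tsv`, `<stem>_item_meta.tsv`, `<stem>_covariates.tsv`.
#'
#' @param ds An [item_dataset()].
#' @param stem File path stem (directory must exist).
#' @return `write_item_dataset()` returns the stem invisibly;
#'   `read_item_dataset()` an `item_dataset`.
#' @export
write_item_dataset <- function(ds, stem) {
  it <- data.frame(participant_id = ds$covariates$participant_id,
                   ds$items, check.names = FALSE)
  write_tsv_table(it, paste0(stem, "_items.tsv"))
  write_tsv_table(ds$item_meta, paste0(stem, "_item_meta.tsv"))
  write_tsv_table(ds$covariates, paste0(stem, "_covariates.tsv"))
  invisible(stem)
}

#' @rdname write_item_dataset
#' @export
read_item_dataset <- function(stem) {
  it <- read_tsv_table(paste0(stem, "_items.tsv"))
  meta <- read_tsv_table(paste0(stem, "_item_meta.tsv"))
  cov <- read_tsv_table(paste0(stem, "_covariates.tsv"))
  items <- as.matrix(it[, -1, drop = FALSE])
  if (!identical(it$participant_id, cov$participant_id)) {
    stop_npdim("items and covariates tables disagree on participant order")
  }
  item_dataset(items, meta, cov)
}
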