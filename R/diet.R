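#' Read long-format diet records
#'
#' Expects columns `species`, `study`, `prey_item`, `importance` and
#' optionally `life_stage` ("adult"/"juvenile"). Importances are proportions
#' in \[0, 1\]; a (species, study) pair may sum to less than 1 (unclassified
#' remainder) but not materially more.
#'
#' @param path CSV file path.
#' @return A validated data frame of diet records.
#' @export
read_diet_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_diet_records(df)
}

#' @rdname read_diet_records
#' @param records A data frame of diet records.
#' @export
validate_diet_records <- function(records) {
  need <- c("species", "study", "prey_item", "importance")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop_validation(paste("missing columns:", paste(miss, collapse = ", ")))
  if (any(records$importance < 0)) stop_validation("negative importance")
  tot <- tapply(records$importance, paste(records$species, records$study, sep = "\r"), sum)
  if (any(tot > 1 + 1e-6)) {
    stop_validation("per (species, study) importances sum to more than 1")
  }
  if (!"life_stage" %in% names(records)) records$life_stage <- "adult"
  records
}

#' Equal importance for a descriptive diet account
#'
#' Diet descriptions that list prey items without quantifying them are
#' converted to records by assigning each listed item importance
#' `1/length(items)`.
#'
#' @param items Character vector of prey-item names.
#' @return Named numeric vector summing to 1.
#' @export
equal_importance <- function(items) {
  if (length(items) == 0L) stop_validation("empty prey-item list")
  stats::setNames(rep(1 / length(items), length(items)), items)
}

#' Aggregate diet records into per-species mean importance profiles
#'
#' Per-item importance is the arithmetic mean across a species' studies (and
#' study partitions, modelled as distinct study ids); an item absent from a
#' study counts as 0 in that study's vector. By default adult records are
#' used, falling back to juvenile records for species that have no adult
#' data.
#'
#' @param records Diet-record data frame (see [read_diet_records()]).
#' @param life_stage `"adult_preferred"` (default), `"adult"`, `"juvenile"`
#'   or `"all"`.
#' @return A species x prey-item matrix of mean importances.
#' @export
aggregate_importances <- function(records, life_stage = "adult_preferred") {
  records <- validate_diet_records(records)
  if (!"life_stage" %in% names(records)) records$life_stage <- "adult"
  records$life_stage[is.na(records$life_stage) | records$life_stage == ""] <- "adult"
  if (life_stage == "adult_preferred") {
    keep <- do.call(rbind, lapply(split(records, records$species), function(r) {
      if (any(r$life_stage == "adult")) r[r$life_stage == "adult", ] else r
    }))
    records <- keep
  } else if (life_stage != "all") {
    records <- records[records$life_stage == life_stage, ]
  }
  if (nrow(records) == 0L) stop_validation("no records left after life-stage filter")
  species <- sort(unique(records$species))
  items <- sort(unique(records$prey_item))
  prof <- matrix(0, length(species), length(items),
                 dimnames = list(species, items))
  for (sp in species) {
    r <- records[records$species == sp, ]
    studies <- unique(r$study)
    acc <- matrix(0, length(studies), length(items),
                  dimnames = list(studies, items))
    for (i in seq_len(nrow(r))) {
      acc[as.character(r$study[i]), r$prey_item[i]] <-
        acc[as.character(r$study[i]), r$prey_item[i]] + r$importance[i]
    }
    prof[sp, ] <- colMeans(acc)
  }
  prof
}

#' Sum per-item importances into per-category importances
#'
#' @param profile Species x prey-item importance matrix.
#' @param categories A `category_set` (see [cut_categories()]), or any data
#'   frame with columns `item` and `category_name`.
#' @return Species x category importance matrix. Row totals are conserved:
#'   the per-category sums equal the per-item sums.
#' @export
categorize_profile <- function(profile, categories) {
  map <- stats::setNames(as.character(categories$category_name), categories$item)
  orphan <- setdiff(colnames(profile), names(map))
  if (length(orphan))
    stop_validation(paste("prey items missing from category set:",
                          paste(orphan, collapse = ", ")))
  cats <- sort(unique(unname(map[colnames(profile)])))
  out <- matrix(0, nrow(profile), length(cats),
                dimnames = list(rownames(profile), cats))
  for (it in colnames(profile)) out[, map[[it]]] <- out[, map[[it]]] + profile[, it]
  out
}

#' Read a species x category importance table
#'
#' Reads a CSV in the layout of the packaged sculpin fixture: one row per
#' species with metadata columns (`habitat`, published `synthetic_category`
#' and `coarse_category` labels, when present) followed by one numeric column
#' per diet category.
#'
#' @param path CSV path.
#' @return List with `importances` (species x category matrix) and `meta`
#'   (data frame of the non-numeric columns).
#' @export
read_category_importances <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  num <- vapply(df, is.numeric, logical(1L))
  imp <- as.matrix(df[, num, drop = FALSE])
  rownames(imp) <- df$species
  list(importances = imp, meta = df[, !num, drop = FALSE])
}

#' Assign each species' primary diet category
#'
#' The primary diet is the category with the largest summed importance.
#' Exact ties are resolved by `tie_rule`:
#' \describe{
#'   \item{`"rare"`}{prefer the category with the smaller dataset-wide total
#'     importance (the rarer niche). Default.}
#'   \item{`"first"`}{prefer the first tied category in column order.}
#'   \item{`"error"`}{fail on any tie.}
#' }
#'
#' @param cat_imp Species x category importance matrix.
#' @param tie_rule Tie-resolution rule, see Details.
#' @return Data frame of class `diet_assignment` with columns `species`,
#'   `category`, `importance` (the winning importance) and `tie`.
#' @export
assign_diet <- function(cat_imp, tie_rule = c("rare", "first", "error")) {
  tie_rule <- match.arg(tie_rule)
  if (any(cat_imp < 0)) stop_validation("negative category importance")
  if (any(rowSums(cat_imp) <= 0)) stop_validation("all-zero importance profile")
  totals <- colSums(cat_imp)
  rows <- lapply(rownames(cat_imp), function(sp) {
    r <- cat_imp[sp, ]
    mx <- max(r)
    winners <- names(r)[r == mx]
    tie <- length(winners) > 1L
    if (tie && tie_rule == "error")
      stop_validation(paste("tied primary diet for", sp))
    win <- if (tie && tie_rule == "rare") {
      winners[which.min(totals[winners])]
    } else winners[1L]
    data.frame(species = sp, category = win, importance = mx, tie = tie,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diet_assignment", "data.frame")
  out
}

#' Assign a coarse diet label by the majority-type rule
#'
#' A species gets the conventional label (insectivore, piscivore, ...) whose
#' mapped prey items make up strictly more than `threshold` of the diet;
#' when no label exceeds the threshold the `fallback` ("omnivore") applies.
#'
#' @param profile Species x prey-item importance matrix.
#' @param type_map Named character vector mapping prey items to coarse
#'   labels.
#' @param threshold Majority threshold (default 0.5, strict).
#' @param fallback Label when no type passes the threshold.
#' @return Named character vector of labels, one per species.
#' @export
assign_coarse <- function(profile, type_map, threshold = 0.5,
                          fallback = "omnivore") {
  unmapped <- setdiff(colnames(profile), names(type_map))
  if (length(unmapped))
    warning("prey items without a coarse type: ",
            paste(unmapped, collapse = ", "))
  labels <- vapply(rownames(profile), function(sp) {
    r <- profile[sp, intersect(colnames(profile), names(type_map))]
    tot <- tapply(r, unname(type_map[names(r)]), sum)
    if (length(tot) && max(tot) > threshold) names(tot)[which.max(tot)] else fallback
  }, character(1L))
  labels
}

#' Summarize how concentrated diets are on single categories
#'
#' @param cat_imp Species x category importance matrix.
#' @param assignment A `diet_assignment` for the same species (computed with
#'   [assign_diet()] if omitted).
#' @param threshold Primary concentration threshold (default 0.5, strict).
#' @param focal Optional focal category for secondary-threshold counts;
#'   defaults to the most common assigned category.
#' @param secondary Secondary thresholds evaluated within the focal
#'   category's species (default 0.70 and 0.90).
#' @return List with `n_species`, `n_concentrated` (species whose maximum
#'   category importance strictly exceeds `threshold`),
#'   `n_unconcentrated`, `category_counts`, `focal`, and `focal_counts`
#'   (data frame with strict `n_over` and inclusive `n_at_least` counts
#'   per secondary threshold; the inclusive count is the natural reading
#'   for values printed at fixed precision).
#' @export
concentration_summary <- function(cat_imp, assignment = assign_diet(cat_imp),
                                  threshold = 0.5, focal = NULL,
                                  secondary = c(0.70, 0.90)) {
  mx <- apply(cat_imp, 1L, max)
  counts <- table(factor(assignment$category, levels = colnames(cat_imp)))
  counts <- sort(counts, decreasing = TRUE)
  if (is.null(focal)) focal <- names(counts)[1L]
  fsp <- assignment$species[assignment$category == focal]
  fimp <- cat_imp[fsp, focal]
  focal_counts <- data.frame(
    threshold = secondary,
    n_over = vapply(secondary, function(s) sum(fimp > s), integer(1L)),
    n_at_least = vapply(secondary, function(s) sum(fimp >= s), integer(1L)))
  list(n_species = nrow(cat_imp),
       n_concentrated = sum(mx > threshold),
       n_unconcentrated = sum(mx <= threshold),
       category_counts = counts,
       focal = focal,
       focal_counts = focal_counts)
}
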