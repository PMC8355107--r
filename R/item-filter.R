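# Item/person filtering applied before item response modelling.

#' Filter an item response table for modelling
#'
#' Applies the two inclusion rules in a fixed, documented order: first drop
#' persons with more than `max_person_missing` missing ratings, then drop
#' items whose valid frequency of 'present' (endorsed / non-missing, among
#' retained persons) is below `min_prevalence`. A report of everything
#' dropped, with reasons, is attached as `attr(, "filter_report")`. The
#' operation is idempotent.
#'
#' @param items tibble with an `id` column and one 0/1/NA column per item.
#' @param min_prevalence minimum valid 'present' frequency (default 0.10;
#'   items at exactly the threshold are kept).
#' @param max_person_missing maximum tolerated missing ratings per person
#'   (default 20; persons at exactly the threshold are kept).
#' @return The filtered tibble (same shape), with `item_map` (if present)
#'   subset accordingly and a `filter_report` attribute.
#' @export
filter_items <- function(items, min_prevalence = 0.10, max_person_missing = 20) {
  item_cols <- setdiff(names(items), "id")
  assert_that(nrow(items) > 0 && length(item_cols) > 0,
              "empty item matrix: nothing to filter")
  X <- as.matrix(items[item_cols])
  assert_that(all(X %in% c(0L, 1L, NA)), "item responses must be 0, 1 or missing")

  n_missing <- rowSums(is.na(X))
  drop_person <- n_missing > max_person_missing
  kept <- X[!drop_person, , drop = FALSE]
  assert_that(nrow(kept) > 0,
              sprintf("all persons exceed the %d-missing-values threshold",
                      max_person_missing))

  prevalence <- colMeans(kept, na.rm = TRUE)
  prevalence[is.nan(prevalence)] <- 0
  drop_item <- prevalence < min_prevalence
  assert_that(!all(drop_item),
              sprintf("all items fall below the %.0f%% valid 'present' threshold",
                      100 * min_prevalence))

  out <- items[!drop_person, c("id", item_cols[!drop_item])]
  map <- attr(items, "item_map")
  if (!is.null(map)) {
    attr(out, "item_map") <- map[map$item %in% item_cols[!drop_item], ]
  }
  attr(out, "filter_report") <- list(
    order = "persons_then_items",
    dropped_persons = tibble(id = items$id[drop_person],
                             n_missing = n_missing[drop_person],
                             reason = sprintf("> %d missing values", max_person_missing)),
    dropped_items = tibble(item = item_cols[drop_item],
                           prevalence = unname(prevalence[drop_item]),
                           reason = sprintf("valid 'present' frequency < %.2f",
                                            min_prevalence)))
  out
}
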