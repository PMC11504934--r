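#' Family-integral, site-stratified train/test split
#'
#' Assigns whole families to the training or testing subsample so that no
#' siblings are separated, stratified by study site: within each site,
#' families are shuffled and accumulated into the training subsample until
#' the training share of that site's children would exceed `ratio`. The
#' realized training fraction per site therefore deviates from `ratio` by at
#' most one family's children.
#'
#' @param cohort A cohort `data.frame` with `participant_id`, `family_id`
#'   and `site_id` columns.
#' @param ratio Target training fraction, in (0, 1).
#' @param seed Integer seed for the family shuffle.
#' @return `cohort` with its `subsample` column set to `"train"`/`"test"`.
#' @export
#' @examples
#' d <- data.frame(participant_id = as.character(1:10),
#'                 family_id = as.character(1:10), site_id = "S01")
#' table(split_train_test(d, 0.5, seed = 1)$subsample)
split_train_test <- function(cohort, ratio = 0.5, seed = 1L) {
  stopifnot(is.data.frame(cohort), ratio > 0, ratio < 1)
  need <- c("participant_id", "family_id", "site_id")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  fams <- unique(cohort$family_id)
  if (length(fams) < 2L)
    stop("cannot split a cohort with a single family", call. = FALSE)

  with_seed(as.integer(seed), {
    assign_train <- character(0)
    for (s in sort(unique(cohort$site_id))) {
      rows <- cohort$site_id == s
      fam_sizes <- table(cohort$family_id[rows])
      fam_names <- sample(names(fam_sizes))
      sizes <- as.integer(fam_sizes[fam_names])
      target <- ratio * sum(sizes)
      cum <- cumsum(sizes)
      # families whose cumulative child count stays within the target
      take <- cum <= target + 1e-9
      # if rounding leaves train empty but a closer-than-not first family
      # exists, taking none is still within one family of the target
      assign_train <- c(assign_train, fam_names[take])
    }
    cohort$subsample <- ifelse(cohort$family_id %in% assign_train,
                               "train", "test")
  })
  cohort
}
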