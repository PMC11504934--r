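#' Read and write cohort tables
#'
#' Cohort tables are UTF-8 comma-delimited files with a header row; missing
#' values are written as empty fields. Identifier columns and `sex` /
#' `subsample` are read as character, everything else as numeric.
#'
#' @param cohort A cohort `data.frame`.
#' @param path File path.
#' @return `read_cohort()` returns a `data.frame`; `write_cohort()` returns
#'   `path` invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  data.table::fwrite(cohort, path, na = "", quote = FALSE, sep = ",")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  char_cols <- c("participant_id", "family_id", "site_id", "subsample", "sex")
  dt <- data.table::fread(path, na.strings = "", sep = ",",
                          colClasses = list(character = char_cols),
                          data.table = FALSE, showProgress = FALSE)
  validate_cohort(dt)
  dt
}

# Structural checks shared by readers and the generator's output contract.
validate_cohort <- function(cohort) {
  need <- c("participant_id", "family_id", "site_id")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) stop("cohort lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$participant_id))
    stop("participant_id values are not unique")
  fam_site <- unique(cohort[, c("family_id", "site_id")])
  if (anyDuplicated(fam_site$family_id))
    stop("a family_id maps to more than one site_id")
  invisible(cohort)
}

#' Read and write simulation ground truth as JSON
#'
#' @param truth A `sim_truth` object.
#' @param path File path.
#' @return `read_truth()` returns a `sim_truth`; `write_truth()` returns
#'   `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "sim_truth"))
  out <- unclass(truth)
  # named vectors must serialize as JSON objects, not bare arrays
  for (f in c("true_beta", "beta_std", "latent_burden",
              "variance_components", "subgroup_shifts", "covariate_beta"))
    out[[f]] <- as.list(out[[f]])
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("true_beta", "beta_std", "latent_burden", "variance_components",
              "subgroup_shifts", "covariate_beta"))
    raw[[f]] <- unlist(raw[[f]])
  raw$exposure_meta <- as.data.frame(raw$exposure_meta,
                                     stringsAsFactors = FALSE)
  raw$collinear_pairs <- lapply(raw$collinear_pairs, unlist)
  structure(raw, class = "sim_truth")
}

#' Read and write ExWAS result tables
#'
#' One row per screened exposure with coefficient, confidence interval,
#' test statistics, FDR-adjusted q-value, direction and significance flag,
#' as a tab-delimited file. This table is the input contract for
#' [compute_scores()].
#'
#' @param exwas An `exwas_result` data frame from [run_exwas()].
#' @param path File path.
#' @return `read_exwas()` returns an `exwas_result`; `write_exwas()` returns
#'   `path` invisibly.
#' @export
write_exwas <- function(exwas, path) {
  stopifnot(is.data.frame(exwas))
  data.table::fwrite(exwas, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_exwas
#' @export
read_exwas <- function(path) {
  dt <- data.table::fread(path, sep = "\t", na.strings = "",
                          data.table = FALSE, showProgress = FALSE)
  class(dt) <- c("exwas_result", "data.frame")
  dt
}

#' Write risk scores as a two-column delimited table
#'
#' @param scores A `score_vector` from [compute_scores()].
#' @param path File path for the `participant_id,z_score` table.
#' @param meta_path Optional path for JSON metadata (score components and
#'   their coefficients).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, meta_path = NULL) {
  stopifnot(is.data.frame(scores))
  data.table::fwrite(scores[, c("participant_id", "z_score")], path,
                     sep = ",", quote = FALSE)
  if (!is.null(meta_path)) {
    meta <- list(n_components = attr(scores, "n_components"),
                 components = attr(scores, "components"))
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  data.table::fread(path, sep = ",", na.strings = "", data.table = FALSE,
                    colClasses = list(character = "participant_id"),
                    showProgress = FALSE)
}

#' Read and write exposure specification tables as JSON
#'
#' @param specs An `exposure_spec` table.
#' @param path File path.
#' @return `read_exposure_specs()` returns an `exposure_spec`;
#'   `write_exposure_specs()` returns `path` invisibly.
#' @export
write_exposure_specs <- function(specs, path) {
  jsonlite::write_json(as.data.frame(specs), path, dataframe = "columns",
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_exposure_specs
#' @export
read_exposure_specs <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_exposure_specs(name = raw$name, measurement = raw$measurement,
                      domain = raw$domain,
                      combine_with = ifelse(is.na(raw$combine_with) |
                                              raw$combine_with == "",
                                            NA_character_, raw$combine_with),
                      outlier_rule_applies = raw$outlier_rule_applies)
}
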