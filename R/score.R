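#' Coefficient-weighted digital exposomic risk scores
#'
#' For each participant in the held-out (testing) subsample, the raw score
#' is the sum over all FDR-significant exposures of the exposure value
#' multiplied by its training-sample mixed-model coefficient — protective
#' (negative) coefficients included with their sign, exposures on the same
#' scale used in the screening fits (no re-standardization). The raw score
#' is then z-scored within the scored subsample for comparability across
#' models; higher scores indicate greater digital exposomic risk.
#'
#' @param test Cohort `data.frame`; rows with `subsample == "test"` are
#'   scored when that column is present. Exposure cells named by the
#'   significant records must be non-missing (impute first).
#' @param exwas An `exwas_result` from [run_exwas()] with at least one
#'   significant record.
#' @return A `score_vector` data frame: `participant_id`, `raw_score`
#'   (outcome-point scale), `z_score`; attributes `n_components` and
#'   `components` (exposure/coefficient table).
#' @export
compute_scores <- function(test, exwas) {
  stopifnot(is.data.frame(exwas))
  if ("subsample" %in% names(test) && any(test$subsample == "test"))
    test <- test[test$subsample == "test", , drop = FALSE]
  sig <- exwas[exwas$significant, , drop = FALSE]
  if (!nrow(sig))
    stop("compute_scores: no significant exposures; score undefined")
  absent <- setdiff(sig$exposure, names(test))
  if (length(absent))
    stop("compute_scores: exposure(s) absent from table: ",
         paste(absent, collapse = ", "))
  X <- as.matrix(test[, sig$exposure, drop = FALSE])
  if (anyNA(X))
    stop("compute_scores: missing exposure values; impute before scoring")
  raw <- as.numeric(X %*% sig$beta)
  s <- sd(raw)
  if (!is.finite(s) || s == 0)
    stop("compute_scores: degenerate score (zero variance)")
  out <- data.frame(participant_id = test$participant_id,
                    raw_score = raw,
                    z_score = (raw - mean(raw)) / s,
                    stringsAsFactors = FALSE)
  attr(out, "n_components") <- nrow(sig)
  attr(out, "components") <- data.frame(exposure = sig$exposure,
                                        beta = sig$beta,
                                        stringsAsFactors = FALSE)
  class(out) <- c("score_vector", "data.frame")
  out
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> %d participants, %d components\n",
              nrow(x), attr(x, "n_components")))
  print(utils::head(as.data.frame(x)), row.names = FALSE)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}
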