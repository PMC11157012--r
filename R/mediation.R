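# Two-step MR mediation decomposition.
#
# beta1: total effect, exposure -> outcome; beta2: exposure -> mediator;
# beta3: mediator -> outcome. The mediated effect is beta2 * beta3 and the
# proportion mediated beta2 * beta3 / beta1. Two rounding profiles are
# exposed: "full_precision" (the analytical default) and
# "published_rounding", which rounds the product to 3 decimals before
# dividing by beta1 and reports the percentage at 2 decimals -- the
# convention needed to reproduce published mediation tables digit for
# digit.

#' Mediation effect decomposition for one triplet
#'
#' @param beta1 total effect (exposure -> outcome), nonzero.
#' @param beta2 exposure -> mediator effect.
#' @param beta3 mediator -> outcome effect.
#' @param profile `"full_precision"` or `"published_rounding"`.
#' @param se2,se3 optional standard errors of beta2/beta3; when both are
#'   given a delta-method SE of the mediated effect,
#'   `sqrt(beta3^2 se2^2 + beta2^2 se3^2)`, is attached (an extension
#'   beyond the published convention, clearly labelled).
#' @param exposure_id,mediator_id,outcome_id labels.
#' @return A list of class `mediation_result`: `beta1..beta3`,
#'   `mediated_effect`, `proportion_pct` (may be negative or exceed 100;
#'   flagged via `proportion_out_of_range`, never clipped),
#'   `rounding_profile`, optional `mediated_se`.
#' @export
mediation_effect <- function(beta1, beta2, beta3,
                             profile = c("full_precision",
                                         "published_rounding"),
                             se2 = NULL, se3 = NULL,
                             exposure_id = NA_character_,
                             mediator_id = NA_character_,
                             outcome_id = NA_character_) {
  profile <- match.arg(profile)
  if (!is.finite(beta1) || beta1 == 0) {
    mr_stop("mr_undefined_proportion",
            "total effect beta1 is zero; proportion mediated undefined")
  }
  if (profile == "published_rounding") {
    mediated <- round(beta2 * beta3, 3)
    pct <- round(100 * mediated / beta1, 2)
  } else {
    mediated <- beta2 * beta3
    pct <- 100 * mediated / beta1
  }
  mediated_se <- if (!is.null(se2) && !is.null(se3)) {
    sqrt(beta3^2 * se2^2 + beta2^2 * se3^2)
  } else NULL
  structure(
    list(exposure_id = exposure_id, mediator_id = mediator_id,
         outcome_id = outcome_id,
         beta1 = beta1, beta2 = beta2, beta3 = beta3,
         mediated_effect = mediated, proportion_pct = pct,
         proportion_out_of_range = pct < 0 || pct > 100,
         rounding_profile = profile, mediated_se = mediated_se),
    class = "mediation_result"
  )
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "<mediation_result> %s -> %s -> %s: b1=%.3f b2=%.3f b3=%.3f mediated=%.3g (%.4g%%)%s\n",
    x$exposure_id, x$mediator_id, x$outcome_id, x$beta1, x$beta2, x$beta3,
    x$mediated_effect, x$proportion_pct,
    if (x$proportion_out_of_range) " [out of 0-100 range]" else ""
  ))
  invisible(x)
}

#' Assemble a mediation table over several triplets
#'
#' One row per exposure-mediator-outcome triplet with beta1, beta2, beta3
#' (reported at 3 decimals), the mediated effect and the mediating ratio.
#' Rows whose mediator -> outcome link was not established upstream (the
#' `established` column is FALSE) are carried with a `not_established`
#' flag and no proportion rather than silently dropped. Established rows
#' with a missing coefficient raise an incomplete-triplet error.
#'
#' @param triplets data.frame with columns `exposure`, `mediator`,
#'   `outcome`, `beta1`, `beta2`, `beta3`, optional logical `established`
#'   (default TRUE).
#' @param profile rounding profile, see [mediation_effect()].
#' @return data.frame with columns `exposure`, `mediator`, `outcome`,
#'   `beta1`, `beta2`, `beta3`, `mediated_effect`, `mediating_ratio_pct`,
#'   `flag`.
#' @export
mediation_table <- function(triplets,
                            profile = c("full_precision",
                                        "published_rounding")) {
  profile <- match.arg(profile)
  needed <- c("exposure", "mediator", "outcome", "beta1", "beta2", "beta3")
  if (!all(needed %in% names(triplets))) {
    mr_stop("mr_config_error", paste0(
      "`triplets` needs columns: ", paste(needed, collapse = ", ")
    ))
  }
  if (!"established" %in% names(triplets)) triplets$established <- TRUE
  out <- data.frame(
    exposure = character(0), mediator = character(0), outcome = character(0),
    beta1 = numeric(0), beta2 = numeric(0), beta3 = numeric(0),
    mediated_effect = numeric(0), mediating_ratio_pct = numeric(0),
    flag = character(0), stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(triplets))) {
    row <- triplets[i, ]
    if (!isTRUE(row$established)) {
      out[nrow(out) + 1L, ] <- list(row$exposure, row$mediator, row$outcome,
                                    row$beta1, row$beta2, NA_real_,
                                    NA_real_, NA_real_, "not_established")
      next
    }
    if (anyNA(c(row$beta1, row$beta2, row$beta3))) {
      mr_stop("mr_incomplete_triplet", paste0(
        "missing upstream estimate for triplet ", row$exposure, " -> ",
        row$mediator, " -> ", row$outcome
      ))
    }
    m <- mediation_effect(row$beta1, row$beta2, row$beta3, profile = profile)
    out[nrow(out) + 1L, ] <- list(
      row$exposure, row$mediator, row$outcome,
      row$beta1, row$beta2, row$beta3,
      m$mediated_effect, m$proportion_pct,
      if (m$proportion_out_of_range) "proportion_out_of_range" else ""
    )
  }
  out
}

#' Write a mediation table to TSV
#'
#' Beta columns at 3 decimals, ratio at 2 decimals, mirroring the
#' conventional published layout.
#'
#' @param tab result of [mediation_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mediation_tsv <- function(tab, path) {
  out <- tab
  for (col in c("beta1", "beta2", "beta3", "mediated_effect")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA",
                         sprintf("%.3f", out[[col]]))
  }
  out$mediating_ratio_pct <- ifelse(is.na(out$mediating_ratio_pct), "NA",
                                    sprintf("%.2f%%",
                                            out$mediating_ratio_pct))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
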