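# Allele harmonization between an exposure and an outcome study.
#
# Both studies must report effects relative to the same effect allele
# before any ratio of outcome to exposure effects is meaningful. Variants
# are matched by rsID; allele-label comparison resolves swapped and
# strand-complemented reports, and allele frequency resolves palindromic
# (A/T, G/C) variants whose strand cannot be read off the labels.

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(a1, a2) .COMPLEMENT[a1] == a2

.HARMONIZE_ACTIONS <- c("unchanged", "sign_flipped", "strand_flipped",
                        "strand_flipped_and_sign_flipped",
                        "dropped_palindromic", "dropped_unmatched")

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the selected variants of two studies onto the exposure's
#' effect-allele convention. For each variant: identical allele labels
#' leave the record unchanged; swapped labels negate the outcome beta and
#' reflect its allele frequency (`sign_flipped`); complement-strand labels
#' are rewritten (`strand_flipped`, with a sign flip when also swapped).
#' Palindromic variants (A/T or G/C) are retained only when allele
#' frequency can confirm the orientation: both studies' frequencies (after
#' label alignment) on the same side of 0.5 and both minor-allele
#' frequencies below `palindromic_maf_limit`; otherwise — including when
#' either frequency is missing or exactly 0.5 — they are
#' `dropped_palindromic`. Variants absent from the outcome study are
#' `dropped_unmatched`. Drops are recorded, never raised as errors.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param snp_ids variant ids to harmonize; must all be present in the
#'   exposure table.
#' @param palindromic_maf_limit strictly between 0 and 0.5; default 0.42.
#'
#' @return An object of class `harmonized_set`: a data.frame with one row
#'   per requested id and columns `variant_id`, `beta_exposure`,
#'   `se_exposure`, `beta_outcome`, `se_outcome`, `eaf` (exposure-study
#'   frequency of the shared effect allele) and `action`; attributes
#'   `exposure_name`, `outcome_name` and `outcome_type`. Only rows whose
#'   action is not `dropped_*` enter the estimators.
#' @export
harmonize <- function(exposure, outcome, snp_ids,
                      palindromic_maf_limit = 0.42) {
  stopifnot(inherits(exposure, "sumstats"), inherits(outcome, "sumstats"))
  if (!(palindromic_maf_limit > 0 && palindromic_maf_limit < 0.5)) {
    stop("palindromic_maf_limit must lie strictly in (0, 0.5)", call. = FALSE)
  }
  snp_ids <- as.character(snp_ids)
  ex <- exposure$records
  ou <- outcome$records
  absent <- setdiff(snp_ids, ex$variant_id)
  if (length(absent)) {
    stop("snp_ids not present in exposure table: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  ei <- match(snp_ids, ex$variant_id)
  oi <- match(snp_ids, ou$variant_id)

  out <- data.frame(
    variant_id = snp_ids,
    beta_exposure = ex$beta[ei],
    se_exposure = ex$se[ei],
    beta_outcome = NA_real_,
    se_outcome = NA_real_,
    eaf = ex$eaf[ei],
    action = NA_character_,
    stringsAsFactors = FALSE
  )

  for (k in seq_along(snp_ids)) {
    if (is.na(oi[k])) {
      out$action[k] <- "dropped_unmatched"
      next
    }
    e1 <- ex$effect_allele[ei[k]]; e2 <- ex$other_allele[ei[k]]
    o1 <- ou$effect_allele[oi[k]]; o2 <- ou$other_allele[oi[k]]
    by <- ou$beta[oi[k]]; sy <- ou$se[oi[k]]; fy <- ou$eaf[oi[k]]
    fx <- ex$eaf[ei[k]]

    if (.is_palindromic(e1, e2)) {
      # label alignment first (swap is indistinguishable from a strand
      # flip here, so the label only fixes the provisional orientation)
      if (o1 == e1 && o2 == e2) {
        act <- "unchanged"
      } else if (o1 == e2 && o2 == e1) {
        act <- "sign_flipped"; by <- -by; fy <- 1 - fy
      } else {
        out$action[k] <- "dropped_unmatched"; next
      }
      ok <- !is.na(fx) && !is.na(fy) &&
        (fx - 0.5) * (fy - 0.5) > 0 &&
        min(fx, 1 - fx) < palindromic_maf_limit &&
        min(fy, 1 - fy) < palindromic_maf_limit
      if (!ok) {
        out$action[k] <- "dropped_palindromic"; next
      }
    } else {
      c1 <- .COMPLEMENT[o1]; c2 <- .COMPLEMENT[o2]
      if (o1 == e1 && o2 == e2) {
        act <- "unchanged"
      } else if (o1 == e2 && o2 == e1) {
        act <- "sign_flipped"; by <- -by; fy <- 1 - fy
      } else if (c1 == e1 && c2 == e2) {
        act <- "strand_flipped"
      } else if (c1 == e2 && c2 == e1) {
        act <- "strand_flipped_and_sign_flipped"; by <- -by; fy <- 1 - fy
      } else {
        out$action[k] <- "dropped_unmatched"; next
      }
    }
    out$beta_outcome[k] <- by
    out$se_outcome[k] <- sy
    out$action[k] <- act
  }

  structure(out,
            exposure_name = exposure$trait_name,
            outcome_name = outcome$trait_name,
            outcome_type = outcome$trait_type,
            class = c("harmonized_set", "data.frame"))
}

#' Retained rows of a harmonized set
#'
#' @param hset a `harmonized_set`.
#' @return The rows whose action is not a drop, as a plain data.frame.
#' @export
retained <- function(hset) {
  keep <- !startsWith(hset$action, "dropped")
  out <- as.data.frame(hset)[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a harmonization audit table
#'
#' One row per requested variant with the action applied, tab-delimited.
#'
#' @param hset a `harmonized_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_harmonization_audit <- function(hset, path) {
  df <- data.frame(variant_id = hset$variant_id, action = hset$action,
                   stringsAsFactors = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  writeLines("variant_id\taction", con)
  writeLines(paste(df$variant_id, df$action, sep = "\t"), con)
  invisible(path)
}
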