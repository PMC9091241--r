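# Instrument selection: genome-wide significance filter, greedy LD
# clumping, proxy substitution, and cross-trait exclusion.

#' Selection parameters
#'
#' Thresholds for instrument selection. Defaults follow standard MR
#' practice: genome-wide significance p < 5e-8, independence r^2 < 0.01,
#' proxies accepted at r^2 > 0.9. The p-value and proxy comparisons are
#' strict inequalities; clumping discards at `r2 >= clump_r2` so the
#' retained set satisfies pairwise `r2 < clump_r2`.
#'
#' @param p_threshold genome-wide significance threshold (strict `<`).
#' @param clump_r2 LD-independence bound.
#' @param proxy_r2_min minimum LD for a proxy (strict `>`).
#' @return An object of class `selection_params`.
#' @export
selection_params <- function(p_threshold = 5e-8, clump_r2 = 0.01,
                             proxy_r2_min = 0.9) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 >= 0, clump_r2 < proxy_r2_min, proxy_r2_min <= 1)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 proxy_r2_min = proxy_r2_min),
            class = "selection_params")
}

#' Filter to genome-wide-significant variants
#'
#' @param table a `sumstats` object.
#' @param p_threshold significance threshold; a variant is retained iff
#'   its p-value is strictly below it.
#' @return Character vector of retained variant ids, in table order. May
#'   be empty.
#' @export
filter_significant <- function(table, p_threshold = 5e-8) {
  stopifnot(inherits(table, "sumstats"))
  rec <- table$records
  rec$variant_id[rec$pvalue < p_threshold]
}

#' Greedy LD clumping
#'
#' Orders candidates by ascending p-value (ties broken lexicographically
#' by variant id), then repeatedly accepts the best remaining variant and
#' discards every remaining variant with `r2 >= clump_r2` against it. The
#' returned set is pairwise `r2 < clump_r2`, and every discarded variant
#' is in LD with some accepted variant. The result depends only on the
#' p-values, ids and panel, not on input order.
#'
#' @param ids candidate variant ids.
#' @param pvalues candidate p-values, same length and order as `ids`.
#' @param panel an `ld_panel` containing every candidate.
#' @param clump_r2 discard threshold.
#' @return Character vector of retained ids, in acceptance (p-value)
#'   order.
#' @export
ld_clump <- function(ids, pvalues, panel, clump_r2 = 0.01) {
  stopifnot(inherits(panel, "ld_panel"), length(ids) == length(pvalues))
  ids <- as.character(ids)
  absent <- setdiff(ids, panel$ids)
  if (length(absent)) {
    stop("candidate(s) absent from LD panel: ",
         paste(utils::head(absent, 5L), collapse = ", "), call. = FALSE)
  }
  if (length(ids) == 0L) return(character(0))
  ord <- order(pvalues, ids)
  ids <- ids[ord]
  kept <- character(0)
  remaining <- ids
  while (length(remaining) > 0L) {
    top <- remaining[1L]
    kept <- c(kept, top)
    remaining <- remaining[-1L]
    if (length(remaining)) {
      remaining <- remaining[panel$r2[top, remaining] < clump_r2]
    }
  }
  kept
}

#' Find a proxy variant in high LD
#'
#' Searches `candidate_ids` for the variant with the highest `r2` against
#' `missing_id`, requiring `r2 > proxy_r2_min` (strict); ties are broken
#' by lexicographically smallest id.
#'
#' @param missing_id the instrument absent from the outcome dataset; must
#'   be in the panel.
#' @param candidate_ids ids available as replacements (e.g. the outcome
#'   dataset's variants).
#' @param panel an `ld_panel`.
#' @param proxy_r2_min minimum LD (strict `>`), default 0.9.
#' @return The proxy id, or `NULL` if none qualifies.
#' @export
find_proxy <- function(missing_id, candidate_ids, panel, proxy_r2_min = 0.9) {
  stopifnot(inherits(panel, "ld_panel"))
  if (!(missing_id %in% panel$ids)) {
    stop("missing_id not in LD panel: ", missing_id, call. = FALSE)
  }
  cand <- setdiff(intersect(as.character(candidate_ids), panel$ids), missing_id)
  if (length(cand) == 0L) return(NULL)
  r2 <- panel$r2[missing_id, cand]
  qual <- r2 > proxy_r2_min
  if (!any(qual)) return(NULL)
  cand <- cand[qual]; r2 <- r2[qual]
  best <- r2 == max(r2)
  sort(cand[best])[1L]
}

#' Orientation of a proxy relative to its index variant
#'
#' Sign of the dosage correlation in the reference panel: `+1` means the
#' counted alleles of the two variants rise together (same orientation),
#' `-1` means opposite. Requires panel dosages.
#'
#' @param panel an `ld_panel` with a dosage matrix.
#' @param index_id,proxy_id variant ids.
#' @return `+1` or `-1`.
#' @export
proxy_orientation <- function(panel, index_id, proxy_id) {
  stopifnot(inherits(panel, "ld_panel"))
  if (is.null(panel$dosage)) stop("panel carries no dosages", call. = FALSE)
  r <- stats::cor(panel$dosage[, index_id], panel$dosage[, proxy_id])
  if (!is.finite(r) || r == 0) stop("dosage correlation undefined between ",
                                    index_id, " and ", proxy_id, call. = FALSE)
  sign(r)
}

#' Remove variants associated with more than one trait
#'
#' A sensitivity filter: drops every variant mapped to two or more traits
#' in the cross-trait table. Variants absent from the table are retained
#' (absence of evidence of multi-trait association).
#'
#' @param ids variant ids.
#' @param xtab a data.frame with columns `variant_id` and `trait`, one row
#'   per known variant-trait association (long format).
#' @return The retained ids, input order preserved.
#' @export
remove_cross_trait <- function(ids, xtab) {
  if (is.null(xtab) || nrow(xtab) == 0L) return(ids)
  stopifnot(all(c("variant_id", "trait") %in% names(xtab)))
  counts <- tapply(xtab$trait, xtab$variant_id, function(tr) length(unique(tr)))
  multi <- names(counts)[counts > 1L]
  ids[!(ids %in% multi)]
}
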