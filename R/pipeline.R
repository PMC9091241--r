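# Study-level orchestration: many exposures x outcomes, selection,
# harmonization, the estimator suite, diagnostics, and multiple-testing
# classification.

#' Bonferroni-corrected significance threshold
#'
#' Family-wise threshold `alpha_family / n_exposures`; the number of
#' outcomes is deliberately not multiplied in (one primary outcome per
#' family of exposures).
#'
#' @param alpha_family family-wise alpha, in (0, 1).
#' @param n_exposures number of exposures tested (>= 1).
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha_family = 0.05, n_exposures) {
  stopifnot(alpha_family > 0, alpha_family < 1)
  if (!(n_exposures >= 1)) stop("n_exposures must be at least 1", call. = FALSE)
  alpha_family / n_exposures
}

#' Classify an association p-value
#'
#' `significant` when p is strictly below the Bonferroni threshold;
#' `suggestive` when it lies in \[bonferroni_p, 0.05); otherwise `null`.
#' A p-value exactly at the Bonferroni threshold is suggestive.
#'
#' @param p the primary (IVW) p-value, in (0, 1].
#' @param bonferroni_p the corrected threshold.
#' @param alpha_upper the upper edge of the suggestive band (default
#'   0.05).
#' @return One of `"significant"`, `"suggestive"`, `"null"`.
#' @export
classify_association <- function(p, bonferroni_p, alpha_upper = 0.05) {
  stopifnot(p > 0, p <= 1)
  if (p < bonferroni_p) "significant"
  else if (p < alpha_upper) "suggestive"
  else "null"
}

#' Study configuration
#'
#' Describes a full MR study: exposures, outcomes (the first is the
#' primary outcome against which every exposure is tested; additional
#' outcomes are strata re-run for exposures significant on the primary),
#' the LD panel, selection thresholds and the multiple-testing family.
#'
#' @param exposures data.frame with columns `name`, `path`, `trait_type`.
#' @param outcomes data.frame with the same columns; first row = primary.
#' @param panel an `ld_panel` or a path readable by [read_ld_panel()].
#' @param params a [selection_params()].
#' @param alpha_family family-wise alpha (default 0.05).
#' @param methods estimators to run besides IVW (always run as primary).
#' @param n_boot bootstrap replicates for the median estimators.
#' @param cross_trait optional cross-trait association table (data.frame
#'   with `variant_id`, `trait`, or a TSV path) triggering the
#'   multi-trait-variant sensitivity rerun.
#' @param palindromic_maf_limit forwarded to [harmonize()].
#' @param seed integer seed; all bootstrap draws are derived from it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(exposures, outcomes, panel,
                         params = selection_params(),
                         alpha_family = 0.05,
                         methods = c("egger", "simple_median", "weighted_median"),
                         n_boot = 1000L,
                         cross_trait = NULL,
                         palindromic_maf_limit = 0.42,
                         seed = 1L) {
  exposures <- as.data.frame(exposures, stringsAsFactors = FALSE)
  outcomes <- as.data.frame(outcomes, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "path", "trait_type") %in% names(exposures)),
            all(c("name", "path", "trait_type") %in% names(outcomes)),
            nrow(exposures) >= 1, nrow(outcomes) >= 1,
            alpha_family > 0, alpha_family < 1,
            inherits(params, "selection_params"))
  structure(list(exposures = exposures, outcomes = outcomes, panel = panel,
                 params = params, alpha_family = alpha_family,
                 methods = methods, n_boot = as.integer(n_boot),
                 cross_trait = cross_trait,
                 palindromic_maf_limit = palindromic_maf_limit,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Read / write a study configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_study_config`: a `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("exposures", "outcomes", "panel")
  miss <- setdiff(need, names(y))
  if (length(miss)) stop("study config missing field(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  as_df <- function(x) do.call(rbind, lapply(x, function(e)
    data.frame(name = e$name, path = e$path, trait_type = e$trait_type,
               stringsAsFactors = FALSE)))
  params <- selection_params(
    p_threshold = y$p_threshold %||% 5e-8,
    clump_r2 = y$clump_r2 %||% 0.01,
    proxy_r2_min = y$proxy_r2_min %||% 0.9)
  study_config(as_df(y$exposures), as_df(y$outcomes), y$panel,
               params = params,
               alpha_family = y$alpha_family %||% 0.05,
               methods = y$methods %||% c("egger", "simple_median", "weighted_median"),
               n_boot = y$n_boot %||% 1000L,
               cross_trait = y$cross_trait,
               palindromic_maf_limit = y$palindromic_maf_limit %||% 0.42,
               seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname read_study_config
#' @param config a `study_config` whose `panel` and `cross_trait` entries
#'   are file paths.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"), is.character(config$panel))
  as_list <- function(df) lapply(seq_len(nrow(df)), function(i)
    list(name = df$name[i], path = df$path[i], trait_type = df$trait_type[i]))
  y <- list(exposures = as_list(config$exposures),
            outcomes = as_list(config$outcomes),
            panel = config$panel,
            p_threshold = config$params$p_threshold,
            clump_r2 = config$params$clump_r2,
            proxy_r2_min = config$params$proxy_r2_min,
            alpha_family = config$alpha_family,
            methods = config$methods,
            n_boot = config$n_boot,
            palindromic_maf_limit = config$palindromic_maf_limit,
            seed = config$seed)
  if (!is.null(config$cross_trait)) y$cross_trait <- config$cross_trait
  yaml::write_yaml(y, path)
  invisible(path)
}

.fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.10g", x))

.write_tsv <- function(df, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  cols <- lapply(df, function(col) {
    if (is.numeric(col) && !is.integer(col)) .fmt_num(col) else {
      out <- as.character(col); out[is.na(out)] <- "NA"; out
    }
  })
  if (nrow(df)) writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

# deterministic per-task bootstrap seed below 2^31
.derive_seed <- function(seed, i, o, m) {
  as.integer((as.numeric(seed) * 7919 + i * 104729 + o * 1299709 + m * 17) %%
               2147483629)
}

.empty_call_row <- function(exposure, outcome, analysis, status) {
  data.frame(exposure = exposure, outcome = outcome, analysis = analysis,
             method = NA_character_, n_snps = 0L,
             estimate = NA_real_, se = NA_real_, ci_low = NA_real_,
             ci_high = NA_real_, pvalue = NA_real_, or = NA_real_,
             or_ci_low = NA_real_, or_ci_high = NA_real_,
             egger_intercept = NA_real_, egger_intercept_p = NA_real_,
             verdict = NA_character_, status = status,
             stringsAsFactors = FALSE)
}

#' Run a full MR study
#'
#' For every exposure: select genome-wide-significant variants, clump them
#' to LD independence, substitute proxies for instruments missing from
#' the outcome dataset, harmonize alleles, run the configured estimator
#' suite plus the MR-Egger intercept test, leave-one-out and
#' instrument-strength diagnostics, and classify the primary (IVW)
#' p-value against the Bonferroni threshold. Exposures significant on the
#' primary outcome are re-run, with the same instrument set, on each
#' additional outcome; when a cross-trait table is supplied, a
#' sensitivity rerun excludes multi-trait variants. An exposure with no
#' surviving instruments is recorded as `no_instruments` and the study
#' continues. Given a seed the run is fully reproducible.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory; when given, the master TSV
#'   (`master.tsv`) and per-exposure audit files are written there.
#' @return An object of class `study_report`: list with `calls` (the
#'   master data.frame: one row per exposure x outcome x method),
#'   `bonferroni_p`, and `details` (per-exposure selection counts,
#'   diagnostics and leave-one-out tables).
#' @export
run_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "study_config"))
  panel <- config$panel
  if (is.character(panel)) panel <- read_ld_panel(panel)
  stopifnot(inherits(panel, "ld_panel"))
  xtab <- config$cross_trait
  if (is.character(xtab)) {
    xtab <- utils::read.table(xtab, header = TRUE, sep = "\t",
                              stringsAsFactors = FALSE)
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  outcomes <- lapply(seq_len(nrow(config$outcomes)), function(o) {
    read_sumstats(config$outcomes$path[o],
                  trait_name = config$outcomes$name[o],
                  trait_type = config$outcomes$trait_type[o])
  })
  n_exp <- nrow(config$exposures)
  bonf <- bonferroni_threshold(config$alpha_family, n_exp)
  prm <- config$params

  all_rows <- list()
  details <- list()

  analyse_pair <- function(ex, instruments, outcome, o_idx, i_idx, analysis,
                           audit_prefix = NULL) {
    exposure_name <- ex$trait_name
    out_ids <- outcome$records$variant_id
    missing <- setdiff(instruments, out_ids)
    proxied <- character(0)
    unproxied <- character(0)
    final <- instruments
    for (m in missing) {
      cand <- intersect(out_ids, ex$records$variant_id)
      pr <- find_proxy(m, cand, panel, prm$proxy_r2_min)
      if (!is.null(pr) && !(pr %in% final)) {
        final[final == m] <- pr
        proxied <- c(proxied, pr)
      } else {
        final <- setdiff(final, m)
        unproxied <- c(unproxied, m)
      }
    }
    if (length(final) == 0L) {
      return(list(rows = .empty_call_row(exposure_name, outcome$trait_name,
                                         analysis, "no_instruments"),
                  detail = list(n_selected = length(instruments), n_proxied = 0L,
                                n_dropped_unproxied = length(unproxied),
                                n_harmonized = 0L)))
    }
    hset <- harmonize(ex, outcome, final,
                      palindromic_maf_limit = config$palindromic_maf_limit)
    if (!is.null(audit_prefix)) {
      write_harmonization_audit(hset, paste0(audit_prefix, "_harmonization.tsv"))
    }
    ret <- retained(hset)
    J <- nrow(ret)
    if (J == 0L) {
      return(list(rows = .empty_call_row(exposure_name, outcome$trait_name,
                                         analysis, "no_instruments"),
                  detail = list(n_selected = length(instruments),
                                n_proxied = length(proxied),
                                n_dropped_unproxied = length(unproxied),
                                n_harmonized = 0L)))
    }

    ivw <- mr_ivw(hset, model = if (J >= 2L) "multiplicative_random" else "fixed")
    verdict <- classify_association(ivw$pvalue, bonf)
    results <- list(ivw)
    egger <- NULL
    if ("egger" %in% config$methods && J >= 3L) {
      egger <- mr_egger(hset)
      results <- c(results, list(egger$slope))
    }
    if ("simple_median" %in% config$methods && J >= 3L) {
      results <- c(results, list(
        mr_median(hset, "simple", n_boot = config$n_boot,
                  seed = .derive_seed(config$seed, i_idx, o_idx, 1L))))
    }
    if ("weighted_median" %in% config$methods && J >= 3L) {
      results <- c(results, list(
        mr_median(hset, "inverse_variance", n_boot = config$n_boot,
                  seed = .derive_seed(config$seed, i_idx, o_idx, 2L))))
    }
    rows <- do.call(rbind, lapply(results, as.data.frame))
    rows <- cbind(data.frame(exposure = exposure_name,
                             outcome = outcome$trait_name,
                             analysis = analysis, stringsAsFactors = FALSE),
                  rows)
    rows$egger_intercept <- NA_real_
    rows$egger_intercept_p <- NA_real_
    if (!is.null(egger)) {
      rows$egger_intercept[rows$method == "egger"] <- egger$intercept
      rows$egger_intercept_p[rows$method == "egger"] <- egger$intercept_pvalue
    }
    rows$verdict <- NA_character_
    rows$verdict[rows$method %in% c("ivw_mre", "ivw_fe")] <- verdict
    rows$status <- "ok"

    n_per <- ex$records$n[match(ret$variant_id, ex$records$variant_id)]
    diag <- instrument_diagnostics(hset, n_per,
                                   n_fallback = max(ex$records$n))
    loo <- if (J >= 2L) leave_one_out(hset, threshold = 0.05) else NULL
    if (!is.null(audit_prefix) && !is.null(loo)) {
      .write_tsv(loo$results, paste0(audit_prefix, "_leave_one_out.tsv"))
    }
    list(rows = rows,
         detail = list(n_selected = length(instruments),
                       n_proxied = length(proxied),
                       n_dropped_unproxied = length(unproxied),
                       n_harmonized = J, diagnostics = diag, loo = loo,
                       verdict = verdict))
  }

  for (i in seq_len(n_exp)) {
    ename <- config$exposures$name[i]
    ex <- read_sumstats(config$exposures$path[i], trait_name = ename,
                        trait_type = config$exposures$trait_type[i])
    sig <- filter_significant(ex, prm$p_threshold)
    in_panel <- intersect(sig, panel$ids)
    pv <- ex$records$pvalue[match(in_panel, ex$records$variant_id)]
    clumped <- ld_clump(in_panel, pv, panel, prm$clump_r2)

    audit_prefix <- if (!is.null(out_dir))
      file.path(out_dir, sprintf("exposure_%03d", i)) else NULL
    if (!is.null(audit_prefix)) {
      status <- ifelse(ex$records$variant_id %in% clumped, "kept",
                ifelse(ex$records$variant_id %in% sig, "clumped",
                       "below_threshold"))
      # name the accepting variant for each clumped candidate
      clump_by <- rep(NA_character_, nrow(ex$records))
      for (v in setdiff(intersect(sig, panel$ids), clumped)) {
        hit <- clumped[panel$r2[v, clumped] >= prm$clump_r2][1L]
        clump_by[ex$records$variant_id == v] <- hit
        status[ex$records$variant_id == v] <- paste0("clumped_by:", hit)
      }
      .write_tsv(data.frame(variant_id = ex$records$variant_id,
                            status = status, stringsAsFactors = FALSE),
                 paste0(audit_prefix, "_selection.tsv"))
    }

    if (length(clumped) == 0L) {
      all_rows[[length(all_rows) + 1L]] <-
        .empty_call_row(ename, outcomes[[1L]]$trait_name, "main", "no_instruments")
      details[[ename]] <- list(n_significant = length(sig), n_clumped = 0L)
      next
    }

    main <- analyse_pair(ex, clumped, outcomes[[1L]], 1L, i, "main",
                         audit_prefix)
    all_rows[[length(all_rows) + 1L]] <- main$rows
    det <- c(list(n_significant = length(sig), n_clumped = length(clumped)),
             main$detail)

    if (identical(main$detail$verdict, "significant") &&
        length(outcomes) > 1L) {
      for (o in seq_along(outcomes)[-1L]) {
        strat <- analyse_pair(ex, clumped, outcomes[[o]], o, i, "stratum")
        all_rows[[length(all_rows) + 1L]] <- strat$rows
      }
    }
    if (!is.null(xtab)) {
      kept <- remove_cross_trait(clumped, xtab)
      if (length(kept) < length(clumped) && length(kept) > 0L) {
        sens <- analyse_pair(ex, kept, outcomes[[1L]], 1L, i, "cross_trait")
        all_rows[[length(all_rows) + 1L]] <- sens$rows
      }
    }
    details[[ename]] <- det
  }

  calls <- do.call(rbind, all_rows)
  rownames(calls) <- NULL
  report <- structure(list(calls = calls, bonferroni_p = bonf,
                           details = details, config = config),
                      class = "study_report")
  if (!is.null(out_dir)) {
    .write_tsv(calls, file.path(out_dir, "master.tsv"))
    diag_rows <- do.call(rbind, lapply(names(details), function(nm) {
      d <- details[[nm]]$diagnostics
      if (is.null(d)) return(NULL)
      data.frame(exposure = nm, n = d$n, k = d$k, r2_total = d$r2_total,
                 F = d$f_stat, stringsAsFactors = FALSE)
    }))
    if (!is.null(diag_rows)) {
      .write_tsv(diag_rows, file.path(out_dir, "diagnostics.tsv"))
    }
  }
  report
}

#' @export
print.study_report <- function(x, ...) {
  primary <- x$calls[x$calls$analysis == "main" &
                       (x$calls$method %in% c("ivw_mre", "ivw_fe") |
                          is.na(x$calls$method)), , drop = FALSE]
  cat(sprintf("MR study: %d exposure(s), Bonferroni threshold %.3g\n",
              nrow(primary), x$bonferroni_p))
  tab <- table(factor(primary$verdict,
                      levels = c("significant", "suggestive", "null")))
  cat(sprintf("  significant %d, suggestive %d, null %d, no instruments %d\n",
              tab[1L], tab[2L], tab[3L], sum(primary$status == "no_instruments")))
  invisible(x)
}
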