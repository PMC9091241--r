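# Reading, validating and writing GWAS summary-statistics tables.
#
# A table is stored as an S3 object of class "sumstats": a list with the
# trait metadata and a data.frame of per-variant association records in a
# fixed canonical column order.

.SUMSTATS_COLS <- c("variant_id", "chrom", "pos", "effect_allele",
                    "other_allele", "eaf", "beta", "se", "pvalue", "n")

# Default header names accepted on disk (GWAS-SSF-like), canonical -> file.
.DEFAULT_COLUMN_MAP <- c(
  variant_id   = "variant_id",
  chrom        = "chromosome",
  pos          = "base_pair_location",
  effect_allele = "effect_allele",
  other_allele = "other_allele",
  eaf          = "effect_allele_frequency",
  beta         = "beta",
  se           = "standard_error",
  pvalue       = "p_value",
  n            = "n"
)

#' Construct a validated summary-statistics table
#'
#' Builds a `sumstats` object from a data.frame of per-variant association
#' records. Rows violating the record invariants (non-SNV or identical
#' alleles, `se <= 0`, p-value outside (0, 1], `n <= 2`, `pos < 1`, allele
#' frequency outside \[0, 1\]) are dropped and counted; alleles are
#' uppercased first. Only single-base A/C/G/T alleles are accepted —
#' indels are rejected as invalid rows.
#'
#' @param records data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf` (may be `NA`), `beta`, `se`,
#'   `pvalue`, `n`.
#' @param trait_name trait label.
#' @param trait_type `"continuous"` or `"binary"` (effects on the log-odds
#'   scale for binary traits).
#' @param ancestry ancestry label (free text).
#'
#' @return An object of class `sumstats`: a list with elements
#'   `trait_name`, `trait_type`, `ancestry`, `records` (the retained rows)
#'   and `n_dropped` (named integer vector of drop counts by reason).
#' @export
sumstats_table <- function(records, trait_name, trait_type = c("continuous", "binary"),
                           ancestry = "unspecified") {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.SUMSTATS_COLS, names(records))
  if (length(missing_cols) > 0L) {
    stop("records is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  rec <- records[, .SUMSTATS_COLS, drop = FALSE]
  rec$variant_id <- as.character(rec$variant_id)
  rec$chrom <- as.character(rec$chrom)
  rec$pos <- as.integer(rec$pos)
  rec$effect_allele <- toupper(as.character(rec$effect_allele))
  rec$other_allele <- toupper(as.character(rec$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue")) rec[[col]] <- as.numeric(rec[[col]])
  rec$n <- as.integer(rec$n)

  ok_allele <- rec$effect_allele %in% c("A", "C", "G", "T") &
    rec$other_allele %in% c("A", "C", "G", "T")
  drops <- c(
    bad_allele    = sum(!ok_allele | rec$effect_allele == rec$other_allele, na.rm = FALSE),
    bad_se        = sum(!(is.finite(rec$se) & rec$se > 0)),
    bad_pvalue    = sum(!(is.finite(rec$pvalue) & rec$pvalue > 0 & rec$pvalue <= 1)),
    bad_n         = sum(!(is.finite(rec$n) & rec$n > 2)),
    bad_pos       = sum(!(is.finite(rec$pos) & rec$pos >= 1)),
    bad_eaf       = sum(!(is.na(rec$eaf) | (rec$eaf >= 0 & rec$eaf <= 1))),
    bad_beta      = sum(!is.finite(rec$beta))
  )
  keep <- (ok_allele & !is.na(rec$effect_allele) & rec$effect_allele != rec$other_allele) &
    is.finite(rec$se) & rec$se > 0 &
    is.finite(rec$pvalue) & rec$pvalue > 0 & rec$pvalue <= 1 &
    !is.na(rec$n) & rec$n > 2 &
    !is.na(rec$pos) & rec$pos >= 1 &
    (is.na(rec$eaf) | (rec$eaf >= 0 & rec$eaf <= 1)) &
    is.finite(rec$beta)
  keep[is.na(keep)] <- FALSE
  rec <- rec[keep, , drop = FALSE]
  rownames(rec) <- NULL

  if (anyDuplicated(rec$variant_id)) {
    stop("duplicate variant_id in table: ",
         rec$variant_id[duplicated(rec$variant_id)][1L], call. = FALSE)
  }

  structure(
    list(trait_name = trait_name, trait_type = trait_type,
         ancestry = ancestry, records = rec,
         n_dropped = drops[drops > 0L]),
    class = "sumstats"
  )
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s, %s)\n",
              x$trait_name, x$trait_type, x$ancestry))
  cat(sprintf("  %d variants", nrow(x$records)))
  if (length(x$n_dropped)) {
    cat(sprintf(" (%d rows dropped on validation)", sum(x$n_dropped)))
  }
  cat("\n")
  invisible(x)
}

#' Read a GWAS summary-statistics file
#'
#' Reads a tab- or comma-delimited association table with a header row,
#' maps its columns onto the canonical record layout and validates every
#' row. Invalid rows are dropped and counted (reported via a message and
#' stored in the returned object); a file with no valid rows is an error.
#'
#' @param path file path.
#' @param trait_name trait label; defaults to the file name without
#'   extension.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param column_map named character vector mapping canonical field names
#'   (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`,
#'   `beta`, `se`, `pvalue`, `n`) to the file's header names; entries
#'   omitted fall back to the GWAS-SSF-like defaults
#'   (`variant_id`, `chromosome`, `base_pair_location`, `effect_allele`,
#'   `other_allele`, `effect_allele_frequency`, `beta`, `standard_error`,
#'   `p_value`, `n`).
#' @param ancestry ancestry label.
#'
#' @return A `sumstats` object.
#' @export
read_sumstats <- function(path, trait_name = NULL,
                          trait_type = c("continuous", "binary"),
                          column_map = NULL, ancestry = "unspecified") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(trait_name)) trait_name <- sub("\\.[^.]*$", "", basename(path))

  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, na.strings = "NA",
                           colClasses = NA, check.names = FALSE,
                           comment.char = "", quote = "")

  cmap <- .DEFAULT_COLUMN_MAP
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(cmap))
    if (length(unknown)) {
      stop("column_map contains unknown field(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    cmap[names(column_map)] <- column_map
  }
  missing <- cmap[!(cmap %in% names(raw))]
  if (length(missing)) {
    stop("missing mandatory column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records <- raw[, unname(cmap), drop = FALSE]
  names(records) <- names(cmap)

  tab <- sumstats_table(records, trait_name = trait_name,
                        trait_type = trait_type, ancestry = ancestry)
  if (nrow(tab$records) == 0L) {
    stop("no valid rows in ", basename(path), call. = FALSE)
  }
  if (length(tab$n_dropped)) {
    message(sprintf("read_sumstats: dropped %d invalid row(s) from %s [%s]",
                    sum(tab$n_dropped), basename(path),
                    paste(names(tab$n_dropped), tab$n_dropped,
                          sep = "=", collapse = ", ")))
  }
  tab
}

#' Write a summary-statistics table
#'
#' Writes a `sumstats` object as a tab-delimited file in the same dialect
#' `read_sumstats` accepts by default. Missing allele frequencies are
#' encoded as the literal string `NA`. Numeric fields are written with
#' full double precision so that `read_sumstats(write_sumstats(x))`
#' reproduces `x` field-by-field.
#'
#' @param table a `sumstats` object with at least one record.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path) {
  stopifnot(inherits(table, "sumstats"))
  if (nrow(table$records) == 0L) {
    stop("refusing to write a table with zero records", call. = FALSE)
  }
  rec <- table$records
  fmt_num <- function(x) ifelse(is.na(x), "NA", sprintf("%.17g", x))
  out <- data.frame(
    variant_id = rec$variant_id,
    chromosome = rec$chrom,
    base_pair_location = rec$pos,
    effect_allele = rec$effect_allele,
    other_allele = rec$other_allele,
    effect_allele_frequency = fmt_num(rec$eaf),
    beta = fmt_num(rec$beta),
    standard_error = fmt_num(rec$se),
    p_value = fmt_num(rec$pvalue),
    n = rec$n,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(out), sep = "\t")), con)
  invisible(path)
}
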