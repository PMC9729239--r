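#' Construct a summary-statistics table
#'
#' A `summary_stats` object is a validated data frame of per-variant association
#' records for one trait (an exposure such as a DNAm probe, a candidate
#' mediator such as a cis transcript, or a GWAS outcome). Effects are kept on
#' the standardized (SD-unit) scale via [standardize_effects()].
#'
#' @param records data frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#'   Missing `beta`/`se` are reconstructed from `z` and `n` when a `z` column
#'   is present.
#' @param trait_id trait identifier.
#' @param trait_role one of `"exposure"`, `"mediator"`, `"outcome"`.
#' @param n_default sample size used where `n` is missing.
#' @param feature_chrom,feature_pos genomic anchor of the molecular feature
#'   (probe position for DNAm exposures, TSS for transcripts); used for cis
#'   windows.
#' @param validate drop invalid rows (with a message) rather than erroring.
#' @return a data frame of class `summary_stats` with attributes `trait_id`,
#'   `trait_role`, `feature_chrom`, `feature_pos`.
#' @export
summary_stats <- function(records, trait_id, trait_role = c("exposure", "mediator", "outcome"),
                          n_default = NULL, feature_chrom = NA_integer_,
                          feature_pos = NA_integer_, validate = TRUE) {
  trait_role <- match.arg(trait_role)
  records <- as.data.frame(records, stringsAsFactors = FALSE)

  if ((!"beta" %in% names(records) || !"se" %in% names(records)) &&
      "z" %in% names(records)) {
    nn <- if ("n" %in% names(records)) records$n else NULL
    if (is.null(nn) && is.null(n_default)) {
      stop("table provides z-scores but no sample size n (and no n_default)")
    }
    if (is.null(nn)) nn <- rep(n_default, nrow(records))
    records$beta <- records$z / sqrt(nn)
    records$se <- 1 / sqrt(nn)
    if (!"n" %in% names(records)) records$n <- nn
  }
  mandatory <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
                 "beta", "se")
  missing_cols <- setdiff(mandatory, names(records))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"n" %in% names(records)) {
    if (is.null(n_default)) stop("missing column n and no n_default supplied")
    records$n <- n_default
  }
  records$n[is.na(records$n)] <- if (is.null(n_default)) NA_integer_ else n_default
  if (!"eaf" %in% names(records)) records$eaf <- NA_real_
  if (!"pvalue" %in% names(records)) {
    records$pvalue <- 2 * stats::pnorm(-abs(records$beta / records$se))
  }
  records$effect_allele <- toupper(records$effect_allele)
  records$other_allele <- toupper(records$other_allele)
  records$chrom <- suppressWarnings(as.integer(gsub("^chr", "", records$chrom)))

  if (validate && nrow(records)) {
    nuc <- c("A", "C", "G", "T")
    ok <- records$effect_allele %in% nuc & records$other_allele %in% nuc &
      records$effect_allele != records$other_allele &
      !is.na(records$beta) & !is.na(records$se) & records$se > 0 &
      !is.na(records$pos) & !is.na(records$n) & records$n > 0 &
      (is.na(records$eaf) | (records$eaf >= 0 & records$eaf <= 1)) &
      !is.na(records$pvalue) & records$pvalue > 0 & records$pvalue <= 1
    ok[is.na(ok)] <- FALSE
    if (any(!ok)) {
      message(sum(!ok), " record(s) failed validation and were dropped (",
              trait_id, ")")
      records <- records[ok, , drop = FALSE]
    }
    if (anyDuplicated(records$variant_id)) {
      # multi-allelic / duplicated sites: drop all copies (conservative)
      dup <- records$variant_id %in% records$variant_id[duplicated(records$variant_id)]
      message(sum(dup), " duplicated/multi-allelic record(s) dropped (", trait_id, ")")
      records <- records[!dup, , drop = FALSE]
    }
    if (!nrow(records)) stop("no valid records left in table '", trait_id, "'")
    zp <- abs(stats::qnorm(records$pvalue / 2)) - abs(records$beta / records$se)
    zp <- zp[is.finite(zp)]
    if (length(zp) && max(abs(zp)) > 0.1) {
      warning("p-values inconsistent with |beta/se| by > 0.1 for ",
              sum(abs(zp) > 0.1), " record(s) in '", trait_id, "'", call. = FALSE)
    }
  }
  rownames(records) <- NULL
  structure(records,
            trait_id = trait_id, trait_role = trait_role,
            feature_chrom = feature_chrom, feature_pos = feature_pos,
            class = c("summary_stats", "data.frame"))
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("<summary_stats> trait '", attr(x, "trait_id"), "' (",
      attr(x, "trait_role"), "), ", nrow(x), " variants\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  invisible(x)
}

trait_id <- function(x) attr(x, "trait_id")
trait_role <- function(x) attr(x, "trait_role")

# rebuild a summary_stats from a row subset, keeping attributes
ss_subset <- function(x, i) {
  summary_stats(as.data.frame(x)[i, , drop = FALSE], attr(x, "trait_id"),
                attr(x, "trait_role"),
                feature_chrom = attr(x, "feature_chrom"),
                feature_pos = attr(x, "feature_pos"), validate = FALSE)
}

#' Read a delimited summary-statistics file
#'
#' Reads a tab-delimited (optionally gzipped) GWAS-SSF-like table. Column names
#' are configurable through `dialect`, a named character vector mapping
#' internal names (`variant_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele`, `eaf`, `beta`, `se`, `z`, `pvalue`, `n`) to the file's
#' column names. Tables carrying `(z, n)` instead of `(beta, se)` are
#' standardized on read (`beta = z/sqrt(n)`, `se = 1/sqrt(n)`).
#'
#' @param path file path.
#' @param trait_id,trait_role,n_default,feature_chrom,feature_pos see
#'   [summary_stats()].
#' @param dialect named character vector of column-name overrides.
#' @param sep field separator (default tab).
#' @return a [summary_stats()] table.
#' @export
read_summary_stats <- function(path, trait_id = basename(path),
                               trait_role = "exposure", dialect = NULL,
                               n_default = NULL, feature_chrom = NA_integer_,
                               feature_pos = NA_integer_, sep = "\t") {
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(dialect)) {
    for (internal in names(dialect)) {
      file_col <- dialect[[internal]]
      if (!file_col %in% names(raw)) {
        stop("dialect maps '", internal, "' to missing column '", file_col, "'")
      }
      names(raw)[names(raw) == file_col] <- internal
    }
  }
  summary_stats(raw, trait_id = trait_id, trait_role = trait_role,
                n_default = n_default, feature_chrom = feature_chrom,
                feature_pos = feature_pos)
}

#' Write a summary-statistics table
#'
#' @param x a [summary_stats()] table.
#' @param path output path (tab-delimited).
#' @export
write_summary_stats <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Standardize effects to the SD scale
#'
#' Z-scores are divided by the square root of the sample size so that all
#' traits are on the same per-SD scale: `beta' = z/sqrt(n)`, `se' = 1/sqrt(n)`.
#' After standardization `var(beta) = 1/n` exactly, the variance convention
#' used throughout the estimators. The operation is idempotent (z = beta/se is
#' unchanged).
#'
#' @param x a [summary_stats()] table with `n` present.
#' @return the standardized table.
#' @export
standardize_effects <- function(x) {
  if (any(is.na(x$n))) stop("sample size n missing; cannot standardize")
  z <- x$beta / x$se
  x$beta <- z / sqrt(x$n)
  x$se <- 1 / sqrt(x$n)
  x
}
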