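# Local / mobile / migrant classification and cohort statistics.

# comparisons of Sr ratios happen at the field's printed 5-decimal precision
r5 <- function(x) round(x, 5)

# half-up rounding for report tables (the convention used by printed tables;
# base round() is half-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classify one individual as local, mobile or migrant
#'
#' An individual is \emph{local} when the enamel \eqn{^{87}Sr/^{86}Sr} ratio
#' lies within the 99\% HDI local range of the burial region (bounds compared
#' at 5-decimal precision; values exactly on a bound count as local --
#' conservative non-local calling). A non-local is a \emph{mobile} when the
#' ratio fits strictly inside the range of at least one other region of the
#' macro study area, and a \emph{migrant} only when every other region can be
#' excluded and the value also falls outside the macro-regional range. A
#' non-local inside the macro range but matching no named region is counted
#' mobile (origin within the macro area cannot be excluded) and flagged.
#' A missing value yields \emph{indeterminate}.
#'
#' @param value Enamel \eqn{^{87}Sr/^{86}Sr} ratio, or \code{NA}.
#' @param burial_region Region code of the burial site.
#' @param ranges Named list of \code{local_range}, one per region (must
#'   include \code{burial_region}).
#' @param macro \code{local_range} for the macro region.
#' @return A one-row data.frame: \code{status}, \code{burial_region},
#'   \code{value}, \code{matched_regions} (comma-joined), \code{direction}
#'   (\code{above}/\code{below}/\code{within} the burial range).
#' @export
#' @examples
#' rg <- published_sr_ranges()
#' classify_individual(0.71481, "AED", rg$regional, rg$macro)$status
classify_individual <- function(value, burial_region, ranges, macro) {
  if (!burial_region %in% names(ranges)) {
    stop("unknown burial region: ", burial_region, call. = FALSE)
  }
  if (is.na(value)) {
    return(data.frame(status = "indeterminate", burial_region = burial_region,
                      value = NA_real_, matched_regions = "",
                      direction = NA_character_, stringsAsFactors = FALSE))
  }
  br <- ranges[[burial_region]]
  v <- r5(value)
  within_burial <- v >= r5(br$lo) && v <= r5(br$hi)
  direction <- if (within_burial) "within" else if (v < r5(br$lo)) "below"
               else "above"
  if (within_burial) {
    status <- "local"; matched <- character()
  } else {
    others <- ranges[setdiff(names(ranges), burial_region)]
    # strict interior: a ratio exactly on another region's printed bound is
    # not positive evidence of compatibility with that region
    matched <- names(others)[vapply(others, function(r) {
      v > r5(r$lo) && v < r5(r$hi)
    }, logical(1))]
    if (length(matched)) {
      status <- "mobile"
    } else if (v < r5(macro$lo) || v > r5(macro$hi)) {
      status <- "migrant"
    } else {
      status <- "mobile"   # inside macro range, no named region: log it
      attr(status, "note") <- "mobile_indeterminate"
    }
  }
  out <- data.frame(status = as.character(status),
                    burial_region = burial_region,
                    value = value,
                    matched_regions = paste(matched, collapse = ","),
                    direction = direction, stringsAsFactors = FALSE)
  if (!is.null(attr(status, "note"))) out$note <- attr(status, "note")
  out
}

#' Classify a cohort of records
#'
#' Applies [classify_individual()] to every record's enamel value against its
#' burial region.
#'
#' @param records An \code{isotope_records} data.frame with a \code{region}
#'   column (see [assign_regions()]).
#' @param ranges Named list of regional \code{local_range}s; default the
#'   published ranges.
#' @param macro Macro-regional \code{local_range}; default published.
#' @return A \code{provenance_calls} data.frame: one row per record with
#'   \code{id}, \code{site}, \code{sex}, \code{zone}, \code{status},
#'   \code{burial_region}, \code{value}, \code{matched_regions},
#'   \code{direction}.
#' @export
classify_records <- function(records,
                             ranges = published_sr_ranges()$regional,
                             macro = published_sr_ranges()$macro) {
  if (!"region" %in% names(records)) {
    stop("records need a 'region' column; run assign_regions() first",
         call. = FALSE)
  }
  calls <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    ci <- classify_individual(records$enamel_sr[i], records$region[i],
                              ranges, macro)
    ci$note <- if ("note" %in% names(ci)) ci$note else NA_character_
    ci
  }))
  out <- cbind(data.frame(id = records$id, site = records$site,
                          sex = if ("sex" %in% names(records)) records$sex
                                else "unknown",
                          zone = if ("zone" %in% names(records)) records$zone
                                 else NA_character_,
                          stringsAsFactors = FALSE),
               calls)
  class(out) <- c("provenance_calls", "data.frame")
  out
}

#' @export
print.provenance_calls <- function(x, ...) {
  tab <- table(factor(x$status,
                      levels = c("local", "mobile", "migrant",
                                 "indeterminate")))
  cat("<provenance_calls> ", nrow(x), " individuals: ",
      paste(names(tab), tab, sep = " = ", collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' Wald confidence interval for a binomial proportion
#'
#' Normal-approximation interval \eqn{k/n \pm z \sqrt{p(1-p)/n}}, truncated to
#' \code{[0, 1]}. Chosen because it back-computes the confidence intervals
#' printed for cohort proportions in this field's reports.
#'
#' @param k Number of successes (\code{0 <= k <= n}).
#' @param n Number of trials (\code{> 0}).
#' @param level Confidence level, default \code{0.95}.
#' @return Numeric vector \code{c(lower, upper)}.
#' @export
#' @examples
#' wald_ci(36, 156)
wald_ci <- function(k, n, level = 0.95) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  stopifnot(k >= 0, k <= n, level > 0, level < 1)
  p <- k / n
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(p * (1 - p) / n)
  ci <- c(p - z * se, p + z * se)
  pmin(pmax(ci, 0), 1)
}

#' Summarise provenance calls by group
#'
#' Counts locals, mobiles and migrants per group and attaches Wald confidence
#' intervals to the non-local, mobile and migrant proportions. Denominators
#' are individuals with an assessable enamel value (\code{indeterminate}
#' excluded).
#'
#' @param calls A \code{provenance_calls} data.frame.
#' @param group_by \code{"all"}, \code{"sex"}, \code{"zone"} or \code{"site"}.
#' @param ci_level Confidence level for the Wald intervals.
#' @return Data.frame with one row per group: \code{group}, \code{n_assessed},
#'   \code{n_nonlocal}, \code{n_mobile}, \code{n_migrant}, \code{p_nonlocal},
#'   \code{ci_lo}, \code{ci_hi} (proportions; \code{NA} and a flag when a
#'   group has no assessable individuals).
#' @export
summarize_cohort <- function(calls, group_by = c("all", "sex", "zone", "site"),
                             ci_level = 0.95) {
  group_by <- match.arg(group_by)
  stopifnot(nrow(calls) > 0)
  grp <- if (group_by == "all") rep("all", nrow(calls)) else calls[[group_by]]
  out <- do.call(rbind, lapply(split(seq_len(nrow(calls)), grp), function(ix) {
    g <- calls[ix, , drop = FALSE]
    assessed <- g[g$status != "indeterminate", , drop = FALSE]
    n <- nrow(assessed)
    n_mobile <- sum(assessed$status == "mobile")
    n_migrant <- sum(assessed$status == "migrant")
    k <- n_mobile + n_migrant
    if (n == 0) {
      data.frame(group = grp[ix][1], n_assessed = 0L, n_nonlocal = k,
                 n_mobile = n_mobile, n_migrant = n_migrant,
                 p_nonlocal = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                 undefined = TRUE, stringsAsFactors = FALSE)
    } else {
      ci <- wald_ci(k, n, ci_level)
      data.frame(group = grp[ix][1], n_assessed = n, n_nonlocal = k,
                 n_mobile = n_mobile, n_migrant = n_migrant,
                 p_nonlocal = k / n, ci_lo = ci[1], ci_hi = ci[2],
                 undefined = FALSE, stringsAsFactors = FALSE)
    }
  }))
  rownames(out) <- NULL
  out
}

#' Minimum frequency of migrants per period
#'
#' For each chronological period, computes the proportion of adults whose
#' enamel \eqn{^{87}Sr/^{86}Sr} falls outside the macro-regional bioavailable
#' range (a lower bound on migration, since isotopically similar origins are
#' undetectable), with Wald confidence intervals, plus a pooled all-period
#' row. Regions whose local variability exceeds the macro range can be
#' excluded from the calculation.
#'
#' @param records \code{isotope_records} with \code{period} (and
#'   \code{region}, if \code{exclude_regions} is used).
#' @param macro Macro-regional \code{local_range}.
#' @param exclude_regions Character vector of region codes to drop.
#' @param ci_level Confidence level.
#' @return An \code{mfm_table} data.frame: \code{period}, \code{n}, \code{k},
#'   \code{mfm}, \code{ci_lo}, \code{ci_hi}; the pooled row has period
#'   \code{"all"}; attribute \code{excluded_regions}.
#' @export
mfm_by_period <- function(records, macro = published_sr_ranges()$macro,
                          exclude_regions = character(), ci_level = 0.95) {
  df <- as.data.frame(records)
  if (length(exclude_regions)) {
    if (!"region" %in% names(df)) {
      stop("records need a 'region' column to exclude regions", call. = FALSE)
    }
    df <- df[!df$region %in% exclude_regions, , drop = FALSE]
  }
  df <- df[df$age_class %in% ADULT_AGE_CLASSES, , drop = FALSE]
  df <- df[!is.na(df$enamel_sr), , drop = FALSE]
  outside <- r5(df$enamel_sr) < r5(macro$lo) | r5(df$enamel_sr) > r5(macro$hi)
  one_row <- function(label, idx) {
    n <- length(idx)
    k <- sum(outside[idx])
    if (n == 0) {
      data.frame(period = label, n = 0L, k = 0L, mfm = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, stringsAsFactors = FALSE)
    } else {
      ci <- wald_ci(k, n, ci_level)
      data.frame(period = label, n = n, k = k, mfm = k / n,
                 ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
    }
  }
  rows <- lapply(split(seq_len(nrow(df)), df$period),
                 function(ix) one_row(df$period[ix][1], ix))
  out <- do.call(rbind, c(rows, list(one_row("all", seq_len(nrow(df))))))
  rownames(out) <- NULL
  attr(out, "excluded_regions") <- exclude_regions
  class(out) <- c("mfm_table", "data.frame")
  out
}

#' Compare group frequencies by chi-square test
#'
#' Pearson chi-square without continuity correction on a contingency table of
#' counts, optionally followed by pairwise (row-wise) post-hoc chi-square
#' tests with Bonferroni adjustment (each raw p multiplied by the number of
#' pairs, capped at 1).
#'
#' @param counts Matrix (or table) of non-negative integer counts.
#' @param method Currently only \code{"chisq"}.
#' @param posthoc \code{"none"} or \code{"pairwise_bonferroni"}.
#' @return A list with \code{statistic}, \code{df}, \code{p_value}, and (when
#'   requested) \code{pairwise}: data.frame of row pairs with raw and adjusted
#'   p-values.
#' @export
#' @examples
#' compare_groups(matrix(c(20, 40, 80, 60), nrow = 2))
compare_groups <- function(counts, method = "chisq",
                           posthoc = c("none", "pairwise_bonferroni")) {
  method <- match.arg(method, "chisq")
  posthoc <- match.arg(posthoc)
  m <- as.matrix(counts)
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("degenerate table: a row or column sums to zero", call. = FALSE)
  }
  test <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  out <- list(statistic = unname(test$statistic), df = unname(test$parameter),
              p_value = unname(test$p.value), method = "pearson_chisq")
  if (posthoc == "pairwise_bonferroni" && nrow(m) > 2) {
    pairs <- utils::combn(nrow(m), 2)
    n_pairs <- ncol(pairs)
    out$pairwise <- do.call(rbind, lapply(seq_len(n_pairs), function(j) {
      sub <- m[pairs[, j], , drop = FALSE]
      p_raw <- suppressWarnings(
        stats::chisq.test(sub, correct = FALSE)$p.value)
      data.frame(row_a = pairs[1, j], row_b = pairs[2, j], p_raw = p_raw,
                 p_adjusted = min(1, n_pairs * p_raw))
    }))
  }
  out
}
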