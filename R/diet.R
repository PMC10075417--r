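# Bone-collagen diet variability, dietary outliers, and bone vs bulk-dentine
# comparison.

#' Default pooled-site diet grouping
#'
#' Neighbouring sites (< 5 km apart, similar ground conditions and catchments)
#' are pooled into one dietary population: Straubing alone, the Regensburg
#' cluster (BWA+BWB+IRM+AEH), Erding alone, and the Munich cluster (PEL+UTH).
#'
#' @return Named character vector mapping site code to group label.
#' @export
default_diet_grouping <- function() {
  c(STB = "STB", BWA = "BW+IRM+AEH", BWB = "BW+IRM+AEH", IRM = "BW+IRM+AEH",
    AEH = "BW+IRM+AEH", AED = "AED", PEL = "PEL+UTH", UTH = "PEL+UTH")
}

#' Common intra-populational diet variability
#'
#' Defines, per pooled-site population and isotope, the "common variability"
#' of the diet as the 99\% highest-density interval of a Gaussian KDE of the
#' bone-collagen values (mode-anchored, via [local_range()]), together with
#' mean and standard deviation. Infans I children are excluded by default so
#' that nursing signals do not inflate the interval.
#'
#' @param records \code{isotope_records} with bone collagen columns.
#' @param grouping Named site-to-group map; default [default_diet_grouping()].
#' @param coverage HDI coverage, default \code{0.99}.
#' @param exclude_infans_I Drop infans I individuals (default \code{TRUE}).
#' @return A \code{diet_variability} data.frame: \code{group},
#'   \code{isotope} (\code{d13c}/\code{d15n}), \code{lo}, \code{hi},
#'   \code{coverage}, \code{n}, \code{mean}, \code{sd}. Groups with n < 8 are
#'   flagged in column \code{small_group} with a warning.
#' @export
diet_variability <- function(records, grouping = default_diet_grouping(),
                             coverage = 0.99, exclude_infans_I = TRUE) {
  df <- as.data.frame(records)
  unmapped <- setdiff(unique(df$site), names(grouping))
  if (length(unmapped)) {
    stop("site(s) without diet group: ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  if (exclude_infans_I) df <- df[df$age_class != "infans_I", , drop = FALSE]
  df$diet_group <- unname(grouping[df$site])
  iso_cols <- c(d13c = "bone_d13c", d15n = "bone_d15n")
  rows <- list()
  for (g in unique(df$diet_group)) {
    for (iso in names(iso_cols)) {
      vals <- df[[iso_cols[[iso]]]][df$diet_group == g]
      vals <- vals[is.finite(vals)]
      if (length(vals) < 2) {
        stop("group ", g, " has fewer than 2 ", iso, " values", call. = FALSE)
      }
      small <- length(vals) < 8
      if (small) {
        warning("diet group ", g, " has n = ", length(vals), " < 8 ", iso,
                " values; variability may be underestimated", call. = FALSE)
      }
      rng <- suppressWarnings(
        local_range(vals, coverage = coverage, anchor = "mode_interval",
                    region_id = g))
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, isotope = iso, lo = rng$lo, hi = rng$hi,
        coverage = coverage, n = length(vals),
        mean = mean(vals), sd = stats::sd(vals),
        small_group = small, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diet_variability", "data.frame")
  out
}

#' Detect dietary outliers against the common variability
#'
#' Flags individuals whose \eqn{\delta^{13}C} and/or \eqn{\delta^{15}N} value
#' lies outside the 99\% HDI of their population (boundary values count as
#' within). An individual is an outlier if either isotope is outside.
#'
#' @param records \code{isotope_records}.
#' @param variability A \code{diet_variability} table covering every group
#'   present.
#' @param tissue \code{"bone"} or \code{"dentine_bulk"} -- which values to
#'   screen.
#' @param grouping Site-to-group map (must match the one used for
#'   \code{variability}).
#' @return Data.frame: \code{id}, \code{group}, \code{tissue},
#'   \code{outlier_d13c}, \code{outlier_d15n}, \code{outlier} (either),
#'   \code{direction_d13c}, \code{direction_d15n}
#'   (\code{above}/\code{below}/\code{within}, NA when unmeasured).
#' @export
detect_outliers <- function(records, variability,
                            tissue = c("bone", "dentine_bulk"),
                            grouping = default_diet_grouping()) {
  tissue <- match.arg(tissue)
  df <- as.data.frame(records)
  df$diet_group <- unname(grouping[df$site])
  cols <- if (tissue == "bone") {
    c(d13c = "bone_d13c", d15n = "bone_d15n")
  } else {
    c(d13c = "dentine_bulk_d13c", d15n = "dentine_bulk_d15n")
  }
  missing_var <- setdiff(unique(df$diet_group),
                         unique(variability$group))
  if (length(missing_var)) {
    stop("no variability estimate for group(s): ",
         paste(missing_var, collapse = ", "), call. = FALSE)
  }
  side <- function(v, lo, hi) {
    ifelse(is.na(v), NA_character_,
           ifelse(v < lo, "below", ifelse(v > hi, "above", "within")))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
    res <- list(id = df$id[i], group = df$diet_group[i], tissue = tissue)
    for (iso in c("d13c", "d15n")) {
      band <- variability[variability$group == df$diet_group[i] &
                            variability$isotope == iso, , drop = FALSE]
      v <- df[[cols[[iso]]]][i]
      d <- side(v, band$lo[1], band$hi[1])
      res[[paste0("direction_", iso)]] <- d
      res[[paste0("outlier_", iso)]] <- !is.na(d) && d != "within"
    }
    res$outlier <- isTRUE(res$outlier_d13c) || isTRUE(res$outlier_d15n)
    as.data.frame(res, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bone versus bulk-dentine collagen differences
#'
#' For every individual with both bone and bulk root-dentine collagen values,
#' computes the absolute difference per isotope (adult versus later-childhood
#' diet). Group means are reported separately for individuals with and
#' without "notable attributes" (by default: ACD, a non-local enamel Sr call,
#' or a bone diet outlier), and the two groups are compared by a Mann-Whitney
#' U test per isotope (exact for small samples without ties, otherwise the
#' normal approximation with tie correction -- the default behaviour of
#' \code{stats::wilcox.test}). Deltas greater than 1.5 permil are flagged in
#' \code{large_delta} for reporting; classification itself stays HDI-based.
#'
#' @param records \code{isotope_records}.
#' @param notable_flags Named logical vector (id -> notable). Individuals
#'   absent from the map count as not notable.
#' @return List: \code{deltas} (per-individual data.frame with
#'   \code{delta_d13c}, \code{delta_d15n}, \code{notable},
#'   \code{large_delta}), \code{group_means} (mean deltas by notable group,
#'   with 1-decimal half-up rounded columns as printed in report tables), and
#'   \code{tests} (Mann-Whitney p-values per isotope, NA when a group is
#'   empty).
#' @export
bone_dentine_deltas <- function(records, notable_flags = NULL) {
  df <- as.data.frame(records)
  both <- !is.na(df$bone_d13c) & !is.na(df$dentine_bulk_d13c) &
    !is.na(df$bone_d15n) & !is.na(df$dentine_bulk_d15n)
  df <- df[both, , drop = FALSE]
  if (nrow(df) == 0) {
    return(structure(list(deltas = NULL, group_means = NULL, tests = NULL),
                     empty = TRUE))
  }
  notable <- if (is.null(notable_flags)) rep(FALSE, nrow(df)) else {
    unname(ifelse(is.na(notable_flags[df$id]), FALSE, notable_flags[df$id]))
  }
  deltas <- data.frame(
    id = df$id,
    delta_d13c = abs(df$bone_d13c - df$dentine_bulk_d13c),
    delta_d15n = abs(df$bone_d15n - df$dentine_bulk_d15n),
    notable = notable, stringsAsFactors = FALSE)
  deltas$large_delta <- deltas$delta_d13c > 1.5 | deltas$delta_d15n > 1.5
  group_means <- do.call(rbind, lapply(split(deltas, deltas$notable),
                                       function(g) {
    data.frame(notable = g$notable[1], n = nrow(g),
               mean_delta_d13c = mean(g$delta_d13c),
               mean_delta_d15n = mean(g$delta_d15n),
               mean_delta_d13c_1dp = round_half_up(mean(g$delta_d13c), 1),
               mean_delta_d15n_1dp = round_half_up(mean(g$delta_d15n), 1))
  }))
  rownames(group_means) <- NULL
  tests <- if (length(unique(deltas$notable)) == 2) {
    list(
      d13c = suppressWarnings(stats::wilcox.test(
        delta_d13c ~ notable, data = deltas)$p.value),
      d15n = suppressWarnings(stats::wilcox.test(
        delta_d15n ~ notable, data = deltas)$p.value))
  } else list(d13c = NA_real_, d15n = NA_real_)
  list(deltas = deltas, group_means = group_means, tests = tests)
}

#' Association between childhood diet outliers and notable attributes
#'
#' Cross-tabulates deviating childhood (bulk-dentine) diet against the
#' presence of a notable attribute over the dentine cohort and tests the
#' association with a Pearson chi-square test (via [compare_groups()]).
#'
#' @param childhood_outliers Named logical vector (id -> childhood outlier).
#' @param notable Named logical vector (id -> notable attribute), defined on
#'   the same ids.
#' @return The [compare_groups()] report with an added \code{table} element.
#' @export
association_childhood_notable <- function(childhood_outliers, notable) {
  ids <- names(childhood_outliers)
  if (is.null(ids) || !setequal(ids, names(notable))) {
    stop("both maps must be named and defined on the same id set",
         call. = FALSE)
  }
  tab <- table(factor(childhood_outliers[ids], levels = c(FALSE, TRUE)),
               factor(notable[ids], levels = c(FALSE, TRUE)),
               dnn = c("childhood_outlier", "notable"))
  res <- compare_groups(unclass(tab))
  res$table <- tab
  res
}
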