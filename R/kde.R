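# Kernel density estimation, highest-density regions, and local
# bioavailable 87Sr/86Sr ranges.

KDE_GRID_N <- 4096L      # 2^12 regular evaluation points
KDE_EXTEND_BW <- 3       # grid extension beyond data range, in bandwidths

#' Sheather-Jones solve-the-equation bandwidth
#'
#' Selects the Gaussian-kernel bandwidth by the Sheather-Jones
#' "solve-the-equation" method. Degenerate samples (zero spread) are an error;
#' if the fixed-point search fails to bracket a root (possible for very small
#' or heavily tied samples) the function falls back to Silverman's
#' rule-of-thumb with a warning, so that pipelines over small regional subsets
#' do not abort.
#'
#' @param values Numeric vector, at least 8 finite values with nonzero spread.
#' @return A positive bandwidth on the scale of \code{values}.
#' @export
#' @examples
#' set.seed(1)
#' sj_bandwidth(rnorm(200))
sj_bandwidth <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 8) {
    stop("need at least 8 finite values for the Sheather-Jones bandwidth",
         call. = FALSE)
  }
  if (stats::sd(x) == 0) stop("degenerate sample: zero variance", call. = FALSE)
  tryCatch(
    stats::bw.SJ(x, method = "ste"),
    error = function(e) {
      warning("Sheather-Jones search failed (", conditionMessage(e),
              "); falling back to Silverman's rule", call. = FALSE)
      stats::bw.nrd0(x)
    }
  )
}

#' Fit a Gaussian kernel density estimate
#'
#' Evaluates a Gaussian-kernel KDE on a regular grid of 4096 points spanning
#' the data range extended by three bandwidths on each side, and renormalises
#' to unit mass on the grid (trapezoid rule). With \code{bandwidth = "auto"}
#' the Sheather-Jones solve-the-equation bandwidth is used.
#'
#' @param values Numeric vector (n >= 1; n >= 8 for \code{"auto"}).
#' @param bandwidth Positive numeric, or \code{"auto"}.
#' @return A \code{kde_model}: list with \code{grid}, \code{density},
#'   \code{bandwidth}, \code{n}, \code{input_range}.
#' @export
fit_kde <- function(values, bandwidth = "auto") {
  x <- values[is.finite(values)]
  if (length(x) == 0) stop("no finite values to fit", call. = FALSE)
  h <- if (identical(bandwidth, "auto")) {
    if (length(x) >= 8) sj_bandwidth(x) else {
      if (length(x) < 2 || stats::sd(x) == 0) {
        stop("degenerate sample: cannot select a bandwidth for ",
             length(x), " value(s) with zero spread", call. = FALSE)
      }
      warning("sample too small for the Sheather-Jones selector (n = ",
              length(x), "); using Silverman's rule", call. = FALSE)
      stats::bw.nrd0(x)
    }
  } else {
    stopifnot(is.numeric(bandwidth), bandwidth > 0)
    bandwidth
  }
  from <- min(x) - KDE_EXTEND_BW * h
  to <- max(x) + KDE_EXTEND_BW * h
  d <- stats::density(x, bw = h, kernel = "gaussian",
                      from = from, to = to, n = KDE_GRID_N)
  mass <- trapezoid_mass(d$x, d$y)
  out <- list(grid = d$x, density = d$y / mass, bandwidth = h,
              n = length(x), input_range = range(x))
  class(out) <- "kde_model"
  out
}

trapezoid_mass <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' @export
print.kde_model <- function(x, ...) {
  cat("<kde_model> n =", x$n, " bandwidth =", signif(x$bandwidth, 4),
      " grid = [", signif(x$grid[1], 6), ",",
      signif(x$grid[length(x$grid)], 6), "] x", length(x$grid), "\n")
  invisible(x)
}

#' Highest-density region of a fitted density
#'
#' Hyndman's density-quantile construction: grid cells are sorted by density
#' and accumulated until the requested probability mass is reached; the
#' density of the last included cell is the threshold \eqn{f_\alpha}, and the
#' HDR is the union of maximal runs of grid cells with density at or above it.
#' For multimodal densities the result can be several disjoint intervals.
#'
#' @param model A \code{kde_model} from [fit_kde()].
#' @param coverage Probability in (0, 1), e.g. \code{0.99}.
#' @return An \code{hdr_result}: list with \code{coverage},
#'   \code{density_threshold}, \code{intervals} (data.frame \code{lo},
#'   \code{hi}, \code{mass}), \code{mode}, \code{mode_interval} (row index into
#'   \code{intervals}).
#' @export
#' @examples
#' m <- fit_kde(rnorm(500), bandwidth = 0.3)
#' hdr(m, 0.95)
hdr <- function(model, coverage) {
  stopifnot(inherits(model, "kde_model"),
            is.numeric(coverage), coverage > 0, coverage < 1)
  g <- model$grid
  f <- model$density
  dx <- g[2] - g[1]
  cell_mass <- f * dx
  cell_mass <- cell_mass / sum(cell_mass)
  ord <- order(f, decreasing = TRUE)
  cum <- cumsum(cell_mass[ord])
  k <- which(cum >= coverage)[1]
  threshold <- f[ord[k]]
  inside <- f >= threshold
  runs <- rle(inside)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- which(runs$values)
  intervals <- data.frame(
    lo = g[starts[keep]],
    hi = g[ends[keep]],
    mass = vapply(keep, function(i) {
      sum(cell_mass[starts[i]:ends[i]])
    }, numeric(1))
  )
  intervals <- intervals[order(intervals$lo), , drop = FALSE]
  rownames(intervals) <- NULL
  mode_x <- g[which.max(f)]
  mode_iv <- which(intervals$lo <= mode_x & mode_x <= intervals$hi)[1]
  out <- list(coverage = coverage, density_threshold = threshold,
              intervals = intervals, mode = mode_x, mode_interval = mode_iv)
  class(out) <- "hdr_result"
  out
}

#' @export
print.hdr_result <- function(x, ...) {
  cat("<hdr_result> ", x$coverage * 100, "% HDR, mode at ",
      signif(x$mode, 6), "\n", sep = "")
  for (i in seq_len(nrow(x$intervals))) {
    cat(sprintf("  [%g, %g]%s\n", x$intervals$lo[i], x$intervals$hi[i],
                if (identical(i, x$mode_interval)) "  <- mode" else ""))
  }
  invisible(x)
}

#' Local bioavailable range from a reference sample
#'
#' Estimates the local range of a region as the highest-density interval of a
#' Gaussian KDE fitted to the pooled biomineral reference values (human and
#' animal, enamel and bone). \code{anchor = "mode_interval"} (default) returns
#' the HDR interval containing the most prominent mode;
#' \code{anchor = "full_hull"} returns the hull over all HDR intervals. For
#' unimodal reference sets the two coincide.
#'
#' @param reference_values Numeric vector of pooled reference measurements.
#' @param coverage HDI coverage, default \code{0.99}.
#' @param anchor \code{"mode_interval"} or \code{"full_hull"}.
#' @param region_id Label carried into the result.
#' @return A \code{local_range}: list with \code{region_id}, \code{lo},
#'   \code{hi}, \code{coverage}, \code{n_reference}, \code{bandwidth},
#'   \code{source = "estimated"}. Reference sets with fewer than 20 values get
#'   a \code{small_sample} attribute and a warning (the range may
#'   underestimate the true variability).
#' @export
local_range <- function(reference_values, coverage = 0.99,
                        anchor = c("mode_interval", "full_hull"),
                        region_id = "region") {
  anchor <- match.arg(anchor)
  x <- reference_values[is.finite(reference_values)]
  model <- fit_kde(x, bandwidth = "auto")
  h <- hdr(model, coverage)
  if (anchor == "mode_interval") {
    lo <- h$intervals$lo[h$mode_interval]
    hi <- h$intervals$hi[h$mode_interval]
  } else {
    lo <- min(h$intervals$lo)
    hi <- max(h$intervals$hi)
  }
  out <- list(region_id = region_id, lo = lo, hi = hi, coverage = coverage,
              n_reference = length(x), bandwidth = model$bandwidth,
              source = "estimated")
  class(out) <- "local_range"
  if (length(x) < 20) {
    attr(out, "small_sample") <- TRUE
    warning("baseline may underestimate variability (n = ", length(x),
            " < 20)", call. = FALSE)
  }
  out
}

#' Construct a published local range
#'
#' Wraps a range taken from the literature (already rounded to reporting
#' precision) in the container used by the classifier.
#'
#' @param region_id Region label.
#' @param lo,hi Interval bounds (\code{lo < hi}).
#' @param coverage Nominal coverage of the published interval.
#' @param n_reference Size of the reference set behind the published range.
#' @return A \code{local_range} with \code{source = "published"}.
#' @export
published_range <- function(region_id, lo, hi, coverage = 0.99,
                            n_reference = NA_integer_) {
  stopifnot(lo < hi)
  out <- list(region_id = region_id, lo = lo, hi = hi, coverage = coverage,
              n_reference = n_reference, bandwidth = NA_real_,
              source = "published")
  class(out) <- "local_range"
  out
}

#' Published regional and macro-regional Sr ranges
#'
#' The 99\% HDI local ranges of bioavailable \eqn{^{87}Sr/^{86}Sr} published
#' for the four regional groups, and the macro range for the whole Northern
#' pre-Alpine foreland south of the Danube, shipped as defaults for
#' classification.
#'
#' @return A list with elements \code{regional} (named list of
#'   \code{local_range}: STB, REG, AED, MUC) and \code{macro} (a
#'   \code{local_range}).
#' @export
#' @examples
#' published_sr_ranges()$regional$STB
published_sr_ranges <- function() {
  list(
    regional = list(
      STB = published_range("STB", 0.70805, 0.71096, n_reference = 217),
      REG = published_range("REG", 0.70813, 0.71195, n_reference = 80),
      AED = published_range("AED", 0.70857, 0.71104, n_reference = 78),
      MUC = published_range("MUC", 0.70802, 0.71021, n_reference = 76)
    ),
    macro = published_range("pre_Alpine", 0.7081, 0.7110, n_reference = 865)
  )
}

#' @export
print.local_range <- function(x, ...) {
  cat(sprintf("<local_range> %s: [%.5f, %.5f] (%g%% HDI, n = %s, %s)\n",
              x$region_id, x$lo, x$hi, x$coverage * 100,
              x$n_reference, x$source))
  invisible(x)
}

#' Export a baseline report as JSON
#'
#' @param range A \code{local_range}.
#' @param path Output path; \code{NULL} returns the JSON string.
#' @param anchor Anchor rule used to derive the interval (metadata only).
#' @return The path (or JSON string), invisibly.
#' @export
baseline_report <- function(range, path = NULL, anchor = "mode_interval") {
  obj <- list(region = range$region_id, lo = range$lo, hi = range$hi,
              coverage = range$coverage, bandwidth = range$bandwidth,
              n = range$n_reference, anchor = anchor, source = range$source)
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}
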