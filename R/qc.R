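# Collagen quality control.
#
# Threshold conventions (documented here once, used nowhere else):
#   atomic C/N in [2.9, 3.6]        -- inclusive ("between")
#   %C  > 13, %N  > 4.8             -- exclusive ("in excess of")
#   %C <= 50, %N <= 19              -- contamination above these (">")
# C/N is the ATOMIC ratio; when absent it is computed from weight percent via
# the molar masses 12.011 (C) and 14.007 (N).

QC_CN_LO <- 2.9
QC_CN_HI <- 3.6
QC_PCT_C_MIN <- 13
QC_PCT_N_MIN <- 4.8
QC_PCT_C_MAX <- 50
QC_PCT_N_MAX <- 19

#' Atomic C/N ratio from weight percentages
#'
#' @param pct_c,pct_n Weight-\% carbon and nitrogen.
#' @return The dimensionless atomic ratio \code{(pct_c/12.011)/(pct_n/14.007)}.
#' @export
cn_atomic_ratio <- function(pct_c, pct_n) {
  (pct_c / 12.011) / (pct_n / 14.007)
}

#' Collagen quality control
#'
#' Screens collagen measurements with the standard acceptance rules for
#' unaltered archaeological collagen: atomic C/N between 2.9 and 3.6
#' (inclusive), carbon in excess of 13 wt-\%, nitrogen in excess of 4.8 wt-\%,
#' and contamination flags above 50 wt-\% C or 19 wt-\% N. A sample passes iff
#' no rule is violated; \code{reasons} lists every violated rule. Rules whose
#' inputs are missing are not assessed; if neither percentage nor ratio is
#' available the sample is unassessable and an error is raised.
#'
#' @param measurements Data.frame with columns \code{sample_id}, and at least
#'   one of \code{pct_c}+\code{pct_n} or \code{cn_atomic}; optional
#'   \code{tissue}.
#' @return Data.frame with columns \code{sample_id}, \code{pass},
#'   \code{cn_atomic} (as used) and a list-column \code{reasons} with values
#'   among \code{cn_out_of_range}, \code{low_carbon}, \code{low_nitrogen},
#'   \code{carbon_contamination}, \code{nitrogen_contamination}.
#' @export
#' @examples
#' collagen_qc(data.frame(sample_id = "a", pct_c = 40, pct_n = 15,
#'                        cn_atomic = 3.2))
collagen_qc <- function(measurements) {
  m <- as.data.frame(measurements)
  if (!"sample_id" %in% names(m)) m$sample_id <- as.character(seq_len(nrow(m)))
  if (!"pct_c" %in% names(m)) m$pct_c <- NA_real_
  if (!"pct_n" %in% names(m)) m$pct_n <- NA_real_
  if (!"cn_atomic" %in% names(m)) m$cn_atomic <- NA_real_
  if (any(m$pct_c < 0 | m$pct_n < 0, na.rm = TRUE)) {
    stop("negative weight percentages are not valid", call. = FALSE)
  }
  cn <- ifelse(is.na(m$cn_atomic) & !is.na(m$pct_c) & !is.na(m$pct_n) &
                 m$pct_n > 0,
               cn_atomic_ratio(m$pct_c, m$pct_n), m$cn_atomic)
  unassessable <- is.na(cn) & is.na(m$pct_c) & is.na(m$pct_n)
  if (any(unassessable)) {
    stop("unassessable: no C/N ratio or weight percentages for sample(s) ",
         paste(m$sample_id[unassessable], collapse = ", "), call. = FALSE)
  }
  reasons <- lapply(seq_len(nrow(m)), function(i) {
    r <- character()
    if (!is.na(cn[i]) && (cn[i] < QC_CN_LO || cn[i] > QC_CN_HI)) {
      r <- c(r, "cn_out_of_range")
    }
    if (!is.na(m$pct_c[i])) {
      if (m$pct_c[i] <= QC_PCT_C_MIN) r <- c(r, "low_carbon")
      if (m$pct_c[i] > QC_PCT_C_MAX) r <- c(r, "carbon_contamination")
    }
    if (!is.na(m$pct_n[i])) {
      if (m$pct_n[i] <= QC_PCT_N_MIN) r <- c(r, "low_nitrogen")
      if (m$pct_n[i] > QC_PCT_N_MAX) r <- c(r, "nitrogen_contamination")
    }
    r
  })
  out <- data.frame(sample_id = m$sample_id,
                    pass = lengths(reasons) == 0,
                    cn_atomic = cn,
                    stringsAsFactors = FALSE)
  out$reasons <- reasons
  if ("tissue" %in% names(m)) out$tissue <- m$tissue
  out
}
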