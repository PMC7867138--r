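#' Intersection over union of two binary masks
#'
#' `|A intersect B| / |A union B|` on same-shape pixel grids; the standard
#' segmentation accuracy measure. Two empty masks score 1, exactly one
#' empty mask scores 0.
#'
#' @param a,b `footwear_mask` objects or logical matrices of equal shape
#' @return IOU in \[0, 1\]
#' @export
mask_iou <- function(a, b) {
  if (inherits(a, "footwear_mask")) {
    if (!inherits(b, "footwear_mask")) stop("mask types differ")
    if (!identical(a$shape, b$shape)) stop("mask shapes differ")
    # intersect the bounding boxes first; masks are never empty
    c0 <- max(a$bbox[1], b$bbox[1]); c1 <- min(a$bbox[3], b$bbox[3])
    r0 <- max(a$bbox[2], b$bbox[2]); r1 <- min(a$bbox[4], b$bbox[4])
    inter <- 0L
    if (c0 <= c1 && r0 <= r1) {
      sa <- a$submask[(r0:r1) - a$bbox[2] + 1L, (c0:c1) - a$bbox[1] + 1L, drop = FALSE]
      sb <- b$submask[(r0:r1) - b$bbox[2] + 1L, (c0:c1) - b$bbox[1] + 1L, drop = FALSE]
      inter <- sum(sa & sb)
    }
    un <- mask_area(a) + mask_area(b) - inter
    return(inter / un)
  }
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  na <- sum(a); nb <- sum(b)
  if (na == 0 && nb == 0) return(1)
  if (na == 0 || nb == 0) return(0)
  inter <- sum(a & b)
  inter / (na + nb - inter)
}

#' RMS error between the bottom edges of two masks
#'
#' Compares per-column lowest occupied rows over the columns the two masks
#' share; columns present in only one mask are excluded and reported via a
#' coverage fraction (shared columns / truth columns). With no shared
#' columns the RMS is undefined and flagged, not an error.
#'
#' @param detected,truth `footwear_mask` objects
#' @return list with `rms` (px, `NA` when undefined), `n_shared`,
#'   `coverage`, and `undefined` flag
#' @export
bottom_edge_rms <- function(detected, truth) {
  bd <- detected$bottom_edge; bt <- truth$bottom_edge
  shared <- intersect(bd[, "col"], bt[, "col"])
  if (length(shared) == 0L) {
    return(list(rms = NA_real_, n_shared = 0L, coverage = 0, undefined = TRUE))
  }
  rd <- bd[match(shared, bd[, "col"]), "row"]
  rt <- bt[match(shared, bt[, "col"]), "row"]
  list(rms = sqrt(mean((rd - rt)^2)),
       n_shared = length(shared),
       coverage = length(shared) / nrow(bt),
       undefined = FALSE)
}

#' Per-pedestrian rater statistics
#'
#' For one pedestrian's repeated MFC measurements: the mean, the sample
#' standard deviation (divisor n-1), and the RMS of deviations from the
#' mean with divisor n — so `rms = sample_sd * sqrt((n-1)/n)`, always at
#' or below the sample SD.
#'
#' @param values numeric vector of at least 2 measurements (mm)
#' @return list with `mean`, `sample_sd`, `rms_vs_mean`, `n`
#' @export
rater_rms <- function(values) {
  n <- length(values)
  if (n < 2L) stop("rater statistics need at least 2 values")
  m <- mean(values)
  s <- stats::sd(values)
  list(mean = m, sample_sd = s, rms_vs_mean = s * sqrt((n - 1) / n), n = n)
}

#' Aggregate RMS over pedestrians
#'
#' The overall error statistic: the arithmetic mean of the per-pedestrian
#' RMS values.
#'
#' @param per_pedestrian_rms numeric vector of per-pedestrian RMS values
#' @return their mean
#' @export
aggregate_rms <- function(per_pedestrian_rms) {
  if (length(per_pedestrian_rms) == 0L) stop("empty RMS list")
  mean(per_pedestrian_rms)
}

#' Bland-Altman agreement statistics
#'
#' For paired measurements: per-pair differences and means, the bias
#' (mean difference) and the 95% limits of agreement
#' `bias +/- 1.96 * SD(differences)` (sample SD). Constant differences
#' give zero-width limits, which is valid.
#'
#' @param a,b paired measurement vectors of equal length >= 2
#' @return list with `bias`, `sd_diff`, `limits` (`c(lower, upper)`), and
#'   `points` data frame (`mean`, `diff`) for plotting
#' @export
bland_altman_stats <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  m <- (a + b) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, sd_diff = s,
       limits = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
       points = data.frame(mean = m, diff = d))
}

#' Compute an agreement report from a rater table
#'
#' A rater table has one row per pedestrian and one column per rater
#' (plus an id column when read from CSV via [read_rater_table()]).
#' The report carries each pedestrian's mean, sample SD and RMS-vs-mean,
#' the aggregate RMS (mean of the per-pedestrian RMS values), and
#' Bland-Altman bias/limits pooled over all rater pairs.
#'
#' @param table numeric matrix or data frame, rows = pedestrians,
#'   columns = raters (>= 2)
#' @return list with `per_pedestrian` (data frame), `aggregate_rms_mm`,
#'   and `bland_altman` (pooled over rater pairs)
#' @export
rater_agreement <- function(table) {
  tab <- as.matrix(table)
  if (ncol(tab) < 2L) stop("agreement statistics need at least 2 raters")
  if (any(tab < 0)) stop("negative MFC measurements in rater table")
  per <- t(apply(tab, 1L, function(v) {
    r <- rater_rms(v)
    c(mean = r$mean, sample_sd = r$sample_sd, rms_vs_mean = r$rms_vs_mean)
  }))
  per <- as.data.frame(per)
  per$pedestrian <- rownames(tab) %||% seq_len(nrow(tab))
  pairs_a <- numeric(0); pairs_b <- numeric(0)
  for (i in seq_len(ncol(tab) - 1L)) {
    for (j in (i + 1L):ncol(tab)) {
      pairs_a <- c(pairs_a, tab[, i]); pairs_b <- c(pairs_b, tab[, j])
    }
  }
  list(per_pedestrian = per[, c("pedestrian", "mean", "sample_sd", "rms_vs_mean")],
       aggregate_rms_mm = aggregate_rms(per$rms_vs_mean),
       bland_altman = bland_altman_stats(pairs_a, pairs_b))
}

#' Read a rater table CSV
#'
#' First column: pedestrian id; remaining columns: one per rater, MFC in
#' mm.
#' @param path CSV path
#' @return numeric matrix with pedestrian ids as row names
#' @export
read_rater_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}

#' Bundled inter-rater reference summary
#'
#' A published field-study summary bundled for validating the agreement
#' statistics: per-pedestrian mean, sample SD and RMS-vs-mean of five
#' manual raters' MFC measurements for 10 pedestrians, plus the RMS of an
#' automated system against the same rater means. The per-pedestrian RMS
#' values relate to the SDs by `rms = sd * sqrt(4/5)` (five raters), and
#' their mean gives the overall manual RMS of 2.32 mm.
#'
#' @return data frame with columns `pedestrian`, `manual_mean`,
#'   `manual_sd`, `manual_rms`, `auto_rms` (all mm)
#' @export
rater_reference_table <- function() {
  utils::read.csv(system.file("extdata", "manual_rater_summary.csv",
                              package = "mfce"))
}
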