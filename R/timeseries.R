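# Temporal analysis of dated taxon count tables: per-sample relative
# abundances with family aggregation, detection fractions across sampling
# points, the fall-winter seasonal window, coexistence richness, and bloom
# calling against a robust (median + MAD) baseline.

META_COLS <- c("sample_id", "date", "plant")

taxa_columns <- function(table) setdiff(names(table), META_COLS)

check_counts <- function(table) {
  taxa <- taxa_columns(table)
  if (!length(taxa)) stop("table has no taxon columns")
  m <- as.matrix(table[taxa])
  if (any(m < 0)) stop("counts must be nonnegative")
  m
}

#' Per-sample relative abundances, with family aggregation
#'
#' Converts counts to per-sample fractions; samples with zero total yield
#' all-zero rows and are flagged. When a species-to-family map is given,
#' family fractions are sums over member species.
#'
#' @param table data.frame with columns `sample_id, date, plant` and one
#'   count column per taxon.
#' @param family_map named character vector mapping taxon id to family id.
#' @return list with `species` (fraction data.frame), `family` (or `NULL`)
#'   and `zero_samples` (flagged sample ids).
#' @export
relative_abundance <- function(table, family_map = NULL) {
  m <- check_counts(table)
  totals <- rowSums(m)
  frac <- m / ifelse(totals > 0, totals, 1)
  frac[totals == 0, ] <- 0
  species <- cbind(table[intersect(META_COLS, names(table))],
                   as.data.frame(frac))
  fam <- NULL
  if (!is.null(family_map)) {
    taxa <- colnames(m)
    if (!all(taxa %in% names(family_map)))
      stop("family_map must cover every taxon column")
    groups <- family_map[taxa]
    famm <- sapply(unique(groups), function(g)
      rowSums(frac[, groups == g, drop = FALSE]))
    if (is.null(dim(famm))) famm <- matrix(famm, nrow = 1L,
                                           dimnames = list(NULL, unique(groups)))
    fam <- cbind(table[intersect(META_COLS, names(table))],
                 as.data.frame(famm))
  }
  list(species = species, family = fam,
       zero_samples = table$sample_id[totals == 0])
}

#' Fraction of sampling points in which a taxon is detected
#'
#' Percentage of samples with a count of at least `min_count` for the taxon
#' (or summed over a set of taxa, e.g. a family), reported to 1 decimal,
#' rounding half away from zero (132 of 268 gives 49.3).
#'
#' @param table count table as in [relative_abundance()].
#' @param taxa one taxon column name or several (summed before testing).
#' @param min_count detection threshold, `>= 1` (default 1).
#' @return percent of samples, one decimal.
#' @export
detection_fraction <- function(table, taxa, min_count = 1L) {
  if (!nrow(table)) stop("empty table")
  if (min_count < 1L) stop("min_count must be >= 1")
  missing_cols <- setdiff(taxa, names(table))
  if (length(missing_cols))
    stop("unknown taxa: ", paste(missing_cols, collapse = ","))
  x <- rowSums(table[, taxa, drop = FALSE])
  round_half_away(100 * sum(x >= min_count) / nrow(table), 1L)
}

#' Seasonal label of a calendar date
#'
#' Labels dates in the fall-winter window, defined as 21 September through
#' 21 March with both boundaries inclusive (year wrap handled by
#' month/day comparison), as `"fall_winter"`; all other dates are
#' `"rest_of_year"`.
#'
#' @param dates `Date` vector (or coercible).
#' @return character vector of labels.
#' @export
season_label <- function(dates) {
  dates <- as.Date(dates)
  if (anyNA(dates)) stop("unparsable date")
  md <- as.integer(format(dates, "%m")) * 100L + as.integer(format(dates, "%d"))
  ifelse(md >= 921L | md <= 321L, "fall_winter", "rest_of_year")
}

#' Per-sample richness of co-occurring taxa
#'
#' Number of taxa per sample whose relative abundance is at least
#' `min_rel_abundance` (and positive), tracking how many symbiont species
#' are detected simultaneously.
#'
#' @param table count table.
#' @param min_rel_abundance relative-abundance floor (default 0.0001).
#' @return integer vector, one value per sample.
#' @export
richness_series <- function(table, min_rel_abundance = 1e-4) {
  if (min_rel_abundance < 0) stop("threshold must be >= 0")
  m <- check_counts(table)
  totals <- rowSums(m)
  frac <- m / ifelse(totals > 0, totals, 1)
  as.integer(rowSums(frac >= min_rel_abundance & frac > 0))
}

#' Call blooms in one taxon's relative-abundance series
#'
#' The series is smoothed with a centered rolling mean of width `window`
#' (shrunk at the edges); a bloom is a maximal run of samples whose
#' smoothed abundance exceeds `median + k_mad * MAD` (median and MAD of the
#' smoothed series) and whose raw peak reaches at least `min_peak`.
#' Smoothing keeps one noisy multi-sample bloom from fragmenting into
#' several events and suppresses single-sample spikes. The MAD uses the
#' usual 1.4826 normal-consistency constant; a constant series (MAD 0,
#' nothing strictly above the median) yields no blooms.
#'
#' @param series numeric vector of relative abundances over time.
#' @param dates optional `Date` vector aligned with `series`.
#' @param window rolling-mean width in samples (default 5); the series must
#'   be strictly longer than the window.
#' @param k_mad MAD multiplier (default 5).
#' @param min_peak raw-peak floor in relative abundance (default 0.0001,
#'   i.e. 0.01%).
#' @return data.frame of class `bloom_events` with one row per bloom:
#'   `start, end` (indices), `start_date, end_date`, `peak` (raw), `fold`
#'   (peak over the series median, `Inf` when the median is 0).
#' @export
detect_blooms <- function(series, dates = NULL, window = 5L, k_mad = 5,
                          min_peak = 1e-4) {
  if (length(series) <= window)
    stop("series must be longer than the window (", window, ")")
  if (!is.null(dates) && length(dates) != length(series))
    stop("dates must align with the series")
  n <- length(series)
  half <- window %/% 2L
  smooth <- vapply(seq_len(n), function(i)
    mean(series[max(1L, i - half):min(n, i + half)]), 0)
  med <- stats::median(smooth)
  M <- stats::mad(smooth)
  thr <- med + k_mad * M
  above <- smooth > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  ev <- data.frame(start = starts[keep], end = ends[keep])
  if (nrow(ev)) {
    ev$peak <- vapply(seq_len(nrow(ev)), function(i)
      max(series[ev$start[i]:ev$end[i]]), 0)
    ev <- ev[ev$peak >= min_peak, , drop = FALSE]
  }
  if (!nrow(ev)) {
    ev <- data.frame(start = integer(0), end = integer(0), peak = numeric(0))
  }
  ev$fold <- if (nrow(ev)) ifelse(med > 0, ev$peak / med, Inf) else numeric(0)
  if (!is.null(dates)) {
    dates <- as.Date(dates)
    ev$start_date <- dates[ev$start]
    ev$end_date <- dates[ev$end]
  }
  rownames(ev) <- NULL
  class(ev) <- c("bloom_events", "data.frame")
  attr(ev, "threshold") <- thr
  ev
}
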