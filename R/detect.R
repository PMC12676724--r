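# Genome presence calling from per-base coverage. Under near-uniform read
# placement the fraction of a genome covered by at least one read (breadth)
# is predicted from the mean depth d as 1 - exp(-0.883 * d); a genome is
# called present when the observed breadth is within the model's tolerance
# of that expectation.

#' Breadth-of-coverage detection model
#'
#' @param k decay coefficient of the expected-breadth curve
#'   `1 - exp(-k * depth)` (default 0.883).
#' @param tolerance relative tolerance band (default 0.15, i.e. "within
#'   15% of the expected breadth").
#' @param sidedness `"one_sided_lower"` (default: detected when breadth is
#'   at least `(1 - tolerance) * expected`; breadth above expectation
#'   indicates evenness, not absence) or `"two_sided"` (literal band).
#' @return an object of class `detection_model`.
#' @export
detection_model <- function(k = 0.883, tolerance = 0.15,
                            sidedness = c("one_sided_lower", "two_sided")) {
  sidedness <- match.arg(sidedness)
  stopifnot(k > 0, tolerance > 0, tolerance < 1)
  structure(list(k = k, tolerance = tolerance, sidedness = sidedness),
            class = "detection_model")
}

#' Per-base coverage profile from mapped hits
#'
#' Increments a depth array over each hit's reference interval. Mean depth
#' is aligned reference bases divided by genome length (soft-clipped read
#' ends are excluded because only the aligned interval is counted); breadth
#' is the fraction of positions with depth at least 1. Wrapped hits on
#' circular genomes (`send > length`) are folded across the origin.
#'
#' @param hits data.frame with `sstart`, `send` (0-based half-open) from
#'   [seeded_map()] or read from a hits TSV.
#' @param genome_length genome length in bases.
#' @param genome_id label carried into the profile.
#' @param circular is the genome circular?
#' @return an object of class `coverage_profile` with `depth`,
#'   `mean_depth` and `breadth`.
#' @export
coverage_profile <- function(hits, genome_length, genome_id = "genome",
                             circular = FALSE) {
  L <- as.integer(genome_length)
  delta <- integer(L + 1L)
  if (!is.null(hits) && nrow(hits)) {
    s <- as.integer(hits$sstart); e <- as.integer(hits$send)
    if (any(s < 0L) || any(s >= L) || any(e < s))
      stop("hit interval out of bounds")
    if (any(e > L)) {
      if (!circular) stop("hit interval beyond the end of a linear genome")
      wrap <- e > L
      # split wrapped intervals at the origin
      s2 <- c(s[!wrap], s[wrap], rep(0L, sum(wrap)))
      e2 <- c(e[!wrap], rep(L, sum(wrap)), e[wrap] - L)
      s <- s2; e <- e2
    }
    delta <- tabulate(s + 1L, nbins = L + 1L) - tabulate(e + 1L, nbins = L + 1L)
  }
  depth <- cumsum(delta[seq_len(L)])
  structure(list(genome_id = genome_id, length = L, depth = depth,
                 mean_depth = sum(as.numeric(depth)) / L,
                 breadth = mean(depth >= 1L)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s: %d bp, depth %.3f, breadth %.3f\n",
              x$genome_id, x$length, x$mean_depth, x$breadth))
  invisible(x)
}

#' Expected breadth at a given depth
#'
#' Evaluates `1 - exp(-k * d)`, the breadth expected under near-uniform
#' read placement at mean depth `d`.
#'
#' @param d mean depth of coverage (>= 0); vectorized.
#' @param model a [detection_model()].
#' @return expected breadth in `[0, 1)`.
#' @export
expected_breadth <- function(d, model = detection_model()) {
  if (any(d < 0)) stop("depth must be >= 0")
  1 - exp(-model$k * d)
}

#' Call genome presence from a coverage profile
#'
#' A genome is considered present when its observed breadth lies within the
#' model tolerance of the expected breadth at the observed depth. With zero
#' depth the genome is never detected and the ratio is reported as 0.
#'
#' @param profile a [coverage_profile()].
#' @param model a [detection_model()].
#' @return an object of class `detection_call` with `b`, `d`, `b_exp`,
#'   `ratio = b / b_exp` and `detected`.
#' @export
call_presence <- function(profile, model = detection_model()) {
  stopifnot(inherits(profile, "coverage_profile"))
  d <- profile$mean_depth; b <- profile$breadth
  if (d == 0) {
    return(structure(list(genome_id = profile$genome_id, b = b, d = d,
                          b_exp = 0, ratio = 0, detected = FALSE,
                          sidedness = model$sidedness),
                     class = "detection_call"))
  }
  b_exp <- expected_breadth(d, model)
  detected <- if (model$sidedness == "one_sided_lower") {
    b >= (1 - model$tolerance) * b_exp
  } else {
    abs(b - b_exp) <= model$tolerance * b_exp
  }
  structure(list(genome_id = profile$genome_id, b = b, d = d, b_exp = b_exp,
                 ratio = b / b_exp, detected = detected,
                 sidedness = model$sidedness),
            class = "detection_call")
}

#' @export
print.detection_call <- function(x, ...) {
  cat(sprintf("<detection_call> %s: depth %.3f, breadth %.3f, expected %.3f (%s) -> %s\n",
              x$genome_id, x$d, x$b, x$b_exp, x$sidedness,
              if (x$detected) "detected" else "not detected"))
  invisible(x)
}
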