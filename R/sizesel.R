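#' Size-selection sampling model
#'
#' Represents fragment size selection as a normal sampling density over
#' fragment length: a fragment of length L enters the library with
#' probability proportional to `dnorm(L, mu, sigma)`, optionally truncated
#' by a hard window. The standard deviation captures sizing precision —
#' small for automated size selection, large for leaky gel excision.
#'
#' @param mu Selection target mean (bp).
#' @param sigma Sampling standard deviation (bp), > 0.
#' @param window Optional `c(lo, hi)` hard bounds; fragments outside get
#'   zero weight.
#' @return Object of class `size_selection_model`.
#' @examples
#' size_selection_model(300, 25)
#' @export
size_selection_model <- function(mu, sigma, window = NULL) {
  if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
  if (!is.null(window)) {
    if (length(window) != 2L || window[1] > window[2])
      stop("window must be c(lo, hi) with lo <= hi")
  }
  structure(list(mu = mu, sigma = sigma, window = window),
            class = "size_selection_model")
}

#' @export
print.size_selection_model <- function(x, ...) {
  cat(sprintf("<size_selection_model> mu = %g bp, sigma = %g bp%s\n",
              x$mu, x$sigma,
              if (is.null(x$window)) "" else
                sprintf(", window [%g, %g]", x$window[1], x$window[2])))
  invisible(x)
}

#' Per-fragment recovery weights under a size-selection model
#'
#' Representation of a fragment in the library is proportional to the
#' normal sampling density at its length; weights are normalised to sum
#' to 1 over the supplied fragments. Fragments outside a hard window get
#' weight 0.
#'
#' @param fragments Fragment data.frame (AB subset) or a numeric vector of
#'   fragment lengths.
#' @param model A [size_selection_model()].
#' @return Numeric weight vector summing to 1.
#' @examples
#' m <- size_selection_model(300, 25)
#' selection_weights(c(300, 325), m)  # density ratio exp(0.5)
#' @export
selection_weights <- function(fragments, model) {
  lens <- if (is.data.frame(fragments)) fragments$length else as.numeric(fragments)
  if (length(lens) == 0L) stop("no fragments supplied")
  w <- stats::dnorm(lens, mean = model$mu, sd = model$sigma)
  if (!is.null(model$window))
    w[lens < model$window[1] | lens > model$window[2]] <- 0
  s <- sum(w)
  if (s <= 0)
    stop("all selection weights are zero: model/window does not overlap the fragment lengths")
  w / s
}

#' Expected number of regions reaching a coverage threshold
#'
#' With R reads allocated multinomially over fragment weights w, the
#' per-fragment read count is approximately Poisson with mean R * w_i, so
#' the expected number of regions at >= c reads is
#' `sum_i P(Poisson(R * w_i) >= c)`. Deterministic; the Monte-Carlo
#' counterpart is [simulate_read_allocation()].
#'
#' @param weights Normalised weight vector from [selection_weights()].
#' @param R Total read investment (reads).
#' @param c Coverage threshold (default 7, the depth generally required
#'   for confident genotypes).
#' @return Expected count (real).
#' @examples
#' expected_regions_at_coverage(rep(0.1, 10), 70)  # 10 * P(Pois(7) >= 7)
#' @export
expected_regions_at_coverage <- function(weights, R, c = 7) {
  if (c < 1) stop("coverage threshold c must be >= 1")
  if (R < 0) stop("R must be >= 0")
  lambda <- R * weights
  sum(stats::ppois(c - 1, lambda, lower.tail = FALSE))
}

#' Simulate a multinomial read allocation over fragments
#'
#' Draws R reads over the fragment weights; the stochastic counterpart of
#' the Poisson expectation in [expected_regions_at_coverage()].
#'
#' @inheritParams expected_regions_at_coverage
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of read counts per fragment, summing to R.
#' @export
simulate_read_allocation <- function(weights, R, seed = NULL) {
  if (R < 0) stop("R must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (R == 0) return(integer(length(weights)))
  as.integer(stats::rmultinom(1, size = R, prob = weights)[, 1])
}

#' Read budget for a mean coverage target
#'
#' Uniform-allocation arithmetic: covering `n_regions` regions at an
#' average depth of `coverage` costs `n_regions * coverage` reads. This is
#' the budgeting rule used to decide how many individuals fit in a lane.
#'
#' @param n_regions Number of targeted regions.
#' @param coverage Mean per-region coverage.
#' @return Read count R.
#' @examples
#' reads_for_mean_coverage(10000, 20)  # 200000 reads per individual
#' @export
reads_for_mean_coverage <- function(n_regions, coverage) {
  if (n_regions < 0 || coverage < 0) stop("arguments must be >= 0")
  n_regions * coverage
}

#' Read investment at which region recovery saturates
#'
#' Scans read budgets on a geometric grid and returns the smallest R at
#' which the marginal gain in expected regions at >= c coverage per
#' additional read drops below `epsilon` (default 0.02: fewer than 2% of
#' new reads recover new regions). Beyond this point extra sequencing
#' mostly deepens already-covered regions — the transition from logistic
#' to asymptotic accumulation.
#'
#' @inheritParams expected_regions_at_coverage
#' @param epsilon Marginal-gain threshold (regions per read).
#' @param grid_factor Geometric grid ratio for candidate R values.
#' @param R_max Upper bound on the scan; beyond it the distribution is
#'   reported unsaturable.
#' @return List with `R_saturation` (NA if unsaturable), `expected_regions`
#'   at that R, and the scanned `grid`.
#' @export
saturation_read_count <- function(weights, c = 7, epsilon = 0.02,
                                  grid_factor = 1.1,
                                  R_max = 1e9) {
  R <- 10
  prevE <- expected_regions_at_coverage(weights, R, c)
  grid <- data.frame(R = R, expected = prevE)
  risen <- FALSE  # accumulation is sigmoidal: skip the initial lag phase
  repeat {
    R2 <- ceiling(R * grid_factor)
    E2 <- expected_regions_at_coverage(weights, R2, c)
    grid <- rbind(grid, data.frame(R = R2, expected = E2))
    gain <- (E2 - prevE) / (R2 - R)
    if (gain >= epsilon) risen <- TRUE
    if (risen && gain < epsilon)
      return(list(R_saturation = R2, expected_regions = E2, grid = grid))
    if (R2 > R_max)
      return(list(R_saturation = NA_real_, expected_regions = E2, grid = grid))
    R <- R2
    prevE <- E2
  }
}

#' Fit the size-selection standard deviation to observed coverage
#'
#' Without a reference genome, observed regions cannot be matched to
#' genomic fragments, so observed and model coverage vectors are compared
#' by rank: for each candidate sigma the expected per-fragment coverage
#' under the model is computed, both vectors are sorted, and the Pearson
#' r-squared of log(coverage + 1) is taken. The sigma maximising r-squared
#' is returned. The observed vector is zero-padded (or the model vector
#' truncated) so both cover the same number of regions.
#'
#' @param observed Observed per-region read counts (coverage >= 1 regions).
#' @param fragments Fragment data.frame or length vector for the digest
#'   being modelled.
#' @param mu Selection mean (bp), fixed during the fit.
#' @param sd_grid Candidate sigmas (default 1-100 bp in 0.5 bp steps).
#' @param R Total read count matching the observation (default
#'   `sum(observed)`).
#' @return List with `sd` (best-fit sigma), `r2`, and the full `grid`
#'   data.frame of candidate sigmas and r-squared values.
#' @export
fit_selection_sd <- function(observed, fragments, mu,
                             sd_grid = seq(1, 100, by = 0.5),
                             R = sum(observed)) {
  if (length(observed) < 10)
    stop("need at least 10 observed regions to fit sigma")
  lens <- if (is.data.frame(fragments)) fragments$length else as.numeric(fragments)
  nfrag <- length(lens)
  obs <- sort(observed, decreasing = TRUE)
  if (length(obs) < nfrag) obs <- c(obs, numeric(nfrag - length(obs)))
  lobs <- log(obs + 1)
  r2 <- vapply(sd_grid, function(s) {
    w <- stats::dnorm(lens, mu, s)
    sw <- sum(w)
    if (sw <= 0) return(NA_real_)
    lam <- sort(R * w / sw, decreasing = TRUE)
    if (length(lam) < length(lobs)) lam <- c(lam, numeric(length(lobs) - length(lam)))
    llam <- log(lam + 1)
    if (stats::sd(llam) == 0 || stats::sd(lobs) == 0) return(NA_real_)
    stats::cor(lobs, llam)^2
  }, numeric(1))
  best <- which.max(r2)
  list(sd = sd_grid[best], r2 = r2[best],
       grid = data.frame(sd = sd_grid, r2 = r2))
}

#' Regions covered at threshold in both of two samples
#'
#' Counts the fragments reaching coverage >= c in both coverage vectors —
#' the shared-region statistic used to assess cross-sample repeatability
#' of size selection.
#'
#' @param counts_a,counts_b Per-fragment read counts over the same index.
#' @param c Coverage threshold.
#' @return Integer count of shared regions.
#' @export
shared_regions <- function(counts_a, counts_b, c = 7) {
  if (length(counts_a) != length(counts_b))
    stop("coverage vectors must have the same length")
  sum(counts_a >= c & counts_b >= c)
}

#' Coverage prediction report
#'
#' Convenience wrapper assembling the standard design-phase prediction for
#' a digest + size selection + read budget: expected regions at coverage
#' and the saturating read count.
#'
#' @param fragments AB fragment data.frame or length vector.
#' @param model A [size_selection_model()].
#' @param R Read investment.
#' @param c Coverage threshold.
#' @return List `n_fragments`, `R`, `c`, `expected_regions`, `R_saturation`.
#' @export
predict_coverage <- function(fragments, model, R, c = 7) {
  w <- selection_weights(fragments, model)
  sat <- saturation_read_count(w, c = c)
  list(n_fragments = length(w), R = R, c = c,
       expected_regions = expected_regions_at_coverage(w, R, c),
       R_saturation = sat$R_saturation)
}
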