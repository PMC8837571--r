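#' Built-in test fixtures
#'
#' Generates small, fully characterized inputs used throughout the test
#' suite and examples:
#' \describe{
#'   \item{\code{"planted-rule"}}{a labelled feature table whose label is
#'     determined by a single threshold rule on one informative feature
#'     (label \code{"higher"} iff \code{f_signal > threshold}, flipped with
#'     probability \code{noise}), plus pure-noise features. The informative
#'     feature is sampled away from the threshold so the decision boundary
#'     sits inside a known gap. Ground truth (feature name, threshold, gap)
#'     is stored in attribute \code{"ground_truth"}.}
#'   \item{\code{"decoupled"}}{a 4-species \code{\link{network_spec}} with no
#'     interactions (\code{r = 0}, no stress coupling), whose equilibria
#'     have the closed form \code{soft_switch(r0)} and whose trajectories
#'     relax exponentially at rates \code{k}.}
#'   \item{\code{"bistable-toy"}}{a 1-species self-activation switch
#'     \code{x' = k (F(r0 + r x + s) - x)} with analytically locatable
#'     folds; its bistable window contains the default protocol baseline
#'     and its upper fold lies below the default pulse peak.}
#' }
#'
#' @param kind one of \code{"planted-rule"}, \code{"decoupled"},
#'   \code{"bistable-toy"}.
#' @param n rows of the planted-rule table.
#' @param n_noise number of pure-noise features.
#' @param noise label-flip probability.
#' @param seed RNG seed for the planted-rule table.
#' @return a data frame (planted-rule) or a \code{network_spec}.
#' @export
make_fixture <- function(kind = c("planted-rule", "decoupled",
                                  "bistable-toy"),
                         n = 400, n_noise = 9, noise = 0.05, seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    "planted-rule" = {
      set.seed(seed)
      thr <- 0.5
      gap <- c(0.45, 0.55)
      a <- stats::runif(n, 0, 1 - diff(gap))
      a <- ifelse(a >= gap[1], a + diff(gap), a)   # uniform outside the gap
      noise_cols <- stats::setNames(
        lapply(seq_len(n_noise), function(i) stats::runif(n)),
        paste0("f_noise", seq_len(n_noise)))
      lab <- ifelse(a > thr, "higher", "control")
      flip <- stats::runif(n) < noise
      lab[flip] <- ifelse(lab[flip] == "higher", "control", "higher")
      out <- data.frame(f_signal = a, noise_cols, label = lab,
                        stringsAsFactors = FALSE)
      attr(out, "ground_truth") <- list(feature = "f_signal",
                                        threshold = thr, gap = gap,
                                        noise = noise)
      out
    },
    "decoupled" = network_spec(
      c("CRH", "ACTH", "COR", "GR"),
      k = c(1, 2, 4, 8), sigma = 1,
      r0 = c(-1, 0.5, -0.25, 2), r = matrix(0, 4, 4),
      stress_coupling = rep(0, 4)),
    "bistable-toy" = network_spec(
      "X", k = 1, sigma = 1, r0 = -3.4,
      r = matrix(6, 1, 1), stress_coupling = 1)
  )
}
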