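#' Default HPA-axis model
#'
#' The shipped wiring of the hypothalamic-pituitary-adrenal (HPA) axis:
#' stress drives CRH; CRH activates ACTH; ACTH activates cortisol (COR); COR
#' activates the glucocorticoid receptor (GR); GR represses CRH and ACTH
#' (negative feedback); CRH and GR each carry positive self-feedback. The
#' stress input enters only through the CRH input weight.
#'
#' The numeric weights are a reconstruction: they encode this wiring with a
#' global steepness \code{sigma = 1}, under which a self-activation weight
#' must exceed 4 for a species to be bistable on its own. Individual virtual
#' patients are obtained by resampling the weights (see
#' \code{\link{default_ranges}} and \code{\link{sample_parameters}}).
#'
#' @return a \code{\link{network_spec}} for species CRH, ACTH, COR, GR.
#' @export
default_hpa_spec <- function() {
  sp <- c("CRH", "ACTH", "COR", "GR")
  r <- matrix(0, 4, 4, dimnames = list(sp, sp))
  r["CRH", "CRH"] <- 3     # CRH positive self-feedback
  r["CRH", "GR"] <- -4     # GR represses CRH
  r["ACTH", "CRH"] <- 4    # CRH activates ACTH
  r["ACTH", "GR"] <- -4    # GR represses ACTH
  r["COR", "ACTH"] <- 4    # ACTH releases cortisol
  r["GR", "COR"] <- 2      # cortisol activates GR
  r["GR", "GR"] <- 3       # GR positive self-feedback
  network_spec(sp,
               k = c(1, 1, 1, 1),
               sigma = 1,
               r0 = c(CRH = -2, ACTH = -2, COR = -2, GR = -3),
               r = r,
               stress_coupling = c(1, 0, 0, 0))
}

#' Default uniform sampling ranges for virtual patients
#'
#' Uniform (low, high) bounds for every sampled parameter of the default HPA
#' model: relaxation rates in [1, 10], basal weights in [-4, 0], activating
#' and positive-feedback weights in [0, 8], repressive weights in [-8, 0].
#' The ranges are a documented reconstruction chosen so that the population
#' contains all three response classes (higher, lower, control).
#'
#' @return a named list of length-2 numeric vectors \code{c(low, high)},
#'   usable with \code{\link{sample_parameters}}.
#' @export
default_ranges <- function() {
  list(
    k_CRH = c(1, 10), k_ACTH = c(1, 10), k_COR = c(1, 10), k_GR = c(1, 10),
    R0_CRH = c(-4, 0), R0_ACTH = c(-4, 0), R0_COR = c(-4, 0),
    R0_GR = c(-4, 0),
    R_CRH_CRH = c(0, 8),   # CRH self-feedback
    R_GR_GR = c(0, 8),     # GR self-feedback
    R_CRH_ACTH = c(0, 8),  # CRH -> ACTH
    R_ACTH_COR = c(0, 8),  # ACTH -> COR
    R_COR_GR = c(0, 8),    # COR -> GR
    R_GR_CRH = c(-8, 0),   # GR -| CRH
    R_GR_ACTH = c(-8, 0)   # GR -| ACTH
  )
}

#' Representative virtual patients
#'
#' Five synthetic representative parameter sets illustrating the response
#' classes and their mechanistic explanations: VP1 is a higher VP whose CRH
#' positive feedback creates a bistable switch (VP2 is VP1 with the CRH
#' self-weight reduced, removing the pathological attractor); VP3 is a lower
#' VP whose GR positive feedback latches on after stress (VP4 is VP3 with the
#' basal ACTH weight reduced; VP5 is VP3 with the GR self-weight reduced,
#' trading the latch for an oscillatory regime at elevated stress). These
#' parameter sets are reconstructions calibrated to reproduce the documented
#' qualitative phenotypes; they are not fitted to data.
#'
#' @param which one of \code{"VP1"} ... \code{"VP5"}.
#' @return a \code{\link{network_spec}}.
#' @export
hpa_example_vp <- function(which = c("VP1", "VP2", "VP3", "VP4", "VP5")) {
  which <- match.arg(which)
  base <- default_hpa_spec()
  edits <- hpa_example_edits()[[which]]
  for (nm in names(edits)) base <- spec_set(base, nm, edits[[nm]])
  base
}

# named edits applied to the default spec for each representative VP.
# VP1's basal CRH weight is calibrated so its upper saddle-node sits at
# stress 0.7; VP5's GR self-weight so its Hopf onset sits at stress 0.4.
hpa_example_edits <- function() {
  vp1 <- list(
    R_CRH_CRH = 6, R0_CRH = -3.161383, R0_GR = -4, R_GR_CRH = -4,
    R_CRH_ACTH = 4, R0_ACTH = -2, R_ACTH_COR = 4, R0_COR = -2,
    R_COR_GR = 2, R_GR_GR = 2, R_GR_ACTH = -4,
    k_CRH = 2, k_ACTH = 2, k_COR = 2, k_GR = 2)
  vp2 <- vp1; vp2$R_CRH_CRH <- 3
  vp3 <- list(
    R_CRH_CRH = 2.422, R0_CRH = -1.31, R_GR_CRH = -6.163,
    R_CRH_ACTH = 7.035, R0_ACTH = -2.355, R_GR_ACTH = -2.331,
    R_ACTH_COR = 7.973, R0_COR = -2.903,
    R_COR_GR = 3.032, R_GR_GR = 8, R0_GR = -4,
    k_CRH = 2, k_ACTH = 2, k_COR = 2, k_GR = 2)
  vp4 <- vp3; vp4$R0_ACTH <- -7
  vp5 <- vp3; vp5$R_GR_GR <- 4.913
  list(VP1 = vp1, VP2 = vp2, VP3 = vp3, VP4 = vp4, VP5 = vp5)
}

# ---- structured-text (YAML) model configuration ---------------------------

#' Read and write model configuration files
#'
#' A model configuration is a YAML file with sections \code{species},
#' \code{k}, \code{sigma}, \code{r0}, \code{influences} (a list of
#' \code{source -> target: weight} entries), \code{stress_coupling},
#' \code{protocol} and optionally \code{ranges}. The shipped default lives at
#' \code{system.file("extdata", "hpa_model.yaml", package = "vpaxis")}.
#'
#' @param path file path.
#' @return \code{read_model_config} returns a list with elements
#'   \code{spec} (a \code{\link{network_spec}}), \code{protocol} (a
#'   \code{\link{stress_protocol}} or NULL) and \code{ranges} (named list or
#'   NULL).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sp <- as.character(cfg$species)
  n <- length(sp)
  r <- matrix(0, n, n, dimnames = list(sp, sp))
  for (ent in cfg$influences) {
    r[ent$target, ent$source] <- as.numeric(ent$weight)
  }
  spec <- network_spec(sp,
                       k = unlist(cfg$k)[sp],
                       sigma = cfg$sigma,
                       r0 = unlist(cfg$r0)[sp],
                       r = r,
                       stress_coupling = unlist(cfg$stress_coupling)[sp])
  protocol <- NULL
  if (!is.null(cfg$protocol))
    protocol <- do.call(stress_protocol, cfg$protocol[
      c("baseline", "t_on", "t_peak", "rate")])
  ranges <- NULL
  if (!is.null(cfg$ranges))
    ranges <- lapply(cfg$ranges, function(b) as.numeric(unlist(b)))
  list(spec = spec, protocol = protocol, ranges = ranges)
}

#' @rdname read_model_config
#' @param spec a \code{\link{network_spec}}.
#' @param protocol optional \code{\link{stress_protocol}} to embed.
#' @param ranges optional named list of sampling ranges to embed.
#' @export
write_model_config <- function(spec, path, protocol = NULL, ranges = NULL) {
  infl <- list()
  for (i in spec$species) for (j in spec$species) {
    if (spec$r[i, j] != 0)
      infl[[length(infl) + 1L]] <-
        list(source = j, target = i, weight = spec$r[i, j])
  }
  cfg <- list(species = as.list(spec$species),
              sigma = spec$sigma,
              k = as.list(spec$k),
              r0 = as.list(spec$r0),
              stress_coupling = as.list(spec$stress_coupling),
              influences = infl)
  if (!is.null(protocol))
    cfg$protocol <- protocol[c("baseline", "t_on", "t_peak", "rate")]
  if (!is.null(ranges))
    cfg$ranges <- lapply(ranges, as.list)
  yaml::write_yaml(cfg, path)
  invisible(path)
}
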