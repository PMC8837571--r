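#' Sample a virtual patient's parameters
#'
#' Draws each named parameter independently from a uniform distribution over
#' its (low, high) bounds and writes the draw into a copy of the base spec;
#' parameters not named in \code{ranges} keep their base values. Uses the
#' current RNG state.
#'
#' @param base_spec a \code{\link{network_spec}}.
#' @param ranges named list of \code{c(low, high)} bounds; names must resolve
#'   to spec parameters (see \code{\link{spec_get}}).
#' @return a \code{network_spec} with the sampled values.
#' @export
sample_parameters <- function(base_spec, ranges) {
  check_ranges(base_spec, ranges)
  spec <- base_spec
  for (nm in names(ranges)) {
    b <- ranges[[nm]]
    spec <- spec_set(spec, nm, stats::runif(1, b[1], b[2]))
  }
  spec
}

check_ranges <- function(base_spec, ranges) {
  if (is.null(names(ranges)) || any(!nzchar(names(ranges))))
    stop("ranges must be a named list")
  for (nm in names(ranges)) {
    b <- ranges[[nm]]
    if (length(b) != 2L || any(!is.finite(b)) || b[1] > b[2])
      stop("range for ", nm, " must be c(low, high) with low <= high")
    spec_get(base_spec, nm)   # errors on unknown names
  }
  invisible(TRUE)
}

#' Simulate and label a single virtual patient
#'
#' Runs the stress protocol on \code{spec} and packages the result.
#'
#' @param spec a \code{\link{network_spec}}.
#' @param protocol a \code{\link{stress_protocol}}.
#' @param id identifier stored with the patient.
#' @param ... passed to \code{\link{run_stress_protocol}}.
#' @return an object of class \code{"virtual_patient"}: list with \code{id},
#'   \code{spec}, \code{label}, \code{ss_before_cor}, \code{ss_after_cor}
#'   and the full \code{response}.
#' @export
simulate_vp <- function(spec, protocol, id = "vp", ...) {
  resp <- run_stress_protocol(spec, protocol, vp_id = id, ...)
  structure(list(id = id, spec = spec, label = resp$label,
                 ss_before_cor = resp$ss_before_cor,
                 ss_after_cor = resp$ss_after_cor,
                 response = resp),
            class = "virtual_patient")
}

#' @export
print.virtual_patient <- function(x, ...) {
  cat(sprintf("Virtual patient %s: %s (COR %.4f -> %.4f)\n", x$id, x$label,
              x$ss_before_cor, x$ss_after_cor))
  invisible(x)
}

#' Derive a new virtual patient by a single parameter edit
#'
#' Returns a patient identical to \code{vp} except for one parameter, which
#' is set to \code{new_value}; the edited model is re-simulated and
#' re-labelled under the same protocol.
#'
#' @param vp a \code{"virtual_patient"}.
#' @param param_name parameter to edit (see \code{\link{spec_get}}).
#' @param new_value finite replacement value.
#' @param protocol a \code{\link{stress_protocol}}.
#' @param id identifier for the derived patient.
#' @param ... passed to \code{\link{run_stress_protocol}}.
#' @return a new \code{"virtual_patient"}.
#' @export
derive_vp <- function(vp, param_name, new_value, protocol,
                      id = paste0(vp$id, "_derived"), ...) {
  spec <- spec_set(vp$spec, param_name, new_value)
  simulate_vp(spec, protocol, id = id, ...)
}

# deterministic per-draw substream seed from the master seed
draw_seed <- function(master_seed, i) {
  (as.numeric(master_seed) * 48271 + i * 16807) %% 2147483647
}

#' Build a labelled virtual-patient population
#'
#' Repeatedly samples parameter sets from \code{ranges}, simulates the stress
#' protocol and labels each draw, keeping draws until every response class
#' (higher, lower, control) holds \code{n_per_class} members; over-quota
#' draws for a filled class are discarded. Each draw uses a substream seed
#' derived deterministically from \code{seed}, so the population is fully
#' reproducible and individual draws can be replayed.
#'
#' @param base_spec a \code{\link{network_spec}}.
#' @param ranges named sampling ranges, see \code{\link{sample_parameters}}.
#' @param protocol a \code{\link{stress_protocol}}.
#' @param n_per_class members required in each of the three classes.
#' @param seed master seed (integer).
#' @param max_attempts cap on total draws before a quota failure is raised.
#' @param label_tol equality tolerance for the control class.
#' @param verbose print progress every 200 draws.
#' @return a \code{data.frame} of class \code{"population_table"}: columns
#'   \code{id}, one column per sampled parameter, \code{ss_before},
#'   \code{ss_after}, \code{label}; attribute \code{provenance} records
#'   seed, ranges, protocol, tolerances and simulation failures.
#' @export
build_population <- function(base_spec, ranges, protocol, n_per_class,
                             seed = 1L,
                             max_attempts = 100 * 3 * n_per_class,
                             label_tol = 1e-3, verbose = FALSE) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  check_ranges(base_spec, ranges)
  classes <- c("higher", "lower", "control")
  quota <- stats::setNames(rep(n_per_class, 3), classes)
  count <- stats::setNames(rep(0L, 3), classes)
  rows <- vector("list", 3L * n_per_class)
  n_kept <- 0L
  failures <- list()
  attempt <- 0L
  while (any(count < quota) && attempt < max_attempts) {
    attempt <- attempt + 1L
    set.seed(draw_seed(seed, attempt))
    spec <- sample_parameters(base_spec, ranges)
    vp <- tryCatch(
      simulate_vp(spec, protocol, id = sprintf("vp%06d", attempt),
                  label_tol = label_tol),
      vpaxis_sim_failure = function(e) e)
    if (inherits(vp, "condition")) {
      failures[[length(failures) + 1L]] <-
        list(attempt = attempt, message = conditionMessage(vp))
      next
    }
    if (count[vp$label] >= quota[vp$label]) next
    count[vp$label] <- count[vp$label] + 1L
    n_kept <- n_kept + 1L
    rows[[n_kept]] <- c(list(id = vp$id),
                        lapply(names(ranges), function(nm)
                          spec_get(spec, nm)) |>
                          stats::setNames(names(ranges)),
                        list(ss_before = vp$ss_before_cor,
                             ss_after = vp$ss_after_cor,
                             label = vp$label))
    if (verbose && attempt %% 200 == 0)
      message(sprintf("attempt %d: higher %d, lower %d, control %d",
                      attempt, count["higher"], count["lower"],
                      count["control"]))
  }
  if (any(count < quota)) {
    stop(structure(
      class = c("vpaxis_quota_failure", "error", "condition"),
      list(message = sprintf(
        paste0("quota not met after %d attempts ",
               "(higher %d/%d, lower %d/%d, control %d/%d)"),
        attempt, count["higher"], n_per_class, count["lower"], n_per_class,
        count["control"], n_per_class),
        call = sys.call(-1), counts = count)))
  }
  pop <- do.call(rbind, lapply(rows[seq_len(n_kept)], function(rw)
    as.data.frame(rw, stringsAsFactors = FALSE)))
  rownames(pop) <- NULL
  attr(pop, "provenance") <- list(
    seed = seed, ranges = ranges,
    protocol = unclass(protocol)[c("baseline", "t_on", "t_peak", "rate")],
    label_tol = label_tol, n_per_class = n_per_class,
    n_attempts = attempt, failures = failures)
  class(pop) <- c("population_table", "data.frame")
  pop
}

#' @export
print.population_table <- function(x, ...) {
  cat("Virtual-patient population:", nrow(x), "patients\n")
  print(table(x$label))
  invisible(x)
}

#' Reconstruct the network spec of one population row
#'
#' @param pop a \code{"population_table"}.
#' @param row row index or \code{id}.
#' @param base_spec the base spec the population was sampled from.
#' @return a \code{\link{network_spec}} carrying that row's parameters.
#' @export
population_spec <- function(pop, row, base_spec) {
  if (is.character(row)) row <- match(row, pop$id)
  prov <- attr(pop, "provenance")
  pnames <- names(prov$ranges)
  spec <- base_spec
  for (nm in pnames) spec <- spec_set(spec, nm, pop[[nm]][row])
  spec
}

#' Write / read a population table
#'
#' The table itself is written as CSV; provenance (seed, ranges, protocol,
#' tolerances, failures) as a JSON sidecar at \code{<path>.json}.
#'
#' @param pop a \code{"population_table"}.
#' @param path CSV file path.
#' @export
write_population <- function(pop, path) {
  utils::write.csv(as.data.frame(pop), path, row.names = FALSE)
  prov <- attr(pop, "provenance")
  if (!is.null(prov))
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- utils::read.csv(path, stringsAsFactors = FALSE)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    prov <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(prov$ranges))
      prov$ranges <- lapply(prov$ranges, as.numeric)
    attr(pop, "provenance") <- prov
  }
  class(pop) <- c("population_table", "data.frame")
  pop
}
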