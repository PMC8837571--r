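#' Assemble a reproducible run configuration
#'
#' Bundles everything a full analysis run depends on — model, protocol,
#' sampling ranges, class quotas, ML and continuation settings, master seed
#' and output directory — into one serializable object; a run is
#' reproducible from the configuration alone.
#'
#' @param spec base \code{\link{network_spec}} (default: the shipped HPA
#'   model).
#' @param protocol a \code{\link{stress_protocol}}.
#' @param ranges named sampling ranges.
#' @param n_per_class virtual patients per response class.
#' @param label_tol control-class equality tolerance.
#' @param seed master seed.
#' @param n_trees random-forest size.
#' @param max_depth decision-tree depth.
#' @param svm_features optional 2-vector of feature names per comparison
#'   (default: top two by forest importance).
#' @param stress_range continuation window.
#' @param out_dir output directory.
#' @return a list of class \code{"run_config"}.
#' @export
run_config <- function(spec = default_hpa_spec(),
                       protocol = stress_protocol(),
                       ranges = default_ranges(),
                       n_per_class = 50, label_tol = 1e-3, seed = 1L,
                       n_trees = 500, max_depth = 3, svm_features = NULL,
                       stress_range = c(0, 2), out_dir = "vpaxis_run") {
  structure(list(spec = spec, protocol = protocol, ranges = ranges,
                 n_per_class = n_per_class, label_tol = label_tol,
                 seed = seed, n_trees = n_trees, max_depth = max_depth,
                 svm_features = svm_features, stress_range = stress_range,
                 out_dir = out_dir),
            class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  payload <- list(
    spec = unclass(config$spec)[c("species", "k", "sigma", "r0",
                                  "stress_coupling")],
    r = as.vector(config$spec$r),
    protocol = unclass(config$protocol),
    ranges = config$ranges, n_per_class = config$n_per_class,
    label_tol = config$label_tol, seed = config$seed,
    n_trees = config$n_trees, max_depth = config$max_depth,
    stress_range = config$stress_range)
  jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full virtual-patient analysis pipeline
#'
#' Executes the staged workflow: (1) build a labelled virtual-patient
#' population by rejection sampling; (2) for each pathological class versus
#' control, rank parameters by random-forest permutation importance, fit a
#' depth-limited decision tree and train a two-feature SVM boundary; (3)
#' trace equilibrium branches versus stress for one representative patient
#' of each pathological class, with fold/Hopf detection and bistable
#' windows. All artifacts are written under \code{config$out_dir} with the
#' configuration hash attached; a rerun with the same configuration
#' reproduces them.
#'
#' @param config a \code{\link{run_config}}.
#' @param verbose print per-stage progress.
#' @return (invisibly) a list with the population, the per-comparison ML
#'   results, the continuation results and the output paths.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- proc.time()[3]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("stage %-12s %6.1f s", name, proc.time()[3] - t0)
    out
  }
  paths <- list()

  pop <- stage("population", build_population(
    config$spec, config$ranges, config$protocol, config$n_per_class,
    seed = config$seed, label_tol = config$label_tol))
  paths$population <- file.path(config$out_dir, "population.csv")
  prov <- attr(pop, "provenance")
  prov$config_hash <- hash
  attr(pop, "provenance") <- prov
  write_population(pop, paths$population)

  features <- names(config$ranges)
  ml <- list()
  for (cls in c("higher", "lower")) {
    cmp <- paste0(cls, "_vs_control")
    res <- stage(cmp, {
      sub <- pop[pop$label %in% c(cls, "control"), , drop = FALSE]
      imp <- rf_importance(sub, features, classes = c(cls, "control"),
                           n_trees = config$n_trees,
                           seed = config$seed)
      tree <- fit_tree(sub, features, classes = c(cls, "control"),
                       max_depth = config$max_depth)
      feats2 <- config$svm_features %||% imp$parameter[1:2]
      svm <- svm_train(sub, feats2, classes = c(cls, "control"),
                       seed = config$seed)
      list(importance = imp, tree = tree, svm = svm,
           svm_features = feats2)
    })
    ml[[cmp]] <- res
    paths[[paste0("importance_", cmp)]] <-
      file.path(config$out_dir, paste0("importance_", cmp, ".json"))
    write_importance_json(res$importance, paths[[paste0("importance_", cmp)]])
    paths[[paste0("tree_", cmp)]] <-
      file.path(config$out_dir, paste0("tree_", cmp, ".json"))
    write_tree_json(res$tree, paths[[paste0("tree_", cmp)]])
  }

  cont <- list()
  for (cls in c("higher", "lower")) {
    res <- stage(paste0("bifurcate_", cls), {
      idx <- which(pop$label == cls)[1]
      spec_i <- population_spec(pop, idx, config$spec)
      summ <- bifurcation_summary(spec_i, config$stress_range)
      summ$vp_id <- pop$id[idx]
      summ
    })
    cont[[cls]] <- res
    for (bi in seq_along(res$branches)) {
      p <- file.path(config$out_dir,
                     sprintf("branch_%s_%d.csv", res$vp_id, bi))
      write_branch_csv(res$branches[[bi]], p)
      paths[[sprintf("branch_%s_%d", res$vp_id, bi)]] <- p
    }
  }

  summary <- list(
    config_hash = hash,
    files = unname(unlist(paths)),
    class_counts = as.list(table(pop$label)),
    top_parameters = lapply(ml, function(m)
      utils::head(m$importance$parameter, 3)),
    folds = lapply(cont, function(cn)
      lapply(cn$folds, function(f) list(stress = f$stress))),
    hopf = lapply(cont, function(cn)
      lapply(cn$hopf, function(h) list(stress = h$stress))),
    bistable = lapply(cont, function(cn)
      apply(cn$bistable, 1, as.list)))
  paths$summary <- file.path(config$out_dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(population = pop, ml = ml, continuation = cont,
                 paths = paths, config_hash = hash))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
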