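#' Assemble a pipeline configuration
#'
#' Collects everything one disparity-through-time analysis needs. Every input
#' can be given either as an in-memory object or as a file path (Newick/NEXUS
#' for the topology, CSV for tables, TPS for landmarks); paths are read when
#' the pipeline runs. A YAML file with the same field names can be loaded
#' with [read_pipeline_config()].
#'
#' @param topology rooted supertree (`phylo` or tree file path).
#' @param ranges stratigraphic range table ([strat_ranges()] or CSV path).
#' @param scores tip score matrix (specimens x axes, or CSV path), or `NULL`
#'   when `configs` is given.
#' @param configs named list of landmark configurations (or TPS path); run
#'   through GPA + PCA with broken-stick selection when `scores` is absent.
#' @param bins time-bin series ([time_bins()] or CSV path).
#' @param constraint_sets list of node-constraint sets (or long CSV path).
#' @param covariates named list of per-bin covariate vectors (or CSV paths;
#'   see [read_covariate()]).
#' @param clades named list of tip-label vectors to analyse as subclades.
#' @param exclude_fossils drop all fossil tips before the analysis?
#' @param n_retained optional override of the broken-stick axis count.
#' @param fossil_age_mode,resolve_polytomies,n_replicates,vartime,seed
#'   ensemble settings, see [timescale_spec()].
#' @param out_dir optional output directory for CSV results.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(topology, ranges, scores = NULL, configs = NULL,
                            bins, constraint_sets = list(), covariates = list(),
                            clades = list(), exclude_fossils = FALSE,
                            n_retained = NULL,
                            fossil_age_mode = "uniform", resolve_polytomies = TRUE,
                            n_replicates = 100L, vartime = 1, seed = 1L,
                            out_dir = NULL) {
  structure(list(topology = topology, ranges = ranges, scores = scores,
                 configs = configs, bins = bins,
                 constraint_sets = constraint_sets, covariates = covariates,
                 clades = clades, exclude_fossils = isTRUE(exclude_fossils),
                 n_retained = n_retained,
                 spec = timescale_spec(fossil_age_mode, resolve_polytomies,
                                       n_replicates, vartime, seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' The YAML fields mirror the arguments of [pipeline_config()]; file-path
#' fields are resolved relative to the YAML file's directory.
#'
#' @param file YAML path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(file) {
  y <- yaml::read_yaml(file)
  base <- dirname(normalizePath(file))
  rel <- function(p) if (is.character(p) && !file.exists(p)) file.path(base, p) else p
  for (f in c("topology", "ranges", "scores", "configs", "bins", "constraint_sets"))
    if (!is.null(y[[f]])) y[[f]] <- rel(y[[f]])
  if (!is.null(y$covariates)) y$covariates <- lapply(y$covariates, rel)
  do.call(pipeline_config, y)
}

## internal: materialise file-path inputs
.load_input <- function(x, reader) if (is.character(x) && length(x) == 1L) reader(x) else x

.read_topology <- function(path) {
  first <- toupper(readLines(path, n = 1L, warn = FALSE))
  if (grepl("^#NEXUS", first)) ape::read.nexus(path) else ape::read.tree(path)
}

#' Run the full disparity-through-time pipeline
#'
#' For each replicate tree of the stochastic ensemble: resolve polytomies (if
#' requested), sample fossil ages, draw a constraint set, time-scale with the
#' 'equal' method, reconstruct ancestral scores under Brownian motion, and
#' compute the disparity curve for the whole tree and each configured clade.
#' Curves are then summarised per analysis unit into ensemble bands, and each
#' covariate is tested against each unit's median curve (Spearman, OLS,
#' AR(1)-GLS, first differences). Reruns with the same configuration and
#' seed are bit-identical; each replicate's derived seed and constraint draw
#' are logged.
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_result` with `ensembles` (named list of
#'   `disparity_ensemble`), `curves` (named list of per-replicate curve
#'   lists), `correlations` (data frame, possibly empty), `log` (per-replicate
#'   bookkeeping), and `shape_space` (when landmarks were supplied). When
#'   `out_dir` is set, ensemble/correlation/log CSVs are written there.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  topology <- .load_input(config$topology, .read_topology)
  ranges <- .load_input(config$ranges, read_strat_ranges)
  bins <- .load_input(config$bins, read_time_bins)
  if (!inherits(bins, "time_bins"))
    bins <- time_bins(bins$older, bins$younger, bins$name,
                      if ("midpoint" %in% names(bins)) bins$midpoint)
  constraint_sets <- .load_input(config$constraint_sets, read_node_constraints)

  space <- NULL
  scores <- config$scores
  if (is.null(scores)) {
    configs <- .load_input(config$configs, read_tps)
    if (is.null(configs)) .input_error("supply either 'scores' or 'configs'")
    space <- principal_components(generalized_procrustes(configs),
                                  n_retained = config$n_retained)
    scores <- retained_scores(space)
  } else {
    scores <- .load_input(scores, read_scores_csv)
    if (!is.null(config$n_retained))
      scores <- scores[, seq_len(config$n_retained), drop = FALSE]
  }

  if (config$exclude_fossils) {
    ext <- drop_fossils(topology, ranges)
    topology <- ext$topology
    ranges <- ext$ranges
  }
  miss <- setdiff(topology$tip.label, rownames(scores))
  if (length(miss)) .input_error("tips without scores: ", paste(miss, collapse = ", "))
  scores <- scores[topology$tip.label, , drop = FALSE]

  ## restrict constraints to tips present in the analysed topology (clades can
  ## lose members to fossil exclusion); constraints with < 2 surviving tips
  ## no longer pin a node and are dropped
  constraint_sets <- lapply(constraint_sets, function(set) {
    set <- lapply(set, function(con) {
      con$tips <- intersect(con$tips, topology$tip.label)
      con
    })
    set[vapply(set, function(con) length(con$tips) >= 2L, logical(1))]
  })

  spec <- config$spec
  units <- c(list(all = topology$tip.label), config$clades)
  curves <- stats::setNames(rep(list(vector("list", spec$n_replicates)), length(units)),
                            names(units))
  log <- data.frame(replicate = seq_len(spec$n_replicates),
                    seed = vapply(seq_len(spec$n_replicates),
                                  function(r) derive_seed(spec$seed, "treeset", r), integer(1)),
                    constraint_set = NA_integer_)
  for (r in seq_len(spec$n_replicates)) {
    set.seed(derive_seed(spec$seed, "treeset", r))
    topo <- if (spec$resolve_polytomies) resolve_polytomies_random(topology) else topology
    tip_ages <- sample_fossil_ages(ranges, spec$fossil_age_mode)
    cons <- list()
    if (length(constraint_sets)) {
      ci <- sample.int(length(constraint_sets), 1L)
      log$constraint_set[r] <- ci
      cons <- constraint_sets[[ci]]
    }
    ct <- time_scale_equal(topo, tip_ages, cons, spec$vartime)
    tt <- ancestral_states(ct, scores)
    for (u in names(units)) {
      sub <- if (identical(units[[u]], topology$tip.label)) tt
             else clade_subset(tt, intersect(units[[u]], topology$tip.label))
      curves[[u]][[r]] <- disparity_curve(sub, bins)
    }
  }
  ensembles <- lapply(curves, ensemble_summary)

  correlations <- data.frame()
  if (length(config$covariates)) {
    covs <- lapply(config$covariates, function(cv)
      if (is.character(cv)) read_covariate(cv, bins) else cv)
    for (u in names(ensembles)) for (cv in names(covs)) {
      res <- tryCatch(
        correlate_disparity(ensembles[[u]], covs[[cv]], label = u, covariate_label = cv),
        error = function(e) {
          warning("correlation '", u, "' vs '", cv, "' skipped: ", conditionMessage(e))
          NULL
        })
      if (!is.null(res)) correlations <- rbind(correlations, res)
    }
  }

  out <- structure(list(ensembles = ensembles, curves = curves,
                        correlations = correlations, log = log,
                        shape_space = space, bins = bins),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (u in names(ensembles))
      write_disparity_csv(ensembles[[u]],
                          file.path(config$out_dir, paste0("ensemble_", u, ".csv")))
    if (nrow(correlations))
      utils::write.csv(correlations, file.path(config$out_dir, "correlations.csv"),
                       row.names = FALSE)
    utils::write.csv(log, file.path(config$out_dir, "replicates_log.csv"),
                     row.names = FALSE)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Disparity pipeline result:", length(x$curves[[1L]]), "replicate tree(s),",
      length(x$ensembles), "analysis unit(s),", nrow(x$bins), "time bins\n")
  if (nrow(x$correlations))
    cat("Covariate comparisons:", nrow(x$correlations), "\n")
  invisible(x)
}
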