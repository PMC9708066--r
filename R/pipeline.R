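# Table/tree I/O and the end-to-end pipeline chaining simulate ->
# derive-traits -> fit-tpc -> phylo-signal -> community-stats.

#' Read a trait table from CSV
#'
#' Validates required columns, numeric types and isolate-key
#' uniqueness; errors name the offending column, key or line.
#'
#' @param path CSV file with one row per isolate; must contain an
#'   `isolate_id` column.
#' @param required additional column names that must be present.
#' @return data.frame.  A header-only file yields an empty table.
#' @export
read_trait_table <- function(path, required = c("topt")) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("isolate_id", required)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  if (nrow(df) == 0) return(df)
  dup <- unique(df$isolate_id[duplicated(df$isolate_id)])
  if (length(dup))
    stop("duplicated isolate key(s): ", paste(dup, collapse = ", "))
  for (cl in setdiff(required, "isolate_id")) {
    v <- df[[cl]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(coerced) & !is.na(v))
      if (length(bad))
        stop("non-numeric value(s) in column '", cl, "' at data row(s): ",
             paste(utils::head(bad, 10), collapse = ", "))
      df[[cl]] <- coerced
    }
  }
  df
}

#' Write analysis results to disk
#'
#' Data frames are written as CSV, trees as newick, everything else as
#' JSON.  Returns the paths written, invisibly.
#'
#' @param objects named list of results.
#' @param dir output directory (created if needed).
#' @return invisible character vector of file paths.
#' @export
write_results <- function(objects, dir) {
  stopifnot(is.list(objects), !is.null(names(objects)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(objects)) {
    ob <- objects[[nm]]
    if (inherits(ob, "phylo")) {
      p <- file.path(dir, paste0(nm, ".nwk"))
      ape::write.tree(ob, file = p)
    } else if (is.data.frame(ob)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(ob, p, row.names = FALSE)
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      ob <- if (is.list(ob)) ob[!vapply(ob, is.function, logical(1))] else ob
      ob <- rapply(as.list(ob), unclass, how = "replace")
      jsonlite::write_json(ob, p, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
    }
    paths[nm] <- p
  }
  invisible(paths)
}

#' Run the full synthetic analysis pipeline
#'
#' Chains the whole workflow on a synthetic community: (1) generate the
#' species-sorting scenario (trait table + phylogeny) and per-isolate
#' temperature-rate observations; (2) fit thermal performance curves to
#' every isolate; (3) estimate phylogenetic signal (Pagel's lambda,
#' Blomberg's K) of the log thermal optimum and reconstruct ancestral
#' states; (4) run the community statistics (sorting regression
#' comparison, trait PCA, ATP-respiration scaling, phylum contrasts).
#' All stages run from one seed and a manifest records parameters,
#' outputs and stage timings, so a rerun with the same config is
#' reproducible.
#'
#' @param config named list of overrides; recognised keys:
#'   `seed` (default 1), `out_dir` (default `NULL` = don't write),
#'   `scenario` (list passed to [generate_community_scenario]),
#'   `tpc` (list: `assay_temps`, `noise_cv`, `replicates`),
#'   `signal` (list: `transform`, `n_permutations`),
#'   `stats` (list: `pca_vars`, `t_target`, `activation_energy`).
#' @param verbose print per-stage progress.
#' @return a list with `traits`, `tree`, `tpc_fits`, `lambda`, `K`,
#'   `asr`, `sorting_regression`, `standard_regression`, `pca`,
#'   `scaling`, `contrasts`, and `manifest` (stage list with parameter
#'   snapshot, output files and wall-clock seconds).
#' @export
run_pipeline <- function(config = list(), verbose = FALSE) {
  known <- c("seed", "out_dir", "scenario", "tpc", "signal", "stats")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  seed <- config$seed %||% 1L
  tpc_cfg <- config$tpc %||% list()
  sig_cfg <- config$signal %||% list()
  st_cfg <- config$stats %||% list()
  stages <- list()
  tick <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- force(expr)
    stages[[name]] <<- list(seconds = proc.time()[["elapsed"]] - t0)
    if (verbose) message(sprintf("stage %s done (%.2fs)",
                                 name, stages[[name]]$seconds))
    val
  }

  scen <- tick("simulate", do.call(generate_community_scenario,
                                   utils::modifyList(list(seed = seed),
                                                     config$scenario %||% list())))
  traits <- scen$traits

  # temperature-rate observations per isolate from each isolate's
  # (scenario-derived) true curve, then TPC fits
  assay_temps <- tpc_cfg$assay_temps %||% c(4, 10, 15, 21, 26, 30, 35, 40, 45, 50)
  noise_cv <- tpc_cfg$noise_cv %||% 0.05
  replicates <- tpc_cfg$replicates %||% 4
  obs <- tick("simulate_tpc", {
    set.seed(seed + 1L)
    do.call(rbind, lapply(seq_len(nrow(traits)), function(i) {
      p <- ss_params(B0 = traits$mu_max[i] / 4, E = 0.65, ED = 3,
                     Tpk = celsius_to_kelvin(traits$topt[i]))
      generate_tpc_observations(p, assay_temps = assay_temps,
                                noise_cv = noise_cv,
                                replicates = replicates,
                                isolate_id = traits$isolate_id[i])
    }))
  })
  fits <- tick("fit_tpc", fit_ss_table(obs))

  # fitted optima feed the downstream analyses where available
  traits$topt_fitted <- fits$topt[match(traits$isolate_id,
                                        fits$isolate_id)]

  transform <- sig_cfg$transform %||% "log"
  nperm <- sig_cfg$n_permutations %||% 999
  tv <- stats::setNames(traits$topt, traits$isolate_id)
  lam <- tick("lambda", estimate_lambda(scen$tree, tv,
                                        transform = transform))
  kk <- tick("blomberg_k", blomberg_k(scen$tree, tv, transform = transform,
                                      n_permutations = nperm,
                                      seed = seed + 2L))
  asr <- tick("asr", ancestral_states_bm(scen$tree, tv,
                                         transform = transform))

  sorting <- traits[traits$isolation_mode == "sorting", ]
  sortreg <- tick("sorting_regression",
                  quadratic_vs_linear(sorting$incubation_temp, sorting$topt))
  standard <- traits[traits$isolation_mode == "standard", ]
  stdreg <- if (nrow(standard) >= 3)
    stats::lm(topt ~ incubation_temp, data = standard) else NULL

  pca_vars <- st_cfg$pca_vars %||% c("topt", "niche_width", "mu_max",
                                     "r_max", "log_atp",
                                     "carrying_capacity")
  pca <- tick("pca", pca_traits(traits, pca_vars))
  scaling <- tick("scaling", {
    by_phy <- split(traits, traits$phylum)
    by_phy <- by_phy[vapply(by_phy, nrow, integer(1)) >= 3]
    lapply(by_phy, function(d) powerlaw_fit(d$r_max, exp(d$log_atp)))
  })
  contrasts <- tick("contrasts", phylum_summary(
    traits,
    t_target = st_cfg$t_target %||% 20,
    E = st_cfg$activation_energy %||% 0.61))

  manifest <- list(seed = seed,
                   parameters = list(tpc = list(assay_temps = assay_temps,
                                                noise_cv = noise_cv,
                                                replicates = replicates),
                                     signal = list(transform = transform,
                                                   n_permutations = nperm)),
                   stages = stages)
  out <- list(traits = traits, tree = scen$tree, observations = obs,
              tpc_fits = fits, lambda = lam, K = kk, asr = asr,
              sorting_regression = sortreg,
              standard_regression = stdreg,
              pca = pca, scaling = scaling, contrasts = contrasts,
              manifest = manifest)
  if (!is.null(config$out_dir)) {
    files <- write_results(list(
      traits = traits, tree = scen$tree, tpc_fits = fits,
      lambda = lam[c("statistic", "value", "p_value", "n_tips")],
      blomberg_k = kk[c("statistic", "value", "p_value", "n_tips",
                        "n_permutations", "seed")],
      contrasts = as.data.frame(contrasts)
    ), config$out_dir)
    manifest$files <- as.list(files)
    manifest$checksums <- as.list(tools::md5sum(unname(files)))
    out$manifest <- manifest
    write_results(list(manifest = manifest), config$out_dir)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
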