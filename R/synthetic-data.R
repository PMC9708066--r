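# Synthetic-data generators: every input the analysis pipeline consumes
# can be produced here with known ground truth, for estimator
# calibration and recovery tests.

#' Simulate a pure-birth (Yule) ultrametric tree
#'
#' Constant speciation, no extinction, conditioned on `n_tips` surviving
#' lineages; the result is rooted, binary and ultrametric.  By default
#' the tree is rescaled to unit depth so that Brownian rates are
#' expressed per total tree height.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per unit time (> 0).
#' @param seed integer seed; identical seeds give identical trees.
#' @param scale_depth rescale the root-to-tip height to this value
#'   (default 1); `NULL` keeps the raw simulated depth.
#' @return an [ape::phylo] tree with tip labels `t1..tn`.
#' @export
generate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL,
                               scale_depth = 1) {
  if (!is.numeric(n_tips) || n_tips < 2) stop("n_tips must be at least 2")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  tree <- ape::rphylo(n = n_tips, birth = birth_rate, death = 0)
  if (!is.null(scale_depth)) {
    depth <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * scale_depth / depth
  }
  tree
}

#' Simulate a trait under lambda-scaled Brownian motion
#'
#' Draws one value per tip from a multivariate normal with mean
#' `root_state` and covariance `sigma2 * lambda_transform(C, lambda)`,
#' where `C` is the tree's Brownian covariance.  `lambda = 1` is plain
#' Brownian motion; `lambda = 0` makes tips independent with variance
#' `sigma2 *` root-to-tip distance.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param sigma2 Brownian rate (variance per unit branch length, > 0;
#'   0 is allowed and returns `root_state` at every tip).
#' @param root_state trait value at the root.
#' @param lambda signal strength in \[0, 1\].
#' @param seed integer seed.
#' @return named numeric vector of tip values.
#' @export
simulate_lambda_bm <- function(tree, sigma2 = 1, root_state = 0,
                               lambda = 1, seed = NULL) {
  if (!is.numeric(lambda) || length(lambda) != 1 ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  n <- length(tree$tip.label)
  if (sigma2 == 0) {
    x <- rep(root_state, n)
    names(x) <- tree$tip.label
    return(x)
  }
  C <- lambda_transform(phylo_covariance(tree), lambda)
  L <- chol(sigma2 * C)
  x <- root_state + as.numeric(crossprod(L, stats::rnorm(n)))
  names(x) <- tree$tip.label
  x
}

#' Simulate temperature-rate observations from a known curve
#'
#' Generates `replicates` observations at each assay temperature whose
#' rates are the true Sharpe-Schoolfield curve multiplied by positive
#' lognormal noise with the requested coefficient of variation (mean 1,
#' so the noise is unbiased on the rate scale).  With `noise_cv = 0`
#' every observation lies exactly on the curve.
#'
#' @param params an [ss_params] object — the true curve.
#' @param assay_temps assay temperatures in degrees Celsius, strictly
#'   increasing.
#' @param noise_cv coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param replicates observations per temperature (>= 1).
#' @param seed integer seed.
#' @param isolate_id label carried into the output.
#' @return data.frame with columns `isolate_id`, `temp` (degC), `rate`,
#'   `replicate`, `true_rate`.
#' @export
generate_tpc_observations <- function(params,
                                      assay_temps = c(4, 10, 15, 21, 30, 40, 50),
                                      noise_cv = 0.05, replicates = 4,
                                      seed = NULL, isolate_id = "sim") {
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (replicates < 1) stop("replicates must be >= 1")
  if (is.unsorted(assay_temps, strictly = TRUE))
    stop("assay_temps must be strictly increasing")
  if (!is.null(seed)) set.seed(seed)
  temps <- rep(assay_temps, each = replicates)
  true_rate <- ss_evaluate(params, celsius_to_kelvin(temps))
  factor <- if (noise_cv == 0) rep(1, length(temps)) else {
    sdlog <- sqrt(log(1 + noise_cv^2))
    exp(stats::rnorm(length(temps), mean = -sdlog^2 / 2, sd = sdlog))
  }
  data.frame(
    isolate_id = isolate_id,
    temp = temps,
    rate = true_rate * factor,
    replicate = rep(seq_len(replicates), times = length(assay_temps)),
    true_rate = true_rate,
    stringsAsFactors = FALSE
  )
}

#' Generate one synthetic assay record from known traits
#'
#' Inverts the trait-derivation chain: given true growth rate,
#' respiration rate and ATP concentration, produces the raw
#' measurements (cell counts, cumulative respired carbon, luminescence
#' series) from which [derive_traits] recovers the truths exactly when
#' noise is off.  Final counts follow exponential growth
#' `C0_cells * exp(mu * t)`; cumulative respired carbon solves the
#' respiration equation for `R = true_R`; the luminescence series peaks
#' at the reading that inverts the ATP calibration to `true_atp`.
#'
#' @param true_mu growth rate, per hour (any finite value).
#' @param true_R respiration rate, per hour (>= 0).
#' @param true_atp ATP concentration, nM (> 0), or `NA` to omit the
#'   luminescence series.
#' @param C0_cells initial cell count (> 0).
#' @param mean_diameter mean cell diameter, micrometres (> 0).
#' @param duration assay duration, hours (> 0).
#' @param assay_temp assay temperature, degrees Celsius.
#' @param isolate_id label.
#' @param count_noise apply Poisson noise to the cell counts (default
#'   off so round-trips are exact).
#' @param seed integer seed (used only when `count_noise = TRUE`).
#' @return a list (an assay record) with fields `isolate_id`,
#'   `assay_temp`, `t`, `initial_count`, `final_count`, `diameters`,
#'   `Rtot`, `rlu_series`, plus `truth = c(mu, R, atp)`.
#' @export
generate_assay_batch <- function(true_mu, true_R, true_atp = 10,
                                 C0_cells = 1e5, mean_diameter = 1,
                                 duration = 4, assay_temp = 20,
                                 isolate_id = "sim", count_noise = FALSE,
                                 seed = NULL) {
  if (!is.finite(true_mu)) stop("true_mu must be finite")
  if (!is.finite(true_R) || true_R < 0) stop("true_R must be >= 0")
  if (C0_cells <= 0) stop("C0_cells must be positive")
  if (mean_diameter <= 0) stop("mean_diameter must be positive")
  if (duration <= 0) stop("duration must be positive")
  if (!is.null(seed)) set.seed(seed)
  vol <- sphere_volume(mean_diameter)
  C0 <- culture_biomass(C0_cells, vol)
  final_cells <- C0_cells * exp(true_mu * duration)
  # invert R = mu * Rtot / (C0 (e^{mu t} - 1)); zero-growth limit Rtot = R C0 t
  Rtot <- if (abs(true_mu * duration) < 1e-8) {
    true_R * C0 * duration
  } else {
    true_R * C0 * (exp(true_mu * duration) - 1) / true_mu
  }
  rlu <- NULL
  if (is.finite(true_atp)) {
    if (true_atp <= 0) stop("true_atp must be positive (or NA)")
    peak_rlu <- 10^((log10(true_atp) - .ATP_INT) / .ATP_SLOPE)
    rlu <- peak_rlu * c(0.55, 1, 0.9, 0.7)  # develops, peaks, decays
  }
  initial_count <- C0_cells
  if (count_noise) {
    initial_count <- stats::rpois(1, C0_cells)
    final_cells <- stats::rpois(1, final_cells)
  }
  list(
    isolate_id = isolate_id, assay_temp = assay_temp, t = duration,
    initial_count = initial_count, final_count = final_cells,
    diameters = mean_diameter, Rtot = Rtot, rlu_series = rlu,
    truth = c(mu = true_mu, R = true_R, atp = true_atp)
  )
}

# Smooth additive cold-end bias on the thermal optimum: full size
# `cold_offset` at the coldest sorting temperature, decaying
# quadratically to 0 at >= `knee` degC (zero slope at the knee).
.cold_bias <- function(temp, cold_offset, knee = 21, coldest = 4) {
  cold_offset * pmax(0, (knee - temp) / (knee - coldest))^2
}

#' Generate a full community species-sorting scenario
#'
#' Builds the trait table and phylogeny of a synthetic species-sorting
#' experiment: soil communities incubated at a ladder of sorting
#' temperatures yield isolates whose thermal optima track the sorting
#' temperature, with an upward bias at cold temperatures (cultivable
#' soil bacteria rarely have optima much below ~20 degC); a parallel
#' set of standard-temperature isolates has optima unrelated to the
#' incubation temperature.  Phylum labels follow the thermal optimum
#' (hot-adapted isolates labelled Firmicutes), and the two phyla carry
#' contrasting r/K life-history trait blocks (Firmicutes: faster
#' growth, higher ATP, lower yield).  Tips of a Yule tree are labelled
#' so that the thermal optimum is phylogenetically clustered, giving
#' strong signal by construction.
#'
#' @param sorting_temps sorting (incubation) temperatures, degC.
#' @param isolates_per_temp isolates per temperature per isolation mode
#'   (>= 1).
#' @param cold_offset upward bias (degC) of the thermal optimum at the
#'   coldest sorting temperature, decaying smoothly to 0 at >= 21 degC.
#' @param phylum_threshold thermal optimum (degC) at or above which an
#'   isolate is labelled Firmicutes (else Proteobacteria).
#' @param rk_contrast enable the r/K trait contrast between phyla.
#' @param include_standard also generate standard-temperature isolates
#'   (`isolation_mode = "standard"`, optima independent of incubation
#'   temperature).
#' @param topt_sd isolate-level standard deviation (degC) around the
#'   expected thermal optimum.
#' @param tree_birth_rate Yule speciation rate for the phylogeny.
#' @param seed integer seed.
#' @return a list with `traits` (data.frame: `isolate_id`,
#'   `incubation_temp`, `isolation_mode`, `topt`, `topt_expected`,
#'   `niche_width`, `mu_max`, `r_max`, `log_atp`, `carrying_capacity`,
#'   `phylum`) and `tree` (an [ape::phylo] whose tip labels are the
#'   isolate ids, on which `topt` carries strong signal).
#' @export
generate_community_scenario <- function(sorting_temps = c(4, 10, 21, 30, 40, 50),
                                        isolates_per_temp = 5,
                                        cold_offset = 8,
                                        phylum_threshold = 30,
                                        rk_contrast = TRUE,
                                        include_standard = TRUE,
                                        topt_sd = 1,
                                        tree_birth_rate = 1,
                                        seed = 1) {
  if (length(sorting_temps) == 0) stop("sorting_temps must be non-empty")
  if (isolates_per_temp < 1) stop("isolates_per_temp must be >= 1")
  set.seed(seed)
  temps <- rep(sorting_temps, each = isolates_per_temp)
  n_sort <- length(temps)
  expected <- temps + .cold_bias(temps, cold_offset,
                                 coldest = min(sorting_temps))
  topt_sort <- expected + stats::rnorm(n_sort, 0, topt_sd)
  sort_df <- data.frame(
    incubation_temp = temps, isolation_mode = "sorting",
    topt = topt_sort, topt_expected = expected,
    stringsAsFactors = FALSE)
  if (include_standard) {
    topt_std <- stats::rnorm(n_sort, 25, 3)
    std_df <- data.frame(
      incubation_temp = temps, isolation_mode = "standard",
      topt = topt_std, topt_expected = 25,
      stringsAsFactors = FALSE)
    df <- rbind(sort_df, std_df)
  } else df <- sort_df
  n <- nrow(df)
  df$isolate_id <- sprintf("iso%02d", seq_len(n))
  df$phylum <- ifelse(df$topt >= phylum_threshold,
                      "Firmicutes", "Proteobacteria")
  firm <- df$phylum == "Firmicutes"
  if (rk_contrast) {
    df$mu_max <- exp(stats::rnorm(n, ifelse(firm, log(0.9), log(0.45)), 0.25))
    df$r_max <- exp(stats::rnorm(n, ifelse(firm, log(0.15), log(0.30)), 0.25))
    df$log_atp <- stats::rnorm(n, ifelse(firm, 1.5, 0.5), 0.4)
    df$carrying_capacity <- pmax(0.05,
      stats::rnorm(n, ifelse(firm, 0.5, 0.9), 0.1))
  } else {
    df$mu_max <- exp(stats::rnorm(n, log(0.6), 0.3))
    df$r_max <- exp(stats::rnorm(n, log(0.2), 0.3))
    df$log_atp <- stats::rnorm(n, 1, 0.5)
    df$carrying_capacity <- pmax(0.05, stats::rnorm(n, 0.7, 0.15))
  }
  df$niche_width <- pmax(2, stats::rnorm(n, 12, 3))

  # Phylogeny: label Yule tips in traversal order with isolates sorted
  # by thermal optimum, so close relatives share similar optima.
  tree <- generate_yule_tree(n, birth_rate = tree_birth_rate,
                             seed = seed + 1L)
  tree <- stats::reorder(tree, "cladewise")
  tip_order <- tree$edge[tree$edge[, 2] <= n, 2]
  tree$tip.label[tip_order] <- df$isolate_id[order(df$topt)]

  df <- df[, c("isolate_id", "incubation_temp", "isolation_mode",
               "topt", "topt_expected", "niche_width", "mu_max", "r_max",
               "log_atp", "carrying_capacity", "phylum")]
  list(traits = df, tree = tree)
}
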