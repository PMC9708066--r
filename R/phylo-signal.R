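# Phylogenetic signal (Pagel's lambda, Blomberg's K) and Brownian-motion
# ancestral state reconstruction for continuous traits on ape "phylo"
# trees.

#' Parse / write a newick tree
#'
#' Thin validating wrappers around [ape::read.tree] and
#' [ape::write.tree].  Parsing requires branch lengths and unique tip
#' labels; violations raise an error naming the problem.
#'
#' @param text a newick string.
#' @return `parse_newick`: an [ape::phylo] tree; `write_newick`: a
#'   newick string.  `parse_newick(write_newick(tree))` preserves
#'   topology, labels and branch lengths.
#' @export
parse_newick <- function(text) {
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("newick parse error: malformed tree string: ",
         substr(text, 1, 60))
  if (anyDuplicated(tree$tip.label))
    stop("newick parse error: duplicate tip label(s): ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("newick parse error: missing branch length(s)")
  tree
}

#' @param tree an [ape::phylo] tree.
#' @rdname parse_newick
#' @export
write_newick <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Phylogenetic variance-covariance matrix
#'
#' The tips-by-tips matrix of shared evolutionary history expected under
#' Brownian motion: entry (i, j) is the length of the root-to-MRCA path
#' shared by tips i and j; the diagonal holds root-to-tip distances.
#' Symmetric and positive semi-definite.  Polytomies are supported.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @return a numeric matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  ape::vcv.phylo(tree)
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies the off-diagonal entries of a phylogenetic covariance
#' matrix by `lambda`; `lambda = 1` leaves the matrix unchanged,
#' `lambda = 0` removes all shared history (diagonal matrix).
#'
#' @param C covariance matrix from [phylo_covariance].
#' @param lambda scalar in \[0, 1\].
#' @return the transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 ||
      lambda < 0 || lambda > 1)
    stop("lambda must be a single value in [0, 1]")
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# Align a trait (named vector, or data.frame with tip_label/value
# columns) to the tree tips.  strict = TRUE errors on any mismatch;
# strict = FALSE drops unmatched entries/tips with a warning and returns
# the trait plus (via attribute "tree") the possibly pruned tree.
.align_trait <- function(tree, trait, strict = TRUE) {
  if (is.data.frame(trait)) {
    stopifnot(ncol(trait) >= 2)
    v <- as.numeric(trait[[2]])
    names(v) <- as.character(trait[[1]])
    trait <- v
  }
  if (is.null(names(trait)))
    stop("trait must be named by tip label")
  tips <- tree$tip.label
  missing_tips <- setdiff(tips, names(trait))
  extra <- setdiff(names(trait), tips)
  if (strict && (length(missing_tips) || length(extra)))
    stop("trait/tip mismatch: missing [",
         paste(missing_tips, collapse = ", "), "], unmatched [",
         paste(extra, collapse = ", "), "]")
  if (length(extra)) {
    warning("dropping ", length(extra), " trait entr(ies) with no matching tip")
    trait <- trait[setdiff(names(trait), extra)]
  }
  if (length(missing_tips)) {
    warning("dropping ", length(missing_tips), " tip(s) with no trait value")
    tree <- ape::drop.tip(tree, missing_tips)
  }
  out <- trait[tree$tip.label]
  if (anyNA(out)) stop("trait contains missing values after alignment")
  attr(out, "tree") <- tree
  out
}

# Profiled Brownian-motion log-likelihood for trait x under covariance C:
# the phylogenetic (GLS) mean and the rate sigma2 are profiled out
# analytically.  Returns the log-likelihood plus the profiled estimates.
.bm_profile_loglik <- function(C, x) {
  n <- length(x)
  R <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance is numerically singular"))
  logdet <- 2 * sum(log(diag(R)))
  ones <- rep(1, n)
  Ci_x <- backsolve(R, backsolve(R, x, transpose = TRUE))
  Ci_1 <- backsolve(R, backsolve(R, ones, transpose = TRUE))
  mu <- sum(Ci_x) / sum(Ci_1)
  r <- x - mu
  Ci_r <- Ci_x - mu * Ci_1
  sigma2 <- sum(r * Ci_r) / n
  ll <- if (sigma2 <= 0) {
    # degenerate: constant trait
    Inf
  } else {
    -0.5 * (n * log(2 * pi) + n * log(sigma2) + logdet + n)
  }
  list(loglik = ll, mu = mu, sigma2 = sigma2)
}

#' Maximum-likelihood Pagel's lambda
#'
#' Estimates the strength of phylogenetic signal in a continuous trait
#' by maximizing the multivariate-normal log-likelihood over
#' `lambda` in \[0, 1\], where the model covariance is
#' `sigma2 * lambda_transform(C, lambda)` and the mean and `sigma2` are
#' profiled out analytically by generalized least squares.
#' `lambda = 1` corresponds to Brownian motion on the tree;
#' `lambda = 0` to phylogenetic independence.  A likelihood-ratio test
#' against `lambda = 0` gives the p-value (`2 * (l(hat) - l(0))`
#' referred to chi-square with 1 df); when `hat(lambda) = 0` the
#' statistic is 0 and p = 1 exactly.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param trait named numeric vector (names = tip labels) or a
#'   data.frame `(tip_label, value)`.
#' @param transform `"identity"` (default) or `"log"` (natural log,
#'   requires positive values) applied to the trait before estimation.
#' @param strict error on trait/tip mismatches (default) rather than
#'   dropping them.
#' @param tol optimizer tolerance on lambda.
#' @return an object of class `"phylo_signal"`: list with `statistic =
#'   "lambda"`, `value`, `log_likelihood`, `loglik0` (at lambda = 0),
#'   `p_value`, `n_tips`, `sigma2`, `mean`, `transform`.
#' @export
estimate_lambda <- function(tree, trait, transform = c("identity", "log"),
                            strict = TRUE, tol = 1e-8) {
  transform <- match.arg(transform)
  x <- .align_trait(tree, trait, strict = strict)
  tree <- attr(x, "tree")
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("at least 3 tips are required")
  if (transform == "log") {
    if (any(x <= 0)) stop("log transform requires positive trait values")
    x <- log(x)
  }
  C <- phylo_covariance(tree)
  ll_of <- function(lam) .bm_profile_loglik(lambda_transform(C, lam), x)$loglik
  opt <- stats::optimize(ll_of, interval = c(0, 1), maximum = TRUE,
                         tol = tol)
  # optimize() never evaluates the endpoints: compare against them
  cand <- c(opt$maximum, 0, 1)
  lls <- c(opt$objective, ll_of(0), ll_of(1))
  best <- which.max(lls)
  lam_hat <- cand[best]
  # snap to 0 when indistinguishable from the no-signal boundary
  if (lls[best] - lls[2] <= 1e-10) lam_hat <- 0
  prof <- .bm_profile_loglik(lambda_transform(C, lam_hat), x)
  ll0 <- ll_of(0)
  lr <- max(0, 2 * (prof$loglik - ll0))
  p <- if (lr == 0) 1 else stats::pchisq(lr, df = 1, lower.tail = FALSE)
  structure(list(
    statistic = "lambda", value = lam_hat,
    log_likelihood = prof$loglik, loglik0 = ll0,
    lr_statistic = lr, p_value = p,
    n_tips = n, sigma2 = prof$sigma2, mean = prof$mu,
    transform = transform
  ), class = "phylo_signal")
}

# K statistic for aligned trait x given C and precomputed pieces.
.k_statistic <- function(x, Cinv, trC, sum_Cinv, n) {
  mu <- sum(Cinv %*% x) / sum_Cinv
  r <- x - mu
  mse0 <- sum(r^2) / (n - 1)
  mse <- as.numeric(crossprod(r, Cinv %*% r)) / (n - 1)
  expected <- (trC - n / sum_Cinv) / (n - 1)
  (mse0 / mse) / expected
}

#' Blomberg's K with a permutation test
#'
#' The ratio of the observed mean squared error of the tip data (about
#' the phylogenetic mean) to the mean squared error under the tree's
#' Brownian-motion covariance structure, scaled by its BM expectation so
#' that `K = 1` indicates exactly the similarity among relatives
#' expected under Brownian motion, `K < 1` less signal, `K > 1` more.
#' Significance is assessed by permuting trait values across tips:
#' `p = (1 + #{K_perm >= K_obs}) / (n_permutations + 1)` (one-sided,
#' upper tail).
#'
#' @inheritParams estimate_lambda
#' @param n_permutations number of tip-label permutations (>= 99;
#'   default 999).
#' @param seed integer seed for the permutation generator; recorded in
#'   the result.
#' @return an object of class `"phylo_signal"`: list with `statistic =
#'   "K"`, `value`, `p_value`, `n_tips`, `n_permutations`, `seed`,
#'   `transform`.
#' @export
blomberg_k <- function(tree, trait, n_permutations = 999, seed = NULL,
                       transform = c("identity", "log"), strict = TRUE) {
  transform <- match.arg(transform)
  if (n_permutations < 99) stop("n_permutations must be at least 99")
  x <- .align_trait(tree, trait, strict = strict)
  tree <- attr(x, "tree")
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3) stop("at least 3 tips are required")
  if (transform == "log") {
    if (any(x <= 0)) stop("log transform requires positive trait values")
    x <- log(x)
  }
  C <- phylo_covariance(tree)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop("phylogenetic covariance is numerically singular"))
  trC <- sum(diag(C))
  sum_Cinv <- sum(Cinv)
  k_obs <- .k_statistic(x, Cinv, trC, sum_Cinv, n)
  if (!is.null(seed)) set.seed(seed)
  k_perm <- vapply(seq_len(n_permutations), function(i)
    .k_statistic(sample(x), Cinv, trC, sum_Cinv, n), numeric(1))
  p <- (1 + sum(k_perm >= k_obs)) / (n_permutations + 1)
  structure(list(
    statistic = "K", value = k_obs, p_value = p,
    n_tips = n, n_permutations = n_permutations, seed = seed,
    transform = transform
  ), class = "phylo_signal")
}

#' @export
print.phylo_signal <- function(x, digits = 4, ...) {
  if (x$statistic == "lambda") {
    cat(sprintf("Pagel's lambda = %.*g (n = %d tips)\n",
                digits, x$value, x$n_tips))
    cat(sprintf("  logL = %.*g (logL at lambda=0: %.*g)\n",
                digits, x$log_likelihood, digits, x$loglik0))
    cat(sprintf("  LRT vs lambda=0: chisq = %.*g, p = %.4g\n",
                digits, x$lr_statistic, x$p_value))
  } else {
    cat(sprintf("Blomberg's K = %.*g (n = %d tips)\n",
                digits, x$value, x$n_tips))
    cat(sprintf("  permutation p = %.4g (%d permutations%s)\n",
                x$p_value, x$n_permutations,
                if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  }
  if (x$transform != "identity")
    cat(sprintf("  trait transform: %s\n", x$transform))
  invisible(x)
}

#' Brownian-motion ancestral state reconstruction
#'
#' Maximum-likelihood estimates of the trait value at every internal
#' node under Brownian motion.  The joint likelihood over node states
#' factorizes across edges, so the ML states solve a weighted tree
#' Laplacian system with edge weights 1/branch-length (tips held at
#' their observed values); this is equivalent to the generalized
#' least-squares construction that treats each internal node as an
#' additional zero-length tip.  Estimation variances come from that GLS
#' construction, with the uncertainty in the (estimated) phylogenetic
#' mean propagated.
#'
#' @inheritParams estimate_lambda
#' @return an object of class `"bm_asr"`: list with `node_states`
#'   (named by internal node number), `node_variances`, `sigma2_hat`
#'   (ML Brownian rate), `root_state`, `n_tips`, `tree`.
#' @export
ancestral_states_bm <- function(tree, trait, transform = c("identity", "log"),
                                strict = TRUE) {
  transform <- match.arg(transform)
  x <- .align_trait(tree, trait, strict = strict)
  tree <- attr(x, "tree")
  x <- as.numeric(x)
  n <- length(x)
  if (n < 2) stop("at least 2 tips are required")
  if (transform == "log") {
    if (any(x <= 0)) stop("log transform requires positive trait values")
    x <- log(x)
  }
  if (any(tree$edge.length <= 0))
    stop("ancestral reconstruction requires strictly positive branch lengths")
  n_node <- tree$Nnode
  internal <- n + seq_len(n_node)
  idx <- function(node) node - n  # internal node -> row in the system
  A <- matrix(0, n_node, n_node)
  b <- numeric(n_node)
  w <- 1 / tree$edge.length
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    A[idx(p), idx(p)] <- A[idx(p), idx(p)] + w[e]
    if (ch > n) {
      A[idx(ch), idx(ch)] <- A[idx(ch), idx(ch)] + w[e]
      A[idx(p), idx(ch)] <- A[idx(p), idx(ch)] - w[e]
      A[idx(ch), idx(p)] <- A[idx(ch), idx(p)] - w[e]
    } else {
      b[idx(p)] <- b[idx(p)] + w[e] * x[ch]
    }
  }
  states <- solve(A, b)
  names(states) <- as.character(internal)

  # ML rate from the GLS residuals about the root state
  C <- phylo_covariance(tree)
  R <- chol(C)
  ones <- rep(1, n)
  Ci_x <- backsolve(R, backsolve(R, x, transpose = TRUE))
  Ci_1 <- backsolve(R, backsolve(R, ones, transpose = TRUE))
  mu <- sum(Ci_x) / sum(Ci_1)
  resid <- x - mu
  Ci_r <- Ci_x - mu * Ci_1
  sigma2 <- sum(resid * Ci_r) / n

  # prediction variances via the extra-tip GLS formula:
  # var = sigma2 * (c_kk - c_k' Cinv c_k + (1 - 1'Cinv c_k)^2 / (1'Cinv 1))
  depths <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)
  sum_Ci1 <- sum(Ci_1)
  vars <- vapply(internal, function(k) {
    ck <- depths[mr[k, seq_len(n)]]
    Ci_ck <- backsolve(R, backsolve(R, ck, transpose = TRUE))
    v <- depths[k] - sum(ck * Ci_ck) + (1 - sum(Ci_ck))^2 / sum_Ci1
    sigma2 * max(v, 0)
  }, numeric(1))
  names(vars) <- names(states)

  structure(list(
    node_states = states, node_variances = vars,
    sigma2_hat = sigma2, root_state = states[[as.character(n + 1)]],
    n_tips = n, transform = transform, tree = tree
  ), class = "bm_asr")
}

#' @export
print.bm_asr <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Brownian-motion ancestral state reconstruction (%d tips, %d nodes)\n",
    x$n_tips, length(x$node_states)))
  cat(sprintf("  root state = %.*g, sigma2 = %.*g\n",
              digits, x$root_state, digits, x$sigma2_hat))
  cat(sprintf("  node states range: [%.*g, %.*g]\n",
              digits, min(x$node_states), digits, max(x$node_states)))
  invisible(x)
}
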