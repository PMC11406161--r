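#' Read a Newick tree sample
#'
#' Thin wrapper over [ape::read.tree()] that always returns a `multiPhylo`
#' list and checks that every tree carries branch lengths.
#'
#' @param path Newick file, one or more trees.
#' @return A `multiPhylo` object.
#' @export
read_tree_sample <- function(path) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  trees <- ape::read.tree(path)
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) == 0) stop("no trees in ", path, call. = FALSE)
  ok <- vapply(trees, function(tr) !is.null(tr$edge.length), logical(1))
  if (!all(ok)) stop("all trees must have branch lengths", call. = FALSE)
  trees
}

#' Simulate a pseudo-posterior tree sample for the three study species
#'
#' Generates ultrametric three-tip trees with the accepted topology
#' ((R.marina, P.terribilis), X.tropicalis), jittering the root depth and
#' the bufonid--dendrobatid split age lognormally across trees to mimic
#' dating uncertainty in a posterior sample.
#'
#' @param n_trees Number of trees.
#' @param seed Integer seed.
#' @param depth Median root-to-tip depth (arbitrary time units).
#' @param split_age Median age of the R. marina / P. terribilis split.
#' @param jitter_sd Lognormal sd of the across-tree age jitter.
#' @return A `multiPhylo` object.
#' @export
simulate_tree_sample <- function(n_trees = 100, seed = 1, depth = 200,
                                 split_age = 75, jitter_sd = 0.1) {
  with_seed(seed, {
    txt <- vapply(seq_len(n_trees), function(i) {
      d <- depth * exp(stats::rnorm(1, 0, jitter_sd))
      s <- split_age * exp(stats::rnorm(1, 0, jitter_sd))
      s <- min(s, 0.95 * d)
      sprintf("((R.marina:%.6f,P.terribilis:%.6f):%.6f,X.tropicalis:%.6f);",
              s, s, d - s, d)
    }, character(1))
    ape::read.tree(text = txt)
  })
}

# Clade key for each edge: sorted tip labels below the edge's child node.
edge_clade_keys <- function(tr) {
  ntip <- length(tr$tip.label)
  vapply(seq_len(nrow(tr$edge)), function(i) {
    child <- tr$edge[i, 2]
    tips <- if (child <= ntip) tr$tip.label[child]
            else ape::extract.clade(tr, child)$tip.label
    paste(sort(tips), collapse = "|")
  }, character(1))
}

#' Consensus tree with mean branch lengths
#'
#' Restricts the sample to its majority topology (the same rooted topology
#' must appear in more than half the trees) and returns that topology with
#' each edge length replaced by its across-tree mean, matching edges by the
#' tip set they subtend.
#'
#' @param trees A `multiPhylo` sample sharing one tip set.
#' @return A single `phylo` tree.
#' @export
mean_branch_tree <- function(trees) {
  if (inherits(trees, "phylo")) trees <- c(trees)
  if (length(trees) == 0) stop("empty tree sample", call. = FALSE)
  keys <- lapply(trees, edge_clade_keys)
  sig <- vapply(keys, function(k) paste(sort(k), collapse = ";"), character(1))
  tab <- table(sig)
  top <- names(tab)[which.max(tab)]
  if (max(tab) <= length(trees) / 2 && length(tab) > 1) {
    stop("no majority topology in the tree sample", call. = FALSE)
  }
  idx <- which(sig == top)
  ref <- trees[[idx[1]]]
  ref_keys <- keys[[idx[1]]]
  len <- matrix(NA_real_, length(idx), length(ref_keys))
  for (j in seq_along(idx)) {
    k <- keys[[idx[j]]]
    len[j, ] <- trees[[idx[j]]]$edge.length[match(ref_keys, k)]
  }
  ref$edge.length <- colMeans(len)
  ref
}

#' Phylogenetic correlation matrix
#'
#' Under Brownian-motion trait evolution the covariance between two tips is
#' the shared root-to-MRCA path length; the correlation divides by the
#' geometric mean of the two root-to-tip depths. The diagonal is exactly 1
#' and a star phylogeny yields the identity.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @return Square correlation matrix with tip labels as dimnames.
#' @export
phylo_correlation <- function(tree) {
  if (length(tree$tip.label) < 2) stop("need >= 2 tips", call. = FALSE)
  C <- ape::vcv.phylo(tree)
  d <- diag(C)
  if (any(d <= 0)) stop("zero root-to-tip depth in tree", call. = FALSE)
  R <- C / sqrt(outer(d, d))
  diag(R) <- 1
  R
}

# Correlation matrix from the packaged synthetic tree sample (memoised).
.ewl_cache <- new.env(parent = emptyenv())
default_phylo_correlation <- function() {
  if (!is.null(.ewl_cache$phylo)) return(.ewl_cache$phylo)
  path <- system.file("extdata", "synthetic_frog_trees.nwk",
                      package = "ewlmm", mustWork = TRUE)
  phylo <- phylo_correlation(mean_branch_tree(read_tree_sample(path)))
  .ewl_cache$phylo <- phylo
  phylo
}

#' Gaussian temporal correlation kernel
#'
#' Correlation between residuals of the same individual separated by `dt`
#' minutes: `rho^((dt / ref_lag)^2)`. The kernel is parameterised by its
#' value `rho` at the reference lag (20 min, the nominal weighing interval)
#' so a uniform(0,1) prior acts directly on an interpretable quantity; it is
#' algebraically the squared-exponential kernel exp(-(dt/l)^2) with
#' bandwidth l = ref_lag / sqrt(-log(rho)).
#'
#' @param dt Time difference(s) in minutes, >= 0.
#' @param rho Correlation at the reference lag, in (0, 1).
#' @param ref_lag Reference lag in minutes, > 0.
#' @return Correlation value(s) in (0, 1].
#' @export
temporal_correlation <- function(dt, rho, ref_lag = 20) {
  if (!is.finite(rho) || rho <= 0 || rho >= 1) {
    stop("rho must lie strictly in (0, 1)", call. = FALSE)
  }
  if (ref_lag <= 0) stop("ref_lag must be > 0", call. = FALSE)
  if (any(dt < 0)) stop("dt must be >= 0", call. = FALSE)
  rho^((dt / ref_lag)^2)
}

#' Convert a squared-exponential bandwidth to the reference-lag correlation
#'
#' @param bandwidth Kernel bandwidth l in minutes of exp(-(dt/l)^2).
#' @param ref_lag Reference lag in minutes.
#' @return The equivalent `rho` at the reference lag.
#' @export
bandwidth_to_rho <- function(bandwidth, ref_lag = 20) {
  if (bandwidth <= 0) stop("bandwidth must be > 0", call. = FALSE)
  exp(-(ref_lag / bandwidth)^2)
}

# Precompute the covariance building blocks for a model frame:
#   W  -- weight on the temporal kernel (same-individual indicator in
#         nested mode; the expanded species correlation in composite mode)
#   D2 -- squared scaled time differences (dt / ref_lag)^2
#   S_* -- 0/1 sharing indicators (frog/housing/date) and the expanded
#         species correlation for the species component.
covariance_structures <- function(frame, phylo,
                                  mode = c("nested", "composite"),
                                  ref_lag = 20) {
  mode <- match.arg(mode)
  sp <- unique(frame$species)
  missing_sp <- setdiff(sp, rownames(phylo))
  if (length(missing_sp)) {
    stop("species absent from the phylogenetic correlation: ",
         paste(missing_sp, collapse = ", "), call. = FALSE)
  }
  n <- nrow(frame)
  same <- function(x) outer(x, x, "==") * 1
  S_species <- phylo[frame$species, frame$species, drop = FALSE]
  dimnames(S_species) <- NULL
  D2 <- (outer(frame$time_min, frame$time_min, "-") / ref_lag)^2
  W <- if (mode == "nested") same(frame$id) else S_species
  list(W = W, D2 = D2,
       S_frog = same(frame$id), S_housing = same(frame$housing),
       S_date = same(frame$date), S_species = S_species,
       mode = mode, ref_lag = ref_lag, n = n)
}

# Assemble the observation covariance from structures and parameters.
assemble_covariance <- function(str, variances, rho, nugget = 1e-8) {
  K <- str$W * rho^str$D2
  sigma <- variances[["error"]] * K +
    variances[["frog"]] * str$S_frog +
    variances[["housing"]] * str$S_housing +
    variances[["date"]] * str$S_date +
    variances[["species"]] * str$S_species
  sigma + diag(nugget, str$n)
}

#' Observation-level residual covariance
#'
#' Builds the n x n covariance of ln mass implied by the marginalised
#' random effects plus the temporally correlated residual.
#'
#' In `"nested"` mode (default) the Gaussian time kernel acts only within
#' an individual's residuals, and the phylogeny enters through the species
#' random effect (`species_variance x Phi`); residuals of different animals
#' are uncorrelated beyond their shared grouping factors. In `"composite"`
#' mode the error term itself is `error_variance x Phi x kernel` for every
#' pair of observations -- the literal composite of phylogenetic and
#' temporal correlation -- while the four random-effect components are
#' unchanged. Both modes share the same marginal variances.
#'
#' @param frame Model frame (or any data frame) with columns `id`,
#'   `species`, `housing`, `date`, `time_min`.
#' @param phylo Species correlation matrix with species dimnames.
#' @param params List with `rho` and optionally `ref_lag` (minutes).
#' @param variances Named variance components ([ewl_variance_components()]).
#' @param mode `"nested"` or `"composite"`.
#' @param nugget Small diagonal jitter ensuring invertibility when two
#'   rows share a timestamp.
#' @return Dense symmetric positive-definite matrix.
#' @export
residual_covariance <- function(frame, phylo, params, variances,
                                mode = c("nested", "composite"),
                                nugget = 1e-8) {
  mode <- match.arg(mode)
  ref_lag <- params$ref_lag %||% 20
  if (!is.finite(params$rho) || params$rho <= 0 || params$rho >= 1) {
    stop("params$rho must lie strictly in (0, 1)", call. = FALSE)
  }
  str <- covariance_structures(frame, phylo, mode, ref_lag)
  assemble_covariance(str, variances, params$rho, nugget)
}
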