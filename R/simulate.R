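#' Simulate a birth-death tree conditioned on a tip count
#'
#' Wraps [ape::rphylo()] (which conditions on the number of surviving tips)
#' with an explicit seed for reproducibility.
#'
#' @param n Number of tips.
#' @param birth,death Speciation and extinction rates per unit time
#'   (`birth > death >= 0`).
#' @param seed Optional integer seed.
#' @return A `phylo` with tip labels `t1..tn`.
#' @export
sim_tree <- function(n, birth = 1, death = 0, seed = NULL) {
  if (!(birth > death && death >= 0)) stop_validation("need birth > death >= 0")
  if (!is.null(seed)) set.seed(seed)
  ape::rphylo(n, birth = birth, death = death)
}

#' Simulate multivariate Brownian traits on a tree
#'
#' Multivariate Brownian motion from a root value of 0, with optional
#' per-group tip mean shifts. Tip values have covariance
#' `rate (x) shared-path-length` (Kronecker), which is sampled directly via
#' Cholesky factors of the phylogenetic covariance and the rate matrix.
#'
#' @param tree A `phylo` with branch lengths.
#' @param rate Trait rate (covariance) matrix, or a scalar for isotropic
#'   traits, or a vector of per-trait rates.
#' @param p Number of traits when `rate` is scalar (default 1).
#' @param shifts Optional group x trait matrix of mean shifts (row names =
#'   group labels).
#' @param groups Optional tip group labels (named by tip, or in tip order),
#'   required with `shifts`.
#' @param seed Optional integer seed.
#' @return Tips x traits matrix with tip labels as row names.
#' @export
sim_bm_traits <- function(tree, rate = 1, p = 1L, shifts = NULL, groups = NULL,
                          seed = NULL) {
  if (is.matrix(rate)) {
    R <- rate
  } else if (length(rate) > 1L) {
    R <- diag(rate)
  } else R <- diag(rate, p)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-10 * max(abs(ev), 1)))
    stop_validation("rate matrix must be positive semi-definite")
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv(tree)
  n <- nrow(C)
  Z <- matrix(stats::rnorm(n * ncol(R)), n, ncol(R))
  Uc <- chol(C + diag(1e-12, n))
  # PSD-safe factor of the rate matrix
  er <- eigen(R, symmetric = TRUE)
  Ur <- diag(sqrt(pmax(er$values, 0)), ncol(R)) %*% t(er$vectors)
  X <- crossprod(Uc, Z) %*% Ur
  rownames(X) <- rownames(C)
  colnames(X) <- colnames(R) %||% paste0("trait", seq_len(ncol(R)))
  if (!is.null(shifts)) {
    if (is.null(groups)) stop_validation("shifts require group labels")
    if (!is.null(names(groups))) groups <- groups[rownames(X)]
    X <- X + shifts[as.character(groups), , drop = FALSE] * 1
  }
  X[tree$tip.label, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate per-study diet records with a planted focal category
#'
#' Per-species category importances are drawn from a Dirichlet distribution
#' tilted toward a planted focal category (the focal category's
#' concentration parameter is multiplied by `focal_weight / (1 -
#' focal_weight)` times the number of other categories, so its expected
#' share is `focal_weight`). Importances are then decomposed uniformly into
#' per-item records within each category.
#'
#' @param species Character vector of species names.
#' @param categories A `category_set` (see [cut_categories()]) giving the
#'   item-to-category map.
#' @param focal Named character vector: planted focal category per species
#'   (defaults to a uniform random draw).
#' @param concentration Base Dirichlet concentration (> 0; default 2).
#' @param focal_weight Expected importance share of the focal category
#'   (default 0.8).
#' @param seed Optional integer seed.
#' @return List with `records` (long-format diet-record data frame, one
#'   study per species), `category_importances` (species x category matrix)
#'   and `focal` (the planted assignment).
#' @export
sim_diet_profiles <- function(species, categories, focal = NULL,
                              concentration = 2, focal_weight = 0.8,
                              seed = NULL) {
  if (concentration <= 0) stop_validation("concentration must be > 0")
  if (focal_weight <= 0 || focal_weight >= 1)
    stop_validation("focal_weight must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  cats <- sort(unique(as.character(categories$category_name)))
  kc <- length(cats)
  if (is.null(focal)) {
    focal <- stats::setNames(sample(cats, length(species), replace = TRUE),
                             species)
  }
  stopifnot(all(species %in% names(focal)))
  imp <- matrix(0, length(species), kc, dimnames = list(species, cats))
  for (sp in species) {
    alpha <- rep(concentration, kc)
    boost <- focal_weight / (1 - focal_weight) * (kc - 1)
    alpha[match(focal[[sp]], cats)] <- concentration * boost
    g <- stats::rgamma(kc, shape = alpha)
    imp[sp, ] <- g / sum(g)
  }
  items_by_cat <- split(categories$item, as.character(categories$category_name))
  recs <- do.call(rbind, lapply(species, function(sp) {
    do.call(rbind, lapply(cats, function(cc) {
      its <- items_by_cat[[cc]]
      data.frame(species = sp, study = "sim1", prey_item = its,
                 importance = imp[sp, cc] / length(its),
                 life_stage = "adult", stringsAsFactors = FALSE)
    }))
  }))
  list(records = recs, category_importances = imp, focal = focal[species])
}

#' Simulate a block-structured binary prey-trait matrix
#'
#' A block-diagonal prototype — block b's items carry block b's traits —
#' with independent Bernoulli bit flips at probability `p_flip`, emulating
#' prey items that share functional syndromes plus coding noise.
#'
#' @param n_blocks Number of planted blocks (default 6).
#' @param items_per_block Items per block (default 5).
#' @param traits_per_block Traits per block (default 4).
#' @param p_flip Flip probability in \[0, 0.5) (default 0.02).
#' @param seed Optional integer seed.
#' @return List with `traits` (binary matrix) and `block` (named integer
#'   vector of planted block memberships).
#' @export
sim_prey_traits <- function(n_blocks = 6L, items_per_block = 5L,
                            traits_per_block = 4L, p_flip = 0.02,
                            seed = NULL) {
  if (p_flip < 0 || p_flip >= 0.5) stop_validation("p_flip must be in [0, 0.5)")
  if (!is.null(seed)) set.seed(seed)
  n <- n_blocks * items_per_block
  tt <- n_blocks * traits_per_block
  block <- rep(seq_len(n_blocks), each = items_per_block)
  proto <- matrix(0L, n, tt)
  for (b in seq_len(n_blocks)) {
    proto[block == b, (b - 1L) * traits_per_block + seq_len(traits_per_block)] <- 1L
  }
  flips <- matrix(stats::rbinom(n * tt, 1L, p_flip), n, tt)
  m <- abs(proto - flips)
  rownames(m) <- sprintf("item_%02d", seq_len(n))
  colnames(m) <- sprintf("trait_%02d", seq_len(tt))
  storage.mode(m) <- "integer"
  list(traits = m, block = stats::setNames(block, rownames(m)))
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on which two partitions agree (both together or
#' both apart); 1 means identical partitions up to label names.
#'
#' @param a,b Cluster label vectors over the same items (aligned by name
#'   when both are named).
#' @return Rand index in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b), !anyNA(b))
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  up <- upper.tri(same_a)
  mean(same_a[up] == same_b[up])
}
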