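#' Principal component analysis of standardized characters
#'
#' Eigen-decomposition of the sample covariance of a (z-transformed)
#' character table. Axis signs follow a fixed convention — the
#' largest-magnitude loading on each axis is positive — so results are
#' byte-stable across platforms.
#'
#' @param z Species x character matrix, typically from [z_transform()].
#' @return Object of class `morpho_pca`: list with `loadings` (characters x
#'   axes, orthonormal), `scores` (species x axes, zero column means),
#'   `var_frac` (variance fractions, summing to 1) and `sdev`.
#' @export
morpho_pca <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) < 2L || ncol(z) < 2L)
    stop_validation("need at least 2 species and 2 characters")
  p <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  if (all(p$sdev < 1e-12)) stop_validation("rank-0 input")
  flip <- vapply(seq_len(ncol(p$rotation)), function(j) {
    l <- p$rotation[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1L))
  p$rotation[, flip] <- -p$rotation[, flip]
  p$x[, flip] <- -p$x[, flip]
  structure(list(loadings = p$rotation, scores = p$x,
                 var_frac = p$sdev^2 / sum(p$sdev^2), sdev = p$sdev),
            class = "morpho_pca")
}

#' @export
print.morpho_pca <- function(x, ...) {
  cat("PCA of", nrow(x$scores), "species x", nrow(x$loadings), "characters\n")
  cat("variance fractions:", paste(sprintf("%.3f", x$var_frac), collapse = " "), "\n")
  invisible(x)
}

#' Broken-stick expected variance fractions
#'
#' Under the broken-stick null, the expected fraction of variance on the
#' j-th largest of p axes is \eqn{b_j = (1/p) \sum_{i=j}^{p} 1/i}. The
#' fractions sum to 1.
#'
#' @param p Number of axes.
#' @return Numeric vector of length `p`.
#' @export
broken_stick <- function(p) {
  vapply(seq_len(p), function(j) sum(1 / (j:p)) / p, numeric(1L))
}

#' Retain PC axes exceeding their broken-stick expectation
#'
#' Axes are retained in order while the observed variance fraction exceeds
#' the broken-stick expectation; retention stops at the first failure.
#'
#' @param var_frac Observed variance fractions (must sum to 1).
#' @return Integer vector of retained axis indices (possibly empty).
#' @export
retain_axes <- function(var_frac) {
  if (abs(sum(var_frac) - 1) > 1e-6)
    stop_validation("variance fractions must sum to 1")
  b <- broken_stick(length(var_frac))
  keep <- var_frac > b
  if (!keep[1L]) return(integer(0))
  n <- which(!keep)[1L]
  if (is.na(n)) seq_along(var_frac) else seq_len(n - 1L)
}

#' Maximum-likelihood ancestral states under Brownian motion
#'
#' Computes the ML ancestral estimates (equivalently, weighted squared-change
#' parsimony with branch-length weights) for one or more continuous traits.
#' The estimates solve the linear system in which each internal node value is
#' the 1/branch-length-weighted mean of its neighbours.
#'
#' @param tree A rooted `phylo` with positive branch lengths.
#' @param x Named numeric vector of tip values, or a tips x traits matrix
#'   with row names matching tip labels.
#' @return Matrix of internal-node values (rows named by ape node number),
#'   one column per trait.
#' @export
bm_node_states <- function(tree, x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L, dimnames = list(names(x), "trait"))
  if (is.null(rownames(x)) || !all(tree$tip.label %in% rownames(x)))
    stop_validation("every tip needs a value")
  if (any(tree$edge.length <= 0)) stop_validation("branch lengths must be > 0")
  x <- x[tree$tip.label, , drop = FALSE]
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  ids <- n + seq_len(nn)                       # internal node numbers
  w <- 1 / tree$edge.length
  # graph Laplacian split into internal-internal and internal-tip blocks
  L_ii <- matrix(0, nn, nn)
  rhs <- matrix(0, nn, ncol(x))
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]; we <- w[e]
    ia <- a - n
    L_ii[ia, ia] <- L_ii[ia, ia] + we
    if (b > n) {
      ib <- b - n
      L_ii[ib, ib] <- L_ii[ib, ib] + we
      L_ii[ia, ib] <- L_ii[ia, ib] - we
      L_ii[ib, ia] <- L_ii[ib, ia] - we
    } else {
      rhs[ia, ] <- rhs[ia, ] + we * x[b, ]
    }
  }
  anc <- solve(L_ii, rhs)
  rownames(anc) <- ids
  colnames(anc) <- colnames(x)
  anc
}

#' Tip and node coordinates for a phylomorphospace plot
#'
#' Projects species and their Brownian-motion ancestral estimates onto the
#' retained PC axes and returns the parent-child segments needed to draw the
#' phylogeny in morphospace.
#'
#' @param tree Rooted `phylo` covering the scored species.
#' @param scores Species x axis score matrix (e.g. `morpho_pca(z)$scores`).
#' @param axes Axis indices to keep (default first two).
#' @return List with `tips`, `nodes` (coordinate matrices) and `edges`
#'   (two-column matrix of ape node numbers).
#' @export
phylomorphospace_data <- function(tree, scores, axes = 1:2) {
  rec <- reconcile_tips(tree, scores)
  tree <- rec$tree; scores <- rec$x[, axes, drop = FALSE]
  nodes <- bm_node_states(tree, scores)
  list(tips = scores, nodes = nodes, edges = tree$edge)
}

#' Align a tree and a species-indexed table
#'
#' Species present in only one of the two inputs are pruned/dropped with a
#' warning naming them; silent disagreement is never allowed.
#'
#' @param tree A `phylo`.
#' @param x Matrix or data frame with species row names.
#' @return List with the pruned `tree` and the row-matched `x`.
#' @export
reconcile_tips <- function(tree, x) {
  sp <- rownames(x)
  only_tree <- setdiff(tree$tip.label, sp)
  only_data <- setdiff(sp, tree$tip.label)
  if (length(only_tree)) {
    warning("dropping tips absent from data: ", paste(only_tree, collapse = ", "))
    tree <- ape::drop.tip(tree, only_tree)
  }
  if (length(only_data)) {
    warning("dropping data rows absent from tree: ", paste(only_data, collapse = ", "))
  }
  list(tree = tree, x = x[tree$tip.label, , drop = FALSE])
}

#' Wilks' lambda for a multivariate group comparison
#'
#' \eqn{\Lambda = \det(W)/\det(W+B)} from the standard MANOVA decomposition
#' of the data into within-group (W) and between-group (B) cross-products.
#'
#' @param X n x p data matrix.
#' @param groups Group labels, length n.
#' @return Wilks' lambda in (0, 1].
#' @export
wilks_lambda <- function(X, groups) {
  X <- as.matrix(X)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop_validation("need at least 2 groups")
  if (nrow(X) - nlevels(groups) < ncol(X))
    stop_validation("singular W: more characters than residual degrees of freedom")
  gm <- rowsum(X, groups) / as.vector(table(groups))
  R <- X - gm[groups, , drop = FALSE]
  W <- crossprod(R)
  Tt <- crossprod(scale(X, center = TRUE, scale = FALSE))
  det(W) / det(Tt)
}

#' Phylogenetic MANOVA with a simulated Wilks null
#'
#' Tests for group differences in multivariate trait means while accounting
#' for phylogenetic non-independence. The observed Wilks' lambda is compared
#' with a null distribution built by simulating `nsim` multivariate
#' Brownian-motion datasets on the tree — using an evolutionary rate
#' (covariance) matrix estimated from the data — with group labels held
#' fixed. Smaller lambda means stronger separation, so
#' \eqn{p = (1 + \#\{\Lambda_{sim} \le \Lambda_{obs}\})/(nsim + 1)}.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param X Species x character matrix (row names = species), typically
#'   z-transformed.
#' @param groups Named group labels (names = species) or vector aligned with
#'   `rownames(X)`.
#' @param nsim Number of null simulations (>= 99; default 1000).
#' @param seed Optional integer seed for reproducibility.
#' @param rate_estimate `"gls"` (default): rate matrix by generalized least
#'   squares, \eqn{(X-\hat\mu)'C^{-1}(X-\hat\mu)/(n-1)}, identical to the
#'   covariance of phylogenetically independent contrasts; or `"raw"`:
#'   ordinary covariance, for sensitivity analysis.
#' @return Object of class `phylo_manova`: list with `lambda`, `p_value`,
#'   `lambda_sim`, `nsim`, `group_sizes`, `rate_matrix`, `seed`.
#' @export
phylo_manova <- function(tree, X, groups, nsim = 1000L, seed = NULL,
                         rate_estimate = c("gls", "raw")) {
  rate_estimate <- match.arg(rate_estimate)
  if (nsim < 99L) stop_validation("nsim must be at least 99")
  X <- as.matrix(X)
  rec <- reconcile_tips(tree, X)
  tree <- rec$tree; X <- rec$x
  if (!is.null(names(groups))) groups <- groups[rownames(X)]
  groups <- droplevels(as.factor(groups))
  if (any(is.na(groups))) stop_validation("missing group label")
  lambda_obs <- wilks_lambda(X, groups)
  C <- ape::vcv(tree)[rownames(X), rownames(X)]
  n <- nrow(X)
  if (rate_estimate == "gls") {
    Ci <- solve(C)
    one <- rep(1, n)
    mu <- drop(crossprod(one, Ci %*% X)) / drop(crossprod(one, Ci %*% one))
    Xc <- sweep(X, 2L, mu)
    R <- crossprod(Xc, Ci %*% Xc) / (n - 1)
  } else {
    R <- stats::cov(X)
  }
  Uc <- chol(C)
  Ur <- chol(R)
  if (!is.null(seed)) set.seed(seed)
  lambda_sim <- vapply(seq_len(nsim), function(i) {
    Z <- matrix(stats::rnorm(n * ncol(X)), n, ncol(X))
    wilks_lambda(crossprod(Uc, Z) %*% Ur, groups)
  }, numeric(1L))
  p <- (1 + sum(lambda_sim <= lambda_obs)) / (nsim + 1)
  structure(list(lambda = lambda_obs, p_value = p, lambda_sim = lambda_sim,
                 nsim = nsim, group_sizes = table(groups),
                 rate_matrix = R, seed = seed),
            class = "phylo_manova")
}

#' @export
print.phylo_manova <- function(x, ...) {
  cat("Phylogenetic MANOVA (simulated Wilks test)\n")
  cat(sprintf("  Wilks lambda = %.4f, simulated p = %.4g (nsim = %d)\n",
              x$lambda, x$p_value, x$nsim))
  cat("  group sizes:", paste(names(x$group_sizes), x$group_sizes,
                              sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# ---- single-rate symmetric Markov (Mk) model ------------------------------

#' Mk transition probability matrix
#'
#' Closed form for the single-rate symmetric (equal-rates) model with k
#' states, parameterized so that `q` is the total rate of leaving a state
#' (each specific change occurring at rate `q/(k-1)`):
#' \eqn{p_{same}(t) = 1/k + (1 - 1/k) e^{-kqt/(k-1)}}.
#'
#' @param q Transition rate (total rate away from a state).
#' @param t Branch length.
#' @param k Number of states.
#' @return k x k transition probability matrix.
#' @export
mk1_pmat <- function(q, t, k) {
  e <- exp(-k * q * t / (k - 1))
  p_same <- 1 / k + (1 - 1 / k) * e
  p_diff <- (1 - e) / k
  m <- matrix(p_diff, k, k)
  diag(m) <- p_same
  m
}

mk1_prepare <- function(tree, tip_states, states) {
  if (is.null(states)) states <- sort(unique(as.character(tip_states)))
  if (length(states) < 2L) stop_validation("need at least 2 states")
  tip_states <- stats::setNames(as.character(tip_states), names(tip_states))
  if (!is.null(names(tip_states))) tip_states <- tip_states[tree$tip.label]
  if (anyNA(tip_states) || !all(tip_states %in% states))
    stop_validation("unknown or missing tip state")
  if (any(tree$edge.length <= 0)) stop_validation("branch lengths must be > 0")
  list(states = states, tip_states = tip_states)
}

#' Log-likelihood of tip states under the Mk single-rate model
#'
#' Felsenstein pruning over the tree with the closed-form transition matrix
#' of [mk1_pmat()] and a uniform root prior.
#'
#' @param tree Rooted `phylo` with positive branch lengths.
#' @param tip_states Character vector of states, named by tip label (or in
#'   tip order).
#' @param q Transition rate.
#' @param states Optional explicit state set (default: observed states).
#' @return Log-likelihood (numeric scalar).
#' @export
mk1_loglik <- function(tree, tip_states, q, states = NULL) {
  prep <- mk1_prepare(tree, tip_states, states)
  k <- length(prep$states)
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  D <- matrix(0, nnode, k)
  D[cbind(seq_len(n), match(prep$tip_states, prep$states))] <- 1
  logscale <- 0
  D[(n + 1):nnode, ] <- 1
  for (e in ape::postorder(tree)) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    P <- mk1_pmat(q, tree$edge.length[e], k)
    D[a, ] <- D[a, ] * drop(P %*% D[b, ])
    s <- max(D[a, ])
    if (s <= 0) return(-Inf)
    D[a, ] <- D[a, ] / s
    logscale <- logscale + log(s)
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  log(sum(D[root, ] / k)) + logscale
}

#' Ancestral state reconstruction under the Mk single-rate model
#'
#' Estimates the single transition rate by one-dimensional maximum
#' likelihood (bracketed on the log scale), then computes the marginal
#' probability of each state at every node by the re-rooting (up-down)
#' algorithm with a uniform root prior. Tips get probability 1 on their
#' observed state.
#'
#' @inheritParams mk1_loglik
#' @param q Optional fixed rate; estimated when `NULL`.
#' @return Object of class `asr_mk1`: list with `states`, `q`, `logLik` and
#'   `marginal` ((tips + nodes) x states probability matrix, rows in ape
#'   node-number order).
#' @export
asr_mk1 <- function(tree, tip_states, states = NULL, q = NULL) {
  prep <- mk1_prepare(tree, tip_states, states)
  states <- prep$states
  k <- length(states)
  if (is.null(q)) {
    depth <- max(ape::node.depth.edgelength(tree))
    f <- function(lq) mk1_loglik(tree, prep$tip_states, exp(lq), states)
    opt <- stats::optimize(f, interval = c(log(1e-8 / depth), log(1e4 / depth)),
                           maximum = TRUE, tol = 1e-10)
    q <- exp(opt$maximum)
  }
  ll <- mk1_loglik(tree, prep$tip_states, q, states)
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  # down pass: conditional likelihood of each clade given its root state
  D <- matrix(0, nnode, k)
  D[cbind(seq_len(n), match(prep$tip_states, states))] <- 1
  D[(n + 1):nnode, ] <- 1
  po <- ape::postorder(tree)
  lift <- matrix(0, nrow(tree$edge), k)   # P(t_e) %*% D[child] per edge
  for (e in po) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    P <- mk1_pmat(q, tree$edge.length[e], k)
    lift[e, ] <- drop(P %*% D[b, ])
    D[a, ] <- D[a, ] * lift[e, ]
    if (max(D[a, ]) > 0) D[a, ] <- D[a, ] / max(D[a, ])
  }
  # up pass: likelihood of everything outside each node's clade
  A <- matrix(0, nnode, k)
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  A[root, ] <- 1 / k
  for (e in rev(po)) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    sib <- A[a, ]
    for (e2 in which(tree$edge[, 1L] == a)) {
      if (e2 != e) sib <- sib * lift[e2, ]
    }
    P <- mk1_pmat(q, tree$edge.length[e], k)
    A[b, ] <- drop(crossprod(P, sib))
    if (max(A[b, ]) > 0) A[b, ] <- A[b, ] / max(A[b, ])
  }
  marg <- D * A
  marg <- marg / rowSums(marg)
  colnames(marg) <- states
  rownames(marg) <- c(tree$tip.label, n + seq_len(tree$Nnode))
  structure(list(states = states, q = q, logLik = ll, marginal = marg,
                 tree = tree),
            class = "asr_mk1")
}

#' @export
print.asr_mk1 <- function(x, ...) {
  cat("Mk single-rate ancestral state reconstruction\n")
  cat(sprintf("  states: %s; rate q = %.5g; logLik = %.4f\n",
              paste(x$states, collapse = ", "), x$q, x$logLik))
  invisible(x)
}

#' Edges implying a state change under an Mk reconstruction
#'
#' Lists edges whose most-probable state differs between parent and child,
#' with both marginal probabilities attached.
#'
#' @param fit An `asr_mk1` object.
#' @return Data frame with columns `parent`, `child`, `parent_state`,
#'   `child_state`, `parent_prob`, `child_prob` (possibly zero rows).
#' @export
asr_transitions <- function(fit) {
  stopifnot(inherits(fit, "asr_mk1"))
  tree <- fit$tree
  best <- max.col(fit$marginal, ties.method = "first")
  out <- lapply(seq_len(nrow(tree$edge)), function(e) {
    a <- tree$edge[e, 1L]; b <- tree$edge[e, 2L]
    if (best[a] == best[b]) return(NULL)
    data.frame(parent = a, child = b,
               parent_state = fit$states[best[a]],
               child_state = fit$states[best[b]],
               parent_prob = fit$marginal[a, best[a]],
               child_prob = fit$marginal[b, best[b]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(parent = integer(0), child = integer(0),
                      parent_state = character(0), child_state = character(0),
                      parent_prob = numeric(0), child_prob = numeric(0))
  out
}

#' Discriminant re-classification of diet from morphology
#'
#' Linear discriminant analysis with a shared within-class covariance,
#' posterior class probabilities by the Gaussian discriminant rule, and the
#' resubstitution confusion matrix. Species whose morphology-predicted class
#' differs from their diet-based class are listed as mismatches.
#'
#' @param z Species x character matrix (z-transformed), row names = species.
#' @param labels Class labels (named by species, or aligned with rows).
#' @param prior `"proportional"` (class sizes; default) or `"uniform"`.
#' @return Object of class `diet_dfa`: list with `lda` (the MASS fit),
#'   `posterior`, `predicted`, `confusion`, `mismatches`, `accuracy`.
#' @export
lda_diet <- function(z, labels, prior = c("proportional", "uniform")) {
  prior <- match.arg(prior)
  z <- as.matrix(z)
  if (!is.null(names(labels))) labels <- labels[rownames(z)]
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2L) stop_validation("need at least 2 classes")
  pr <- if (prior == "uniform") {
    rep(1 / nlevels(labels), nlevels(labels))
  } else as.vector(table(labels)) / length(labels)
  fit <- tryCatch(MASS::lda(z, grouping = labels, prior = pr),
                  error = function(e) NULL)
  if (is.null(fit)) {
    # numerically singular pooled covariance: ridge-regularized Gaussian rule
    post <- ridge_lda_posterior(z, labels, pr)
    pred <- factor(colnames(post)[max.col(post)], levels = levels(labels))
    scaling <- NULL
  } else {
    p <- stats::predict(fit)
    post <- p$posterior
    pred <- p$class
    scaling <- fit$scaling
  }
  conf <- table(observed = labels, predicted = pred)
  mism <- rownames(z)[pred != labels]
  structure(list(lda = fit, scaling = scaling, posterior = post,
                 predicted = stats::setNames(pred, rownames(z)),
                 confusion = conf, mismatches = mism,
                 accuracy = mean(pred == labels)),
            class = "diet_dfa")
}

ridge_lda_posterior <- function(z, labels, pr) {
  p <- ncol(z)
  mu <- rowsum(z, labels) / as.vector(table(labels))
  R <- z - mu[labels, , drop = FALSE]
  S <- crossprod(R) / (nrow(z) - nlevels(labels))
  S <- S + diag(1e-8 * sum(diag(S)) / p, p)
  Si <- solve(S)
  disc <- sapply(seq_len(nlevels(labels)), function(g) {
    d <- sweep(z, 2L, mu[g, ])
    -0.5 * rowSums((d %*% Si) * d) + log(pr[g])
  })
  colnames(disc) <- levels(labels)
  e <- exp(disc - apply(disc, 1L, max))
  e / rowSums(e)
}

#' @export
print.diet_dfa <- function(x, ...) {
  cat("Discriminant re-classification\n")
  cat(sprintf("  resubstitution accuracy %.3f (%d mismatching of %d)\n",
              x$accuracy, length(x$mismatches), nrow(x$posterior)))
  invisible(x)
}
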