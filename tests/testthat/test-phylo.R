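test_that("PCA conserves variance and reconstructs the data", {
  set.seed(21)
  x <- matrix(rnorm(35 * 5), 35, 5, dimnames = list(NULL, paste0("c", 1:5)))
  z <- z_transform(x)
  p <- morpho_pca(z)
  expect_equal(sum(p$var_frac), 1, tolerance = 1e-12)
  expect_equal(unname(colMeans(p$scores)), rep(0, 5), tolerance = 1e-10)
  expect_equal(crossprod(p$loadings), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  center <- colMeans(z)
  recon <- p$scores %*% t(p$loadings) + rep(1, nrow(z)) %o% center
  expect_equal(unname(recon), unname(unclass(z)), tolerance = 1e-8)
  # fixed sign convention: dominant loading positive on every axis
  dom <- apply(p$loadings, 2, function(l) l[which.max(abs(l))])
  expect_true(all(dom > 0))
})

test_that("perfectly correlated characters put all variance on one axis", {
  x <- cbind(a = 1:10, b = 2 * (1:10))
  p <- morpho_pca(scale(x))
  expect_equal(p$var_frac[1], 1, tolerance = 1e-12)
})

test_that("isotropic data spreads variance evenly over axes", {
  set.seed(99)
  x <- matrix(rnorm(1000), 500, 2)
  p <- morpho_pca(x)
  expect_true(all(p$var_frac > 0.45 & p$var_frac < 0.55))
})

test_that("broken-stick expectations are exact and drive retention", {
  expect_equal(sum(broken_stick(7)), 1, tolerance = 1e-12)
  expect_equal(broken_stick(2), c(0.75, 0.25))
  expect_equal(broken_stick(3), c(11 / 18, 5 / 18, 2 / 18), tolerance = 1e-12)
  expect_equal(retain_axes(c(0.9, 0.1)), 1L)
  expect_equal(retain_axes(rep(1 / 4, 4)), integer(0))
  expect_equal(retain_axes(c(0.5, 0.3, 0.2)), integer(0))
  # retention stops at the first failing axis even if later axes pass
  expect_equal(retain_axes(c(0.55, 0.1, 0.3, 0.05)), 1L)
})

test_that("broken-stick expectations agree with the community ecology standard", {
  skip_if_not_installed("vegan")
  b <- broken_stick(7)
  expect_equal(unname(vegan::bstick(7, tot.var = 1)), b, tolerance = 1e-12)
})

test_that("Brownian ancestral states match closed forms", {
  star <- ape::stree(5, "star")
  star$edge.length <- rep(1, 5)
  x <- c(t1 = 1, t2 = 2, t3 = 3, t4 = 4, t5 = 10)
  expect_equal(unname(bm_node_states(star, x)[1, 1]), mean(x))

  two <- ape::read.tree(text = "(A:2,B:0.5);")
  anc <- bm_node_states(two, c(A = 4, B = 1))
  expect_equal(unname(anc[1, 1]), (4 / 2 + 1 / 0.5) / (1 / 2 + 1 / 0.5))

  tr <- ape::rtree(8)
  const <- setNames(rep(3.7, 8), tr$tip.label)
  expect_equal(unname(bm_node_states(tr, const)[, 1]), rep(3.7, tr$Nnode))
})

test_that("Brownian ancestral states equal independent oracles on small trees", {
  set.seed(5)
  for (n in c(4, 6)) {
    tr <- ape::rtree(n)
    x <- setNames(rnorm(n), tr$tip.label)
    mine <- bm_node_states(tr, x)[, 1]
    # oracle 1: numerical minimization of the weighted squared-change objective
    obj <- function(u) {
      v <- c(x[tr$tip.label], u)
      sum((v[tr$edge[, 2]] - v[tr$edge[, 1]])^2 / tr$edge.length)
    }
    opt <- optim(rep(mean(x), tr$Nnode), obj, method = "BFGS",
                 control = list(reltol = 1e-16, maxit = 5000))
    expect_equal(unname(mine), opt$par, tolerance = 1e-6)
    # oracle 2: re-rooting ML implementation
    skip_if_not_installed("phytools")
    fa <- phytools::fastAnc(tr, x)
    expect_equal(unname(mine), unname(fa[as.character(names(mine))]),
                 tolerance = 1e-10)
  }
})

test_that("Wilks lambda matches brute-force and stats::manova", {
  set.seed(8)
  X <- matrix(rnorm(12), 6, 2)
  g <- factor(rep(c("a", "b", "c"), each = 2))
  lam <- wilks_lambda(X, g)
  # brute force with explicit loops
  W <- matrix(0, 2, 2); B <- matrix(0, 2, 2)
  gm <- colMeans(X)
  for (lev in levels(g)) {
    rows <- X[g == lev, , drop = FALSE]
    mu <- colMeans(rows)
    for (i in seq_len(nrow(rows))) {
      W <- W + tcrossprod(rows[i, ] - mu)
    }
    B <- B + nrow(rows) * tcrossprod(mu - gm)
  }
  expect_equal(lam, det(W) / det(W + B), tolerance = 1e-10)
  sm <- summary(manova(X ~ g), test = "Wilks")
  expect_equal(lam, sm$stats[1, "Wilks"], tolerance = 1e-10)
  expect_error(wilks_lambda(matrix(rnorm(12), 4, 3), factor(c(1, 1, 2, 2))),
               "singular W")
})

test_that("phylogenetic MANOVA detects maximal separation and is seeded", {
  tree <- sim_tree(20, seed = 31)
  z <- sim_bm_traits(tree, rate = diag(3), seed = 32)
  g <- setNames(rep(c("a", "b"), each = 10), tree$tip.label)
  z[g == "b", ] <- z[g == "b", ] + 10   # ten pooled SDs apart
  fit <- phylo_manova(tree, z, g, nsim = 199, seed = 41)
  expect_equal(fit$p_value, 1 / 200)
  refit <- phylo_manova(tree, z, g, nsim = 199, seed = 41)
  expect_identical(fit$lambda_sim, refit$lambda_sim)
  expect_true(fit$lambda > 0 && fit$lambda <= 1)
  expect_gte(fit$p_value, 1 / (fit$nsim + 1))
})

test_that("tip/data mismatches are reconciled loudly", {
  tree <- sim_tree(6, seed = 2)
  z <- matrix(rnorm(10), 5, 2,
              dimnames = list(tree$tip.label[1:5], c("a", "b")))
  expect_warning(rec <- reconcile_tips(tree, z), "t6")
  expect_equal(sort(rec$tree$tip.label), sort(rownames(z)))
})

test_that("Mk likelihood equals state-enumeration on 4-tip trees", {
  tr <- ape::read.tree(text = "((A:1,B:2):0.5,(C:1.5,D:0.7):1.2);")
  cases <- list(
    list(states = c("x", "y"), tips = c(A = "x", B = "x", C = "y", D = "x")),
    list(states = c("x", "y", "z"), tips = c(A = "x", B = "z", C = "y", D = "x")))
  for (cs in cases) {
    for (q in c(0.05, 0.3, 2)) {
      expect_equal(mk1_loglik(tr, cs$tips, q, states = cs$states),
                   mk1_loglik_enum(tr, cs$tips, q, cs$states),
                   tolerance = 1e-8)
    }
  }
})

test_that("Mk transition probabilities match the matrix exponential", {
  for (k in 2:4) for (t in c(0.1, 1, 5)) {
    expect_equal(mk1_pmat(0.4, t, k), expm_eigen(mk1_Q(0.4, k) * t),
                 tolerance = 1e-10)
  }
})

test_that("Mk marginals on a two-tip tree match hand computation", {
  tr <- ape::read.tree(text = "(A:1,B:2);")
  tips <- c(A = "x", B = "y")
  q <- 0.4
  fit <- asr_mk1(tr, tips, q = q)
  P1 <- expm_eigen(mk1_Q(q, 2) * 1)
  P2 <- expm_eigen(mk1_Q(q, 2) * 2)
  root_lik <- c(P1[1, 1] * P2[1, 2], P1[2, 1] * P2[2, 2]) / 2
  expect_equal(unname(fit$marginal["3", ]), root_lik / sum(root_lik),
               tolerance = 1e-10)
  expect_equal(unname(fit$marginal["A", ]), c(1, 0))
  expect_equal(fit$logLik, log(sum(root_lik)), tolerance = 1e-10)
})

test_that("uniform tip states reconstruct as the ancestral state", {
  tr <- ape::rtree(10)
  tips <- setNames(rep("a", 10), tr$tip.label)
  fit <- asr_mk1(tr, tips, states = c("a", "b"), q = 0.01)
  expect_gte(fit$marginal["11", "a"], 0.99)
  expect_equal(nrow(asr_transitions(fit)), 0L)
})

test_that("Mk likelihood is invariant to the root position", {
  skip_if_not_installed("phytools")
  set.seed(13)
  tr <- ape::rtree(8)
  tips <- setNames(sample(c("a", "b"), 8, replace = TRUE), tr$tip.label)
  base <- mk1_loglik(tr, tips, 0.7)
  for (node in c(11, 13)) {
    rr <- phytools::reroot(tr, node, position = 0.3 * tr$edge.length[
      which(tr$edge[, 2] == node)])
    expect_equal(mk1_loglik(rr, tips, 0.7), base, tolerance = 1e-8)
  }
})

test_that("Mk rate estimate agrees with an independent ER fit", {
  set.seed(17)
  tr <- ape::rphylo(25, 1, 0)
  tips <- ape::rTraitDisc(tr, model = "ER", rate = 0.3, states = c("a", "b"))
  fit <- asr_mk1(tr, tips)
  af <- ape::ace(tips, tr, type = "discrete", model = "ER")
  # with 2 states the per-change and total-rate parameterizations coincide;
  # ape reports the root sum without the uniform 1/k prior factor
  expect_equal(fit$q, unname(af$rates), tolerance = 1e-4)
  expect_equal(fit$logLik + log(2), af$loglik, tolerance = 1e-6)
})

test_that("state-change edges are localized to derived clades", {
  # one derived clade: the cherry (D,E)
  tr <- ape::read.tree(text = "((A:1,B:1):1,((D:1,E:1):1,C:1):1);")
  tips <- c(A = "anc", B = "anc", C = "anc", D = "der", E = "der")
  fit <- asr_mk1(tr, tips, q = 0.05)
  trans <- asr_transitions(fit)
  expect_equal(nrow(trans), 1L)
  mrca_de <- ape::getMRCA(tr, c("D", "E"))
  expect_equal(trans$child, mrca_de)
  # two independent origins (a derived cherry and a derived singleton)
  tr2 <- ape::read.tree(
    text = "(((A:1,B:1):1,(C:1,D:1):1):1,((E:1,F:1):1,(G:1,H:1):1):1);")
  tips2 <- c(A = "der", B = "der", C = "anc", D = "anc",
             E = "der", F = "anc", G = "anc", H = "anc")
  fit2 <- asr_mk1(tr2, tips2, q = 0.05)
  tx <- asr_transitions(fit2)
  expect_equal(nrow(tx), 2L)
  expect_setequal(tx$child, c(ape::getMRCA(tr2, c("A", "B")),
                              which(tr2$tip.label == "E")))
})

test_that("discriminant posteriors follow the Gaussian rule", {
  # 1-D equal-prior case: boundary at the midpoint of the class means
  set.seed(6)
  z <- cbind(v = c(rnorm(30, 0, 1), rnorm(30, 4, 1)))
  rownames(z) <- paste0("s", 1:60)
  lab <- setNames(rep(c("lo", "hi"), each = 30), rownames(z))
  fit <- lda_diet(z, lab, prior = "uniform")
  mid <- (mean(z[1:30, 1]) + mean(z[31:60, 1])) / 2
  post_at <- function(x) {
    p <- predict(fit$lda, newdata = cbind(v = x))$posterior
    p[1, "lo"] - p[1, "hi"]
  }
  expect_gt(post_at(mid - 0.2), 0)
  expect_lt(post_at(mid + 0.2), 0)
  expect_lt(abs(post_at(mid)), 0.1)
  expect_equal(unname(rowSums(fit$posterior)), rep(1, 60), tolerance = 1e-12)
})

test_that("widely separated classes classify perfectly; confusion sums match", {
  set.seed(14)
  z <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 20), 20))
  colnames(z) <- c("a", "b"); rownames(z) <- paste0("s", 1:40)
  lab <- setNames(rep(c("p", "q"), each = 20), rownames(z))
  fit <- lda_diet(z, lab)
  expect_equal(fit$accuracy, 1)
  expect_length(fit$mismatches, 0)
  expect_equal(unname(rowSums(fit$confusion)), c(20, 20))
})

test_that("discriminant posteriors match a hand-rolled reference", {
  set.seed(23)
  n <- 45
  z <- rbind(matrix(rnorm(2 * 15, 0), ncol = 2),
             matrix(rnorm(2 * 15, 1.5), ncol = 2),
             matrix(rnorm(2 * 15, c(0, 3)), ncol = 2))
  colnames(z) <- c("a", "b"); rownames(z) <- paste0("s", 1:n)
  lab <- setNames(rep(c("g1", "g2", "g3"), each = 15), rownames(z))
  fit <- lda_diet(z, lab)
  # reference: pooled-covariance Gaussian discriminant posteriors
  mu <- rowsum(z, lab) / 15
  R <- z - mu[lab, ]
  S <- crossprod(R) / (n - 3)
  Si <- solve(S)
  disc <- sapply(rownames(mu), function(g) {
    d <- sweep(z, 2, mu[g, ])
    -0.5 * rowSums((d %*% Si) * d) + log(1 / 3)
  })
  ref <- exp(disc - apply(disc, 1, max))
  ref <- ref / rowSums(ref)
  expect_equal(unname(fit$posterior), unname(ref[, colnames(fit$posterior)]),
               tolerance = 1e-6)
  expect_identical(unname(fit$predicted),
                   factor(colnames(ref)[max.col(ref)], levels = levels(fit$predicted)))
})

test_that("phylomorphospace nodes are ancestral estimates on retained axes", {
  tree <- sim_tree(10, seed = 51)
  z <- sim_bm_traits(tree, rate = diag(4), seed = 52)
  p <- morpho_pca(z)
  pms <- phylomorphospace_data(tree, p$scores, axes = 1:2)
  expect_equal(ncol(pms$tips), 2L)
  expect_equal(nrow(pms$nodes), tree$Nnode)
  expect_equal(nrow(pms$edges), nrow(tree$edge))
  # a star phylogeny places the root at the tip mean
  star <- ape::stree(6, "star"); star$edge.length <- rep(1, 6)
  sc <- matrix(rnorm(12), 6, 2, dimnames = list(star$tip.label, NULL))
  pms2 <- phylomorphospace_data(star, sc, axes = 1:2)
  expect_equal(unname(pms2$nodes[1, ]), unname(colMeans(sc)))
})
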