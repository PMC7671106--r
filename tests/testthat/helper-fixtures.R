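# Shared fixtures built in code.

prey_fixture <- function() {
  read_prey_traits(dietmorph_example("prey_traits.csv"))
}

diet_fixture <- function() {
  read_category_importances(dietmorph_example("diet_category_importances.csv"))
}

# The six published prey groups (Results section of the source study).
published_prey_groups <- list(
  benthic_arthropods = c("Cumacea", "Isopoda", "Gammaridae", "Insecta",
                         "Crab", "Hermit crab", "Crayfish", "Pandelid shrimp"),
  pelagic_arthropods = c("Ostracoda", "Euphausiidae", "Pelagic amphipod",
                         "Copepoda", "Mysidae"),
  stationary_benthic_items = c("Eggs", "Algae and plant matter", "Detritus"),
  squishy_swimmers = c("Octopus", "Fishes", "Larval fishes"),
  tentacles_and_appendages = c("Barnacle cirri", "Anemone", "Ctenophora"),
  vermes = c("Bivalvia", "Gastropoda", "Leech (Hirudinea)",
             "Polychaete annelid", "Planaria", "Oligochaeta", "Sipuncula"))

partition_matches <- function(membership, groups) {
  got <- lapply(split(membership$item, membership$category_id), sort)
  all(vapply(groups, function(g) {
    any(vapply(got, identical, logical(1L), y = sort(g)))
  }, logical(1L)))
}

# A small fixed specimen table with positive, jaw-plausible measurements.
toy_measurements <- function(n_species = 8L, seed = 42L) {
  set.seed(seed)
  sp <- sprintf("sp%02d", seq_len(n_species))
  data.frame(
    species = sp,
    SL = stats::runif(n_species, 50, 120),
    AsPr = stats::runif(n_species, 3, 8),
    PMLn = stats::runif(n_species, 8, 16),
    HdLn = stats::runif(n_species, 15, 35),
    DnLn = stats::runif(n_species, 8, 16),
    AtOL = stats::runif(n_species, 8, 18),
    PoOL = stats::runif(n_species, 4, 9),
    ArOS = stats::runif(n_species, 0.5, 3),
    InLr = stats::runif(n_species, 2, 6),
    MaSH = stats::runif(n_species, 1.5, 5),
    tooth_height = stats::runif(n_species, 0.5, 2.5),
    tooth_width = stats::runif(n_species, 0.4, 1.2),
    stringsAsFactors = FALSE)
}

# Eigen-based matrix exponential, independent of mk1_pmat.
expm_eigen <- function(M) {
  e <- eigen(M)
  Re(e$vectors %*% diag(exp(e$values), nrow(M)) %*% solve(e$vectors))
}

# Rate matrix for the k-state single-rate model in the package's
# parameterization (total leave rate q).
mk1_Q <- function(q, k) {
  Q <- matrix(q / (k - 1), k, k)
  diag(Q) <- -q
  Q
}

# Brute-force Mk likelihood: enumerate all internal-node state combinations.
mk1_loglik_enum <- function(tree, tip_states, q, states) {
  k <- length(states)
  n <- length(tree$tip.label)
  nnode <- tree$Nnode
  P <- lapply(tree$edge.length, function(t) expm_eigen(mk1_Q(q, k) * t))
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), nnode)))
  tip_idx <- match(tip_states[tree$tip.label], states)
  state_of <- function(node, combo) {
    if (node <= n) tip_idx[node] else combo[node - n]
  }
  tot <- 0
  for (i in seq_len(nrow(combos))) {
    combo <- combos[i, ]
    pr <- 1 / k   # uniform root prior
    for (e in seq_len(nrow(tree$edge))) {
      a <- state_of(tree$edge[e, 1L], combo)
      b <- state_of(tree$edge[e, 2L], combo)
      pr <- pr * P[[e]][a, b]
    }
    tot <- tot + pr
  }
  log(tot)
}
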