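# Independent oracles used across tests. These deliberately avoid the code
# paths they check: relatedness by explicit root-to-tip edge-path
# intersection, Brownian covariance by simulating the walk edge by edge,
# HPD by exhaustive window search.

# root-to-tip edge paths, keyed by tip label
edge_paths <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent_of <- integer(max(tree$edge))
  edge_to <- integer(max(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    parent_of[tree$edge[e, 2]] <- tree$edge[e, 1]
    edge_to[tree$edge[e, 2]] <- e
  }
  lapply(seq_len(n_tip), function(tip) {
    path <- integer(0)
    node <- tip
    while (node != root) {
      path <- c(path, edge_to[node])
      node <- parent_of[node]
    }
    path
  }) |> setNames(tree$tip.label)
}

# brute-force relatedness: shared root-to-MRCA path length per taxon pair
bf_relatedness <- function(tree) {
  paths <- edge_paths(tree)
  taxa <- tree$tip.label
  n <- length(taxa)
  A <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      shared <- intersect(paths[[i]], paths[[j]])
      A[i, j] <- sum(tree$edge.length[shared])
    }
  }
  A
}

# simulate Brownian motion down the tree, edge by edge; returns nrep x n_tip
bm_tip_values <- function(tree, nrep) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  vals <- matrix(0, nrep, max(tree$edge))
  # preorder: ape trees list edges parent-before-child from the root in cladewise order
  ord <- reorder(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    vals[, ch] <- vals[, p] + rnorm(nrep, 0, sqrt(ord$edge.length[e]))
  }
  v <- vals[, seq_len(n_tip), drop = FALSE]
  colnames(v) <- tree$tip.label
  v
}

# exhaustive minimum-width window HPD
bf_hpd <- function(draws, mass = 0.95) {
  x <- sort(draws)
  n <- length(x)
  h <- ceiling(mass * n)
  if (h >= n) return(c(x[1], x[n]))
  best <- c(Inf, NA, NA)
  for (i in 1:(n - h + 1)) {
    w <- x[i + h - 1] - x[i]
    if (w < best[1]) best <- c(w, x[i], x[i + h - 1])
  }
  best[2:3]
}

# small latent trait table straight from the model, bypassing sim_params
# defaults where a test needs full control
toy_trait_table <- function(A, vp, ve, means, blocks = 2, seed = 1,
                            wing = NULL) {
  m <- nrow(A)
  k <- nrow(vp)
  labs <- trait_labels()[seq_len(k), ]
  U <- simulate_species_effects(A, vp, seed = seed)
  set.seed(seed + 1000L)
  if (is.null(wing)) wing <- rep(0, m)
  grid <- tidyr::expand_grid(species = rownames(A),
                             trait_index = seq_len(k),
                             block = seq_len(blocks))
  si <- match(grid$species, rownames(A))
  grid$value <- means[grid$trait_index] + U[cbind(si, grid$trait_index)] +
    rnorm(nrow(grid), 0, sqrt(ve[grid$trait_index]))
  grid$wing <- wing[si]
  out <- dplyr::left_join(grid, labs, by = "trait_index")
  out$observation_id <- as.character(seq_len(nrow(out)))
  list(table = out, U = U)
}

identity_relatedness <- function(m, prefix = "sp") {
  A <- diag(m)
  rownames(A) <- colnames(A) <- sprintf("%s%02d", prefix, seq_len(m))
  A
}
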