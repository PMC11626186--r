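# shared fixtures: small trees, datasets and fast MCMC settings

toy_tree <- function() ape::read.tree(text = "((a:1,b:1):2,c:3);")

toy_specimen_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "specimen_id,species,cc_cm3,bm_kg,age_min_ma,age_max_ma,rock_unit,realm,flags",
    "KNM-1,sp_a,450,35,2.1,2.5,Gelasian,Afrotropical,",
    "KNM-2,sp_a;sp_b,510,,1.8,2.0,Calabrian,Afrotropical,adult_projected",
    "D-1,sp_b,600,48.5,1.1,1.4,Calabrian,Palearctic,"
  ), path)
  path
}

quick_ctl <- function(seed, iterations = 6000, burn_in = 1000, thinning = 5) {
  mcmc_control(iterations = iterations, burn_in = burn_in,
               thinning = thinning, seed = seed)
}

# independent oracle: shared root-to-tip path length by edge-set intersection
brute_force_cov <- function(tree) {
  n <- length(tree$tip.label)
  # edges on the path root -> node, identified by child node id
  path_edges <- function(tip) {
    edges <- integer(0)
    node <- tip
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (length(e) == 0L) break
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  }
  paths <- lapply(seq_len(n), path_edges)
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n))
    V[i, j] <- sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
  V
}

# independent oracle: nodes on the root-to-tip path (root counted, tip not),
# walking the edge table upward
brute_force_node_count <- function(tree, tip) {
  count <- 0L
  node <- tip
  repeat {
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 0L) break
    count <- count + 1L          # parent of this edge is on the path
    node <- tree$edge[e, 1]
  }
  count
}
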