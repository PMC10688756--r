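# small fixtures built in code, shared across test files

# three-tip caterpillar used throughout the hand-computed examples
tiny_tree <- function() {
  ape::read.tree(text = "((A:1,B:1):1,C:2);")
}

# community of 4 sites x 4 species with coordinates
tiny_cm <- function() {
  inc <- rbind(s1 = c(1, 1, 0, 0),
               s2 = c(0, 1, 1, 0),
               s3 = c(1, 0, 1, 1),
               s4 = c(1, 1, 1, 1))
  colnames(inc) <- c("A", "B", "C", "D")
  community_matrix(inc, cbind(lon = c(-50, -51, -52, -53),
                              lat = c(-20, -21, -22, -23)))
}

# random community matrix with every site holding >= min_rich species
random_cm <- function(n_sites, n_species, fill = 0.3, min_rich = 2L,
                      seed = 1L) {
  set.seed(seed)
  inc <- matrix(rbinom(n_sites * n_species, 1L, fill), n_sites, n_species)
  for (i in seq_len(n_sites)) {
    while (sum(inc[i, ]) < min_rich) {
      inc[i, ] <- rbinom(n_species, 1L, fill)
    }
  }
  dimnames(inc) <- list(sprintf("s%03d", seq_len(n_sites)),
                        sprintf("sp%03d", seq_len(n_species)))
  community_matrix(inc, cbind(lon = runif(n_sites, -55, -35),
                              lat = runif(n_sites, -30, -5)))
}

# brute-force patristic distance: sum branch lengths along tip-to-tip paths
brute_cophenetic <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(n + tree$Nnode)
  plen <- numeric(n + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  plen[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    nodes <- numeric(0)
    while (v != root) {
      nodes <- c(nodes, v)
      v <- parent[v]
    }
    nodes
  }
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n - 1)) {
    pi_ <- path_to_root(i)
    for (j in seq((i + 1), n)) {
      pj <- path_to_root(j)
      shared <- intersect(pi_, pj)
      d[i, j] <- d[j, i] <- sum(plen[setdiff(c(pi_, pj), shared)])
    }
  }
  d
}

# all permutations of 1:n (n small)
combinat_permn <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in combinat_permn(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# brute-force root-inclusive dendrogram FD: union of tip-to-root edges
brute_fd <- function(dend, tips) {
  n <- length(dend$tip.label)
  root <- n + 1L
  parent <- integer(n + dend$Nnode)
  elen <- numeric(n + dend$Nnode)
  parent[dend$edge[, 2]] <- dend$edge[, 1]
  elen[dend$edge[, 2]] <- dend$edge.length
  edges <- integer(0)
  for (tip in match(tips, dend$tip.label)) {
    v <- tip
    while (v != root) {
      edges <- c(edges, v)  # identify each edge by its child node
      v <- parent[v]
    }
  }
  sum(elen[unique(edges)])
}
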