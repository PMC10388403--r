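# Independent brute-force oracles used across tests. These deliberately use
# naive path-walking and explicit matrix inversion, never the package's own
# factorized code paths.

# covariance by walking root-to-tip node paths and summing edge lengths up to
# the last node the two paths share
brute_vcv <- function(tree) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  root <- ntip + 1L
  parent_of <- integer(max(edge))
  elen <- numeric(max(edge))
  parent_of[edge[, 2]] <- edge[, 1]
  elen[edge[, 2]] <- tree$edge.length
  path_nodes <- function(tip) {
    p <- tip
    out <- tip
    while (p != root) {
      p <- parent_of[p]
      out <- c(p, out)
    }
    out
  }
  paths <- lapply(seq_len(ntip), path_nodes)
  depth_of <- function(node) {
    d <- 0
    while (node != root) {
      d <- d + elen[node]
      node <- parent_of[node]
    }
    d
  }
  V <- matrix(0, ntip, ntip,
              dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip)) {
    for (j in i:ntip) {
      common <- intersect(paths[[i]], paths[[j]])
      mrca <- common[length(common)]
      V[i, j] <- V[j, i] <- depth_of(mrca)
    }
  }
  V
}

# explicit-inversion GLS oracle for y = b0 + b1 x, cov sigma2 V
gls_oracle <- function(y, x, V = diag(length(y))) {
  X <- cbind(1, x)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X) %*% (t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2 <- as.numeric(t(r) %*% Vi %*% r) / (length(y) - 2)
  covb <- s2 * solve(t(X) %*% Vi %*% X)
  list(beta0 = beta[1], beta1 = beta[2], se1 = sqrt(covb[2, 2]),
       t = beta[2] / sqrt(covb[2, 2]))
}

# explicit-inversion Blomberg's K oracle
k_oracle <- function(x, V) {
  n <- length(x)
  Vi <- solve(V)
  one <- rep(1, n)
  a <- as.numeric(solve(t(one) %*% Vi %*% one) %*% (t(one) %*% Vi %*% x))
  mse0 <- sum((x - a)^2) / (n - 1)
  mse <- as.numeric(t(x - a) %*% Vi %*% (x - a)) / (n - 1)
  exp_ratio <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  list(ahat = a, K = (mse0 / mse) / exp_ratio)
}

# equal-branch star phylogeny as newick
star_newick <- function(n, len = 1) {
  paste0("(", paste0("s", seq_len(n), ":", len, collapse = ","), ");")
}

# random occupancy over 9 patches (3 per urbanization level), every species
# guaranteed at least one presence
random_occupancy <- function(n_species, p = 0.3) {
  patches <- data.frame(
    patch_id = paste0("P", 1:9),
    impervious_pct = c(5, 10, 15, 25, 35, 45, 60, 75, 90))
  rows <- list()
  for (i in seq_len(n_species)) {
    repeat {
      pres <- runif(9) < p
      if (any(pres)) break
    }
    rows[[i]] <- data.frame(species = sprintf("sp%03d", i),
                            patch_id = patches$patch_id[pres],
                            count = sample(1:20, sum(pres), replace = TRUE))
  }
  list(patches = patches, occupancy = do.call(rbind, rows))
}

# set-based re-derivation of the occupancy groups, independent of the
# package's implementation
group_oracle <- function(occupancy, patches) {
  lev <- ifelse(patches$impervious_pct < 20, "low",
                ifelse(patches$impervious_pct <= 50, "moderate", "high"))
  names(lev) <- patches$patch_id
  occ <- occupancy[occupancy$count > 0, ]
  sp_lev <- split(lev[as.character(occ$patch_id)], occ$species)
  vapply(sp_lev, function(ls) {
    h <- "high" %in% ls
    l <- "low" %in% ls
    m <- "moderate" %in% ls
    if (h && l) "general" else if (h) "urban" else if (l) "rural"
    else if (m) "middle" else NA_character_
  }, character(1))
}
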