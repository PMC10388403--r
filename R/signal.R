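# Blomberg's K and its tip-shuffling permutation test.
#
# All GLS-type quantities are computed through the Cholesky factor of V
# (V = R'R, R upper triangular); V is never inverted explicitly. With
# u = R'^{-1} x and v = R'^{-1} 1:
#   1'V^{-1}1 = v'v,  1'V^{-1}x = v'u,  x'V^{-1}x = u'u
#   a-hat = (v'u)/(v'v)
#   (x - a 1)' V^{-1} (x - a 1) = u'u - (v'u)^2 / (v'v)

chol_or_fail <- function(V) {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    stop("phylogenetic covariance matrix is singular or not positive ",
         "definite; sanitize zero-length branches first ",
         "(see sanitize_branch_lengths)")
  }
  R
}

align_trait_to_vcv <- function(x, V) {
  if (!is.null(names(x))) {
    if (!setequal(names(x), rownames(V))) {
      stop("trait vector names do not match covariance matrix taxa")
    }
    x <- x[rownames(V)]
  } else if (length(x) != nrow(V)) {
    stop("trait vector length (", length(x), ") does not match covariance ",
         "dimension (", nrow(V), ")")
  }
  as.numeric(x)
}

#' Phylogenetic (GLS) mean of a trait
#'
#' The generalized-least-squares estimate of the root state,
#' a-hat = (1'V^-1 1)^-1 1'V^-1 x. Equals the arithmetic mean when V is a
#' scalar multiple of the identity (a star tree with equal branches).
#'
#' @param x numeric trait vector, optionally named by taxon; names must match
#'   the rows of `V`.
#' @param V phylogenetic covariance matrix from [phylo_vcv()].
#' @return the scalar GLS mean.
#' @export
phylo_mean <- function(x, V) {
  x <- align_trait_to_vcv(x, V)
  if (length(x) < 2L) stop("need at least 2 taxa")
  R <- chol_or_fail(V)
  u <- forwardsolve(t(R), x)
  v <- forwardsolve(t(R), rep(1, length(x)))
  sum(v * u) / sum(v * v)
}

# core statistics reused by the permutation loop; Rt is t(chol(V))
k_stats <- function(x, Rt, v, trV) {
  n <- length(x)
  u <- forwardsolve(Rt, x)
  vv <- sum(v * v)
  vu <- sum(v * u)
  ahat <- vu / vv
  mse <- (sum(u * u) - vu^2 / vv) / (n - 1)
  mse0 <- sum((x - ahat)^2) / (n - 1)
  exp_ratio <- (trV - n / vv) / (n - 1)
  list(ahat = ahat, mse = mse, mse0 = mse0,
       K = (mse0 / mse) / exp_ratio)
}

#' Blomberg's K phylogenetic signal statistic
#'
#' K is the ratio MSE0/MSE -- the mean squared deviation of the trait from
#' its GLS mean computed without (MSE0) and with (MSE) weighting by the
#' inverse phylogenetic covariance matrix -- standardized by its expectation
#' under Brownian motion, `(tr(V) - n / (1'V^-1 1)) / (n - 1)`. K = 1 matches
#' the Brownian expectation; K < 1 indicates less phylogenetic signal than
#' Brownian motion, K > 1 more. K is invariant to affine transforms of the
#' trait and to rescaling all branch lengths.
#'
#' @inheritParams phylo_mean
#' @return the scalar K (non-negative).
#' @references Blomberg, Garland & Ives (2003) Evolution 57:717-745.
#' @export
blomberg_k <- function(x, V) {
  x <- align_trait_to_vcv(x, V)
  n <- length(x)
  if (n < 3L) stop("Blomberg's K needs at least 3 taxa (got ", n, ")")
  if (stats::var(x) == 0) stop("degenerate trait: zero variance across taxa")
  R <- chol_or_fail(V)
  k_stats(x, t(R), forwardsolve(t(R), rep(1, n)), sum(diag(V)))$K
}

#' Permutation test for phylogenetic signal
#'
#' Computes Blomberg's K and a one-tailed permutation p-value. The null model
#' shuffles trait values across the tips of the phylogeny `n_perm` times
#' (default 999). The default test statistic is the phylogenetically weighted
#' MSE (smaller MSE means trait variation tracks the tree, i.e. stronger
#' signal); `statistic = "k"` permutes on K itself (larger K = stronger
#' signal), which orders permutations identically for a fixed tree up to the
#' re-estimated unweighted MSE0. The add-one rule
#' p = (1 + #{null at least as extreme}) / (n_perm + 1) guarantees p > 0.
#'
#' @inheritParams phylo_mean
#' @param n_perm number of tip shuffles (default 999).
#' @param seed integer seed for the shuffles; required for reproducibility.
#' @param statistic `"mse"` (default) or `"k"`.
#' @return a list with elements `K`, `p_value`, `mse`, `mse0`, `n`, `n_perm`,
#'   `seed`, `statistic`.
#' @export
phylo_signal_test <- function(x, V, n_perm = 999L, seed = 1L,
                              statistic = c("mse", "k")) {
  statistic <- match.arg(statistic)
  x <- align_trait_to_vcv(x, V)
  n <- length(x)
  if (n < 3L) stop("Blomberg's K needs at least 3 taxa (got ", n, ")")
  if (stats::var(x) == 0) stop("degenerate trait: zero variance across taxa")
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  R <- chol_or_fail(V)
  Rt <- t(R)
  v <- forwardsolve(Rt, rep(1, n))
  trV <- sum(diag(V))
  obs <- k_stats(x, Rt, v, trV)
  null_stat <- numeric(n_perm)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  for (b in seq_len(n_perm)) {
    s <- k_stats(sample(x), Rt, v, trV)
    null_stat[b] <- if (statistic == "mse") s$mse else s$K
  }
  hits <- if (statistic == "mse") {
    sum(null_stat <= obs$mse)
  } else {
    sum(null_stat >= obs$K)
  }
  list(K = obs$K, p_value = (1 + hits) / (n_perm + 1),
       mse = obs$mse, mse0 = obs$mse0, n = n,
       n_perm = n_perm, seed = as.integer(seed), statistic = statistic)
}

# deterministic per-cell seed derived from the root seed and the cell labels,
# so each habit/group/trait cell is reproducible independently of run order
derive_seed <- function(root_seed, ...) {
  key <- paste(c(...), collapse = "\r")
  h <- 0
  for (ci in utf8ToInt(key)) h <- (h * 31 + ci) %% 2147480009
  as.integer((as.numeric(root_seed) + h) %% 2147480009)
}

#' Phylogenetic signal table per habit, group and trait
#'
#' For every combination of growth habit, occupancy group and trait column,
#' prunes the tree to the species of that cell with non-missing trait values,
#' and runs [phylo_signal_test()]. Cells with fewer than `min_n` species are
#' flagged `insufficient_n` with K and p absent; species are dropped
#' per-trait when the trait value is missing (pairwise deletion).
#'
#' @param tree a `phylo` object covering all species.
#' @param traits data frame with columns `species`, `habit` and one numeric
#'   column per trait.
#' @param groups data frame with columns `species`, `group` (from
#'   [assign_species_groups()]).
#' @param trait_names trait columns to test; defaults to all numeric columns.
#' @param n_perm permutations per cell (default 999).
#' @param seed root seed; per-cell seeds are derived deterministically from
#'   it and the cell labels.
#' @param alpha significance level for the `signal_flag` column (default .05,
#'   strict inequality).
#' @param statistic permutation statistic, see [phylo_signal_test()].
#' @param min_n minimum species per cell (default 4).
#' @return data frame with one row per habit x group x trait:
#'   `habit`, `group`, `trait`, `n`, `K`, `p_value`, `signal_flag`, `status`.
#' @export
signal_table <- function(tree, traits, groups, trait_names = NULL,
                         n_perm = 999L, seed = 1L, alpha = 0.05,
                         statistic = "mse", min_n = 4L) {
  tree <- sanitize_branch_lengths(tree)
  traits$species <- normalize_taxon_names(traits$species)
  groups$species <- normalize_taxon_names(groups$species)
  if (is.null(trait_names)) {
    trait_names <- names(traits)[vapply(traits, is.numeric, logical(1))]
  }
  merged <- merge(traits, groups, by = "species")
  habits <- sort(unique(merged$habit))
  group_levels <- c("urban", "rural", "general", "middle")
  out <- list()
  for (habit in habits) {
    for (grp in group_levels) {
      sub <- merged[merged$habit == habit & merged$group == grp, , drop = FALSE]
      for (tr in trait_names) {
        vals <- sub[[tr]]
        keep <- !is.na(vals)
        sp <- sub$species[keep]
        sp <- intersect(sp, tree$tip.label)
        row <- data.frame(habit = habit, group = grp, trait = tr,
                          n = length(sp), K = NA_real_, p_value = NA_real_,
                          signal_flag = FALSE, status = "ok",
                          stringsAsFactors = FALSE)
        if (length(sp) < min_n) {
          row$status <- "insufficient_n"
        } else {
          x <- vals[keep][match(sp, sub$species[keep])]
          names(x) <- sp
          if (stats::var(x) == 0) {
            row$status <- "degenerate_trait"
          } else {
            V <- phylo_vcv(prune_to_taxa(tree, sp))
            cell_seed <- derive_seed(seed, habit, grp, tr)
            res <- phylo_signal_test(x, V, n_perm = n_perm, seed = cell_seed,
                                     statistic = statistic)
            row$K <- res$K
            row$p_value <- res$p_value
            row$signal_flag <- res$p_value < alpha
          }
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  do.call(rbind, out)
}
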