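# Trait-abundance regressions: ordinary GLS (identity covariance = OLS) and
# phylogenetic GLS with Brownian-motion covariance V from the tree.
# beta-hat = (X'V^-1 X)^-1 X'V^-1 y, sigma2-hat = RSS_V / (n - 2),
# cov(beta-hat) = sigma2-hat (X'V^-1 X)^-1, all via the Cholesky factor of V.

#' Generalized least squares fit of a simple linear model
#'
#' Fits `y = b0 + b1 x + e`, `e ~ N(0, sigma2 V)`. With `V = NULL` (or the
#' identity) the estimates equal ordinary least squares exactly. The slope
#' t-statistic and its two-sided p-value on n - 2 degrees of freedom are
#' returned; t is invariant to multiplying V by any positive constant.
#'
#' @param y numeric response vector.
#' @param x numeric predictor vector.
#' @param V covariance structure matrix (e.g. from [phylo_vcv()]), or `NULL`
#'   for the identity.
#' @return a list with `beta0`, `beta1`, `se1`, `t`, `df`, `p_value`, `n`,
#'   `sigma2`.
#' @export
fit_gls <- function(y, x, V = NULL) {
  n <- length(y)
  if (length(x) != n) stop("x and y lengths differ")
  if (n < 3L) stop("need at least 3 observations (df = n - 2 >= 1)")
  if (stats::var(x) == 0) stop("constant predictor: slope is not identifiable")
  if (is.null(V)) {
    yt <- y
    X <- cbind(1, x)
  } else {
    if (!all(dim(V) == n)) stop("V dimension does not match data")
    R <- chol_or_fail(V)
    Rt <- t(R)
    yt <- forwardsolve(Rt, y)
    X <- cbind(forwardsolve(Rt, rep(1, n)), forwardsolve(Rt, x))
  }
  XtX <- crossprod(X)
  Xty <- crossprod(X, yt)
  beta <- solve(XtX, Xty)
  resid <- yt - X %*% beta
  rss <- sum(resid^2)
  df <- n - 2L
  sigma2 <- rss / df
  covb <- sigma2 * solve(XtX)
  se1 <- sqrt(covb[2, 2])
  if (sigma2 <= .Machine$double.eps * sum(yt^2) || se1 == 0) {
    warning("degenerate fit: residual variance is zero")
    tval <- sign(beta[2]) * Inf
    p <- 0
  } else {
    tval <- beta[2] / se1
    p <- 2 * stats::pt(abs(tval), df = df, lower.tail = FALSE)
  }
  list(beta0 = unname(beta[1]), beta1 = unname(beta[2]), se1 = unname(se1),
       t = unname(tval), df = df, p_value = unname(p), n = n,
       sigma2 = unname(sigma2))
}

#' Trait-abundance regression with or without phylogenetic correction
#'
#' Regresses species abundance on a functional trait either by ordinary
#' least squares (`mode = "GLS"`, identity covariance) or by phylogenetic
#' generalized least squares (`mode = "PGLS"`), in which the residual
#' covariance is proportional to the Brownian-motion covariance matrix of
#' the tree pruned to the analyzed species. By default abundance is the
#' response and the trait the predictor; `response = "trait"` swaps them
#' (the two directions give the same slope t under OLS but not under PGLS).
#'
#' @param trait named numeric vector of trait values (names = species).
#' @param abundance named numeric vector of abundances (names = species).
#' @param tree `phylo` object containing at least the named species.
#' @param mode `"GLS"` or `"PGLS"`.
#' @param response which variable is the response, `"abundance"` (default)
#'   or `"trait"`.
#' @param log10_abundance log10-transform abundance before fitting
#'   (default FALSE).
#' @param min_n minimum species (default 5, so df >= 3).
#' @return a list as from [fit_gls()] plus `mode`, `response`, `n`.
#' @export
fit_trait_abundance <- function(trait, abundance, tree,
                                mode = c("GLS", "PGLS"),
                                response = c("abundance", "trait"),
                                log10_abundance = FALSE, min_n = 5L) {
  mode <- match.arg(mode)
  response <- match.arg(response)
  if (is.null(names(trait)) || is.null(names(abundance))) {
    stop("trait and abundance must be named by species")
  }
  names(trait) <- normalize_taxon_names(names(trait))
  names(abundance) <- normalize_taxon_names(names(abundance))
  sp <- intersect(names(trait), names(abundance))
  sp <- sp[!is.na(trait[sp]) & !is.na(abundance[sp])]
  miss_tree <- setdiff(sp, tree$tip.label)
  if (length(miss_tree)) {
    stop("species absent from tree: ", paste(miss_tree, collapse = ", "))
  }
  if (length(sp) < min_n) {
    return(list(status = "insufficient_n", n = length(sp), mode = mode))
  }
  ab <- abundance[sp]
  if (log10_abundance) ab <- log10(ab)
  tr <- trait[sp]
  V <- NULL
  if (mode == "PGLS") {
    sub <- sanitize_branch_lengths(prune_to_taxa(tree, sp))
    V <- phylo_vcv(sub)[sp, sp]
  }
  fit <- if (response == "abundance") {
    fit_gls(as.numeric(ab), as.numeric(tr), V)
  } else {
    fit_gls(as.numeric(tr), as.numeric(ab), V)
  }
  c(fit, list(mode = mode, response = response, status = "ok"))
}

#' GLS and PGLS model table per habit, group and trait
#'
#' For every habit x group x trait cell, fits the trait-abundance regression
#' twice (ordinary GLS and Brownian PGLS) on the species of that cell with
#' non-missing values, and flags slopes significant at `alpha` (default .01,
#' strict).
#'
#' @inheritParams signal_table
#' @param abundance data frame with columns `species`, `total_count`.
#' @param alpha significance level for the model flag (default .01).
#' @param response,log10_abundance passed to [fit_trait_abundance()].
#' @param min_n minimum species per cell (default 5).
#' @return data frame with one row per habit x group x trait x model:
#'   `habit`, `group`, `trait`, `model`, `n`, `beta1`, `se1`, `t`, `df`,
#'   `p_value`, `model_flag`, `status`.
#' @export
model_table <- function(tree, traits, groups, abundance, trait_names = NULL,
                        alpha = 0.01, response = "abundance",
                        log10_abundance = FALSE, min_n = 5L) {
  tree <- sanitize_branch_lengths(tree)
  traits$species <- normalize_taxon_names(traits$species)
  groups$species <- normalize_taxon_names(groups$species)
  abundance$species <- normalize_taxon_names(abundance$species)
  if (is.null(trait_names)) {
    trait_names <- names(traits)[vapply(traits, is.numeric, logical(1))]
  }
  merged <- merge(merge(traits, groups, by = "species"),
                  abundance, by = "species")
  habits <- sort(unique(merged$habit))
  group_levels <- c("urban", "rural", "general", "middle")
  out <- list()
  for (habit in habits) {
    for (grp in group_levels) {
      sub <- merged[merged$habit == habit & merged$group == grp, , drop = FALSE]
      for (tr in trait_names) {
        for (mode in c("GLS", "PGLS")) {
          row <- data.frame(habit = habit, group = grp, trait = tr,
                            model = mode, n = 0L, beta1 = NA_real_,
                            se1 = NA_real_, t = NA_real_, df = NA_integer_,
                            p_value = NA_real_, model_flag = FALSE,
                            status = "ok", stringsAsFactors = FALSE)
          keep <- !is.na(sub[[tr]]) & sub$species %in% tree$tip.label
          n_sp <- sum(keep)
          row$n <- n_sp
          if (n_sp < min_n) {
            row$status <- "insufficient_n"
          } else if (stats::var(sub[[tr]][keep]) == 0) {
            row$status <- "degenerate_trait"
          } else {
            trait_vec <- stats::setNames(sub[[tr]][keep], sub$species[keep])
            ab_vec <- stats::setNames(sub$total_count[keep], sub$species[keep])
            fit <- fit_trait_abundance(trait_vec, ab_vec, tree, mode = mode,
                                       response = response,
                                       log10_abundance = log10_abundance,
                                       min_n = min_n)
            if (identical(fit$status, "ok")) {
              row$beta1 <- fit$beta1
              row$se1 <- fit$se1
              row$t <- fit$t
              row$df <- fit$df
              row$p_value <- fit$p_value
              row$model_flag <- fit$p_value < alpha
            } else {
              row$status <- fit$status
            }
          }
          out[[length(out) + 1L]] <- row
        }
      }
    }
  }
  do.call(rbind, out)
}
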