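# Synthetic-data generators: pure-birth trees, Brownian traits with tunable
# signal, stratified patch occupancy and negative-binomial abundance.
# Every generator is deterministic for a fixed seed; seeds are applied
# locally so callers' RNG streams are left untouched.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  set.seed(seed)
  on.exit(if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv())) {
    rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

#' Simulate a Yule (pure-birth) phylogeny
#'
#' Forward simulation: the process starts with two lineages at the root;
#' waiting times between speciation events are exponential with rate
#' `k * birth_rate` for `k` extant lineages, and the lineage that splits is
#' chosen uniformly. After the `n_tips`-th lineage appears one further
#' exponential waiting time is added so terminal branches are positive.
#' The result is a rooted binary tree with `2 * n_tips - 2` edges and tips
#' labelled `t1 ... t<n_tips>` in order of appearance.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate, events per lineage per unit time (> 0).
#' @param seed integer seed.
#' @return a `phylo` object.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  n_tips <- as.integer(n_tips)
  if (is.na(n_tips) || n_tips < 2L) stop("n_tips must be >= 2")
  if (!is.finite(birth_rate) || birth_rate <= 0) stop("birth_rate must be > 0")
  nwk <- with_seed(seed, {
    # node records; nodes 1 and 2 are the root's children
    parent <- c(NA_integer_, NA_integer_)
    btime <- c(0, 0)
    dtime <- c(NA_real_, NA_real_)
    active <- c(1L, 2L)
    t <- 0
    while (length(active) < n_tips) {
      k <- length(active)
      t <- t + stats::rexp(1, rate = k * birth_rate)
      i <- active[sample.int(k, 1L)]
      dtime[i] <- t
      j <- length(parent) + 1L
      parent <- c(parent, i, i)
      btime <- c(btime, t, t)
      dtime <- c(dtime, NA_real_, NA_real_)
      active <- c(setdiff(active, i), j, j + 1L)
    }
    t_end <- t + stats::rexp(1, rate = n_tips * birth_rate)
    dtime[active] <- t_end
    kids <- split(seq_along(parent), parent)
    tip_counter <- 0L
    as_newick <- function(i) {
      len <- dtime[i] - btime[i]
      ch <- kids[[as.character(i)]]
      if (is.null(ch)) {
        tip_counter <<- tip_counter + 1L
        paste0("t", tip_counter, ":", format(len, digits = 17))
      } else {
        paste0("(", as_newick(ch[1]), ",", as_newick(ch[2]), "):",
               format(len, digits = 17))
      }
    }
    paste0("(", as_newick(1L), ",", as_newick(2L), ");")
  })
  read_phylogeny(text = nwk)
}

#' Simulate continuous traits with tunable phylogenetic signal
#'
#' Tip values are `signal_weight` times a Brownian-motion realization
#' (multivariate normal with covariance `sigma2 * V`, `V` from
#' [phylo_vcv()]) plus `1 - signal_weight` times independent white noise
#' with the same marginal variance per tip (`sigma2 * diag(V)`), shifted by
#' `root_value`. `signal_weight = 1` gives pure Brownian motion,
#' `signal_weight = 0` pure noise with matched scale.
#'
#' @param tree a `phylo` object.
#' @param sigma2 Brownian rate, trait variance per unit branch length (>= 0).
#' @param root_value ancestral state added to every tip.
#' @param signal_weight blend weight in \[0, 1\].
#' @param seed integer seed.
#' @param n_rep number of independent replicate traits (default 1).
#' @return a named numeric vector (tip labels), or a tips x `n_rep` matrix
#'   when `n_rep > 1`.
#' @export
simulate_bm_traits <- function(tree, sigma2 = 1, root_value = 0,
                               signal_weight = 1, seed = 1L, n_rep = 1L) {
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (signal_weight < 0 || signal_weight > 1) {
    stop("signal_weight must be in [0, 1]")
  }
  tree <- validate_phylogeny(tree)
  n <- length(tree$tip.label)
  if (sigma2 == 0) {
    out <- matrix(root_value, n, n_rep,
                  dimnames = list(tree$tip.label, NULL))
    return(if (n_rep == 1L) out[, 1] else out)
  }
  V <- phylo_vcv(sanitize_branch_lengths(tree))
  R <- chol_or_fail(V)
  sd_marg <- sqrt(sigma2 * diag(V))
  out <- with_seed(seed, {
    m <- matrix(NA_real_, n, n_rep, dimnames = list(tree$tip.label, NULL))
    for (r in seq_len(n_rep)) {
      bm <- sqrt(sigma2) * as.numeric(crossprod(R, stats::rnorm(n)))
      wn <- stats::rnorm(n, 0, sd_marg)
      m[, r] <- signal_weight * bm + (1 - signal_weight) * wn + root_value
    }
    m
  })
  if (n_rep == 1L) out[, 1] else out
}

#' Simulation configuration
#'
#' Bundles and validates the parameters of the community generator. Defaults
#' emulate the shape of the study system: ~100 woody species across 9 forest
#' patches, 3 per urbanization level, with overdispersed counts.
#'
#' @param n_species number of species (>= 4).
#' @param birth_rate Yule speciation rate.
#' @param sigma2_bm Brownian trait rate.
#' @param signal_weight phylogenetic-signal blend weight in \[0, 1\].
#' @param occupancy_probs named vector of per-patch presence probabilities in
#'   (0, 1\], names `low`, `moderate`, `high`.
#' @param abundance_slope effect of the standardized focal trait on
#'   log mean abundance.
#' @param abundance_dispersion negative-binomial size parameter (> 0; larger
#'   means closer to Poisson).
#' @param focal_trait trait column driving abundance (default `max_height`).
#' @param seed root seed.
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 100L, birth_rate = 1,
                              sigma2_bm = 1, signal_weight = 1,
                              occupancy_probs = c(low = 0.2, moderate = 0.2,
                                                  high = 0.2),
                              abundance_slope = 0.5,
                              abundance_dispersion = 5,
                              focal_trait = "max_height", seed = 1L) {
  if (n_species < 4L) stop("n_species must be >= 4")
  req <- c("low", "moderate", "high")
  if (!all(req %in% names(occupancy_probs))) {
    stop("occupancy_probs needs names low, moderate, high")
  }
  if (any(occupancy_probs <= 0 | occupancy_probs > 1)) {
    stop("occupancy probabilities must be in (0, 1]")
  }
  if (abundance_dispersion <= 0) stop("abundance_dispersion must be > 0")
  structure(list(n_species = as.integer(n_species), birth_rate = birth_rate,
                 sigma2_bm = sigma2_bm, signal_weight = signal_weight,
                 occupancy_probs = occupancy_probs[req],
                 abundance_slope = abundance_slope,
                 abundance_dispersion = abundance_dispersion,
                 focal_trait = focal_trait, seed = as.integer(seed)),
            class = "simulation_config")
}

# scales on which the nine latent traits are mapped to realistic values;
# positive traits are log-normal around a field-plausible baseline,
# germination rate is a logistic map to (0, 100)
trait_transforms <- list(
  leaf_N = function(z) 20 * exp(0.3 * z),
  leaf_C = function(z) 450 * exp(0.1 * z),
  leaf_CN = function(z) 22 * exp(0.3 * z),
  leaf_thickness = function(z) 0.03 * exp(0.3 * z),
  leaf_area = function(z) 25 * exp(0.6 * z),
  SLA = function(z) 15000 * exp(0.4 * z),
  germination_rate = function(z) 100 * stats::plogis(0.8 * z + 0.5),
  seed_mass = function(z) 50 * exp(1.0 * z),
  max_height = function(z) 8 * exp(0.5 * z)
)

#' Simulate a nine-trait table on a phylogeny
#'
#' Each trait is an independent latent variable from [simulate_bm_traits()]
#' (standardized to unit marginal scale) mapped onto a realistic positive
#' scale; the germination rate is mapped through a logistic to (0, 100).
#' Growth habit is an independent fair coin per species.
#'
#' @inheritParams simulate_bm_traits
#' @return data frame with columns `species`, `habit` and the nine traits
#'   `leaf_N`, `leaf_C`, `leaf_CN`, `leaf_thickness`, `leaf_area`, `SLA`,
#'   `germination_rate`, `seed_mass`, `max_height`.
#' @export
simulate_trait_table <- function(tree, sigma2 = 1, signal_weight = 1,
                                 seed = 1L) {
  tree <- validate_phylogeny(tree)
  n <- length(tree$tip.label)
  V <- phylo_vcv(sanitize_branch_lengths(tree))
  scale_z <- sqrt(mean(diag(V)) * sigma2)
  lat <- simulate_bm_traits(tree, sigma2 = sigma2,
                            signal_weight = signal_weight,
                            seed = derive_seed(seed, "traits"),
                            n_rep = length(trait_transforms))
  habit <- with_seed(derive_seed(seed, "habit"), {
    sample(c("tree", "shrub"), n, replace = TRUE)
  })
  out <- data.frame(species = tree$tip.label, habit = habit,
                    stringsAsFactors = FALSE)
  for (k in seq_along(trait_transforms)) {
    out[[names(trait_transforms)[k]]] <-
      trait_transforms[[k]](lat[, k] / scale_z)
  }
  out
}

#' Simulate patches, occupancy and abundance
#'
#' Draws 9 patches with impervious-surface percentages landing 3 per
#' urbanization level; each species is present in each patch with the
#' per-level probability from `config` (re-drawn until the species occurs
#' somewhere); counts in occupied patches are `1 + NB(mu, size)` with
#' `log(mu) = intercept + abundance_slope * z(focal trait) + g`, where `g`
#' is a Brownian random effect on the tree (log-scale SD 0.5 at the mean
#' tip depth) and `size = abundance_dispersion`.
#'
#' @param tree a `phylo` object.
#' @param trait named numeric vector: the focal trait per species.
#' @param config a [simulation_config()].
#' @return list with data frames `patches` (`patch_id`, `impervious_pct`),
#'   `occupancy` (`species`, `patch_id`, `count`) and `abundance`
#'   (`species`, `total_count`).
#' @export
simulate_community <- function(tree, trait, config) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- validate_phylogeny(tree)
  sp <- tree$tip.label
  if (!all(sp %in% names(trait))) stop("trait must cover all tree tips")
  trait <- trait[sp]
  V <- phylo_vcv(sanitize_branch_lengths(tree))
  g <- simulate_bm_traits(tree, sigma2 = 0.25 / mean(diag(V)),
                          seed = derive_seed(config$seed, "raneff"))
  with_seed(derive_seed(config$seed, "community"), {
    levels3 <- c("low", "moderate", "high")
    imperv <- c(stats::runif(3, 5, 18), stats::runif(3, 22, 48),
                stats::runif(3, 55, 90))
    patches <- data.frame(patch_id = paste0("P", 1:9),
                          impervious_pct = imperv,
                          stringsAsFactors = FALSE)
    patch_level <- rep(levels3, each = 3)
    p_patch <- config$occupancy_probs[patch_level]
    pres <- matrix(FALSE, length(sp), 9,
                   dimnames = list(sp, patches$patch_id))
    for (i in seq_along(sp)) {
      repeat {
        row <- stats::runif(9) < p_patch
        if (any(row)) break
      }
      pres[i, ] <- row
    }
    z <- as.numeric(scale(trait))
    eta <- log(5) + config$abundance_slope * z + g
    occ <- list()
    for (i in seq_along(sp)) {
      js <- which(pres[i, ])
      counts <- 1L + stats::rnbinom(length(js), mu = exp(eta[i]),
                                    size = config$abundance_dispersion)
      occ[[i]] <- data.frame(species = sp[i],
                             patch_id = patches$patch_id[js],
                             count = counts, stringsAsFactors = FALSE)
    }
    occupancy <- do.call(rbind, occ)
    abundance <- stats::aggregate(count ~ species, occupancy, sum)
    names(abundance)[2] <- "total_count"
    list(patches = patches, occupancy = occupancy, abundance = abundance)
  })
}

#' Simulate a regression dataset with Brownian residuals
#'
#' Generates `y = beta0 + beta1 x + e` with `e` multivariate normal with
#' covariance `sigma2 * V` -- exactly the PGLS generating model. Used for
#' parameter-recovery and null-calibration checks.
#'
#' @param tree a `phylo` object.
#' @param beta0,beta1 intercept and slope.
#' @param sigma2 residual Brownian rate.
#' @param seed integer seed.
#' @param x optional predictor; defaults to a unit-rate Brownian trait.
#' @return list with named vectors `x`, `y`.
#' @export
simulate_pgls_data <- function(tree, beta0 = 0, beta1 = 0, sigma2 = 1,
                               seed = 1L, x = NULL) {
  tree <- validate_phylogeny(tree)
  if (is.null(x)) {
    x <- simulate_bm_traits(tree, sigma2 = 1, seed = derive_seed(seed, "x"))
  }
  e <- simulate_bm_traits(tree, sigma2 = sigma2,
                          seed = derive_seed(seed, "resid"))
  y <- beta0 + beta1 * x[tree$tip.label] + e
  list(x = x[tree$tip.label], y = y)
}

#' Simulate a complete study dataset
#'
#' Runs the full generator: a pure-birth tree, the nine-trait table and the
#' patch/occupancy/abundance tables, all from one [simulation_config()].
#'
#' @param config a [simulation_config()].
#' @return list with `tree`, `traits`, `patches`, `occupancy`, `abundance`,
#'   `config`.
#' @export
simulate_study <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- simulate_yule_tree(config$n_species, config$birth_rate,
                             seed = derive_seed(config$seed, "tree"))
  traits <- simulate_trait_table(tree, sigma2 = config$sigma2_bm,
                                 signal_weight = config$signal_weight,
                                 seed = config$seed)
  focal <- stats::setNames(traits[[config$focal_trait]], traits$species)
  comm <- simulate_community(tree, focal, config)
  c(list(tree = tree, traits = traits), comm, list(config = config))
}

#' Write a simulated study to disk
#'
#' Emits the same files the pipeline reads: `tree.nwk`, `traits.csv`,
#' `patches.csv`, `occupancy.csv`.
#'
#' @param study result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             traits = file.path(dir, "traits.csv"),
             patches = file.path(dir, "patches.csv"),
             occupancy = file.path(dir, "occupancy.csv"))
  write_phylogeny(study$tree, paths["tree"])
  utils::write.csv(study$traits, paths["traits"], row.names = FALSE)
  utils::write.csv(study$patches, paths["patches"], row.names = FALSE)
  utils::write.csv(study$occupancy, paths["occupancy"], row.names = FALSE)
  invisible(paths)
}
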