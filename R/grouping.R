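# Urbanization strata and species occupancy groups.

#' Classify impervious-surface cover into urbanization levels
#'
#' Low urbanization is < 20% impervious surface within the patch buffer,
#' moderate is 20-50% (both endpoints included), high is > 50%.
#'
#' @param impervious_pct numeric vector of impervious-surface percentages in
#'   \[0, 100\].
#' @return ordered factor with levels `low < moderate < high`.
#' @export
classify_urbanization <- function(impervious_pct) {
  if (anyNA(impervious_pct) || any(impervious_pct < 0 | impervious_pct > 100)) {
    stop("impervious_pct must be in [0, 100] with no NA")
  }
  lev <- ifelse(impervious_pct < 20, "low",
                ifelse(impervious_pct <= 50, "moderate", "high"))
  factor(lev, levels = c("low", "moderate", "high"), ordered = TRUE)
}

#' Assign species to urban/rural/general/middle occupancy groups
#'
#' With H, M, L the sets of species present in at least one patch under
#' high, moderate and low urbanization respectively:
#' urban = H \ L (present under high, absent under low, regardless of
#' moderate), rural = L \ H, general = H intersect L, middle = species found
#' only under moderate urbanization. The four groups always partition the
#' recorded species.
#'
#' @param occupancy data frame with columns `species`, `patch_id` and either
#'   `count` (> 0 means present) or logical `present`.
#' @param patches data frame with columns `patch_id`, `impervious_pct`.
#' @return data frame with columns `species`, `group` (factor with levels
#'   urban, rural, general, middle).
#' @export
assign_species_groups <- function(occupancy, patches) {
  occupancy$species <- normalize_taxon_names(occupancy$species)
  if (!"present" %in% names(occupancy)) {
    if (!"count" %in% names(occupancy)) {
      stop("occupancy needs a `count` or `present` column")
    }
    occupancy$present <- occupancy$count > 0
  }
  unknown <- setdiff(occupancy$patch_id, patches$patch_id)
  if (length(unknown)) {
    stop("occupancy references unknown patches: ",
         paste(unique(unknown), collapse = ", "))
  }
  level <- classify_urbanization(patches$impervious_pct)
  names(level) <- patches$patch_id
  occ <- occupancy[occupancy$present, , drop = FALSE]
  species <- sort(unique(occupancy$species))
  no_occ <- setdiff(species, occ$species)
  if (length(no_occ)) {
    stop("species with no occupancy: ", paste(no_occ, collapse = ", "))
  }
  occ$level <- level[as.character(occ$patch_id)]
  in_level <- function(lv) unique(occ$species[occ$level == lv])
  H <- in_level("high"); M <- in_level("moderate"); L <- in_level("low")
  grp <- stats::setNames(rep(NA_character_, length(species)), species)
  grp[setdiff(H, L)] <- "urban"
  grp[setdiff(L, H)] <- "rural"
  grp[intersect(H, L)] <- "general"
  grp[setdiff(M, union(H, L))] <- "middle"
  data.frame(species = species,
             group = factor(unname(grp[species]),
                            levels = c("urban", "rural", "general", "middle")),
             stringsAsFactors = FALSE)
}

#' Per-group trait summaries (mean, SE, 95% CI)
#'
#' Arithmetic mean over the species of each group x trait cell with
#' non-missing values; SE = sd / sqrt(n); 95% CI = mean +/- t(.975, n-1) SE.
#' Single-species cells report the value with SE and CI undefined; empty
#' cells are flagged, not an error.
#'
#' @param traits data frame with columns `species`, `habit` and numeric trait
#'   columns.
#' @param groups data frame from [assign_species_groups()].
#' @param habit optional habit filter (`"tree"` or `"shrub"`).
#' @param trait_names trait columns; defaults to all numeric columns.
#' @return data frame with `habit`, `group`, `trait`, `n`, `mean`, `se`,
#'   `ci_lo`, `ci_hi`, `status`.
#' @export
summarize_group_traits <- function(traits, groups, habit = NULL,
                                   trait_names = NULL) {
  traits$species <- normalize_taxon_names(traits$species)
  groups$species <- normalize_taxon_names(groups$species)
  if (is.null(trait_names)) {
    trait_names <- names(traits)[vapply(traits, is.numeric, logical(1))]
  }
  merged <- merge(traits, groups, by = "species")
  habits <- if (is.null(habit)) sort(unique(merged$habit)) else habit
  group_levels <- c("urban", "rural", "general", "middle")
  out <- list()
  for (h in habits) {
    for (grp in group_levels) {
      sub <- merged[merged$habit == h & merged$group == grp, , drop = FALSE]
      for (tr in trait_names) {
        vals <- sub[[tr]]
        vals <- vals[!is.na(vals)]
        n <- length(vals)
        row <- data.frame(habit = h, group = grp, trait = tr, n = n,
                          mean = NA_real_, se = NA_real_,
                          ci_lo = NA_real_, ci_hi = NA_real_,
                          status = "ok", stringsAsFactors = FALSE)
        if (n == 0L) {
          row$status <- "empty"
        } else if (n == 1L) {
          row$mean <- vals
          row$status <- "se_undefined"
        } else {
          m <- mean(vals)
          se <- stats::sd(vals) / sqrt(n)
          tq <- stats::qt(0.975, df = n - 1)
          row$mean <- m; row$se <- se
          row$ci_lo <- m - tq * se; row$ci_hi <- m + tq * se
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  do.call(rbind, out)
}
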