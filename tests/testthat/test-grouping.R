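nine_patches <- data.frame(
  patch_id = paste0("P", 1:9),
  impervious_pct = c(5, 10, 15, 25, 35, 45, 60, 75, 90))
# P1-P3 low, P4-P6 moderate, P7-P9 high

occ_at <- function(species, patch_ids) {
  data.frame(species = species, patch_id = patch_ids, count = 1L)
}

test_that("impervious-surface thresholds classify urbanization levels", {
  expect_equal(as.character(classify_urbanization(c(10, 35, 72))),
               c("low", "moderate", "high"))
  # boundary convention: both 20 and 50 fall in the moderate band
  expect_equal(as.character(classify_urbanization(c(20, 50))),
               c("moderate", "moderate"))
  expect_equal(as.character(classify_urbanization(c(0, 19.999, 50.001, 100))),
               c("low", "low", "high", "high"))
  expect_error(classify_urbanization(-1), "0, 100")
  expect_error(classify_urbanization(101), "0, 100")
})

test_that("classification is monotone in impervious cover", {
  lv <- classify_urbanization(sort(runif(50, 0, 100)))
  expect_true(all(diff(as.integer(lv)) >= 0))
})

test_that("the six worked occupancy cases assign the documented groups", {
  cases <- list(
    list(patches = "P7", group = "urban"),            # high only
    list(patches = c("P7", "P4"), group = "urban"),   # high + moderate
    list(patches = "P4", group = "middle"),           # moderate only
    list(patches = c("P4", "P1"), group = "rural"),   # moderate + low
    list(patches = c("P7", "P1"), group = "general"), # high + low
    list(patches = c("P7", "P4", "P1"), group = "general"))  # all three
  for (cs in cases) {
    occ <- occ_at("sp1", cs$patches)
    g <- assign_species_groups(occ, nine_patches)
    expect_equal(as.character(g$group), cs$group, label = cs$group)
  }
  # low only -> rural
  g <- assign_species_groups(occ_at("sp1", "P2"), nine_patches)
  expect_equal(as.character(g$group), "rural")
})

test_that("groups always partition the species set (random occupancy)", {
  set.seed(99)
  for (rep in 1:50) {
    sim <- random_occupancy(sample(20:200, 1), p = runif(1, 0.1, 0.6))
    g <- assign_species_groups(sim$occupancy, sim$patches)
    expect_setequal(g$species, unique(sim$occupancy$species))
    expect_false(anyNA(g$group))
    expect_equal(anyDuplicated(g$species), 0L)
    # independent set-based oracle
    orc <- group_oracle(sim$occupancy, sim$patches)
    expect_equal(setNames(as.character(g$group), g$species),
                 orc[g$species])
  }
})

test_that("assignment depends only on the species x level pattern", {
  set.seed(7)
  sim <- random_occupancy(80, p = 0.3)
  g1 <- assign_species_groups(sim$occupancy, sim$patches)
  # permute patch ids within each urbanization level
  perm <- c(sample(paste0("P", 1:3)), sample(paste0("P", 4:6)),
            sample(paste0("P", 7:9)))
  names(perm) <- paste0("P", 1:9)
  occ2 <- sim$occupancy
  occ2$patch_id <- perm[occ2$patch_id]
  g2 <- assign_species_groups(occ2, sim$patches)
  expect_equal(g1, g2)
})

test_that("species without occupancy and unknown patches are errors", {
  occ <- rbind(occ_at("sp1", "P1"),
               data.frame(species = "sp2", patch_id = "P1", count = 0L))
  expect_error(assign_species_groups(occ, nine_patches),
               "no occupancy.*sp2")
  expect_error(assign_species_groups(occ_at("sp1", "P99"), nine_patches),
               "unknown patches")
})

test_that("trait summaries match hand values and the t-interval oracle", {
  traits <- data.frame(species = c("a", "b", "c"), habit = "tree",
                       h = c(1, 2, 3))
  groups <- data.frame(species = c("a", "b", "c"),
                       group = factor("urban",
                                      levels = c("urban", "rural",
                                                 "general", "middle")))
  s <- summarize_group_traits(traits, groups)
  cell <- s[s$group == "urban" & s$trait == "h", ]
  expect_equal(cell$mean, 2)
  expect_equal(cell$se, 1 / sqrt(3), tolerance = 1e-12)

  set.seed(12)
  vals <- rnorm(30, 10, 2)
  traits30 <- data.frame(species = sprintf("s%02d", 1:30), habit = "shrub",
                         h = vals)
  groups30 <- data.frame(species = sprintf("s%02d", 1:30),
                         group = factor("general",
                                        levels = c("urban", "rural",
                                                   "general", "middle")))
  s30 <- summarize_group_traits(traits30, groups30)
  cell <- s30[s30$group == "general" & s30$trait == "h", ]
  ci <- t.test(vals)$conf.int  # independent t-interval oracle
  expect_equal(c(cell$ci_lo, cell$ci_hi), as.numeric(ci), tolerance = 1e-10)
})

test_that("single-species and empty summary cells are flagged, not errors", {
  traits <- data.frame(species = "a", habit = "tree", h = 4.2)
  groups <- data.frame(species = "a",
                       group = factor("middle",
                                      levels = c("urban", "rural",
                                                 "general", "middle")))
  s <- summarize_group_traits(traits, groups)
  one <- s[s$group == "middle", ]
  expect_equal(one$mean, 4.2)
  expect_identical(one$status, "se_undefined")
  expect_true(is.na(one$se))
  empty <- s[s$group == "urban", ]
  expect_identical(empty$status, "empty")
})

test_that("missing trait values are dropped per trait, not per species", {
  traits <- data.frame(species = c("a", "b", "c", "d"), habit = "tree",
                       h1 = c(1, 2, NA, 4), h2 = c(1, 2, 3, 4))
  groups <- data.frame(species = c("a", "b", "c", "d"),
                       group = factor("urban",
                                      levels = c("urban", "rural",
                                                 "general", "middle")))
  s <- summarize_group_traits(traits, groups)
  expect_equal(s$n[s$trait == "h1" & s$group == "urban"], 3L)
  expect_equal(s$n[s$trait == "h2" & s$group == "urban"], 4L)
})
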