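# Orchestration: read inputs, reconcile names, run grouping -> signal ->
# models -> summaries, and serialize report tables shaped like the study's
# published tables (trait rows, group columns, GLS/PGLS row pairs).

#' Analysis configuration
#'
#' @param tree,traits,patches,occupancy input file paths (newick tree;
#'   CSVs: traits with `species`, `habit` + trait columns; patches with
#'   `patch_id`, `impervious_pct`; occupancy with `species`, `patch_id`,
#'   `count`).
#' @param out_dir output directory, or `NULL` to skip writing.
#' @param n_perm permutations for the signal test (>= 99, default 999).
#' @param alpha_signal significance level for phylogenetic signal flags
#'   (default .05).
#' @param alpha_model significance level for GLS/PGLS slope flags
#'   (default .01).
#' @param response regression response, `"abundance"` (default) or
#'   `"trait"`.
#' @param abundance_aggregation `"total"` (default: individuals summed over
#'   all patches) or `"patch_mean"` (mean count over occupied patches).
#' @param log10_abundance log10-transform abundance (default FALSE).
#' @param statistic permutation statistic, `"mse"` (default) or `"k"`.
#' @param min_n_signal,min_n_model minimum species per cell (4 and 5).
#' @param on_mismatch `"error"` (default) or `"drop"` unmatched species
#'   names.
#' @param seed root seed.
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(tree, traits, patches, occupancy,
                            out_dir = NULL, n_perm = 999L,
                            alpha_signal = 0.05, alpha_model = 0.01,
                            response = "abundance",
                            abundance_aggregation = "total",
                            log10_abundance = FALSE,
                            statistic = "mse", min_n_signal = 4L,
                            min_n_model = 5L, on_mismatch = "error",
                            seed = 1L) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 99L) stop("n_perm must be >= 99")
  if (alpha_signal <= 0 || alpha_signal >= 1 ||
      alpha_model <= 0 || alpha_model >= 1) {
    stop("alpha levels must be in (0, 1)")
  }
  structure(list(tree = tree, traits = traits, patches = patches,
                 occupancy = occupancy, out_dir = out_dir, n_perm = n_perm,
                 alpha_signal = alpha_signal, alpha_model = alpha_model,
                 response = match.arg(response, c("abundance", "trait")),
                 abundance_aggregation = match.arg(
                   abundance_aggregation, c("total", "patch_mean")),
                 log10_abundance = isTRUE(log10_abundance),
                 statistic = match.arg(statistic, c("mse", "k")),
                 min_n_signal = as.integer(min_n_signal),
                 min_n_model = as.integer(min_n_model),
                 on_mismatch = match.arg(on_mismatch, c("error", "drop")),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Recognized keys are the arguments of [analysis_config()]; relative input
#' paths are resolved against the directory of the config file.
#'
#' @param path YAML file.
#' @return an `analysis_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(analysis_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  base <- dirname(normalizePath(path))
  for (key in c("tree", "traits", "patches", "occupancy")) {
    if (!is.null(vals[[key]]) && !grepl("^(/|[A-Za-z]:)", vals[[key]])) {
      vals[[key]] <- file.path(base, vals[[key]])
    }
  }
  do.call(analysis_config, vals)
}

read_table_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " file ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  df
}

#' Run the full analysis
#'
#' Reads and cross-validates the inputs, assigns urbanization levels and
#' species groups, computes the per-habit phylogenetic-signal table
#' (Blomberg's K + permutation p), the GLS/PGLS trait-abundance table, the
#' per-group trait summaries, and the tally of significant PGLS
#' relationships per habit. When `config$out_dir` is set, report tables are
#' written there (see Details). The run is deterministic for a fixed config.
#'
#' @details Output files: `signal_<habit>.tsv` (trait rows, K/p column pair
#' per group), `models_<habit>.tsv` (trait rows, GLS/PGLS row pairs, t/p per
#' group), `trait_summary.tsv` (group means, SE, 95% CI), `groups.csv`
#' (species group assignment), `tally.tsv` (significant PGLS and GLS counts
#' per habit) and `run.log`.
#'
#' @param config an [analysis_config()].
#' @return (invisibly) a list of class `urbanphylo_analysis` with elements
#'   `groups`, `signal`, `models`, `summary`, `tally`, `config`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  log_msg <- character()
  say <- function(...) {
    m <- paste0(...)
    message(m)
    log_msg <<- c(log_msg, m)
  }
  say("reading tree: ", config$tree)
  tree <- sanitize_branch_lengths(read_phylogeny(config$tree))
  traits <- read_table_checked(config$traits, c("species", "habit"), "traits")
  patches <- read_table_checked(config$patches,
                                c("patch_id", "impervious_pct"), "patches")
  occupancy <- read_table_checked(config$occupancy,
                                  c("species", "patch_id", "count"),
                                  "occupancy")
  traits$species <- normalize_taxon_names(traits$species)
  occupancy$species <- normalize_taxon_names(occupancy$species)

  table_species <- union(traits$species, occupancy$species)
  keep_sp <- reconcile_taxa(tree$tip.label, table_species,
                            on_mismatch = config$on_mismatch)
  if (config$on_mismatch == "drop") {
    traits <- traits[traits$species %in% keep_sp, , drop = FALSE]
    occupancy <- occupancy[occupancy$species %in% keep_sp, , drop = FALSE]
    if (length(keep_sp) < 2L) stop("fewer than 2 species left after dropping")
    tree <- prune_to_taxa(tree, keep_sp)
  }
  say(length(keep_sp), " species reconciled across tree and tables")

  say("assigning urbanization levels and species groups")
  groups <- assign_species_groups(occupancy, patches)
  agg_fun <- if (config$abundance_aggregation == "patch_mean") mean else sum
  abundance <- stats::aggregate(count ~ species, occupancy, agg_fun)
  names(abundance)[2] <- "total_count"

  say("testing phylogenetic signal (n_perm = ", config$n_perm, ")")
  sig <- signal_table(tree, traits, groups, n_perm = config$n_perm,
                      seed = config$seed, alpha = config$alpha_signal,
                      statistic = config$statistic,
                      min_n = config$min_n_signal)
  say("fitting GLS and PGLS trait-abundance models")
  mod <- model_table(tree, traits, groups, abundance,
                     alpha = config$alpha_model, response = config$response,
                     log10_abundance = config$log10_abundance,
                     min_n = config$min_n_model)
  summ <- summarize_group_traits(traits, groups)

  pgls <- mod[mod$model == "PGLS", , drop = FALSE]
  gls <- mod[mod$model == "GLS", , drop = FALSE]
  habits <- sort(unique(mod$habit))
  tally <- data.frame(
    habit = habits,
    n_significant_pgls = vapply(habits, function(h) {
      sum(pgls$model_flag[pgls$habit == h], na.rm = TRUE)
    }, integer(1)),
    n_significant_gls = vapply(habits, function(h) {
      sum(gls$model_flag[gls$habit == h], na.rm = TRUE)
    }, integer(1)),
    stringsAsFactors = FALSE)
  for (h in habits) {
    say(h, ": ", tally$n_significant_pgls[tally$habit == h],
        " significant PGLS relationship(s) at alpha = ", config$alpha_model)
  }

  result <- structure(list(groups = groups, signal = sig, models = mod,
                           summary = summ, tally = tally, config = config),
                      class = "urbanphylo_analysis")
  if (!is.null(config$out_dir)) {
    write_report(result, config$out_dir, log_msg)
    say("report written to ", config$out_dir)
  }
  invisible(result)
}

fmt3 <- function(x) ifelse(is.na(x), "NA", sprintf("%.3f", x))

# wide table: one trait row, a K/p (or t/p) column pair per group
widen <- function(df, stat_col) {
  groups <- c("urban", "rural", "general", "middle")
  traits <- unique(df$trait)
  has_model <- "model" %in% names(df)
  rows <- list()
  combos <- if (has_model) {
    expand.grid(trait = traits, model = c("GLS", "PGLS"),
                stringsAsFactors = FALSE)
  } else {
    data.frame(trait = traits, stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(combos))) {
    sel <- df$trait == combos$trait[i]
    if (has_model) sel <- sel & df$model == combos$model[i]
    row <- combos[i, , drop = FALSE]
    for (g in groups) {
      cell <- df[sel & df$group == g, , drop = FALSE]
      stat <- if (nrow(cell)) cell[[stat_col]][1] else NA_real_
      p <- if (nrow(cell)) cell$p_value[1] else NA_real_
      status <- if (nrow(cell)) cell$status[1] else "missing"
      row[[paste0(g, "_", stat_col)]] <-
        if (identical(status, "ok")) fmt3(stat) else status
      row[[paste0(g, "_p")]] <-
        if (identical(status, "ok")) fmt3(p) else ""
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

write_report <- function(result, out_dir, log_msg = character()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, file) {
    utils::write.table(df, file.path(out_dir, file), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  for (h in unique(result$signal$habit)) {
    tsv(widen(result$signal[result$signal$habit == h, ], "K"),
        paste0("signal_", h, ".tsv"))
    tsv(widen(result$models[result$models$habit == h, ], "t"),
        paste0("models_", h, ".tsv"))
  }
  tsv(result$summary, "trait_summary.tsv")
  utils::write.csv(result$groups, file.path(out_dir, "groups.csv"),
                   row.names = FALSE)
  tsv(result$tally, "tally.tsv")
  writeLines(log_msg, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.urbanphylo_analysis <- function(x, ...) {
  cat("urbanphylo analysis\n")
  cat("  species:", nrow(x$groups), "| groups:",
      paste(sprintf("%s=%d", levels(x$groups$group),
                    tabulate(x$groups$group, 4)), collapse = " "), "\n")
  cat("  signal cells:", nrow(x$signal), "| significant (p <",
      x$config$alpha_signal, "):", sum(x$signal$signal_flag), "\n")
  for (i in seq_len(nrow(x$tally))) {
    cat("  ", x$tally$habit[i], ": ", x$tally$n_significant_pgls[i],
        " significant PGLS, ", x$tally$n_significant_gls[i],
        " significant GLS (p < ", x$config$alpha_model, ")\n", sep = "")
  }
  invisible(x)
}
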