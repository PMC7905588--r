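#' Study configuration
#'
#' Bundles every tunable of the end-to-end analysis.  Defaults reproduce the
#' fixed study recipe: synthetic cohort of 742 / 361 / 1529 subjects, core
#' size 10, sub-health symptom associations kept above normalized weight 0.5,
#' disease-group associations reported as top-10 pairs, Tukey inner fence 1.5
#' for tongue/pulse outlier exclusion, and per-group planted tongue-pulse
#' canonical correlations (0.475 healthy, 0.05 sub-health, 0.42 disease)
#' matching the pattern of a strong healthy association, no sub-health
#' association, and a moderate disease association.
#'
#' @param seed master seed; every stage's randomness derives from it.
#' @param out_dir output directory for artifacts (created if missing).
#' @param n_healthy,n_subhealth,n_disease synthetic group sizes.
#' @param cohort_csv optional path to an existing cohort CSV (schema of
#'   [write_cohort()]); when given, the generator is skipped.
#' @param core_k core set size.
#' @param assoc_threshold normalized-weight threshold for the sub-health
#'   symptom association table.
#' @param assoc_top_k top-k for the disease-group association tables.
#' @param rho per-group planted tongue-pulse canonical correlation (named
#'   vector healthy/subhealth/disease).
#' @param fence_inner Tukey fence for outlier exclusion (may be `Inf`).
#' @param cohesion a [cohesion_params()] object.
#' @return list of class `study_config`.
#' @export
study_config <- function(seed = 1L, out_dir = tempfile("fatiguenet_run_"),
                         n_healthy = 742L, n_subhealth = 361L,
                         n_disease = 1529L, cohort_csv = NULL,
                         core_k = 10L, assoc_threshold = 0.5,
                         assoc_top_k = 10L,
                         rho = c(healthy = 0.475, subhealth = 0.05,
                                 disease = 0.42),
                         fence_inner = 1.5,
                         cohesion = cohesion_params()) {
  stopifnot(core_k >= 1, assoc_top_k >= 1,
            assoc_threshold >= 0, assoc_threshold < 1)
  if (!is.null(cohort_csv) && !file.exists(cohort_csv)) {
    stop("cohort_csv does not exist: ", cohort_csv)
  }
  stopifnot(all(c("healthy", "subhealth", "disease") %in% names(rho)))
  structure(list(seed = as.integer(seed), out_dir = out_dir,
                 n_healthy = as.integer(n_healthy),
                 n_subhealth = as.integer(n_subhealth),
                 n_disease = as.integer(n_disease),
                 cohort_csv = cohort_csv,
                 core_k = as.integer(core_k),
                 assoc_threshold = assoc_threshold,
                 assoc_top_k = as.integer(assoc_top_k),
                 rho = rho, fence_inner = fence_inner,
                 cohesion = cohesion),
            class = "study_config")
}

#' Load a study configuration from a YAML file
#'
#' Keys mirror the arguments of [study_config()]; missing keys fall back to
#' the defaults, so an empty file reproduces the standard recipe.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file.
#' @return a `study_config`.
#' @export
load_study_config <- function(path, ...) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  dots <- list(...)
  raw[names(dots)] <- dots
  if (!is.null(raw$rho)) raw$rho <- unlist(raw$rho)
  allowed <- names(formals(study_config))
  bad <- setdiff(names(raw), allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(study_config, raw)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

fmt3 <- function(x) formatC(x, digits = 3, format = "f")

#' Run the full study pipeline
#'
#' Executes the complete analysis flow: generate (or load) the cohort, assign
#' study groups, build per-group symptom co-occurrence networks (plus index
#' and combined symptom-index networks for the disease group), rank nodes by
#' IMC, extract and export core subnetworks (Pajek), produce association
#' tables, and run the tongue-pulse canonical correlation analysis per group
#' after Tukey-fence outlier exclusion.  All artifacts are written under
#' `config$out_dir` together with a `manifest.yaml` listing the seed,
#' parameters, and an md5 checksum for every file; a rerun with the same seed
#' produces a byte-identical manifest.
#'
#' @param config a [study_config()].
#' @return (invisibly) a list of class `study_report`: `groups` (per-group
#'   importance tables, association tables, core networks, CCA summaries),
#'   `counts`, `manifest_path`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  add_file <- function(path) files[[length(files) + 1L]] <<- path

  # --- cohort -----------------------------------------------------------
  if (!is.null(config$cohort_csv)) {
    cohort <- read_cohort(config$cohort_csv)
  } else {
    spec <- cohort_spec(n_healthy = config$n_healthy,
                        n_subhealth = config$n_subhealth,
                        n_disease = config$n_disease,
                        seed = config$seed)
    cohort <- gen_binary_cohort(spec)
  }
  cohort_path <- file.path(config$out_dir, "cohort.csv")
  write_cohort(cohort, cohort_path)
  add_file(cohort_path)

  # groups re-derived through the grouping rule (not trusted from the file);
  # "positive indexes" here means a clinician-confirmed diagnosis, so sporadic
  # isolated index abnormalities do not unclassify healthy subjects
  lab <- assign_group(cohort$subjects$h20, cohort$subjects$fatigue,
                      cohort$subjects$disease,
                      positive_index = cohort$subjects$disease)
  group_of <- c(healthy = "healthy", subhealth_fatigue = "subhealth",
                disease_fatigue = "disease")[as.character(lab)]

  groups <- c("healthy", "subhealth", "disease")
  counts <- stats::setNames(vapply(groups, function(g)
    sum(group_of %in% g), numeric(1L)), groups)
  report <- list(groups = list(), counts = counts)

  for (gi in seq_along(groups)) {
    g <- groups[gi]
    gres <- list()
    sel <- which(group_of %in% g)
    if (length(sel) == 0L) {
      warning(sprintf("group '%s' has no subjects; stages skipped", g))
      report$groups[[g]] <- gres
      next
    }
    gdir <- file.path(config$out_dir, g)
    dir.create(gdir, showWarnings = FALSE)
    mat <- cohort$mat[sel, , drop = FALSE]

    # --- symptom network + IMC core -----------------------------------
    if (g %in% c("subhealth", "disease")) {
      net_s <- build_network(mat, features = cohort$features,
                             blocks = "symptom")
      rc_s <- rank_core(net_s, config$cohesion, k = config$core_k)
      core_s <- extract_core_subnetwork(net_s, rc_s$core)
      imp <- rc_s$table
      imp$imc <- fmt3(imp$imc)
      add_file(write_tsv(imp, file.path(gdir, "symptom_importance.tsv")))
      add_file(write_pajek(core_s, file.path(gdir, "symptom_core.net")))

      if (g == "subhealth") {
        # sub-health: associations within the core symptom network,
        # normalized by its own maximum, thresholded
        assoc_out <- filter_associations(normalize_weights(core_s),
                                         "threshold",
                                         config$assoc_threshold)
        tabw <- assoc_out
        tabw$normalized_weight <- fmt3(tabw$normalized_weight)
        add_file(write_tsv(tabw, file.path(gdir, "symptom_assoc.tsv")))
        gres$symptom_assoc <- assoc_out
      }
      gres$symptom_importance <- rc_s$table
      gres$symptom_core <- rc_s$core
      gres$symptom_network <- net_s
    }

    # --- index + combined networks (disease group) --------------------
    if (g == "disease") {
      net_i <- build_network(mat, features = cohort$features,
                             blocks = "index")
      rc_i <- rank_core(net_i, config$cohesion, k = config$core_k)
      core_i <- extract_core_subnetwork(net_i, rc_i$core)
      imp_i <- rc_i$table
      imp_i$imc <- fmt3(imp_i$imc)
      add_file(write_tsv(imp_i, file.path(gdir, "index_importance.tsv")))
      add_file(write_pajek(core_i, file.path(gdir, "index_core.net")))

      net_all <- build_network(mat, features = cohort$features)
      comb <- extract_core_subnetwork(net_all, gres$symptom_core, rc_i$core)
      add_file(write_pajek(comb, file.path(gdir, "combined_core.net")))

      # one normalization maximum for the whole combined core network, then
      # top-k tables split by pair type (symptom-symptom / index-index /
      # symptom-index)
      assoc_all <- normalize_weights(comb)
      both <- function(tab, block) tab[tab$block_a == block &
                                         tab$block_b == block, , drop = FALSE]
      assoc_ss <- filter_associations(both(assoc_all, "symptom"),
                                      "top_k", config$assoc_top_k)
      assoc_ii <- filter_associations(both(assoc_all, "index"),
                                      "top_k", config$assoc_top_k)
      assoc_si <- filter_associations(assoc_all, "top_k",
                                      config$assoc_top_k,
                                      pair_type = "cross")
      outs <- list(symptom_assoc.tsv = assoc_ss, index_assoc.tsv = assoc_ii,
                   symptom_index_assoc.tsv = assoc_si)
      for (nm in names(outs)) {
        tabw <- outs[[nm]]
        tabw$normalized_weight <- fmt3(tabw$normalized_weight)
        add_file(write_tsv(tabw, file.path(gdir, nm)))
      }
      gres$index_importance <- rc_i$table
      gres$index_core <- rc_i$core
      gres$combined_network <- comb
      gres$symptom_assoc <- assoc_ss
      gres$index_assoc <- assoc_ii
      gres$symptom_index_assoc <- assoc_si
    }

    # --- tongue-pulse CCA ---------------------------------------------
    tp_spec <- tongue_pulse_spec(n_subjects = length(sel),
                                 rho = unname(config$rho[[g]]),
                                 seed = config$seed + 1000L + gi)
    tp <- gen_tongue_pulse(tp_spec)
    tp$id <- cohort$subjects$id[sel]
    add_file(write_tongue_pulse(tp, file.path(gdir, "tongue_pulse.csv")))

    excl <- exclude_outlier_subjects(tp, fence_inner = config$fence_inner)
    add_file(write_tsv(excl$log, file.path(gdir, "exclusions.tsv")))

    blocks <- tongue_pulse_blocks(excl$table)
    if (nrow(blocks$tongue) > ncol(blocks$tongue) + ncol(blocks$pulse)) {
      fit <- fit_cca(blocks$tongue, blocks$pulse)
      loads <- structure_loadings(fit)
      loads$loading <- fmt3(loads$loading)
      add_file(write_tsv(loads, file.path(gdir, "cca_loadings.tsv")))
      summ <- data.frame(group = g,
                         n_total = length(sel),
                         n_excluded = excl$n_dropped,
                         n_analyzed = nrow(blocks$tongue),
                         first_canonical_correlation = fmt3(fit$cor[1L]),
                         p_value = format(fit$p_value[1L], digits = 4))
      add_file(write_tsv(summ, file.path(gdir, "cca_summary.tsv")))
      gres$cca <- fit
      gres$cca_n <- nrow(blocks$tongue)
      gres$n_excluded <- excl$n_dropped
    } else {
      warning(sprintf("group '%s': too few subjects after exclusion for CCA", g))
    }
    report$groups[[g]] <- gres
  }

  # --- manifest ---------------------------------------------------------
  files <- unlist(files)
  prefix <- paste0(sub("/+$", "", config$out_dir), "/")
  rel <- ifelse(startsWith(files, prefix),
                substring(files, nchar(prefix) + 1L), files)
  sums <- tools::md5sum(files)
  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("fatiguenet")),
    parameters = list(core_k = config$core_k,
                      assoc_threshold = config$assoc_threshold,
                      assoc_top_k = config$assoc_top_k,
                      fence_inner = config$fence_inner,
                      rho = as.list(config$rho),
                      n_healthy = config$n_healthy,
                      n_subhealth = config$n_subhealth,
                      n_disease = config$n_disease),
    group_sizes = as.list(counts),
    files = stats::setNames(as.list(unname(sums)), rel))
  manifest_path <- file.path(config$out_dir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  report$manifest_path <- manifest_path
  class(report) <- "study_report"
  invisible(report)
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n  group sizes:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = ", "),
      "\n")
  for (g in names(x$groups)) {
    gr <- x$groups[[g]]
    if (!is.null(gr$cca)) {
      cat(sprintf("  %s: first canonical correlation %.3f (p = %.3g, n = %d)\n",
                  g, gr$cca$cor[1L], gr$cca$p_value[1L], gr$cca_n))
    }
  }
  invisible(x)
}

#' Baseline descriptive statistics (convenience)
#'
#' Per-group summary of continuous covariates (mean, SD) with a one-way
#' ANOVA p-value, and of 0/1 features (count, percent) — the routine
#' "Table 1"-style descriptives.  Provided as an untested convenience.
#'
#' @param cohort a `cohort` object.
#' @param vars continuous subject columns to summarize (default `"h20"`).
#' @return data.frame of group summaries.
#' @export
baseline_summary <- function(cohort, vars = "h20") {
  stopifnot(inherits(cohort, "cohort"))
  g <- cohort$subjects$group
  rows <- lapply(vars, function(v) {
    x <- cohort$subjects[[v]]
    p <- tryCatch(stats::anova(stats::lm(x ~ g))[["Pr(>F)"]][1L],
                  error = function(e) NA_real_)
    agg <- stats::aggregate(x, list(group = g),
                            function(z) sprintf("%.2f ± %.2f",
                                                mean(z), stats::sd(z)))
    data.frame(variable = v, group = agg$group, summary = agg$x,
               anova_p = p)
  })
  do.call(rbind, rows)
}
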