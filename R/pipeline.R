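# End-to-end orchestration: configuration, validation, the analysis
# sequence, and tidy CSV output with provenance headers.

#' Pipeline configuration
#'
#' @param measurements_csv Specimen-level measurement CSV (long layout);
#'   ignored when `species_csv` is given.
#' @param species_csv Species-level trait CSV (bypasses morphometrics).
#' @param tree Newick tree path.
#' @param out_dir Output directory.
#' @param do_allometry,do_components,do_limbs,do_rrpp Analysis toggles.
#' @param bootstrap_reps Bootstrap replicates (default 1000).
#' @param rrpp_iters RRPP iterations (default 1000).
#' @param isometric_slope Isometry reference slope (default 0; shape is a
#'   dimensionless ratio).
#' @param limb_mode `"full"`, `"reduced"`, or `"both"`.
#' @param aggregation Specimen aggregation rule (see
#'   [aggregate_species()]).
#' @param seed Integer seed for every stochastic step.
#' @param verbose Emit progress messages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(measurements_csv = NULL, species_csv = NULL,
                            tree, out_dir,
                            do_allometry = TRUE, do_components = TRUE,
                            do_limbs = TRUE, do_rrpp = TRUE,
                            bootstrap_reps = 1000, rrpp_iters = 1000,
                            isometric_slope = 0,
                            limb_mode = c("both", "full", "reduced"),
                            aggregation = "index_then_mean",
                            seed = 1L, verbose = TRUE) {
  limb_mode <- match.arg(limb_mode)
  stopifnot(bootstrap_reps >= 1, rrpp_iters >= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write a pipeline config to a flat key=value file
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  kv <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, "=", if (is.null(v)) "" else as.character(v))
  }, "")
  writeLines(kv, path)
  invisible(path)
}

#' Read a pipeline config from a flat key=value file
#' @param path Config file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- strsplit(ln, "=", fixed = TRUE)
  vals <- stats::setNames(lapply(kv, function(x)
    paste(x[-1], collapse = "=")), vapply(kv, `[`, "", 1))
  cast <- function(x) {
    if (!nzchar(x)) return(NULL)
    if (x %in% c("TRUE", "FALSE")) return(as.logical(x))
    num <- suppressWarnings(as.numeric(x))
    if (!is.na(num)) return(num)
    x
  }
  args <- lapply(vals, cast)
  do.call(pipeline_config, args[names(args) %in% names(formals(pipeline_config))])
}

.pversion <- function() {
  tryCatch(as.character(utils::packageVersion("squamorph")),
           error = function(e) "dev")
}

.provenance <- function(config, inputs) {
  sums <- vapply(inputs, function(p)
    if (!is.null(p) && file.exists(p)) unname(tools::md5sum(p)) else NA_character_, "")
  c(sprintf("squamorph %s | seed %d", .pversion(), as.integer(config$seed)),
    sprintf("input %s md5 %s", names(sums), sums))
}

# tidy one bootstrapped allometry model into rows
.allometry_rows <- function(model_name, fit, boot, isometric_slope) {
  if (!is.null(boot$group_slopes)) {
    gs <- boot$group_slopes
    do.call(rbind, lapply(names(gs$point), function(g) {
      cl <- classify_allometry(gs$point[[g]], gs$ci[g, ], isometric_slope)
      data.frame(model = model_name, group = g, estimate = gs$point[[g]],
                 boot_mean = gs$replicate_mean[[g]],
                 ci_lower = gs$ci[g, "lower"], ci_upper = gs$ci[g, "upper"],
                 lambda = fit$lambda, adj_R2 = fit$adj_R2, call = cl$call)
    }))
  } else {
    slope_name <- setdiff(names(fit$coefficients), "(Intercept)")[1]
    ci <- boot$ci[slope_name, ]
    cl <- classify_allometry(fit$coefficients[[slope_name]], ci, isometric_slope)
    data.frame(model = model_name, group = "all",
               estimate = fit$coefficients[[slope_name]],
               boot_mean = mean(boot$replicates[, slope_name]),
               ci_lower = ci[["lower"]], ci_upper = ci[["upper"]],
               lambda = fit$lambda, adj_R2 = fit$adj_R2, call = cl$call)
  }
}

.write_table <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full body-shape analysis pipeline
#'
#' Executes, in order: trait computation/aggregation (skipped when a
#' species CSV is supplied), tree pruning and covariance construction,
#' overall and per-ecotype body-shape allometry with bootstrap CIs and
#' allometry calls, component allometries (head ER, four regional AEIs,
#' size-corrected rib length), limb analyses (size correction, shape
#' relationships, ecotype means), and the RRPP decomposition of body
#' shape into its six components (overall and per ecotype) with
#' Benjamini-Hochberg adjustment. Every stochastic step is seeded from
#' `config$seed`; tables are written to `config$out_dir` with a
#' provenance header (version, seed, input checksums).
#'
#' @param config A [pipeline_config()].
#' @return A named results list, invisibly; tables on disk in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  seed <- as.integer(config$seed)

  # -- inputs ------------------------------------------------------------
  if (!is.null(config$species_csv)) {
    say("reading species traits: %s", config$species_csv)
    traits <- read_species_traits(config$species_csv)
  } else {
    if (is.null(config$measurements_csv))
      stop("config needs measurements_csv or species_csv")
    say("reading measurements: %s", config$measurements_csv)
    md <- read_measurements(config$measurements_csv)
    if (is.null(md$ecotypes))
      stop("measurement CSV carries no ecotype column")
    traits <- aggregate_species(md$records, md$ecotypes,
                                rule = config$aggregation)
  }
  tree <- read_phylogeny(config$tree)
  ovl <- taxa_overlap_report(traits$species_id, tree)
  say("%s", ovl$text)
  if (!length(ovl$matched)) stop("no species shared between data and tree")
  if (length(ovl$data_only))
    stop(errorCondition(
      paste0("species in data but not tree: ",
             paste(ovl$data_only, collapse = ", ")),
      class = c("squamorph_taxa_mismatch", "error", "condition")))
  tree <- prune_phylogeny(tree, traits$species_id)
  if (any(!ecotype_levels() %in% traits$ecotype))
    warning("empty ecotype group(s): ",
            paste(setdiff(ecotype_levels(), traits$ecotype), collapse = ", "))
  traits$ecotype <- factor(traits$ecotype,
                           levels = intersect(ecotype_levels(),
                                              unique(traits$ecotype)))
  prov <- .provenance(config, list(measurements = config$measurements_csv,
                                   species = config$species_csv,
                                   tree = config$tree))
  res <- list(traits = traits, tree = tree, overlap = ovl)
  iso <- config$isometric_slope
  B <- config$bootstrap_reps

  # size-corrected rib length is used by components and RRPP alike
  rib_sc <- size_correct(traits, "ln_rib_length", "ln_body_size", tree)
  traits$ln_rib_corrected <- unname(rib_sc$residuals[traits$species_id])

  # -- body-shape allometry ---------------------------------------------
  if (isTRUE(config$do_allometry)) {
    say("body-shape allometry (bootstrap x%d)", B)
    f_all <- fit_pgls(ln_hbER ~ ln_body_size, traits, tree)
    b_all <- bootstrap_cis(f_all, n_reps = B, seed = seed)
    f_anc <- fit_pgls(ln_hbER ~ ln_body_size * ecotype, traits, tree)
    b_anc <- bootstrap_cis(f_anc, n_reps = B, seed = seed + 1L)
    rows <- rbind(.allometry_rows("ln_hbER~ln_body_size", f_all, b_all, iso),
                  .allometry_rows("ln_hbER~ln_body_size*ecotype", f_anc, b_anc, iso))
    slope_cmp <- compare_group_slopes(b_anc$group_slopes$point,
                                      b_anc$group_slopes$ci)
    res$allometry <- list(overall = list(fit = f_all, boot = b_all),
                          ancova = list(fit = f_anc, boot = b_anc,
                                        anova = type2_anova(f_anc)),
                          table = rows, slope_comparison = slope_cmp)
    .write_table(rows, file.path(config$out_dir, "allometry_shape.csv"), prov)
  }

  # -- component allometries --------------------------------------------
  if (isTRUE(config$do_components)) {
    say("component allometries")
    comps <- c("ln_head_ER", paste0("ln_AEI_", axial_regions()),
               "ln_rib_corrected")
    rows <- list()
    res$components <- list()
    for (i in seq_along(comps)) {
      cm <- comps[i]
      f1 <- fit_pgls(stats::reformulate("ln_body_size", cm), traits, tree)
      b1 <- bootstrap_cis(f1, n_reps = B, seed = seed + 10L + i)
      f2 <- fit_pgls(stats::reformulate("ln_body_size * ecotype", cm),
                     traits, tree)
      b2 <- bootstrap_cis(f2, n_reps = B, seed = seed + 40L + i)
      rows[[cm]] <- rbind(
        .allometry_rows(paste0(cm, "~ln_body_size"), f1, b1, iso),
        .allometry_rows(paste0(cm, "~ln_body_size*ecotype"), f2, b2, iso))
      res$components[[cm]] <- list(overall = f1, overall_boot = b1,
                                   ancova = f2, ancova_boot = b2)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    res$components_table <- tab
    .write_table(tab, file.path(config$out_dir, "allometry_components.csv"), prov)
  }

  # -- limb analyses -----------------------------------------------------
  if (isTRUE(config$do_limbs)) {
    modes <- if (config$limb_mode == "both") c("full", "reduced") else config$limb_mode
    res$limbs <- list()
    rows <- list(); mrows <- list()
    for (mode in modes) {
      limb_cols <- paste0("ln_", c("forelimb_", "hindlimb_"), mode)
      keep <- stats::complete.cases(traits[, limb_cols])
      say("limb analyses (%s): %d species excluded without limb data",
          mode, sum(!keep))
      ld <- traits[keep, ]
      ltree <- prune_phylogeny(tree, ld$species_id)
      for (lc in limb_cols) {
        sc <- size_correct(ld, lc, "ln_body_size", ltree)
        ld[[paste0(lc, "_corrected")]] <- unname(sc$residuals[ld$species_id])
        rc <- paste0(lc, "_corrected")
        f1 <- fit_pgls(stats::reformulate("ln_hbER", rc), ld, ltree)
        b1 <- bootstrap_cis(f1, n_reps = B, seed = seed + 100L)
        f2 <- fit_pgls(stats::reformulate("ln_hbER * ecotype", rc), ld, ltree)
        b2 <- bootstrap_cis(f2, n_reps = B, seed = seed + 101L)
        rows[[paste(mode, lc)]] <- rbind(
          .allometry_rows(paste0(rc, "~ln_hbER"), f1, b1, iso),
          .allometry_rows(paste0(rc, "~ln_hbER*ecotype"), f2, b2, iso))
        gm <- group_mean_comparison(ld, rc, "ecotype", ltree,
                                    n_reps = B, seed = seed + 102L)
        mrows[[paste(mode, lc)]] <- data.frame(
          mode = mode, limb = rc, group = names(gm$means),
          mean = unname(gm$means),
          ci_lower = gm$ci[, "lower"], ci_upper = gm$ci[, "upper"],
          differs_from_all_others =
            vapply(names(gm$means), function(g)
              all(gm$one_way[g, setdiff(names(gm$means), g)]), TRUE))
        res$limbs[[paste(mode, lc, sep = "_")]] <-
          list(shape_fit = f1, shape_boot = b1, ancova = f2,
               ancova_boot = b2, means = gm, excluded = sum(!keep))
      }
    }
    res$limb_table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    res$limb_means <- do.call(rbind, c(mrows, list(make.row.names = FALSE)))
    .write_table(res$limb_table, file.path(config$out_dir, "limb_shape.csv"), prov)
    .write_table(res$limb_means, file.path(config$out_dir, "limb_means.csv"), prov)
  }

  # -- RRPP decomposition ------------------------------------------------
  if (isTRUE(config$do_rrpp)) {
    say("RRPP decomposition (x%d iterations)", config$rrpp_iters)
    form <- ln_hbER ~ ln_head_ER + ln_AEI_cervical + ln_AEI_thoracic +
      ln_AEI_lumbar + ln_AEI_sacral + ln_rib_corrected
    groups <- c("all", levels(traits$ecotype))
    res$rrpp <- list()
    rrows <- list()
    for (g in groups) {
      d <- if (g == "all") traits else traits[traits$ecotype == g, ]
      if (nrow(d) < 8) { say("skipping RRPP for '%s' (n = %d)", g, nrow(d)); next }
      gtree <- prune_phylogeny(tree, d$species_id)
      rr <- rrpp_multiple_regression(form, d, gtree,
                                     n_iter = config$rrpp_iters,
                                     seed = seed + match(g, groups))
      res$rrpp[[g]] <- rr
      rrows[[g]] <- cbind(group = g, rr$table)
    }
    res$rrpp_table <- do.call(rbind, c(rrows, list(make.row.names = FALSE)))
    .write_table(res$rrpp_table, file.path(config$out_dir, "rrpp_components.csv"), prov)
  }

  say("pipeline complete; tables in %s", config$out_dir)
  invisible(res)
}
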