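# Synthetic-data generator: pure-birth trees, Brownian ln size, ecotype-
# specific allometry on ln shape and its components, and specimen-level
# measurement synthesis that inverts the morphometric formulas exactly
# before noise is added.

#' Simulation configuration
#'
#' Defaults describe the study system the package targets: 87 species in
#' four ecotypes (chipmunk 15, gliding 11, ground 29, tree 32) on a
#' unit-depth ultrametric tree; ln body size evolving by Brownian motion;
#' ln body shape following ecotype-specific allometric lines with
#' phylogenetically correlated residuals (Pagel's lambda); 1-5 specimens
#' per species with multiplicative measurement noise. Slope defaults are
#' the per-ecotype body-shape allometries the package is designed to
#' detect (chipmunk 0.24, gliding 0.12, ground -0.11, tree -0.02).
#'
#' @param n_species Number of tips.
#' @param ecotype_sizes Named integer vector summing to `n_species`;
#'   `NULL` (default) allocates the study's 15:11:29:32 proportions by
#'   largest-remainder rounding.
#' @param lambda_true Pagel's lambda of the residual covariance.
#' @param intercepts,slopes Named per-ecotype intercepts/slopes of
#'   `ln shape ~ ln size`.
#' @param sigma Residual SD of ln shape.
#' @param size_bm_var Brownian-motion variance of ln size (tip variance
#'   on the unit-depth tree).
#' @param root_size Root value of ln size (ln mm).
#' @param component_slopes,component_intercepts,component_sigma Allometry
#'   of the ln component traits (head ER and the four regional AEIs).
#' @param limb_intercepts,limb_slopes,limb_sigma Allometry of ln full
#'   fore-/hind-limb length; `gliding_forelimb_offset` adds relatively
#'   longer glider forelimbs.
#' @param gliding_forelimb_offset Additive ln offset for glider forelimbs.
#' @param limb_missing_frac Fraction of species with no limb material.
#' @param specimens_range Integer range of specimens per species.
#' @param noise_cv Coefficient of variation of per-measurement noise.
#' @param vertebral_counts Vertebrae per region (mammalian counts are
#'   nearly constant, so they are fixed).
#' @param length_fractions Fractions of total head+body length allotted
#'   to the cranium and the four vertebral regions (must sum to 1).
#' @param clade_ecotypes Assign ecotypes as contiguous blocks in the
#'   tree's cladewise tip order (default) or at random.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_species = 87,
                       ecotype_sizes = NULL,
                       lambda_true = 0.8,
                       intercepts = c(chipmunk = 0.69, gliding = 1.23,
                                      ground = 1.80, tree = 1.55),
                       slopes = c(chipmunk = 0.24, gliding = 0.12,
                                  ground = -0.11, tree = -0.02),
                       sigma = 0.05,
                       size_bm_var = 0.15,
                       root_size = 3.5,
                       component_slopes = c(head_ER = 0.18,
                                            AEI_cervical = 0.22,
                                            AEI_thoracic = 0.00,
                                            AEI_lumbar = -0.09,
                                            AEI_sacral = 0.00),
                       component_intercepts = c(head_ER = 0.245,
                                                AEI_cervical = -0.182,
                                                AEI_thoracic = 1.281,
                                                AEI_lumbar = 1.509,
                                                AEI_sacral = 0.405),
                       component_sigma = 0.08,
                       limb_intercepts = c(forelimb = 0.99, hindlimb = 1.19),
                       limb_slopes = c(forelimb = 1, hindlimb = 1),
                       limb_sigma = 0.08,
                       gliding_forelimb_offset = 0.2,
                       limb_missing_frac = 11 / 87,
                       specimens_range = c(1L, 5L),
                       noise_cv = 0.03,
                       vertebral_counts = c(cervical = 7, thoracic = 12,
                                            lumbar = 7, sacral = 3),
                       length_fractions = c(head = 0.22, cervical = 0.12,
                                            thoracic = 0.30, lumbar = 0.26,
                                            sacral = 0.10),
                       clade_ecotypes = TRUE,
                       seed = 1L) {
  if (is.null(ecotype_sizes)) {
    # study proportions 15:11:29:32, largest-remainder rounding
    prop <- c(chipmunk = 15, gliding = 11, ground = 29, tree = 32) / 87
    raw <- prop * n_species
    ecotype_sizes <- floor(raw)
    rem <- n_species - sum(ecotype_sizes)
    if (rem > 0) {
      up <- order(raw - floor(raw), decreasing = TRUE)[seq_len(rem)]
      ecotype_sizes[up] <- ecotype_sizes[up] + 1L
    }
    ecotype_sizes <- stats::setNames(as.integer(ecotype_sizes), names(prop))
  }
  stopifnot(sum(ecotype_sizes) == n_species,
            all(names(ecotype_sizes) %in% ecotype_levels()),
            lambda_true >= 0, lambda_true <= 1,
            sigma >= 0, size_bm_var >= 0, noise_cv >= 0,
            abs(sum(length_fractions) - 1) < 1e-8)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate an ultrametric pure-birth tree
#'
#' A Yule tree with `n_species` tips, rescaled to unit root-to-tip depth,
#' tips relabeled `sp001`, `sp002`, ...
#'
#' @param config A [sim_config()].
#' @return An `ape::phylo`.
#' @export
simulate_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"), config$n_species >= 2)
  set.seed(as.integer(config$seed))
  tr <- ape::rphylo(config$n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / depth
  tr$tip.label <- sprintf("sp%03d", seq_len(config$n_species))
  tr
}

# tips in cladewise (plot) order, so contiguous blocks approximate clades
.tip_order <- function(tree) {
  tr <- stats::reorder(tree, "cladewise")
  e2 <- tr$edge[, 2]
  tr$tip.label[e2[e2 <= length(tr$tip.label)]]
}

#' Simulate species traits with known allometric structure
#'
#' ln body size evolves by Brownian motion on the tree; ecotypes are
#' assigned as contiguous clade-ordered blocks (or at random); ln body
#' shape is `a_g + b_g * ln size` plus multivariate-normal residuals with
#' covariance `sigma^2 * V(lambda_true)`; the ln component traits get
#' their own allometric lines and residuals. Rib length (body depth) and
#' the geometric-mean body size are *derived* from an exactly consistent
#' skeletal geometry, so that specimens synthesized from these traits
#' reproduce them to machine precision (see [synthesize_specimens()]).
#'
#' @param tree Tree from [simulate_tree()].
#' @param config A [sim_config()].
#' @return List with `traits` (species data frame, raw and `ln_` columns)
#'   and `truth` (all generating parameters and latent values).
#' @export
simulate_traits <- function(tree, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(config$seed) + 1L)
  n <- config$n_species
  V <- ape::vcv(tree)
  sp <- rownames(V)

  ln_size <- config$root_size + if (config$size_bm_var > 0)
    drop(crossprod(chol(config$size_bm_var * V + diag(1e-12, n)),
                   stats::rnorm(n))) else numeric(n)
  names(ln_size) <- sp

  eco <- character(n)
  ord <- if (config$clade_ecotypes) .tip_order(tree) else sample(sp)
  blocks <- rep(names(config$ecotype_sizes), config$ecotype_sizes)
  eco[match(ord, sp)] <- blocks
  names(eco) <- sp

  Vl <- .lambda_V(V, config$lambda_true)
  Lres <- chol(Vl + diag(1e-12, n))
  mvn <- function(s) if (s > 0) drop(crossprod(Lres, stats::rnorm(n))) * s
                     else numeric(n)

  a <- config$intercepts[eco]
  b <- config$slopes[eco]
  ln_shape <- unname(a + b * ln_size) + mvn(config$sigma)

  comp <- sapply(names(config$component_slopes), function(cn) {
    config$component_intercepts[[cn]] +
      config$component_slopes[[cn]] * ln_size + mvn(config$component_sigma)
  })
  rownames(comp) <- sp

  ln_fore <- config$limb_intercepts[["forelimb"]] +
    config$limb_slopes[["forelimb"]] * ln_size + mvn(config$limb_sigma) +
    ifelse(eco == "gliding", config$gliding_forelimb_offset, 0)
  ln_hind <- config$limb_intercepts[["hindlimb"]] +
    config$limb_slopes[["hindlimb"]] * ln_size + mvn(config$limb_sigma)
  limb_missing <- stats::runif(n) < config$limb_missing_frac

  # exact skeletal geometry: unit-depth skeleton from the ratios, then a
  # global rescale so the 11-component geometric mean equals ln_size
  geom <- t(vapply(seq_len(n), function(i) {
    sk <- .unit_skeleton(exp(ln_shape[i]), exp(comp[i, "head_ER"]),
                         exp(comp[i, paste0("AEI_", axial_regions())]),
                         config)
    u <- exp(ln_size[i]) / sk$gm
    c(rib_length = u, body_size = exp(ln_size[i]))
  }, c(rib_length = 0, body_size = 0)))

  tr <- data.frame(species_id = sp, ecotype = unname(eco),
                   hbER = exp(ln_shape),
                   head_ER = exp(comp[, "head_ER"]),
                   AEI_cervical = exp(comp[, "AEI_cervical"]),
                   AEI_thoracic = exp(comp[, "AEI_thoracic"]),
                   AEI_lumbar = exp(comp[, "AEI_lumbar"]),
                   AEI_sacral = exp(comp[, "AEI_sacral"]),
                   rib_length = geom[, "rib_length"],
                   body_size = geom[, "body_size"],
                   forelimb_full = ifelse(limb_missing, NA, exp(ln_fore)),
                   hindlimb_full = ifelse(limb_missing, NA, exp(ln_hind)),
                   n_specimens = NA_integer_,
                   row.names = NULL)
  fr <- .limb_fractions()
  tr$forelimb_reduced <- tr$forelimb_full * (fr$fore[["humerus"]] + fr$fore[["radius"]])
  tr$hindlimb_reduced <- tr$hindlimb_full * (fr$hind[["femur"]] + fr$hind[["tibia"]])
  tr <- tr[, c("species_id", "ecotype", .trait_cols(), "n_specimens")]
  for (cl in .trait_cols()) tr[[paste0("ln_", cl)]] <- log(tr[[cl]])

  truth <- list(config = unclass(config), ln_size = ln_size,
                ecotype = eco, ln_shape = stats::setNames(ln_shape, sp),
                intercepts = config$intercepts, slopes = config$slopes,
                lambda_true = config$lambda_true,
                limb_missing = stats::setNames(limb_missing, sp))
  list(traits = tr, truth = truth)
}

# fixed fractions decomposing full limb lengths into bones
.limb_fractions <- function() {
  list(fore = c(scapula = 0.28, humerus = 0.32, radius = 0.30, metacarpal3 = 0.10),
       hind = c(femur = 0.40, tibia = 0.45, metatarsal3 = 0.15))
}

# skeleton with body depth = 1 realizing the given ratios; returns the
# 11 size components and their geometric mean
.unit_skeleton <- function(hbER, head_ER, aei, config) {
  total <- hbER * 1                      # L_H + L_B at unit depth
  fr <- config$length_fractions
  L_H <- fr[["head"]] * total
  S <- total * fr[axial_regions()] / 1   # regional centrum sums
  names(S) <- axial_regions()
  H_H <- L_H / head_ER
  Hm <- S / unname(aei[paste0("AEI_", axial_regions())])
  comps <- c(L_H, H_H, S, Hm, 1)
  list(L_H = L_H, H_H = H_H, S = S, Hm = Hm, depth = 1,
       gm = exp(mean(log(comps))))
}

#' Synthesize specimen records from species traits
#'
#' Builds, for each species, specimens whose computed indices equal the
#' species' target traits exactly when `noise_cv = 0`: vertebral counts
#' fixed per region, equal centrum lengths and heights within a region,
#' six ribs with the four longest equal to the body depth, and limb bones
#' in fixed proportions of the full limb lengths. Each measurement is
#' then multiplied by independent lognormal noise with the configured
#' coefficient of variation (unit mean).
#'
#' @param traits Species trait table from [simulate_traits()].
#' @param config A [sim_config()].
#' @return List of [specimen_record()] objects.
#' @export
synthesize_specimens <- function(traits, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(config$seed) + 2L)
  cv <- config$noise_cv
  sdlog <- sqrt(log(1 + cv^2))
  jitter <- function(x) {
    if (cv == 0) return(x)
    x * stats::rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  fr <- .limb_fractions()
  counts <- config$vertebral_counts

  recs <- list()
  for (i in seq_len(nrow(traits))) {
    row <- traits[i, ]
    aei <- stats::setNames(as.numeric(row[paste0("AEI_", axial_regions())]),
                           paste0("AEI_", axial_regions()))
    sk <- .unit_skeleton(row$hbER, row$head_ER, aei, config)
    u <- row$body_size / sk$gm           # global scale: gm == body_size
    n_spec <- sample(seq(config$specimens_range[1], config$specimens_range[2]), 1)
    for (s in seq_len(n_spec)) {
      vert <- lapply(axial_regions(), function(r) {
        k <- counts[[r]]
        data.frame(centrum_length = jitter(rep(u * sk$S[[r]] / k, k)),
                   vertebral_height = jitter(rep(u * sk$Hm[[r]], k)))
      })
      names(vert) <- axial_regions()
      ribs <- jitter(u * c(1, 1, 1, 1, 0.92, 0.85))
      limbs <- NULL
      if (!is.na(row$forelimb_full)) {
        limbs <- c(jitter(row$forelimb_full * fr$fore),
                   jitter(row$hindlimb_full * fr$hind))
      }
      recs[[length(recs) + 1L]] <- specimen_record(
        specimen_id = sprintf("%s_%02d", row$species_id, s),
        species_id = row$species_id,
        cranial_length = jitter(u * sk$L_H),
        cranial_height = jitter(u * sk$H_H),
        vertebrae = vert, rib_lengths = ribs, limb_bones = limbs)
    }
  }
  recs
}

#' Generate and write a complete synthetic data bundle
#'
#' Runs [simulate_tree()], [simulate_traits()], [synthesize_specimens()]
#' and writes the measurement CSV, species CSV, Newick tree, and a truth
#' JSON into `dir`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list of file paths (`measurements`, `species`,
#'   `tree`, `truth`) plus the in-memory objects (`phylo`, `traits`,
#'   `truth_values`, `records`).
#' @export
simulate_dataset <- function(config = sim_config(), dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tree <- simulate_tree(config)
  st <- simulate_traits(tree, config)
  recs <- synthesize_specimens(st$traits, config)
  eco <- stats::setNames(st$traits$ecotype, st$traits$species_id)
  paths <- list(measurements = file.path(dir, "measurements.csv"),
                species = file.path(dir, "species_traits.csv"),
                tree = file.path(dir, "tree.nwk"),
                truth = file.path(dir, "truth.json"))
  write_measurements(recs, paths$measurements, ecotypes = eco)
  write_species_traits(st$traits, paths$species,
                       header_comment = sprintf("synthetic data, seed %d",
                                                config$seed))
  write_phylogeny(tree, paths$tree)
  jsonlite::write_json(
    list(seed = config$seed,
         lambda_true = config$lambda_true,
         intercepts = as.list(config$intercepts),
         slopes = as.list(config$slopes),
         sigma = config$sigma,
         ecotype = as.list(st$truth$ecotype),
         ln_size = as.list(st$truth$ln_size)),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, list(phylo = tree, traits = st$traits,
                          truth_values = st$truth, records = recs)))
}
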