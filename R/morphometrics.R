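# Formula-defined skeletal elongation statistics and specimen -> species
# aggregation.

#' Vertebral regions used throughout the package
#'
#' Ordered names of the four axial regions measured on each specimen.
#'
#' @return Character vector `c("cervical", "thoracic", "lumbar", "sacral")`.
#' @export
axial_regions <- function() c("cervical", "thoracic", "lumbar", "sacral")

#' Ecotype levels
#'
#' The four locomotor ecotypes, in the fixed factor order used by every
#' model in the package (chipmunk is the reference level).
#'
#' @return Character vector of ecotype names.
#' @export
ecotype_levels <- function() c("chipmunk", "gliding", "ground", "tree")

#' Limb bones recognised in specimen records
#' @return Character vector of bone names.
#' @export
limb_bone_names <- function() {
  c("scapula", "humerus", "radius", "metacarpal3",
    "femur", "tibia", "metatarsal3")
}

.stop_measurement <- function(field, value) {
  stop(errorCondition(
    sprintf("invalid measurement: '%s' must be strictly positive (got %s)",
            field, paste(format(value), collapse = ", ")),
    class = c("squamorph_invalid_measurement", "error", "condition")))
}

.stop_region <- function(region) {
  stop(errorCondition(
    sprintf("missing vertebral region: '%s' has no vertebrae", region),
    class = c("squamorph_missing_region", "error", "condition")))
}

.check_positive <- function(x, field) {
  if (length(x) == 0 || anyNA(x) || any(x <= 0)) .stop_measurement(field, x)
  invisible(x)
}

#' Construct a specimen record
#'
#' Bundles the raw skeletal measurements of one museum specimen: cranial
#' length and height, per-region vertebral centrum lengths and heights,
#' rib curve lengths, and (optionally) limb bone lengths. All lengths are
#' in millimetres and must be strictly positive; limb bones may be absent
#' (`NA` or omitted), reflecting incomplete museum material.
#'
#' @param specimen_id Unique specimen identifier.
#' @param species_id Species the specimen belongs to.
#' @param cranial_length,cranial_height Cranial measurements (mm).
#' @param vertebrae Named list with elements `cervical`, `thoracic`,
#'   `lumbar`, `sacral`; each a data frame (or list) with numeric columns
#'   `centrum_length` and `vertebral_height`, one row per vertebra in
#'   anatomical order.
#' @param rib_lengths Numeric vector of rib curve lengths (>= 4 expected
#'   for body-depth computation).
#' @param limb_bones Optional named numeric vector; recognised names are
#'   given by [limb_bone_names()]. Missing bones may be `NA` or absent.
#' @return An object of class `specimen_record`.
#' @export
specimen_record <- function(specimen_id, species_id,
                            cranial_length, cranial_height,
                            vertebrae, rib_lengths, limb_bones = NULL) {
  stopifnot(is.character(specimen_id) || is.factor(specimen_id),
            length(specimen_id) == 1L, length(species_id) == 1L)
  .check_positive(cranial_length, "cranial_length")
  .check_positive(cranial_height, "cranial_height")
  if (!all(axial_regions() %in% names(vertebrae)))
    .stop_region(setdiff(axial_regions(), names(vertebrae))[1])
  vert <- lapply(axial_regions(), function(r) {
    v <- as.data.frame(vertebrae[[r]])
    if (nrow(v) == 0) .stop_region(r)
    .check_positive(v$centrum_length, paste0(r, " centrum_length"))
    .check_positive(v$vertebral_height, paste0(r, " vertebral_height"))
    v[, c("centrum_length", "vertebral_height")]
  })
  names(vert) <- axial_regions()
  .check_positive(rib_lengths, "rib_lengths")
  lb <- rep(NA_real_, length(limb_bone_names()))
  names(lb) <- limb_bone_names()
  if (!is.null(limb_bones)) {
    limb_bones <- limb_bones[!is.na(limb_bones)]
    unknown <- setdiff(names(limb_bones), limb_bone_names())
    if (length(unknown))
      stop("unknown limb bone(s): ", paste(unknown, collapse = ", "))
    if (length(limb_bones)) .check_positive(unlist(limb_bones), "limb_bones")
    lb[names(limb_bones)] <- unlist(limb_bones)
  }
  structure(list(specimen_id = as.character(specimen_id),
                 species_id = as.character(species_id),
                 cranial_length = cranial_length,
                 cranial_height = cranial_height,
                 vertebrae = vert,
                 rib_lengths = as.numeric(rib_lengths),
                 limb_bones = lb),
            class = "specimen_record")
}

#' @export
print.specimen_record <- function(x, ...) {
  nv <- vapply(x$vertebrae, nrow, 0L)
  cat(sprintf("<specimen_record> %s (%s): cranium %.2f x %.2f mm, vertebrae %s, %d ribs, %d limb bones\n",
              x$specimen_id, x$species_id, x$cranial_length, x$cranial_height,
              paste(nv, collapse = "/"), length(x$rib_lengths),
              sum(!is.na(x$limb_bones))))
  invisible(x)
}

#' Head-body elongation ratio
#'
#' `hbER = (L_H + L_B) / L_R`: cranial length plus summed centrum length,
#' divided by body depth. Dimensionless; higher values indicate a more
#' elongate body.
#'
#' @param L_H Cranial (condylobasal) length, mm.
#' @param L_B Body length: summed vertebral centrum lengths, mm.
#' @param L_R Body depth: mean of the four longest ribs, mm.
#' @return The dimensionless ratio.
#' @examples
#' compute_hbER(1, 1, 1)            # 2
#' compute_hbER(4.2, 20.3, 6.1)     # ~4.016
#' @export
compute_hbER <- function(L_H, L_B, L_R) {
  .check_positive(L_H, "L_H")
  .check_positive(L_B, "L_B")
  .check_positive(L_R, "L_R")
  (L_H + L_B) / L_R
}

#' Body length from vertebral centra
#'
#' Sums centrum lengths over the cervical, thoracic, lumbar, and sacral
#' regions of a specimen record (or an equivalently structured list).
#'
#' @param vertebrae A `specimen_record` or its `vertebrae` list.
#' @return Body length in mm.
#' @export
compute_body_length <- function(vertebrae) {
  if (inherits(vertebrae, "specimen_record")) vertebrae <- vertebrae$vertebrae
  tot <- 0
  for (r in axial_regions()) {
    v <- vertebrae[[r]]
    if (is.null(v) || NROW(v) == 0) .stop_region(r)
    tot <- tot + sum(as.data.frame(v)$centrum_length)
  }
  tot
}

#' Body depth from rib lengths
#'
#' Mean of the four longest rib curve lengths.
#'
#' @param rib_lengths Numeric vector of rib lengths (mm), length >= 4.
#' @return Body depth in mm.
#' @export
compute_body_depth <- function(rib_lengths) {
  if (length(rib_lengths) < 4)
    stop(errorCondition(
      sprintf("insufficient ribs: need >= 4 lengths, got %d",
              length(rib_lengths)),
      class = c("squamorph_insufficient_ribs", "error", "condition")))
  .check_positive(rib_lengths, "rib_lengths")
  mean(sort(rib_lengths, decreasing = TRUE)[1:4])
}

#' Head elongation ratio
#'
#' Cranial length divided by cranial height.
#'
#' @param L_H Cranial length (mm).
#' @param H_H Cranial height (mm).
#' @return Dimensionless ratio.
#' @export
compute_head_ER <- function(L_H, H_H) {
  .check_positive(L_H, "L_H")
  .check_positive(H_H, "H_H")
  L_H / H_H
}

#' Axial elongation index of one vertebral region
#'
#' `AEI = sum(L_V) / mean(H_V)`: summed centrum lengths divided by mean
#' vertebral height, for the vertebrae of one region.
#'
#' @param region Data frame with columns `centrum_length` and
#'   `vertebral_height` (one row per vertebra), or a list with those
#'   elements.
#' @return Dimensionless ratio.
#' @examples
#' compute_AEI(data.frame(centrum_length = c(4.1, 4.3, 4.0),
#'                        vertebral_height = c(7, 8, 9)))  # 1.55
#' @export
compute_AEI <- function(region) {
  v <- as.data.frame(region)
  if (nrow(v) == 0) .stop_region("(anonymous)")
  .check_positive(v$centrum_length, "centrum_length")
  .check_positive(v$vertebral_height, "vertebral_height")
  sum(v$centrum_length) / mean(v$vertebral_height)
}

#' Geometric-mean body size
#'
#' The 11th root of the product of the 11 cranial/axial size components:
#' cranial length, cranial height, the four regional summed centrum
#' lengths, the four regional mean vertebral heights, and body depth.
#' Computed as `exp(mean(log(x)))` for numerical stability.
#'
#' @param components Numeric vector of exactly 11 strictly positive
#'   lengths (mm).
#' @return Geometric mean (mm).
#' @export
compute_geometric_mean <- function(components) {
  if (length(components) != 11L || anyNA(components) || any(components <= 0))
    stop(errorCondition(
      sprintf("invalid size components: need 11 strictly positive lengths, got %d value(s)%s",
              length(components),
              if (anyNA(components) || any(components <= 0, na.rm = TRUE))
                " including non-positive or missing entries" else ""),
      class = c("squamorph_invalid_size_components", "error", "condition")))
  exp(mean(log(components)))
}

.size_components <- function(rec) {
  sums <- vapply(rec$vertebrae, function(v) sum(v$centrum_length), 0)
  hts  <- vapply(rec$vertebrae, function(v) mean(v$vertebral_height), 0)
  c(cranial_length = rec$cranial_length,
    cranial_height = rec$cranial_height,
    sums, hts,
    body_depth = compute_body_depth(rec$rib_lengths))
}

#' Fore- and hind-limb lengths from individual bones
#'
#' `mode = "full"` sums scapula + humerus + radius + third metacarpal
#' (forelimb) and femur + tibia + third metatarsal (hind limb);
#' `mode = "reduced"` uses only the long bones (humerus + radius, femur +
#' tibia). A limb is `NA` when any required bone is missing.
#'
#' @param limb_bones Named numeric vector (see [limb_bone_names()]); `NA`
#'   marks a missing bone.
#' @param mode `"full"` or `"reduced"`.
#' @return Named numeric vector `c(forelimb =, hindlimb =)`, possibly `NA`.
#' @export
compute_limb_lengths <- function(limb_bones, mode = c("full", "reduced")) {
  mode <- match.arg(mode)
  get <- function(b) if (b %in% names(limb_bones)) limb_bones[[b]] else NA_real_
  fore_bones <- if (mode == "full")
    c("scapula", "humerus", "radius", "metacarpal3") else c("humerus", "radius")
  hind_bones <- if (mode == "full")
    c("femur", "tibia", "metatarsal3") else c("femur", "tibia")
  s <- function(b) {
    v <- vapply(b, get, 0)
    if (anyNA(v)) NA_real_ else sum(v)
  }
  c(forelimb = s(fore_bones), hindlimb = s(hind_bones))
}

#' Per-specimen derived indices
#'
#' Computes every derived statistic for a single specimen record: hbER,
#' head ER, per-region AEIs, body depth (rib length), geometric-mean body
#' size, and limb lengths in both modes.
#'
#' @param rec A `specimen_record`.
#' @return Named numeric vector of indices.
#' @export
specimen_indices <- function(rec) {
  stopifnot(inherits(rec, "specimen_record"))
  L_B <- compute_body_length(rec)
  L_R <- compute_body_depth(rec$rib_lengths)
  aei <- vapply(rec$vertebrae, compute_AEI, 0)
  names(aei) <- paste0("AEI_", names(aei))
  lf <- compute_limb_lengths(rec$limb_bones, "full")
  lr <- compute_limb_lengths(rec$limb_bones, "reduced")
  c(hbER = compute_hbER(rec$cranial_length, L_B, L_R),
    head_ER = compute_head_ER(rec$cranial_length, rec$cranial_height),
    aei,
    rib_length = L_R,
    body_size = compute_geometric_mean(unname(.size_components(rec))),
    forelimb_full = unname(lf["forelimb"]),
    hindlimb_full = unname(lf["hindlimb"]),
    forelimb_reduced = unname(lr["forelimb"]),
    hindlimb_reduced = unname(lr["hindlimb"]))
}

.trait_cols <- function() {
  c("hbER", "head_ER", paste0("AEI_", axial_regions()),
    "rib_length", "body_size",
    "forelimb_full", "hindlimb_full", "forelimb_reduced", "hindlimb_reduced")
}

#' Aggregate specimen records to species-level traits
#'
#' Each derived index is computed per specimen and then averaged
#' arithmetically across the specimens of a species ("index-then-mean",
#' the default); the natural-log columns are logs of the species means.
#' Limb fields are averaged over the subset of specimens possessing the
#' required bones, and are `NA` for species without any limb data.
#' Specimens that fail a measurement precondition (e.g. fewer than 4
#' ribs) are dropped with a warning rather than aborting the run.
#'
#' @param records List of `specimen_record` objects.
#' @param ecotypes Named character vector or data frame
#'   (`species_id`, `ecotype`) mapping every species to one of
#'   [ecotype_levels()].
#' @param rule `"index_then_mean"` (default) or `"mean_then_index"`; the
#'   latter averages the raw measurements per species first and computes
#'   indices from the mean skeleton (sensitivity option).
#' @return Data frame with one row per species: identifiers, ecotype,
#'   raw trait columns, `ln_`-prefixed natural-log columns, and
#'   `n_specimens`.
#' @export
aggregate_species <- function(records, ecotypes,
                              rule = c("index_then_mean", "mean_then_index")) {
  rule <- match.arg(rule)
  if (is.data.frame(ecotypes)) {
    eco <- stats::setNames(as.character(ecotypes$ecotype),
                           as.character(ecotypes$species_id))
  } else eco <- ecotypes
  ids <- vapply(records, function(r) r$specimen_id, "")
  if (anyDuplicated(ids))
    stop("duplicate specimen_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))

  ok <- logical(length(records))
  idx <- vector("list", length(records))
  for (i in seq_along(records)) {
    res <- tryCatch(specimen_indices(records[[i]]), error = identity)
    if (inherits(res, "error")) {
      warning(sprintf("excluding specimen '%s': %s",
                      records[[i]]$specimen_id, conditionMessage(res)),
              call. = FALSE)
    } else {
      ok[i] <- TRUE
      idx[[i]] <- res
    }
  }
  records <- records[ok]
  idx <- idx[ok]
  if (!length(records)) stop("no usable specimens")

  sp <- vapply(records, function(r) r$species_id, "")
  species <- sort(unique(sp))
  missing_eco <- setdiff(species, names(eco))
  if (length(missing_eco))
    stop(errorCondition(
      paste0("species missing from ecotype map: ",
             paste(missing_eco, collapse = ", ")),
      class = c("squamorph_label_error", "error", "condition")))
  bad_eco <- setdiff(unique(eco[species]), ecotype_levels())
  if (length(bad_eco))
    stop(errorCondition(
      paste0("unknown ecotype label(s): ", paste(bad_eco, collapse = ", ")),
      class = c("squamorph_label_error", "error", "condition")))

  rows <- lapply(species, function(s) {
    recs <- records[sp == s]
    vals <- if (rule == "index_then_mean") {
      m <- do.call(rbind, idx[sp == s])
      colMeans(m, na.rm = TRUE)   # limb NAs: mean over specimens with bones
    } else {
      .mean_skeleton_indices(recs)
    }
    vals[is.nan(vals)] <- NA_real_
    out <- as.data.frame(as.list(vals))
    out$species_id <- s
    out$ecotype <- unname(eco[[s]])
    out$n_specimens <- length(recs)
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[, c("species_id", "ecotype", .trait_cols(), "n_specimens")]
  for (cl in .trait_cols()) tab[[paste0("ln_", cl)]] <- log(tab[[cl]])
  rownames(tab) <- NULL
  tab
}

# sensitivity alternative: average raw measurements across specimens, then
# compute the indices once from the mean skeleton (requires equal vertebral
# counts per region, the usual case for conspecifics)
.mean_skeleton_indices <- function(recs) {
  mean_df <- function(get) {
    mats <- lapply(recs, get)
    Reduce(`+`, mats) / length(mats)
  }
  base <- recs[[1]]
  vert <- lapply(axial_regions(), function(r) {
    n <- vapply(recs, function(x) nrow(x$vertebrae[[r]]), 0L)
    if (length(unique(n)) != 1L)
      stop("mean_then_index requires equal vertebral counts in region ", r)
    mean_df(function(x) as.matrix(x$vertebrae[[r]]))
  })
  names(vert) <- axial_regions()
  vert <- lapply(vert, as.data.frame)
  nr <- min(vapply(recs, function(x) length(x$rib_lengths), 0L))
  ribs <- rowMeans(vapply(recs, function(x)
    sort(x$rib_lengths, decreasing = TRUE)[seq_len(nr)], numeric(nr)))
  limb <- rowMeans(vapply(recs, function(x) x$limb_bones,
                          numeric(length(limb_bone_names()))), na.rm = TRUE)
  limb[is.nan(limb)] <- NA_real_
  rec <- specimen_record("mean", base$species_id,
                         mean(vapply(recs, function(x) x$cranial_length, 0)),
                         mean(vapply(recs, function(x) x$cranial_height, 0)),
                         vert, ribs,
                         limb[!is.na(limb)])
  specimen_indices(rec)
}
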