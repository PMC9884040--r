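# Reading and writing specimen-level measurement tables.
#
# Canonical long layout: one row per vertebra with the specimen-level
# columns repeated. Columns:
#   specimen_id, species, ecotype, cranial_length, cranial_height,
#   region, vertebra_index, centrum_length, vertebral_height,
#   rib1..ribK, scapula, humerus, radius, metacarpal3, femur, tibia,
#   metatarsal3
# A wide per-vertebra layout (one row per specimen, vertebra columns named
# "<region><index>_length" / "<region><index>_height") is accepted after
# renaming through a column-mapping config, so supplementary-style raw
# tables can be ingested without reshaping by hand.

#' Read a specimen measurement CSV
#'
#' Parses the canonical long layout (see package vignette) into a list of
#' [specimen_record()] objects plus the ecotype map. A `mapping` (named
#' character vector `c(file_column = canonical_name)`, or a two-column CSV
#' with columns `from,to`) renames columns before parsing, which also
#' allows a wide one-row-per-specimen layout whose vertebra columns map to
#' canonical names `"<region><index>_length"` / `"<region><index>_height"`
#' (e.g. `cervical1_length`).
#'
#' @param path CSV file path.
#' @param mapping Optional column mapping (named vector or CSV path).
#' @return List with elements `records` (list of `specimen_record`) and
#'   `ecotypes` (named character vector, species -> ecotype), or `NULL`
#'   ecotypes if the file carries no ecotype column.
#' @export
read_measurements <- function(path, mapping = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping)) {
      m <- utils::read.csv(mapping, stringsAsFactors = FALSE)
      mapping <- stats::setNames(m$to, m$from)
    }
    hit <- names(df) %in% names(mapping)
    names(df)[hit] <- unname(mapping[names(df)[hit]])
  }
  long <- "region" %in% names(df)
  recs <- if (long) .parse_long(df) else .parse_wide(df)
  eco <- NULL
  if ("ecotype" %in% names(df)) {
    u <- unique(df[, c("species", "ecotype")])
    eco <- stats::setNames(as.character(u$ecotype), as.character(u$species))
  }
  list(records = recs, ecotypes = eco)
}

.rib_cols <- function(df) grep("^rib[0-9]+$", names(df), value = TRUE)

.limb_from_row <- function(row) {
  have <- intersect(limb_bone_names(), names(row))
  lb <- suppressWarnings(as.numeric(row[have]))
  names(lb) <- have
  lb <- lb[!is.na(lb)]
  if (length(lb)) lb else NULL
}

.record_from_parts <- function(id, species, row, vert) {
  ribs <- suppressWarnings(as.numeric(row[.rib_cols(row)]))
  ribs <- ribs[!is.na(ribs)]
  specimen_record(
    specimen_id = id, species_id = species,
    cranial_length = as.numeric(row[["cranial_length"]]),
    cranial_height = as.numeric(row[["cranial_height"]]),
    vertebrae = vert, rib_lengths = ribs,
    limb_bones = .limb_from_row(row))
}

.parse_long <- function(df) {
  need <- c("specimen_id", "species", "cranial_length", "cranial_height",
            "region", "vertebra_index", "centrum_length", "vertebral_height")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("measurement CSV missing column(s): ", paste(miss, collapse = ", "))
  lapply(split(df, df$specimen_id), function(d) {
    d <- d[order(match(d$region, axial_regions()), d$vertebra_index), ]
    vert <- lapply(split(d, factor(d$region, axial_regions())), function(v)
      data.frame(centrum_length = v$centrum_length,
                 vertebral_height = v$vertebral_height))
    row <- lapply(d[1, , drop = FALSE], identity)
    .record_from_parts(d$specimen_id[1], d$species[1], row, vert)
  })
}

.parse_wide <- function(df) {
  pat <- "^(cervical|thoracic|lumbar|sacral)([0-9]+)_(length|height)$"
  vc <- grep(pat, names(df), value = TRUE)
  if (!length(vc))
    stop("wide layout: no vertebra columns matching '<region><i>_length/height' after mapping")
  lapply(seq_len(nrow(df)), function(i) {
    row <- lapply(df[i, , drop = FALSE], identity)
    vert <- lapply(axial_regions(), function(r) {
      ls <- sort(grep(sprintf("^%s[0-9]+_length$", r), names(df), value = TRUE))
      vals_l <- as.numeric(row[ls])
      hs <- sub("_length$", "_height", ls)
      vals_h <- as.numeric(row[hs])
      keep <- !is.na(vals_l) & !is.na(vals_h)
      data.frame(centrum_length = vals_l[keep], vertebral_height = vals_h[keep])
    })
    names(vert) <- axial_regions()
    .record_from_parts(as.character(row[["specimen_id"]]),
                       as.character(row[["species"]]), row, vert)
  })
}

#' Write specimen records to the canonical long CSV layout
#'
#' @param records List of `specimen_record` objects.
#' @param ecotypes Optional named character vector (species -> ecotype).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path, ecotypes = NULL) {
  nrib <- max(vapply(records, function(r) length(r$rib_lengths), 0L))
  rows <- lapply(records, function(r) {
    vt <- do.call(rbind, lapply(axial_regions(), function(rg) {
      v <- r$vertebrae[[rg]]
      data.frame(region = rg, vertebra_index = seq_len(nrow(v)),
                 centrum_length = v$centrum_length,
                 vertebral_height = v$vertebral_height)
    }))
    ribs <- c(r$rib_lengths, rep(NA_real_, nrib - length(r$rib_lengths)))
    base <- data.frame(specimen_id = r$specimen_id, species = r$species_id,
                       ecotype = if (!is.null(ecotypes))
                         unname(ecotypes[r$species_id]) else NA_character_,
                       cranial_length = r$cranial_length,
                       cranial_height = r$cranial_height)
    ribdf <- as.data.frame(as.list(stats::setNames(ribs, paste0("rib", seq_len(nrib)))))
    limbdf <- as.data.frame(as.list(r$limb_bones))
    cbind(base[rep(1, nrow(vt)), , drop = FALSE], vt,
          ribdf[rep(1, nrow(vt)), , drop = FALSE],
          limbdf[rep(1, nrow(vt)), , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a species trait table to CSV
#'
#' One row per species with all trait fields; natural-log columns carry
#' the `ln_` prefix.
#'
#' @param traits Species trait data frame from [aggregate_species()].
#' @param path Output CSV path.
#' @param header_comment Optional character vector written as `#`-prefixed
#'   comment lines above the header (provenance: seed, version, checksums).
#' @return `path`, invisibly.
#' @export
write_species_traits <- function(traits, path, header_comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header_comment))
    writeLines(paste0("# ", header_comment), con)
  utils::write.csv(traits, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a species trait table written by [write_species_traits()]
#'
#' Also accepts any tidy per-species CSV with at least `species_id`,
#' `ecotype`, and the ln-scale trait columns; missing `ln_` columns are
#' derived from the raw columns.
#'
#' @param path CSV path (lines starting with `#` are skipped).
#' @return Species trait data frame.
#' @export
read_species_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("species_id", "ecotype") %in% names(df)))
    stop("species CSV must contain 'species_id' and 'ecotype' columns")
  for (cl in intersect(.trait_cols(), names(df))) {
    ln <- paste0("ln_", cl)
    if (!ln %in% names(df)) df[[ln]] <- log(df[[cl]])
  }
  df
}
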