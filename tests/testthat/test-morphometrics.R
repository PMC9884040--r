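# Formula-defined elongation statistics and species aggregation.

make_vert <- function(lens, hts) data.frame(centrum_length = lens,
                                            vertebral_height = hts)

toy_specimen <- function(id = "s1", species = "spA", scale = 1,
                         limb = c(scapula = 1, humerus = 1, radius = 1,
                                  metacarpal3 = 1, femur = 1, tibia = 1,
                                  metatarsal3 = 1)) {
  specimen_record(id, species,
                  cranial_length = 4.2 * scale, cranial_height = 2.0 * scale,
                  vertebrae = list(cervical = make_vert(c(1, 1.1) * scale, c(0.8, 0.9) * scale),
                                   thoracic = make_vert(c(2, 2.2, 2.1) * scale, c(1.5, 1.6, 1.4) * scale),
                                   lumbar = make_vert(c(2.5, 2.4) * scale, c(1.8, 1.7) * scale),
                                   sacral = make_vert(1.2 * scale, 1.0 * scale)),
                  rib_lengths = c(6.1, 6.0, 5.8, 5.5, 5.0) * scale,
                  limb_bones = limb * scale)
}

test_that("hbER, head ER, AEI, body length/depth match direct arithmetic", {
  expect_equal(compute_hbER(1, 1, 1), 2)
  expect_equal(compute_hbER(10, 10, 10), 2)
  expect_equal(compute_hbER(4.2, 20.3, 6.1), 24.5 / 6.1)
  expect_error(compute_hbER(-1, 2, 3), class = "squamorph_invalid_measurement")

  expect_equal(compute_head_ER(1, 1), 1)
  expect_equal(compute_head_ER(3, 2), 1.5)
  expect_equal(compute_head_ER(41.7, 17.2), 41.7 / 17.2)

  expect_equal(compute_AEI(make_vert(2, 1)), 2)
  expect_equal(compute_AEI(make_vert(c(1, 1, 1), c(1, 1, 1))), 3)
  expect_equal(compute_AEI(make_vert(c(4.1, 4.3, 4.0), c(7, 8, 9))), 12.4 / 8)
  expect_error(compute_AEI(make_vert(numeric(), numeric())),
               class = "squamorph_missing_region")

  v <- list(cervical = make_vert(1, 1), thoracic = make_vert(1, 1),
            lumbar = make_vert(1, 1), sacral = make_vert(1, 1))
  expect_equal(compute_body_length(v), 4)
  v2 <- list(cervical = make_vert(2, 1), thoracic = make_vert(3, 1),
             lumbar = make_vert(4, 1), sacral = make_vert(5, 1))
  expect_equal(compute_body_length(v2), 14)
  expect_error(compute_body_length(v[1:3]), class = "squamorph_missing_region")

  expect_equal(compute_body_depth(c(3, 3, 3, 3)), 3)
  expect_equal(compute_body_depth(1:6), mean(c(6, 5, 4, 3)))
  expect_error(compute_body_depth(c(2, 2, 2)),
               class = "squamorph_insufficient_ribs")

  # randomized cross-checks against independent summation oracles
  set.seed(42)
  for (i in 1:20) {
    lens <- lapply(1:4, function(.) runif(sample(1:8, 1), 0.5, 5))
    hts <- lapply(lens, function(l) runif(length(l), 0.5, 5))
    vv <- setNames(Map(make_vert, lens, hts), axial_regions())
    expect_equal(compute_body_length(vv), sum(unlist(lens)))
    ribs <- runif(sample(4:9, 1), 1, 10)
    expect_equal(compute_body_depth(ribs),
                 mean(rev(sort(ribs))[1:4]))
  }
})

test_that("geometric mean equals 11th root of the product", {
  expect_equal(compute_geometric_mean(rep(2, 11)), 2)
  expect_equal(compute_geometric_mean(rep(1, 11)), 1)
  set.seed(7)
  for (i in 1:10) {
    x <- runif(11, 0.1, 50)
    expect_equal(compute_geometric_mean(x), prod(x)^(1 / 11), tolerance = 1e-12)
    # scale equivariance
    expect_equal(compute_geometric_mean(3.7 * x),
                 3.7 * compute_geometric_mean(x), tolerance = 1e-12)
  }
  expect_error(compute_geometric_mean(rep(1, 10)),
               class = "squamorph_invalid_size_components")
  expect_error(compute_geometric_mean(c(rep(1, 10), -1)),
               class = "squamorph_invalid_size_components")
})

test_that("limb length modes and missingness contract", {
  all1 <- setNames(rep(1, 7), limb_bone_names())
  expect_equal(compute_limb_lengths(all1, "full"),
               c(forelimb = 4, hindlimb = 3))
  expect_equal(compute_limb_lengths(all1, "reduced"),
               c(forelimb = 2, hindlimb = 2))
  no_scap <- all1[setdiff(names(all1), "scapula")]
  expect_true(is.na(compute_limb_lengths(no_scap, "full")["forelimb"]))
  expect_equal(compute_limb_lengths(no_scap, "reduced")[["forelimb"]], 2)
  expect_equal(compute_limb_lengths(no_scap, "full")[["hindlimb"]], 3)
})

test_that("ratio statistics are invariant to uniform rescaling", {
  set.seed(11)
  base <- specimen_indices(toy_specimen())
  ratio_fields <- c("hbER", "head_ER", paste0("AEI_", axial_regions()))
  for (s in runif(5, 0.1, 40)) {
    sc <- specimen_indices(toy_specimen(scale = s))
    expect_equal(sc[ratio_fields], base[ratio_fields], tolerance = 1e-10)
    expect_equal(sc[["body_size"]], s * base[["body_size"]], tolerance = 1e-10)
  }
})

test_that("aggregate_species averages indices and honors the contracts", {
  eco <- c(spA = "tree", spB = "ground")
  r1 <- toy_specimen("s1", "spA")
  tab1 <- aggregate_species(list(r1), eco)
  expect_equal(tab1$hbER, unname(specimen_indices(r1)["hbER"]))
  expect_equal(tab1$ln_hbER, log(tab1$hbER))
  expect_equal(tab1$n_specimens, 1L)

  # two specimens with engineered hbER values average arithmetically
  r2 <- toy_specimen("s2", "spA", scale = 1.3)
  i1 <- specimen_indices(r1)["hbER"]; i2 <- specimen_indices(r2)["hbER"]
  tab2 <- aggregate_species(list(r1, r2), eco)
  expect_equal(tab2$hbER, unname((i1 + i2) / 2))

  # permutation invariance over specimen order
  r3 <- toy_specimen("s3", "spB", scale = 0.7)
  t_ab <- aggregate_species(list(r1, r2, r3), eco)
  t_ba <- aggregate_species(list(r3, r1, r2), eco)
  expect_equal(t_ab, t_ba)

  expect_error(aggregate_species(list(r1, r3), c(spA = "tree")),
               class = "squamorph_label_error")
  expect_error(aggregate_species(list(r1), c(spA = "arboreal")),
               class = "squamorph_label_error")

  # a specimen failing a precondition is excluded with a warning
  bad <- toy_specimen("s4", "spB")
  bad$rib_lengths <- bad$rib_lengths[1:3]
  expect_warning(tb <- aggregate_species(list(r1, bad, r3), eco),
                 "excluding specimen 's4'")
  expect_equal(nrow(tb), 2L)
})

test_that("measurement CSV round-trips, and the wide layout maps in", {
  eco <- c(spA = "tree", spB = "ground")
  recs <- list(toy_specimen("s1", "spA"), toy_specimen("s2", "spB", 1.4))
  p <- withr::local_tempfile(fileext = ".csv")
  write_measurements(recs, p, ecotypes = eco)
  back <- read_measurements(p)
  expect_equal(back$ecotypes, eco)
  expect_equal(specimen_indices(back$records[["s1"]]),
               specimen_indices(recs[[1]]), tolerance = 1e-12)

  # wide layout: one row per specimen, mapped column names
  wide <- data.frame(ID = "w1", SPECIES = "spA", CL = 4, CH = 2,
                     c1L = 1, c1H = 0.8, t1L = 2, t1H = 1.5,
                     l1L = 2.5, l1H = 1.8, s1L = 1.2, s1H = 1,
                     rib1 = 6, rib2 = 6, rib3 = 6, rib4 = 6)
  pw <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, pw, row.names = FALSE)
  mapping <- c(ID = "specimen_id", SPECIES = "species",
               CL = "cranial_length", CH = "cranial_height",
               c1L = "cervical1_length", c1H = "cervical1_height",
               t1L = "thoracic1_length", t1H = "thoracic1_height",
               l1L = "lumbar1_length", l1H = "lumbar1_height",
               s1L = "sacral1_length", s1H = "sacral1_height")
  got <- read_measurements(pw, mapping = mapping)
  expect_length(got$records, 1L)
  idx <- specimen_indices(got$records[[1]])
  expect_equal(unname(idx["hbER"]), (4 + 1 + 2 + 2.5 + 1.2) / 6)
  expect_equal(unname(idx["head_ER"]), 2)
})
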