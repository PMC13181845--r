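test_that("a toy screen CSV parses row for row", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    plate_id = "P1", well_id = paste0("W", 1:4),
    compound_id = c("DMSO", "A", "B", "C"), smiles = "",
    library = "L", concentration = c(NA, 1, 1, 10),
    cell_line = "E1", nuclei_count = c(100, 50, 80, 20),
    role = c("dmso", rep("treatment", 3)))
  write.csv(df, path, row.names = FALSE)
  wells <- read_screen_table(path)
  expect_s3_class(wells, "well_measurements")
  expect_equal(nrow(wells), 4)
  expect_equal(wells$compound_id, df$compound_id)
  expect_equal(nrow(attr(wells, "rejected")), 0)
})

test_that("a missing mapped column is a schema error naming the column", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(plate_id = "P1", well_id = "W1"), path,
            row.names = FALSE)
  expect_error(read_screen_table(path), "nuclei_count",
               class = "schema_error")
})

test_that("rows with invalid counts are rejected and reported, not fatal", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(
    plate_id = "P1", well_id = paste0("W", 1:3),
    compound_id = c("A", "B", "DMSO"), smiles = "", library = "L",
    concentration = c(1, 1, NA), cell_line = "E1",
    nuclei_count = c("120", "NA", "100"),
    role = c("treatment", "treatment", "dmso"))
  write.csv(df, path, row.names = FALSE)
  wells <- read_screen_table(path)
  expect_equal(nrow(wells), 2)
  rej <- attr(wells, "rejected")
  expect_equal(rej$row, 2)
  expect_match(rej$reason, "nuclei_count")
})

test_that("survival is the percent of the plate DMSO mean", {
  wells <- make_wells(
    well(100), well(100, well_id = "W2"),
    well(50, cmpd = "A", role = "treatment", conc = 1))
  prof <- normalise_to_dmso(wells)
  expect_equal(prof$survival_percent, 50)

  wells2 <- make_wells(well(100), well(100, cmpd = "A", role = "treatment",
                                       conc = 1))
  expect_equal(normalise_to_dmso(wells2)$survival_percent, 100)
})

test_that("normalisation is per plate: same count, different DMSO means", {
  wells <- make_wells(
    well(80, plate = "P1"), well(120, plate = "P2"),
    well(60, cmpd = "A", role = "treatment", conc = 1, plate = "P1"),
    well(60, cmpd = "B", role = "treatment", conc = 1, plate = "P2"))
  prof <- normalise_to_dmso(wells)
  expect_equal(prof[prof$compound_id == "A"]$survival_percent, 75)
  expect_equal(prof[prof$compound_id == "B"]$survival_percent, 50)
})

test_that("per-plate DMSO wells average to exactly 100 percent", {
  set.seed(41)
  counts <- rpois(6, 900)
  args <- lapply(seq_along(counts), function(i)
    well(counts[i], plate = "P1", well_id = paste0("D", i)))
  # a treatment well at the DMSO mean count must read exactly 100%
  args <- c(args, list(well(mean(counts), cmpd = "A", role = "treatment",
                            conc = 1, plate = "P1")))
  prof <- normalise_to_dmso(do.call(make_wells, args))
  expect_equal(prof$survival_percent, 100)
})

test_that("normalisation is invariant to rescaling all counts on a plate", {
  wells <- make_wells(
    well(100), well(110, well_id = "W2"),
    well(55, cmpd = "A", role = "treatment", conc = 1),
    well(70, cmpd = "B", role = "treatment", conc = 3))
  scaled <- data.table::copy(data.table::as.data.table(wells))
  scaled[, nuclei_count := nuclei_count * 3.7]
  expect_equal(normalise_to_dmso(scaled)$survival_percent,
               normalise_to_dmso(wells)$survival_percent)
})

test_that("plates without DMSO or with zero DMSO mean are errors", {
  no_dmso <- make_wells(well(50, cmpd = "A", role = "treatment", conc = 1))
  expect_error(normalise_to_dmso(no_dmso), "P1",
               class = "normalisation_error")
  zero <- make_wells(well(0), well(50, cmpd = "A", role = "treatment",
                                   conc = 1))
  expect_error(normalise_to_dmso(zero), "zero DMSO",
               class = "normalisation_error")
})

test_that("duplicates across libraries merge into a union profile", {
  wells <- make_wells(
    well(100, plate = "P1"), well(100, plate = "P2"),
    well(50, cmpd = "A1", smiles = "CCO", lib = "L1", role = "treatment",
         conc = 1, plate = "P1"),
    well(20, cmpd = "A2", smiles = "OCC", lib = "L2", role = "treatment",
         conc = 10, plate = "P2"))
  dd <- deduplicate_compounds(normalise_to_dmso(wells))
  expect_equal(length(unique(dd$profiles$compound_id)), 1)
  expect_equal(sort(dd$profiles$concentration), c(1, 10))
  expect_equal(dd$merge_log$absorbed_id, "A2")
  expect_equal(dd$merge_log$surviving_id, "A1")
})

test_that("unparsable SMILES are quarantined, not dropped", {
  wells <- make_wells(
    well(100),
    well(50, cmpd = "A", smiles = "CCO", role = "treatment", conc = 1),
    well(30, cmpd = "B", smiles = "not_a_smiles", role = "treatment",
         conc = 1))
  dd <- deduplicate_compounds(normalise_to_dmso(wells))
  expect_equal(dd$quarantine$compound_id, "B")
  expect_true("B" %in% dd$profiles$compound_id)
})

test_that("empty input deduplicates to empty output", {
  prof <- normalise_to_dmso(make_wells(well(100)))
  dd <- deduplicate_compounds(prof)
  expect_equal(nrow(dd$profiles), 0)
})

test_that("dedup and normalise commute without replicate collisions", {
  cfg <- screen_sim_config(
    library_specs = list(A = list(n_compounds = 30L,
                                  concentrations = c(0.1, 1)),
                         B = list(n_compounds = 20L,
                                  concentrations = c(0.5, 5))),
    n_duplicates = 6L, seed = 9)
  sim <- generate_screen(cfg)
  a <- deduplicate_compounds(normalise_to_dmso(sim$wells))$profiles
  data.table::setorder(a, compound_id, cell_line, concentration)
  # dedup-first route: relabel duplicate compound ids before normalising
  sid <- sim$truth$compound_structure
  wells2 <- data.table::as.data.table(sim$wells)
  first_id <- names(sid)[match(unique(sid), sid)]
  canon_id <- setNames(first_id[match(sid, unique(sid))], names(sid))
  wells2[role == "treatment", compound_id := canon_id[compound_id]]
  b <- normalise_to_dmso(wells2)
  data.table::setorder(b, compound_id, cell_line, concentration)
  expect_equal(a$compound_id, b$compound_id)
  expect_equal(a$survival_percent, b$survival_percent, tolerance = 1e-12)
})
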