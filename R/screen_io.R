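#' Default column mapping for long-format screen tables
#'
#' Maps the canonical well-measurement fields onto the column names of an
#' input CSV. Override individual entries to read tables exported with other
#' headers.
#'
#' @param plate_id,well_id,compound_id,smiles,library,concentration,cell_line,nuclei_count,role
#'   Column names in the input file holding each field. `role` must contain
#'   the values `"treatment"`, `"dmso"` or `"positive_control"`.
#' @return Named character vector usable as the `schema` argument of
#'   [read_screen_table()].
#' @export
screen_schema <- function(plate_id = "plate_id", well_id = "well_id",
                          compound_id = "compound_id", smiles = "smiles",
                          library = "library", concentration = "concentration",
                          cell_line = "cell_line",
                          nuclei_count = "nuclei_count", role = "role") {
  c(plate_id = plate_id, well_id = well_id, compound_id = compound_id,
    smiles = smiles, library = library, concentration = concentration,
    cell_line = cell_line, nuclei_count = nuclei_count, role = role)
}

WELL_ROLES <- c("treatment", "dmso", "positive_control")

#' Read a long-format screen table of per-well nuclei counts
#'
#' Reads one row per imaged well (plate, well, compound, concentration in
#' micromolar, cell line, nuclei count, control role) and validates it into a
#' well-measurement table. Rows that fail validation (non-numeric or negative
#' counts, unknown roles, treatment wells without a positive concentration)
#' are collected into a rejection report instead of aborting the read.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema Column mapping from [screen_schema()].
#' @return A `data.table` of class `well_measurements` with the canonical
#'   columns, row order preserved, and attribute `rejected` — a data.frame
#'   listing the file row index and reason for every rejected row.
#' @export
read_screen_table <- function(path, schema = screen_schema()) {
  if (!file.exists(path)) stop_glio(paste0("file not found: ", path), "io_error")
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(unname(schema), names(raw))
  if (length(missing) > 0) {
    stop_glio(paste0("screen table is missing mapped column(s): ",
                     paste(missing, collapse = ", ")), "schema_error")
  }
  dt <- data.table::data.table(
    plate_id = as.character(raw[[schema[["plate_id"]]]]),
    well_id = as.character(raw[[schema[["well_id"]]]]),
    compound_id = as.character(raw[[schema[["compound_id"]]]]),
    smiles = as.character(raw[[schema[["smiles"]]]]),
    library = as.character(raw[[schema[["library"]]]]),
    concentration = suppressWarnings(
      as.numeric(raw[[schema[["concentration"]]]])),
    cell_line = as.character(raw[[schema[["cell_line"]]]]),
    nuclei_count = suppressWarnings(
      as.numeric(raw[[schema[["nuclei_count"]]]])),
    role = as.character(raw[[schema[["role"]]]])
  )
  validate_wells(dt)
}

# Shared validator: returns the surviving rows with a `rejected` attribute.
validate_wells <- function(dt) {
  dt <- data.table::as.data.table(dt)
  reason <- rep(NA_character_, nrow(dt))
  bad_count <- is.na(dt$nuclei_count) | dt$nuclei_count < 0
  reason[bad_count] <- "nuclei_count missing, non-numeric or negative"
  bad_role <- !(dt$role %in% WELL_ROLES)
  reason[bad_role & is.na(reason)] <- "unknown well role"
  bad_conc <- dt$role == "treatment" &
    (is.na(dt$concentration) | dt$concentration <= 0)
  reason[bad_conc & is.na(reason)] <-
    "treatment well without positive concentration"
  rejected <- data.frame(row = which(!is.na(reason)),
                         reason = reason[!is.na(reason)])
  out <- dt[is.na(reason)]
  out[role != "treatment", concentration := NA_real_]
  data.table::setattr(out, "rejected", rejected)
  data.table::setattr(out, "class",
                      c("well_measurements", class(out)))
  out[]
}

#' Normalise nuclei counts to the plate DMSO mean
#'
#' Converts raw per-well nuclei counts into percent survival relative to the
#' mean DMSO (vehicle) count on the same plate and cell line, so that 100
#' means no effect. Wells sharing (plate, compound, concentration, cell line)
#' are averaged before normalisation, and a compound measured on several
#' plates has its per-plate survival values averaged into one profile cell.
#' Survival is not capped: values above 100 (proliferation) are retained.
#'
#' @param wells A `well_measurements` table from [read_screen_table()] or
#'   [generate_screen()].
#' @return A `data.table` of class `viability_profiles`, one row per
#'   compound x cell line x concentration, with columns `compound_id`,
#'   `smiles`, `library`, `cell_line`, `concentration`, `survival_percent`
#'   and `n_wells` (replicate wells behind the value).
#' @export
normalise_to_dmso <- function(wells) {
  wells <- data.table::as.data.table(wells)
  dmso <- wells[role == "dmso",
                .(dmso_mean = mean(nuclei_count)),
                by = .(plate_id, cell_line)]
  trt <- wells[role == "treatment"]
  plates_used <- unique(trt[, .(plate_id, cell_line)])
  no_ctrl <- plates_used[!dmso, on = c("plate_id", "cell_line")]
  if (nrow(no_ctrl) > 0) {
    stop_glio(paste0("plate(s) without DMSO control wells: ",
                     paste(unique(no_ctrl$plate_id), collapse = ", ")),
              "normalisation_error")
  }
  if (any(dmso$dmso_mean == 0)) {
    stop_glio(paste0("plate(s) with zero DMSO mean count: ",
                     paste(unique(dmso[dmso_mean == 0]$plate_id),
                           collapse = ", ")), "normalisation_error")
  }
  trt <- dmso[trt, on = c("plate_id", "cell_line")]
  # replicate wells on one plate first, then across plates
  per_plate <- trt[, .(survival = 100 * mean(nuclei_count) / dmso_mean[1],
                       n_wells = .N),
                   by = .(plate_id, compound_id, smiles, library,
                          cell_line, concentration)]
  prof <- per_plate[, .(survival_percent = mean(survival),
                        n_wells = sum(n_wells)),
                    by = .(compound_id, smiles, library, cell_line,
                           concentration)]
  data.table::setorder(prof, compound_id, cell_line, concentration)
  data.table::setattr(prof, "class",
                      c("viability_profiles", class(prof)))
  prof[]
}

#' Merge duplicate compounds across libraries
#'
#' Screens assembled from several vendor libraries usually contain the same
#' molecule more than once. Profiles sharing a key — by default the
#' salt-stripped canonical structure — are merged into a single profile: the
#' union of their cell line x concentration cells, with replicate means where
#' cells collide. Compounds whose SMILES cannot be parsed are routed to a
#' quarantine list, never silently dropped.
#'
#' @param profiles A `viability_profiles` table from [normalise_to_dmso()].
#' @param key `"canonical_structure"` (default) to merge on the canonical
#'   salt-stripped SMILES, or `"compound_id"` for data without structures.
#' @return A list with elements `profiles` (deduplicated
#'   `viability_profiles`, one surviving `compound_id` per key), `merge_log`
#'   (data.frame mapping each absorbed compound id to its surviving id) and
#'   `quarantine` (data.frame of compounds with unparsable SMILES, untouched
#'   by merging).
#' @export
deduplicate_compounds <- function(profiles,
                                  key = c("canonical_structure",
                                          "compound_id")) {
  key <- match.arg(key)
  prof <- data.table::as.data.table(profiles)
  if (nrow(prof) == 0) {
    return(list(profiles = prof, merge_log = data.frame(),
                quarantine = data.frame()))
  }
  cmpd <- unique(prof[, .(compound_id, smiles)])
  quarantine <- data.frame()
  if (key == "compound_id") {
    cmpd[, key := compound_id]
  } else {
    can <- canonicalise_smiles(cmpd$smiles, on_error = "na")
    bad <- is.na(can)
    if (any(bad)) {
      quarantine <- data.frame(compound_id = cmpd$compound_id[bad],
                               smiles = cmpd$smiles[bad],
                               reason = "unparsable SMILES")
    }
    cmpd[, key := can]
    cmpd <- cmpd[!bad]
  }
  # first-seen compound id survives per key
  cmpd[, keep_id := compound_id[1], by = key]
  merge_log <- as.data.frame(
    cmpd[compound_id != keep_id,
         .(absorbed_id = compound_id, surviving_id = keep_id)])
  keep_map <- cmpd[, .(compound_id, keep_id, key)]
  merged <- keep_map[prof, on = "compound_id", nomatch = NULL]
  merged <- merged[, .(survival_percent =
                         sum(survival_percent * n_wells) / sum(n_wells),
                       n_wells = sum(n_wells),
                       smiles = smiles[1], library = library[1]),
                   by = .(compound_id = keep_id, cell_line, concentration)]
  quarantined <- prof[compound_id %in% quarantine$compound_id]
  out <- data.table::rbindlist(list(
    merged[, .(compound_id, smiles, library, cell_line, concentration,
               survival_percent, n_wells)],
    quarantined[, .(compound_id, smiles, library, cell_line, concentration,
                    survival_percent, n_wells)]))
  data.table::setorder(out, compound_id, cell_line, concentration)
  data.table::setattr(out, "class", c("viability_profiles", class(out)))
  list(profiles = out[], merge_log = merge_log, quarantine = quarantine)
}

#' Write viability profiles as a tidy CSV
#'
#' @param profiles A `viability_profiles` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  utils::write.csv(as.data.frame(profiles), path, row.names = FALSE)
  invisible(path)
}
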