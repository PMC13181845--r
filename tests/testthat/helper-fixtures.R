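# Small well-table builder for hand-arithmetic tests.
make_wells <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(plate_id = r$plate %||% "P1", well_id = r$well %||% "W1",
               compound_id = r$cmpd %||% "DMSO", smiles = r$smiles %||% "",
               library = r$lib %||% "L", concentration = r$conc %||% NA_real_,
               cell_line = r$line %||% "E1", nuclei_count = r$count,
               role = r$role %||% "treatment")
  }))
  glioscreen:::validate_wells(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

well <- function(count, cmpd = "DMSO", role = "dmso", plate = "P1",
                 conc = NA_real_, line = "E1", lib = "L", smiles = "",
                 well_id = NULL) {
  list(count = count, cmpd = cmpd, role = role, plate = plate, conc = conc,
       line = line, lib = lib, smiles = smiles,
       well = well_id %||% paste0("W", sample.int(1e6, 1)))
}

# Single-compound profile table for labelling tests: survivals is a matrix
# (concentrations x cell lines) or a named list conc -> per-line survivals.
make_profile <- function(survivals, compound_id = "C1") {
  concs <- as.numeric(rownames(survivals))
  lines <- colnames(survivals)
  data.frame(compound_id = compound_id,
             smiles = "", library = "L",
             cell_line = rep(lines, each = length(concs)),
             concentration = rep(concs, length(lines)),
             survival_percent = as.vector(survivals))
}

surv_matrix <- function(concs, ...) {
  vals <- list(...)
  m <- do.call(cbind, vals)
  rownames(m) <- as.character(concs)
  colnames(m) <- names(vals)
  m
}

# A handful of real drug SMILES (typed from their public structures) for
# canonicalisation round-trips without any download.
drug_smiles <- c(
  ethanol = "CCO",
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  alanine = "C[C@H](N)C(=O)O",
  ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  naproxen = "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
  temozolomide = "Cn1nnc2c(c1=O)c(ncn2)C(=O)N"
)
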