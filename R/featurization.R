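#' Canonicalise SMILES with salt stripping
#'
#' Splits each SMILES on `"."`, keeps the largest organic fragment (most
#' heavy atoms among fragments containing carbon; the whole string when no
#' fragment contains carbon), and converts it to OpenBabel canonical SMILES.
#' Stereochemistry in the input is preserved, so isomeric SMILES stay
#' isomeric. The operation is idempotent: canonical input returns unchanged.
#'
#' @param smiles Character vector of SMILES strings.
#' @param on_error `"error"` (default) to raise a parse error naming the
#'   offending strings, `"na"` to return `NA` for unparsable entries so the
#'   caller can quarantine them.
#' @return Character vector of canonical salt-stripped SMILES.
#' @export
canonicalise_smiles <- function(smiles, on_error = c("error", "na")) {
  on_error <- match.arg(on_error)
  smiles <- as.character(smiles)
  out <- rep(NA_character_, length(smiles))
  nonblank <- !is.na(smiles) & nzchar(trimws(smiles))
  frags <- vapply(smiles[nonblank], largest_organic_fragment, "",
                  USE.NAMES = FALSE)
  out[nonblank] <- ob_canonical(frags)
  if (on_error == "error" && any(is.na(out) & nonblank)) {
    bad <- smiles[is.na(out) & nonblank]
    stop_glio(paste0("unparsable SMILES: ",
                     paste(utils::head(bad, 5), collapse = ", ")),
              "smiles_parse_error")
  }
  if (on_error == "error" && any(!nonblank)) {
    stop_glio("empty SMILES string", "smiles_parse_error")
  }
  out
}

# Heavy-atom count of a SMILES fragment, by token scan. Bracket atoms count
# as one heavy atom unless they are explicit hydrogens.
smiles_heavy_atoms <- function(s) {
  toks <- regmatches(s, gregexpr(
    "Cl|Br|\\[[^]]*\\]|[BCNOPSFIbcnops]", s))[[1]]
  elems <- ifelse(grepl("^\\[", toks),
                  sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", toks), toks)
  sum(!(elems %in% c("H", "h")))
}

smiles_has_carbon <- function(s) {
  toks <- regmatches(s, gregexpr(
    "Cl|Br|\\[[^]]*\\]|[BCNOPSFIbcnops]", s))[[1]]
  elems <- ifelse(grepl("^\\[", toks),
                  sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", toks), toks)
  any(elems %in% c("C", "c"))
}

largest_organic_fragment <- function(s) {
  parts <- strsplit(trimws(s), ".", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) <= 1) return(trimws(s))
  organic <- vapply(parts, smiles_has_carbon, TRUE)
  if (any(organic)) parts <- parts[organic]
  sizes <- vapply(parts, smiles_heavy_atoms, 0L)
  parts[which.max(sizes)]
}

# Canonicalise a vector of single-fragment SMILES through OpenBabel.
# Conversion is chunked; OpenBabel aborts a batch at the first bad string,
# so any chunk that comes back short is redone molecule by molecule and
# failures become NA. Output/input alignment uses per-line integer titles.
ob_canonical <- function(smi, chunk = 500L) {
  n <- length(smi)
  out <- rep(NA_character_, n)
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    res <- ob_can_batch(smi[idx], idx)
    short <- idx[is.na(res[as.character(idx)])]
    for (i in short) {
      one <- tryCatch(ob_can_batch(smi[i], i), error = function(e) NULL)
      if (!is.null(one)) res[as.character(i)] <- one[as.character(i)]
    }
    out[idx] <- res[as.character(idx)]
  }
  out
}

ob_can_batch <- function(smi, ids) {
  inp <- paste(paste(smi, ids), collapse = "\n")
  res <- tryCatch(ChemmineOB::convertFormat("SMI", "CAN", inp),
                  error = function(e) "")
  lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  got <- stats::setNames(
    trimws(vapply(fields, `[`, "", 1L)),
    trimws(vapply(fields, function(f) f[2] %||% NA_character_, "")))
  out <- rep(NA_character_, length(ids))
  names(out) <- as.character(ids)
  hit <- intersect(names(got), names(out))
  out[hit] <- got[hit]
  out[!nzchar(out) | is.na(out)] <- NA_character_
  out
}

#' Compute physicochemical descriptors for canonical SMILES
#'
#' Featurises each molecule with the toolkit's full numeric property set:
#' OpenBabel's calculated properties (molecular weight, logP, molar
#' refractivity, TPSA, hydrogen-bond donor/acceptor counts, atom and bond
#' counts by order) plus per-element heavy-atom counts. Descriptor names are
#' stable and the code downstream keys on names, never on the count.
#' Non-finite descriptor values are imputed to 0 with a warning.
#'
#' @param smiles Character vector of canonicalised SMILES.
#' @return A numeric feature matrix (provenance `"raw"`), one row per
#'   molecule (rownames = `names(smiles)` if set, else the SMILES), one
#'   column per descriptor.
#' @export
compute_descriptors <- function(smiles) {
  if (length(smiles) == 0) stop_glio("no SMILES given", "input_error")
  sdf <- ChemmineR::smiles2sdf(smiles)
  props <- ChemmineR::propOB(sdf)
  num_cols <- intersect(
    c("HBA1", "HBA2", "HBD", "logP", "MR", "MW", "nF", "TPSA"),
    names(props))
  m <- as.matrix(props[, num_cols, drop = FALSE])
  bonds <- ChemmineR::bondblock(sdf)
  atoms <- ChemmineR::atomblock(sdf)
  elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I")
  counts <- t(vapply(smiles, smiles_element_counts, numeric(length(elements)),
                     elements = elements))
  colnames(counts) <- paste0("n_", elements)
  m <- cbind(m, counts,
             heavy_atoms = vapply(smiles, smiles_heavy_atoms, 0L),
             n_atoms = vapply(atoms, nrow, 0L),
             n_bonds = vapply(bonds, nrow, 0L),
             n_double_bonds = vapply(bonds, function(b)
               sum(b[, 3] == 2), 0),
             n_aromatic_atoms = vapply(smiles, function(s)
               smiles_heavy_atoms(s) - smiles_heavy_atoms(
                 gsub("[bcnops]|\\[[0-9]*[a-z][^]]*\\]", "", s)), 0))
  if (any(!is.finite(m))) {
    warning("non-finite descriptor values imputed to 0")
    m[!is.finite(m)] <- 0
  }
  rownames(m) <- names(smiles) %||% smiles
  new_feature_matrix(m, provenance = "raw")
}

smiles_element_counts <- function(s, elements) {
  toks <- regmatches(s, gregexpr(
    "Cl|Br|\\[[^]]*\\]|[BCNOPSFIbcnops]", s))[[1]]
  elems <- ifelse(grepl("^\\[", toks),
                  sub("^\\[[0-9]*([A-Za-z][a-z]?).*$", "\\1", toks), toks)
  elems <- ifelse(elems %in% c("b", "c", "n", "o", "p", "s"),
                  toupper(elems), elems)
  vapply(elements, function(e) sum(elems == e), 0)
}

new_feature_matrix <- function(m, provenance, scaler = NULL) {
  stopifnot(is.matrix(m), is.numeric(m), !is.null(colnames(m)),
            !anyDuplicated(colnames(m)))
  attr(m, "provenance") <- provenance
  attr(m, "scaler") <- scaler
  m
}

#' Provenance of a feature matrix
#' @param m A feature matrix.
#' @return One of `"raw"`, `"constant_filtered"`, `"importance_selected"`,
#'   `"zscored"`.
#' @export
feature_provenance <- function(m) attr(m, "provenance") %||% "raw"

#' Drop features constant across all compounds
#'
#' @param m A raw feature matrix.
#' @return The matrix without zero-variance columns, provenance
#'   `"constant_filtered"`, with attribute `dropped_features` naming the
#'   removed columns. Errors if every feature is constant.
#' @export
drop_constant_features <- function(m) {
  rng <- apply(m, 2, function(x) diff(range(x)))
  constant <- rng == 0
  if (all(constant)) stop_glio("all features are constant", "input_error")
  out <- new_feature_matrix(m[, !constant, drop = FALSE],
                            provenance = "constant_filtered")
  attr(out, "dropped_features") <- colnames(m)[constant]
  out
}

#' Select features by Gini impurity importance
#'
#' Fits a random forest on the full labelled set and keeps the features whose
#' mean decrease in Gini impurity is strictly positive; zero-importance
#' features carry no signal (impurity importances are never negative). The
#' selection is performed once, globally, before the Monte-Carlo training
#' loop.
#'
#' @param m A constant-filtered feature matrix.
#' @param labels Binary labels (0/1 or factor) aligned to `m`'s rows.
#' @param seed Integer seed for the forest.
#' @param num_trees Number of trees. Default 500.
#' @return The matrix restricted to retained columns, provenance
#'   `"importance_selected"`, with attribute `importance_table` — a
#'   data.frame of every input feature's importance and whether it was kept.
#' @export
select_features_by_importance <- function(m, labels, seed = 1L,
                                          num_trees = 500L) {
  y <- factor(labels)
  if (nlevels(y) < 2) stop_glio("labels contain a single class", "input_error")
  fit <- ranger::ranger(x = as.data.frame(unclass(m)), y = y,
                        importance = "impurity", num.trees = num_trees,
                        seed = seed, num.threads = 1)
  imp <- fit$variable.importance[colnames(m)]
  keep <- imp > 0
  tab <- data.frame(feature = colnames(m), importance = unname(imp),
                    kept = unname(keep))
  tab <- tab[order(-tab$importance), ]
  out <- new_feature_matrix(m[, keep, drop = FALSE],
                            provenance = "importance_selected")
  attr(out, "importance_table") <- tab
  out
}

#' Z-score a feature matrix
#'
#' Per-feature mean and standard deviation are estimated on `fit_rows` only
#' and applied to every row, so held-out or screening rows are scaled with
#' the training statistics (no leakage). Features with zero standard
#' deviation on the fit rows map to 0 with a warning.
#'
#' @param m A feature matrix.
#' @param fit_rows Row indices to estimate the scaler on. Default all rows.
#' @return The scaled matrix, provenance `"zscored"`, carrying the scaler
#'   (`attr(, "scaler")`, a list with `mean` and `sd`) that produced it.
#' @export
zscore_features <- function(m, fit_rows = seq_len(nrow(m))) {
  if (length(fit_rows) == 0) stop_glio("empty fit_rows", "input_error")
  mu <- colMeans(m[fit_rows, , drop = FALSE])
  sdv <- apply(m[fit_rows, , drop = FALSE], 2, stats::sd)
  if (any(sdv == 0)) {
    warning("zero-variance feature(s) on fit rows mapped to 0: ",
            paste(colnames(m)[sdv == 0], collapse = ", "))
  }
  scaler <- list(mean = mu, sd = sdv)
  new_feature_matrix(apply_scaler(m, scaler), provenance = "zscored",
                     scaler = scaler)
}

#' Apply a stored z-score scaler to new rows
#' @param m Feature matrix on the raw scale (same feature names as the
#'   scaler).
#' @param scaler A scaler list (`mean`, `sd`) from [zscore_features()].
#' @return Scaled numeric matrix.
#' @export
apply_scaler <- function(m, scaler) {
  if (!setequal(colnames(m), names(scaler$mean))) {
    stop_glio("feature names do not match the scaler", "feature_mismatch")
  }
  m <- m[, names(scaler$mean), drop = FALSE]
  sdv <- scaler$sd
  out <- sweep(m, 2, scaler$mean, "-")
  out <- sweep(out, 2, ifelse(sdv == 0, 1, sdv), "/")
  out[, sdv == 0] <- 0
  out
}
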