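#' Default library layout of the simulated screen
#'
#' Five libraries with the screen's sizes and concentration grids: C3L (786
#' compounds at 0.003/0.03/0.3/3 uM), KCGS (187 at 0.1/1), LOPAC (1277 at
#' 0.5/3), Prestwick (1276 at 1/10) and TargetMol (330 at 0.01/0.1/1/10),
#' 3856 compounds in total.
#'
#' @return Named list: per library, the compound count and concentration
#'   grid (uM).
#' @export
default_library_specs <- function() {
  list(
    C3L = list(n_compounds = 786L, concentrations = c(0.003, 0.03, 0.3, 3)),
    KCGS = list(n_compounds = 187L, concentrations = c(0.1, 1)),
    LOPAC = list(n_compounds = 1277L, concentrations = c(0.5, 3)),
    Prestwick = list(n_compounds = 1276L, concentrations = c(1, 10)),
    TargetMol = list(n_compounds = 330L, concentrations = c(0.01, 0.1, 1, 10))
  )
}

#' Configuration of the synthetic screen generator
#'
#' Defines the simulated study: library layout, a panel of heterogeneous
#' cell lines, per-compound Hill dose-responses for the planted actives,
#' plate structure with DMSO and positive-control wells, and multiplicative
#' lognormal count noise. Planted actives are drawn so that, noiselessly,
#' they satisfy the positive labelling rule (at or below the survival cutoff
#' in at least `min_lines` but not all lines at the chosen concentration);
#' the number of sensitive lines is uniform over 2..(n_cell_lines - 1).
#'
#' @param library_specs Library layout as in [default_library_specs()].
#' @param n_cell_lines Number of cell lines in the panel. Default 6.
#' @param fraction_true_active Fraction of compounds that are true actives.
#'   Default 0.03 (close to the screen's 2.9% positive rate).
#' @param ic50_range Log-uniform range for sensitive-line IC50s, expressed
#'   as fractions of each library's top concentration. Default
#'   `c(1/30, 1/5)` so the top dose sits well past the midpoint.
#' @param hill_range Uniform range of Hill slopes. Default `c(1.5, 3)`.
#' @param plate_size Treatment wells per plate. Default 320.
#' @param n_dmso_wells DMSO wells per plate. Default 16.
#' @param n_positive_control_wells Positive-control wells per plate
#'   (staurosporine/paclitaxel-like, fixed 30% survival). Default 8.
#' @param baseline_count Mean plate DMSO nuclei count. Default 1500.
#' @param plate_effect_cv Between-plate lognormal CV of the baseline count.
#'   Default 0.1.
#' @param noise_cv Within-plate lognormal CV on well counts (0 =
#'   noiseless). Default 0.1.
#' @param noise_model `"lognormal"` (default; plate-dominated multiplicative
#'   noise) or `"poisson"`.
#' @param n_duplicates Structural duplicates planted across libraries
#'   (re-emissions of an earlier compound under a new id). Default 295, so
#'   the default screen holds 3856 compounds, 3561 unique.
#' @param label_cfg The [label_config()] the ground-truth labels are
#'   computed against.
#' @param seed Seed; the seed and config fully determine the output.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(library_specs = default_library_specs(),
                              n_cell_lines = 6L,
                              fraction_true_active = 0.03,
                              ic50_range = c(1 / 30, 1 / 5),
                              hill_range = c(1.5, 3),
                              plate_size = 320L, n_dmso_wells = 16L,
                              n_positive_control_wells = 8L,
                              baseline_count = 1500,
                              plate_effect_cv = 0.1, noise_cv = 0.1,
                              noise_model = c("lognormal", "poisson"),
                              n_duplicates = 295L,
                              label_cfg = label_config(), seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(fraction_true_active >= 0, fraction_true_active <= 1,
            n_cell_lines >= 3, plate_size >= 1, n_dmso_wells >= 1)
  for (spec in library_specs) {
    stopifnot(all(spec$concentrations > 0),
              !is.unsorted(spec$concentrations))
  }
  structure(list(library_specs = library_specs,
                 n_cell_lines = as.integer(n_cell_lines),
                 fraction_true_active = fraction_true_active,
                 ic50_range = ic50_range, hill_range = hill_range,
                 plate_size = as.integer(plate_size),
                 n_dmso_wells = as.integer(n_dmso_wells),
                 n_positive_control_wells =
                   as.integer(n_positive_control_wells),
                 baseline_count = baseline_count,
                 plate_effect_cv = plate_effect_cv, noise_cv = noise_cv,
                 noise_model = noise_model,
                 n_duplicates = as.integer(n_duplicates),
                 label_cfg = label_cfg, seed = as.integer(seed)),
            class = "screen_sim_config")
}

# Hill survival fraction (1 = untouched) at dose d.
hill_survival <- function(dose, ic50, slope) 1 / (1 + (dose / ic50)^slope)

# Random valid unbranched heteroatom-chain SMILES, unique as molecules:
# each chain is stored as the lexicographic minimum of itself and its
# reversal, so no two generated strings denote the same linear molecule.
random_chain_smiles <- function(n) {
  atoms <- c("C", "C", "C", "C", "N", "O", "S")
  out <- character(0)
  seen <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    cand <- vapply(seq_len(need * 2), function(i) {
      s <- sample(atoms, sample(8:16, 1), replace = TRUE)
      fwd <- paste(s, collapse = "")
      rev <- paste(rev(s), collapse = "")
      min(fwd, rev)
    }, "")
    cand <- setdiff(unique(cand), seen)
    seen <- c(seen, cand)
    out <- c(out, cand)
  }
  out[seq_len(n)]
}

#' Generate a synthetic multi-library phenotypic screen
#'
#' Emits per-well nuclei counts for the configured libraries, cell lines and
#' concentration grids, with per-plate DMSO and positive-control wells, and
#' the ground truth needed to verify every downstream module: each
#' compound's true-active flag, sensitive lines, Hill parameters and the
#' label the rule assigns in the noiseless limit.
#'
#' Expected well counts are `baseline x Hill survival` for treatment wells
#' (survival 1 for inactives), drawn through the configured noise model and
#' rounded to integers. Planted duplicates re-emit earlier compounds'
#' structures under fresh compound ids in later libraries.
#'
#' @param cfg A [screen_sim_config()].
#' @return List of class `synthetic_screen`: `wells` (a `well_measurements`
#'   table), `truth` (per unique structure: `active`, `expected_label`,
#'   `sensitive_lines`; plus Hill parameter tables), `compounds` (one row
#'   per emitted compound, duplicates included).
#' @export
generate_screen <- function(cfg = screen_sim_config()) {
  with_seed(cfg$seed, generate_screen_impl(cfg))
}

generate_screen_impl <- function(cfg) {
  specs <- cfg$library_specs
  n_total <- sum(vapply(specs, function(s) s$n_compounds, 0L))
  if (cfg$n_duplicates >= n_total) {
    stop_glio("n_duplicates must be below the total compound count",
              "config_error")
  }
  n_unique <- n_total - cfg$n_duplicates
  lines <- sprintf("LINE%02d", seq_len(cfg$n_cell_lines))

  # unique structures first, then re-emission slots for duplicates
  smiles_pool <- random_chain_smiles(n_unique)
  n_active <- round(cfg$fraction_true_active * n_unique)
  active <- c(rep(TRUE, n_active), rep(FALSE, n_unique - n_active))
  active <- sample(active)

  # per-structure Hill truth; actives are redrawn until the noiseless
  # labelling rule accepts them (guaranteed-positive planting)
  ic50 <- matrix(Inf, n_unique, cfg$n_cell_lines,
                 dimnames = list(NULL, lines))
  slope <- matrix(1, n_unique, cfg$n_cell_lines,
                  dimnames = list(NULL, lines))
  struct_lib <- rep(NA_character_, n_unique)
  # assign each unique structure a home library (fills specs in order)
  lib_names <- names(specs)
  lib_sizes <- vapply(specs, function(s) s$n_compounds, 0L)
  dup_per_lib <- draw_duplicate_slots(lib_sizes, cfg$n_duplicates)
  unique_per_lib <- lib_sizes - dup_per_lib
  struct_lib <- rep(lib_names, unique_per_lib)
  sensitive <- vector("list", n_unique)
  for (i in which(active)) {
    grid <- specs[[struct_lib[i]]]$concentrations
    drawn <- draw_active_truth(grid, cfg, lines)
    ic50[i, ] <- drawn$ic50
    slope[i, ] <- drawn$slope
    sensitive[[i]] <- drawn$sensitive
  }
  expected_label <- vapply(seq_len(n_unique), function(i) {
    noiseless_label(specs[[struct_lib[i]]]$concentrations,
                    ic50[i, ], slope[i, ], cfg$label_cfg)
  }, "")

  # emitted compounds: uniques in their home library + duplicate
  # re-emissions of randomly chosen earlier structures
  structures <- data.frame(
    structure_id = seq_len(n_unique), smiles = smiles_pool,
    library = struct_lib, active = active,
    expected_label = expected_label, stringsAsFactors = FALSE)
  emit <- structures[, c("structure_id", "smiles", "library")]
  for (lb in lib_names[dup_per_lib > 0]) {
    donors <- sample(which(structures$library != lb), dup_per_lib[lb])
    emit <- rbind(emit, data.frame(structure_id = donors,
                                   smiles = structures$smiles[donors],
                                   library = lb))
  }
  emit <- emit[order(match(emit$library, lib_names)), ]
  emit$compound_id <- sprintf("CMP%05d", seq_len(nrow(emit)))

  wells <- build_wells(emit, structures, ic50, slope, specs, lines, cfg)
  truth <- list(structures = structures, ic50 = ic50, slope = slope,
                sensitive_lines = sensitive,
                compound_structure = stats::setNames(emit$structure_id,
                                                     emit$compound_id))
  structure(list(wells = wells, truth = truth, compounds = emit),
            class = "synthetic_screen")
}

# Spread duplicate re-emissions over libraries (never more than a library's
# size; later libraries preferred, mimicking cross-library overlap).
draw_duplicate_slots <- function(lib_sizes, n_dup) {
  slots <- stats::setNames(integer(length(lib_sizes)), names(lib_sizes))
  if (n_dup == 0 || length(lib_sizes) < 2) return(slots)
  probs <- lib_sizes / sum(lib_sizes)
  draw <- table(sample(names(lib_sizes), n_dup, replace = TRUE,
                       prob = probs))
  slots[names(draw)] <- as.integer(draw)
  # a library cannot be pure duplicates of itself; cap and respill
  over <- pmax(slots - (lib_sizes - 1L), 0L)
  slots <- slots - over
  spill <- sum(over)
  while (spill > 0) {
    room <- which(slots < lib_sizes - 1L)
    take <- room[seq_len(min(spill, length(room)))]
    slots[take] <- slots[take] + 1L
    spill <- spill - length(take)
  }
  slots
}

# Draw Hill parameters for one active until the noiseless labelling rule
# calls it positive with some slack to every decision boundary, so that
# integer rounding of well counts cannot flip a noiseless label.
draw_active_truth <- function(grid, cfg, lines, max_tries = 200L,
                              margin = 0.5) {
  top <- max(grid)
  for (try in seq_len(max_tries)) {
    k <- sample(2:(length(lines) - 1L), 1)
    sens <- sample(lines, k)
    ic <- stats::setNames(rep(Inf, length(lines)), lines)
    sl <- stats::setNames(rep(1, length(lines)), lines)
    ic[sens] <- top * exp(stats::runif(k, log(cfg$ic50_range[1]),
                                       log(cfg$ic50_range[2])))
    sl[sens] <- stats::runif(k, cfg$hill_range[1], cfg$hill_range[2])
    if (noiseless_label(grid, ic, sl, cfg$label_cfg) == "positive" &&
        rule_margin(grid, ic, sl, cfg$label_cfg) >= margin) {
      return(list(ic50 = ic, slope = sl, sensitive = sens))
    }
  }
  stop_glio("could not draw a rule-satisfying active", "config_error")
}

# Smallest slack (in survival percentage points) between a compound's exact
# survival surface and any decision boundary of the labelling rule: the
# impact threshold, the choice among impacting concentrations, and the
# per-line survival cutoff at the chosen concentration.
rule_margin <- function(grid, ic50, slope, label_cfg) {
  surv <- 100 * outer(grid, seq_along(ic50),
                      function(d, j) hill_survival(d, ic50[j], slope[j]))
  means <- rowMeans(surv)
  m_impact <- min(abs(means - label_cfg$impact_threshold_percent))
  impacting <- which(means < label_cfg$impact_threshold_percent)
  if (length(impacting) == 0) return(m_impact)
  dist <- abs(means[impacting] - label_cfg$midpoint_target_percent)
  star <- impacting[order(dist, grid[impacting])][1]
  m_choice <- if (length(impacting) > 1) {
    d_sorted <- sort(dist)
    d_sorted[2] - d_sorted[1]
  } else Inf
  m_cutoff <- min(abs(surv[star, ] - label_cfg$survival_cutoff_percent))
  min(m_impact, m_choice, m_cutoff)
}

# Label a compound from its exact Hill survival surface.
noiseless_label <- function(grid, ic50, slope, label_cfg) {
  surv <- 100 * outer(grid, seq_along(ic50),
                      function(d, j) hill_survival(d, ic50[j], slope[j]))
  prof <- data.frame(
    compound_id = "x",
    cell_line = rep(names(ic50) %||% as.character(seq_along(ic50)),
                    each = length(grid)),
    concentration = rep(grid, length(ic50)),
    survival_percent = as.vector(surv))
  label_compound(prof, label_cfg)$label
}

# Assemble the well table: per (library, cell line, concentration),
# treatment wells chunked into plates with DMSO and positive controls.
build_wells <- function(emit, structures, ic50, slope, specs, lines, cfg) {
  plate_counter <- 0L
  blocks <- list()
  for (lb in names(specs)) {
    lib_rows <- emit[emit$library == lb, ]
    grid <- specs[[lb]]$concentrations
    n_cmp <- nrow(lib_rows)
    n_plates <- ceiling(n_cmp / cfg$plate_size)
    plate_of <- rep(seq_len(n_plates), each = cfg$plate_size)[seq_len(n_cmp)]
    for (line in lines) {
      for (conc in grid) {
        for (p in seq_len(n_plates)) {
          plate_counter <- plate_counter + 1L
          pid <- sprintf("P%04d", plate_counter)
          rows <- lib_rows[plate_of == p, ]
          sid <- rows$structure_id
          surv <- hill_survival(conc, ic50[cbind(sid, match(line, lines))],
                                slope[cbind(sid, match(line, lines))])
          base <- cfg$baseline_count *
            noise_factor(1, cfg$plate_effect_cv)
          n_t <- nrow(rows)
          trt_mu <- base * surv
          ctrl_mu <- rep(base, cfg$n_dmso_wells)
          pos_mu <- rep(base * 0.3, cfg$n_positive_control_wells)
          mu <- c(trt_mu, ctrl_mu, pos_mu)
          counts <- draw_counts(mu, cfg)
          n_w <- length(mu)
          blocks[[length(blocks) + 1L]] <- data.table::data.table(
            plate_id = pid,
            well_id = sprintf("W%03d", seq_len(n_w)),
            compound_id = c(rows$compound_id,
                            rep("DMSO", cfg$n_dmso_wells),
                            rep("POSCTRL", cfg$n_positive_control_wells)),
            smiles = c(rows$smiles,
                       rep("", n_w - n_t)),
            library = lb,
            concentration = c(rep(conc, n_t), rep(NA_real_, n_w - n_t)),
            cell_line = line,
            nuclei_count = counts,
            role = c(rep("treatment", n_t),
                     rep("dmso", cfg$n_dmso_wells),
                     rep("positive_control",
                         cfg$n_positive_control_wells)))
        }
      }
    }
  }
  wells <- data.table::rbindlist(blocks)
  data.table::setattr(wells, "class",
                      c("well_measurements", class(wells)))
  wells[]
}

# Mean-preserving multiplicative lognormal factor(s).
noise_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

draw_counts <- function(mu, cfg) {
  if (cfg$noise_model == "poisson") {
    return(stats::rpois(length(mu), mu))
  }
  round(mu * noise_factor(length(mu), cfg$noise_cv))
}

#' Generate class-conditional Gaussian features with known signal
#'
#' Stand-in for descriptor space in classifier tests: informative features
#' differ in mean by `effect_size` standard deviations between classes, the
#' rest are pure noise, and constant columns can be planted to exercise the
#' constant-feature filter.
#'
#' @param n_pos,n_neg Class sizes.
#' @param n_features Total feature count (default 200).
#' @param n_informative Features carrying class signal (default 10).
#' @param effect_size Between-class mean shift in sd units.
#' @param n_constant Constant columns planted among the features
#'   (default 0).
#' @param seed Seed.
#' @return List: `features` (raw feature matrix, rows
#'   `POS...`/`NEG...`), `labels` (integer 0/1), `informative` (names of
#'   signal features), `constant` (names of planted constants).
#' @export
generate_labelled_features <- function(n_pos, n_neg, n_features = 200L,
                                       n_informative = 10L, effect_size = 1,
                                       n_constant = 0L, seed = 1L) {
  stopifnot(n_pos >= 1, n_neg >= 1,
            n_informative + n_constant <= n_features)
  with_seed(seed, {
    n <- n_pos + n_neg
    labels <- c(rep(1L, n_pos), rep(0L, n_neg))
    m <- matrix(stats::rnorm(n * n_features), n, n_features)
    colnames(m) <- sprintf("f%03d", seq_len(n_features))
    rownames(m) <- sprintf("%s%05d", ifelse(labels == 1, "POS", "NEG"),
                           seq_len(n))
    informative <- colnames(m)[seq_len(n_informative)]
    m[labels == 1, seq_len(n_informative)] <-
      m[labels == 1, seq_len(n_informative)] + effect_size
    constant <- character(0)
    if (n_constant > 0) {
      const_idx <- (n_features - n_constant + 1L):n_features
      m[, const_idx] <- rep(stats::runif(n_constant, -1, 1),
                            each = n)
      constant <- colnames(m)[const_idx]
    }
    list(features = new_feature_matrix(m, provenance = "raw"),
         labels = labels, informative = informative, constant = constant)
  })
}

#' Generate a synthetic screening library with planted structure
#'
#' Builds a SMILES-bearing library containing internal duplicates, overlaps
#' with a training set, and a known subset of "positive-like" compounds
#' drawn from the positive-class feature distribution, for exercising
#' library preparation and ensemble scoring end to end.
#'
#' @param n_unique Unique library compounds after deduplication and
#'   training-overlap removal.
#' @param n_dup Planted internal duplicates.
#' @param n_training_overlap Compounds re-using training structures.
#' @param training_smiles Canonical training structures to overlap with
#'   (needed when `n_training_overlap > 0`).
#' @param positive_like_fraction Fraction of the `n_unique` survivors drawn
#'   from the positive-class feature model.
#' @param feature_template A `generate_labelled_features()`-style
#'   description of the feature model: list with `n_features`,
#'   `n_informative`, `effect_size`.
#' @param seed Seed.
#' @return List: `library` (data.frame `compound_id`, `smiles`),
#'   `features` (raw feature matrix for all emitted compounds),
#'   `positive_like` (compound ids drawn from the positive model).
#' @export
generate_screen_library <- function(n_unique, n_dup = 0L,
                                    n_training_overlap = 0L,
                                    training_smiles = character(0),
                                    positive_like_fraction = 0,
                                    feature_template =
                                      list(n_features = 200L,
                                           n_informative = 10L,
                                           effect_size = 3),
                                    seed = 1L) {
  stopifnot(n_unique >= 0, n_dup >= 0, n_training_overlap >= 0,
            n_training_overlap == 0 || length(training_smiles) > 0)
  with_seed(seed, {
    uniq_smiles <- random_chain_smiles(n_unique + length(training_smiles))
    uniq_smiles <- setdiff(uniq_smiles, training_smiles)[seq_len(n_unique)]
    n_pos_like <- round(positive_like_fraction * n_unique)
    pos_like <- rep(c(TRUE, FALSE), c(n_pos_like, n_unique - n_pos_like))
    pos_like <- sample(pos_like)
    smiles <- c(uniq_smiles,
                if (n_dup > 0) sample(uniq_smiles, n_dup,
                                      replace = n_dup > n_unique),
                if (n_training_overlap > 0)
                  sample(training_smiles, n_training_overlap,
                         replace = n_training_overlap >
                           length(training_smiles)))
    if (length(smiles) == 0) {
      return(list(library = data.frame(compound_id = character(),
                                       smiles = character()),
                  features = NULL, positive_like = character(0)))
    }
    # uniques first so first-occurrence deduplication keeps them; planted
    # duplicates reuse their source compound's feature vector
    ids <- sprintf("LIB%05d", seq_along(smiles))
    nf <- feature_template$n_features
    ni <- feature_template$n_informative
    m <- matrix(stats::rnorm(length(smiles) * nf), length(smiles), nf)
    colnames(m) <- sprintf("f%03d", seq_len(nf))
    rownames(m) <- ids
    is_pos_like <- c(pos_like, rep(FALSE, length(smiles) - n_unique))
    m[is_pos_like, seq_len(ni)] <- m[is_pos_like, seq_len(ni)] +
      feature_template$effect_size
    if (n_dup > 0) {
      dup_rows <- n_unique + seq_len(n_dup)
      m[dup_rows, ] <- m[match(smiles[dup_rows], uniq_smiles), ]
    }
    list(library = data.frame(compound_id = ids, smiles = smiles),
         features = new_feature_matrix(m, provenance = "raw"),
         positive_like = ids[is_pos_like])
  })
}

#' Generate synthetic 4PL dose-response data
#'
#' @param true_params List with `top`, `bottom`, `ic50`, `hill`.
#' @param doses Positive dose vector.
#' @param n_replicates Replicates per dose.
#' @param cv Multiplicative lognormal noise CV (0 = exact curve).
#' @param seed Seed.
#' @return Data.frame with columns `dose`, `replicate`,
#'   `survival_percent`, and the generating parameters as attribute
#'   `truth`.
#' @export
generate_dose_response <- function(true_params, doses, n_replicates = 3L,
                                   cv = 0.1, seed = 1L) {
  stopifnot(all(doses > 0))
  with_seed(seed, {
    mu <- true_params$bottom + (true_params$top - true_params$bottom) /
      (1 + (doses / true_params$ic50)^true_params$hill)
    out <- data.frame(
      dose = rep(doses, each = n_replicates),
      replicate = rep(seq_len(n_replicates), length(doses)),
      survival_percent = rep(mu, each = n_replicates) *
        noise_factor(length(doses) * n_replicates, cv))
    attr(out, "truth") <- true_params
    out
  })
}
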