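#' Configuration of the concentration- and cell-line-sensitive labelling rule
#'
#' The rule first picks, per compound, a single reference concentration: among
#' the tested concentrations whose cross-line mean survival falls below
#' `impact_threshold_percent` (the "impacting" concentrations), the one whose
#' mean survival is closest to `midpoint_target_percent`, ties going to the
#' lower concentration. At that concentration the compound is labelled
#' positive if it brings at least `min_lines` — but not all — cell lines to
#' `survival_cutoff_percent` or below. Compounds below the cutoff in every
#' line are pan-toxic and labelled negative when `exclude_pan_toxic` is on,
#' screening out general cytotoxins with a narrow therapeutic index.
#'
#' @param survival_cutoff_percent Survival at or below which a cell line
#'   counts as eliminated. Default 35, anchored on the paclitaxel positive
#'   control (36% survival at 5 nM).
#' @param min_lines Minimum number of eliminated lines for a positive.
#'   Default 2.
#' @param exclude_pan_toxic Label compounds eliminating every line as
#'   negative. Default `TRUE`.
#' @param impact_threshold_percent Cross-line mean survival below which a
#'   concentration counts as impacting. Default 70.
#' @param midpoint_target_percent Mean-survival target used to choose among
#'   several impacting concentrations. Default 50.
#' @return A list of class `label_config`.
#' @export
label_config <- function(survival_cutoff_percent = 35, min_lines = 2L,
                         exclude_pan_toxic = TRUE,
                         impact_threshold_percent = 70,
                         midpoint_target_percent = 50) {
  stopifnot(survival_cutoff_percent > 0, survival_cutoff_percent < 100,
            min_lines >= 1)
  structure(list(survival_cutoff_percent = survival_cutoff_percent,
                 min_lines = as.integer(min_lines),
                 exclude_pan_toxic = isTRUE(exclude_pan_toxic),
                 impact_threshold_percent = impact_threshold_percent,
                 midpoint_target_percent = midpoint_target_percent),
            class = "label_config")
}

#' Choose the reference concentration for one compound
#'
#' @param profile A `viability_profiles` table restricted to one compound
#'   (columns `cell_line`, `concentration`, `survival_percent`).
#' @param cfg A [label_config()].
#' @return The chosen concentration in micromolar, or `NA` when no tested
#'   concentration impacts the panel.
#' @export
select_reference_concentration <- function(profile, cfg = label_config()) {
  profile <- data.table::as.data.table(profile)
  if (nrow(profile) == 0 || all(is.na(profile$survival_percent))) {
    stop_glio("profile has no survival data", "input_error")
  }
  means <- profile[, .(mean_survival = mean(survival_percent)),
                   by = concentration]
  impacting <- means[mean_survival < cfg$impact_threshold_percent]
  if (nrow(impacting) == 0) return(NA_real_)
  dist <- abs(impacting$mean_survival - cfg$midpoint_target_percent)
  # ties toward the lower concentration: order by (distance, concentration)
  impacting$concentration[order(dist, impacting$concentration)][1]
}

#' Label one compound from its viability profile
#'
#' @inheritParams select_reference_concentration
#' @return A list of class `label_decision` with fields `compound_id`,
#'   `chosen_concentration`, `survival_at_chosen` (named by cell line),
#'   `n_lines_below_cutoff`, `n_cell_lines`, `label` (`"positive"` /
#'   `"negative"`) and `reason` (`"positive"`, `"no_impact"`, `"pan_toxic"`
#'   or `"insufficient_lines"`).
#' @export
label_compound <- function(profile, cfg = label_config()) {
  profile <- data.table::as.data.table(profile)
  n_lines <- length(unique(profile$cell_line))
  if (n_lines < cfg$min_lines) {
    stop_glio("profile covers fewer cell lines than min_lines", "input_error")
  }
  chosen <- select_reference_concentration(profile, cfg)
  cid <- profile$compound_id[1] %||% NA_character_
  if (is.na(chosen)) {
    return(structure(list(compound_id = cid,
                          chosen_concentration = NA_real_,
                          survival_at_chosen = NULL,
                          n_lines_below_cutoff = 0L,
                          n_cell_lines = n_lines,
                          label = "negative", reason = "no_impact"),
                     class = "label_decision"))
  }
  at <- profile[concentration == chosen,
                .(survival = mean(survival_percent)), by = cell_line]
  surv <- stats::setNames(at$survival, at$cell_line)
  n_below <- sum(surv <= cfg$survival_cutoff_percent)
  if (n_below >= n_lines && cfg$exclude_pan_toxic) {
    label <- "negative"; reason <- "pan_toxic"
  } else if (n_below >= cfg$min_lines) {
    label <- "positive"; reason <- "positive"
  } else {
    label <- "negative"; reason <- "insufficient_lines"
  }
  structure(list(compound_id = cid, chosen_concentration = chosen,
                 survival_at_chosen = surv,
                 n_lines_below_cutoff = as.integer(n_below),
                 n_cell_lines = n_lines, label = label, reason = reason),
            class = "label_decision")
}

#' Label every compound in a screen
#'
#' Applies [label_compound()] to each compound in a (deduplicated) profile
#' table. Per-compound failures are recorded in the report, not fatal.
#'
#' @param profiles A `viability_profiles` table.
#' @param cfg A [label_config()].
#' @return A list of class `labelled_dataset`: `labels` — a data.frame with
#'   one row per compound (`compound_id`, `smiles`, `library`, `label`,
#'   `reason`, `chosen_concentration`, `n_lines_below_cutoff`); `summary` —
#'   label counts, class-imbalance percentage and a reason histogram;
#'   `errors` — per-compound failures.
#' @export
build_labelled_dataset <- function(profiles, cfg = label_config()) {
  prof <- data.table::as.data.table(profiles)
  ids <- unique(prof$compound_id)
  rows <- vector("list", length(ids))
  errs <- list()
  split_prof <- split(prof, by = "compound_id", sorted = FALSE)
  for (i in seq_along(ids)) {
    p <- split_prof[[ids[i]]]
    dec <- tryCatch(label_compound(p, cfg), error = function(e) e)
    if (inherits(dec, "error")) {
      errs[[length(errs) + 1L]] <-
        data.frame(compound_id = ids[i], error = conditionMessage(dec))
      next
    }
    rows[[i]] <- data.frame(
      compound_id = dec$compound_id, smiles = p$smiles[1],
      library = p$library[1], label = dec$label, reason = dec$reason,
      chosen_concentration = dec$chosen_concentration,
      n_lines_below_cutoff = dec$n_lines_below_cutoff)
  }
  labels <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  n_pos <- sum(labels$label == "positive")
  n_neg <- sum(labels$label == "negative")
  summary <- list(
    n_compounds = nrow(labels), n_positive = n_pos, n_negative = n_neg,
    imbalance_percent = 100 * n_pos / nrow(labels),
    reason_histogram = table(labels$reason))
  structure(list(labels = labels, summary = summary,
                 errors = if (length(errs)) do.call(rbind, errs)
                          else data.frame()),
            class = "labelled_dataset")
}

#' @export
print.labelled_dataset <- function(x, ...) {
  cat(sprintf(
    "Labelled screen: %d compounds, %d positive / %d negative (imbalance %.1f%%)\n",
    x$summary$n_compounds, x$summary$n_positive, x$summary$n_negative,
    x$summary$imbalance_percent))
  print(x$summary$reason_histogram)
  invisible(x)
}
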