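#' Stability flags implied by a flocculation regime
#'
#' The four regimes observed as polymer concentration rises: `a1` dilute and
#' stable (individual droplets cream slowly), `a2` extensive depletion
#' flocculation with creaming, `a3` flocculation whose creaming is arrested by
#' aqueous-phase viscoelasticity, `a4` fully arrested - the entangled network
#' stops droplet motion so no flocs form and nothing creams.
#'
#' @param regime Character vector of regime labels (`a1`-`a4`).
#' @return A data.frame with logical columns `flocculated` and `creams`.
#' @export
regime_flags <- function(regime) {
  stop_unless(is.character(regime) && all(regime %in% c("a1", "a2", "a3", "a4")),
              "regime must be one of a1, a2, a3, a4")
  data.frame(
    flocculated = regime %in% c("a2", "a3"),
    creams = regime %in% c("a1", "a2"))
}

#' Classify a polymer/emulsion mixture into a stability regime
#'
#' Places a concentration on the axis set by the polymer's two critical
#' concentrations: below the CFC the depletion attraction is too weak to
#' flocculate (`a1`); between CFC and CVC droplets flocculate and the flocs
#' cream (`a2`); above the CVC the continuous phase is viscoelastic enough to
#' stop creaming but not yet droplet encounters (`a3`); beyond
#' `arrest_multiplier * CVC` the entangled network arrests droplet motion
#' entirely (`a4`). Intervals are half-open with the lower bound included, so
#' a concentration exactly at a boundary takes the higher regime.
#'
#' @param sol A [solution_state()]; its concentration may be a vector.
#' @param emulsion An [emulsion_spec()].
#' @param constants A [model_constants()].
#' @param arrest_multiplier Multiple of the CVC placing the a3/a4 boundary
#'   (>= 1, default 2). This boundary is the least constrained part of the
#'   framework; see the package vignette.
#' @return A data.frame of class `stability_prediction`, one row per
#'   concentration, with columns `polymer`, `c_wtpct`, `cvc`, `cfc`,
#'   `regime`, `flocculated`, `creams`. The regime boundaries are attached as
#'   attribute `boundaries`.
#' @examples
#' guar <- polymer_spec("guar_gum", 2490, 78)
#' classify_regime(solution_state(guar, c(0.025, 0.05, 0.15, 1.0)))
#' @export
classify_regime <- function(sol, emulsion = emulsion_spec(),
                            constants = model_constants(),
                            arrest_multiplier = 2) {
  stop_unless(inherits(sol, "solution_state"), "sol must be a solution_state")
  stop_unless(is_scalar_num(arrest_multiplier) && arrest_multiplier >= 1,
              "arrest_multiplier must be >= 1")
  p <- sol$polymer
  cvc_w <- cvc(p, constants)
  cfc_w <- cfc(p, emulsion, constants)$cfc
  arrest <- arrest_multiplier * cvc_w
  regime <- vapply(sol$concentration, function(cw) {
    if (cw < cfc_w) "a1"
    else if (cw < cvc_w) "a2"
    else if (cw < arrest) "a3"
    else "a4"
  }, character(1))
  out <- cbind(
    data.frame(polymer = p$name, c_wtpct = sol$concentration,
               cvc = cvc_w, cfc = cfc_w, regime = regime,
               stringsAsFactors = FALSE),
    regime_flags(regime))
  attr(out, "boundaries") <- c(cfc = cfc_w, cvc = cvc_w, arrest = arrest)
  class(out) <- c("stability_prediction", "data.frame")
  out
}

#' Tabular stability phase diagram
#'
#' One [classify_regime()] prediction per (polymer, concentration) cell; the
#' tabular analogue of a concentration-vs-polymer stability map.
#'
#' @param polymers A list of [polymer_spec()] or a polymer table data.frame;
#'   may be empty.
#' @param c_grid Strictly increasing concentrations in wt%.
#' @inheritParams classify_regime
#' @return A `stability_prediction` data.frame with one row per cell.
#' @examples
#' phase_diagram(reference_polymer_table(), c_grid = c(0.025, 0.05, 0.1, 0.5, 1))
#' @export
phase_diagram <- function(polymers, emulsion = emulsion_spec(),
                          c_grid = c(0.025, 0.05, 0.1, 0.25, 0.5, 1.0),
                          constants = model_constants(),
                          arrest_multiplier = 2) {
  ps <- as_polymer_list(polymers)
  stop_unless(is.numeric(c_grid) && length(c_grid) >= 1L && all(c_grid >= 0),
              "c_grid must be non-negative concentrations (wt%)")
  if (is.unsorted(c_grid, strictly = TRUE))
    stop("c_grid must be strictly increasing", call. = FALSE)
  rows <- lapply(ps, function(p)
    classify_regime(solution_state(p, c_grid), emulsion, constants,
                    arrest_multiplier))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(polymer = character(0), c_wtpct = numeric(0), cvc = numeric(0),
               cfc = numeric(0), regime = character(0),
               flocculated = logical(0), creams = logical(0))
  rownames(out) <- NULL
  class(out) <- c("stability_prediction", "data.frame")
  out
}

#' Flocculation onset and window width of a polymer
#'
#' The CFC is the onset of depletion flocculation and the ratio CVC/CFC is a
#' dimensionless surrogate for how wide the unstable concentration window is
#' before viscosity arrests creaming: small, high-Mw polymers thicken before
#' they flocculate (small ratio), while compact low-Mw polymers flocculate
#' over a wide range before the solution thickens (large ratio).
#'
#' @inheritParams classify_regime
#' @param polymer A [polymer_spec()].
#' @return A list with `onset` (the CFC, wt%), `ratio` (CVC/CFC), and the
#'   underlying `cvc` and `cfc`.
#' @examples
#' flocculation_window(polymer_spec("BG3", 272, 23))
#' @export
flocculation_window <- function(polymer, emulsion = emulsion_spec(),
                                constants = model_constants(),
                                arrest_multiplier = 2) {
  cvc_w <- cvc(polymer, constants)
  cfc_w <- cfc(polymer, emulsion, constants)$cfc
  list(onset = cfc_w, ratio = cvc_w / cfc_w, cvc = cvc_w, cfc = cfc_w)
}

#' Score predictions against qualitative regime observations
#'
#' Matches each observation (polymer name + concentration) to the prediction
#' for the same cell and counts agreements. Observations labelled `unknown`
#' are skipped and counted separately.
#'
#' @param predictions A `stability_prediction` data.frame
#'   (e.g. from [phase_diagram()]).
#' @param observations A data.frame with columns `name`, `c_wtpct`, `regime`
#'   (a1-a4 or `unknown`), e.g. from [read_observations()].
#' @return A list with `detail` (per-observation data.frame with `predicted`,
#'   `observed`, `match`), `n_match`, `n_scored`, `n_unknown` and `agreement`
#'   (fraction, `NA` if nothing scored).
#' @export
compare_to_observations <- function(predictions, observations) {
  stop_unless(is.data.frame(predictions) &&
                all(c("polymer", "c_wtpct", "regime") %in% names(predictions)),
              "predictions must have columns polymer, c_wtpct, regime")
  stop_unless(is.data.frame(observations) &&
                all(c("name", "c_wtpct", "regime") %in% names(observations)),
              "observations must have columns name, c_wtpct, regime")
  if (nrow(observations) == 0L)
    return(list(detail = data.frame(), n_match = 0L, n_scored = 0L,
                n_unknown = 0L, agreement = NA_real_))
  predicted <- character(nrow(observations))
  for (i in seq_len(nrow(observations))) {
    hit <- predictions$polymer == observations$name[i] &
      abs(predictions$c_wtpct - observations$c_wtpct[i]) <
        1e-9 * pmax(1, observations$c_wtpct[i])
    if (!any(hit))
      stop(sprintf("no prediction found for observation '%s' at %g wt%%",
                   observations$name[i], observations$c_wtpct[i]), call. = FALSE)
    predicted[i] <- predictions$regime[which(hit)[1]]
  }
  detail <- data.frame(
    name = observations$name, c_wtpct = observations$c_wtpct,
    observed = observations$regime, predicted = predicted,
    match = ifelse(observations$regime == "unknown", NA,
                   predicted == observations$regime),
    stringsAsFactors = FALSE)
  scored <- !is.na(detail$match)
  list(detail = detail,
       n_match = sum(detail$match[scored]),
       n_scored = sum(scored),
       n_unknown = sum(!scored),
       agreement = if (any(scored)) mean(detail$match[scored]) else NA_real_)
}

#' The two universal dilute-end observations
#'
#' Every polymer of the purified panel left the emulsion unflocculated at
#' 0.025 wt% (a1) and strongly flocculated at 0.05 wt% (a2); these eight
#' cells are the only per-cell regime assignments quoted outright, so they
#' are the encoded observation set.
#'
#' @param names Polymer names to expand over (defaults to the packaged panel).
#' @return An observations data.frame (`name`, `c_wtpct`, `regime`).
#' @export
universal_observations <- function(names = reference_polymer_table()$name) {
  data.frame(
    name = rep(names, each = 2L),
    c_wtpct = rep(c(0.025, 0.05), times = length(names)),
    regime = rep(c("a1", "a2"), times = length(names)),
    stringsAsFactors = FALSE)
}

#' Side-by-side reproduction report for the purified-polymer panel
#'
#' Recomputes CVC and CFC for the packaged panel and lines them up against
#' the originally reported values, both at full precision and truncated to
#' the reported table's decimal precision (2 decimals for CVC, 3 for CFC; see
#' [truncate_decimals()] for why truncation). Match columns flag where the
#' computed value reproduces the reported one and where it does not (BG1 and
#' BG3, whose reported values trace back to unrounded instrument data).
#'
#' @param polymers Polymer table (default the packaged panel).
#' @param reported Reported-value table (default the packaged one).
#' @inheritParams classify_regime
#' @return A data.frame, one row per polymer.
#' @examples
#' reproduction_report()
#' @export
reproduction_report <- function(polymers = reference_polymer_table(),
                                reported = reported_critical_concentrations(),
                                emulsion = emulsion_spec(),
                                constants = model_constants()) {
  ps <- as_polymer_list(polymers)
  rows <- lapply(ps, function(p) {
    cv <- cvc(p, constants)
    cf <- cfc(p, emulsion, constants)$cfc
    data.frame(name = p$name, mw_kg_per_mol = p$mw, rh_nm = p$rh,
               cvc_computed = cv, cvc_table = truncate_decimals(cv, 2),
               cfc_computed = cf, cfc_table = truncate_decimals(cf, 3),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- merge(out, reported, by = "name", all.x = TRUE, sort = FALSE)
  out$cvc_match <- !is.na(out$cvc_reported_wtpct) &
    abs(out$cvc_table - out$cvc_reported_wtpct) < 1e-12
  out$cfc_match <- !is.na(out$cfc_reported_wtpct) &
    abs(out$cfc_table - out$cfc_reported_wtpct) < 1e-12
  out
}

#' Stability report for oat-extract/emulsion mixtures
#'
#' Classifies each oat-extract solution mixed with the baseline emulsion.
#' Extract records carry the beta-glucan concentration measured in the
#' incubation extract; mixing with the emulsion dilutes the polymer by
#' `dilution` (default 20/30.64, i.e. 20 mL of extract receiving 10.64 mL of
#' emulsion). Both the undiluted-extract and mixture concentrations are
#' classified, and the extracts are ranked by depletion-attraction magnitude
#' at the mixture concentration within each incubation time (the predicted
#' flocculation-tendency ordering).
#'
#' @param extracts Extract records from [oat_extract_fixtures()] (columns
#'   `source`, `incubation_h`, `c_extract_wtpct`, `mw_kg_per_mol`, `rh_nm`,
#'   `rh_imputed`).
#' @inheritParams classify_regime
#' @param dilution Multiplicative dilution applied on mixing with the
#'   emulsion. Set to 9/37.5 to model the polymer level in the simulated
#'   duodenal digestion mix instead, or 1 for no dilution.
#' @param include_control Add a zero-concentration control row (classified
#'   a1 by construction of the model) to anchor the ranking.
#' @return A data.frame with one row per extract record: concentrations,
#'   CVC/CFC of the extract polymer, regimes for extract and mixture,
#'   depletion potential at the mixture concentration (`w_mixture`, kT) and
#'   `tendency_rank` (1 = strongest flocculation tendency within its
#'   incubation time).
#' @examples
#' extract_stability_report()
#' @export
extract_stability_report <- function(extracts = oat_extract_fixtures(),
                                     emulsion = emulsion_spec(),
                                     constants = model_constants(),
                                     arrest_multiplier = 2,
                                     dilution = 20 / 30.64,
                                     include_control = TRUE) {
  req <- c("source", "incubation_h", "c_extract_wtpct", "mw_kg_per_mol", "rh_nm")
  stop_unless(is.data.frame(extracts) && all(req %in% names(extracts)),
              paste("extracts must have columns",
                    paste(req, collapse = ", ")))
  stop_unless(all(is.finite(extracts$mw_kg_per_mol)) &&
                all(is.finite(extracts$c_extract_wtpct)),
              "extract records are missing Mw or concentration values")
  stop_unless(is_scalar_num(dilution) && dilution > 0 && dilution <= 1,
              "dilution must lie in (0, 1]")
  if (include_control) {
    ctrl <- extracts[0, ]
    for (h in unique(extracts$incubation_h)) {
      row <- data.frame(source = "control", incubation_h = h,
                        c_extract_wtpct = 0,
                        mw_kg_per_mol = stats::median(extracts$mw_kg_per_mol),
                        rh_nm = stats::median(extracts$rh_nm),
                        stringsAsFactors = FALSE)
      extra <- setdiff(names(extracts), names(row))
      for (nm in extra) row[[nm]] <- extracts[[nm]][1]
      ctrl <- rbind(ctrl, row[, names(extracts)])
    }
    extracts <- rbind(extracts, ctrl)
  }
  rows <- lapply(seq_len(nrow(extracts)), function(i) {
    e <- extracts[i, ]
    p <- polymer_spec(paste0(e$source, "_", e$incubation_h, "h"),
                      e$mw_kg_per_mol, e$rh_nm)
    c_mix <- e$c_extract_wtpct * dilution
    pred_ext <- classify_regime(solution_state(p, max(e$c_extract_wtpct, 0)),
                                emulsion, constants, arrest_multiplier)
    pred_mix <- classify_regime(solution_state(p, c_mix),
                                emulsion, constants, arrest_multiplier)
    w_mix <- depletion_potential_contact(solution_state(p, c_mix),
                                         emulsion, constants)
    data.frame(source = e$source, incubation_h = e$incubation_h,
               mw_kg_per_mol = e$mw_kg_per_mol, rh_nm = e$rh_nm,
               rh_imputed = if ("rh_imputed" %in% names(e)) e$rh_imputed else NA,
               c_extract_wtpct = e$c_extract_wtpct, c_mixture_wtpct = c_mix,
               cvc = pred_mix$cvc, cfc = pred_mix$cfc,
               regime_extract = pred_ext$regime, regime_mixture = pred_mix$regime,
               flocculated = pred_mix$flocculated, creams = pred_mix$creams,
               w_mixture = w_mix, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$tendency_rank <- NA_integer_
  for (h in unique(out$incubation_h)) {
    sel <- out$incubation_h == h
    out$tendency_rank[sel] <- rank(out$w_mixture[sel], ties.method = "min")
  }
  rownames(out) <- NULL
  out
}
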