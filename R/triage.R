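# triage: the exposure -> absorption -> distribution decision logic for
# parent compounds and metabolites, priority propagation to similarity-
# flagged inactives, and promiscuity flagging.
#
# Gate semantics: exposure category 4 (low/no exposure likelihood) demotes
# immediately and short-circuits the remaining gates; "Negligible" absorption
# and "No" BBB distribution demote; "Limited" absorption keeps high priority
# with a ranking note; unknown or unannotated gate values never demote,
# because insufficient data cannot confidently assign low-priority status.

.low_reasons <- c("no_exposure", "negligible_absorption", "no_bbb_distribution",
                  "inherited_from_low_priority_neighbor")

new_priority_call <- function(chemical_id, reasons, rank_notes, gate_trace,
                              route = "parent") {
  structure(list(
    chemical_id = chemical_id,
    priority = if (length(reasons)) "low" else "high",
    reasons = reasons,
    rank_notes = unique(rank_notes),
    gate_trace = gate_trace,
    route = route
  ), class = "priority_call")
}

trace_row <- function(gate, input, outcome, source) {
  data.frame(gate = gate, input = input, outcome = outcome, source = source,
             stringsAsFactors = FALSE)
}

metabolism_rank_notes <- function(code) {
  if (is.null(code) || length(code) == 0L || is.na(code)) return(character(0))
  switch(code,
         "+" = "metabolism_activating",
         "-" = "metabolism_detoxifying",
         "+-" = c("metabolism_activating", "metabolism_detoxifying"),
         character(0))
}

# Resolve one gate's effective value and source: an explicit annotation wins;
# otherwise a supplied predicted call is used; otherwise the gate is unknown.
resolve_gate <- function(annotation, call, value_field) {
  if (!is.null(annotation) && length(annotation) == 1L && !is.na(annotation))
    return(list(value = annotation, source = "annotation"))
  if (!is.null(call))
    return(list(value = call[[value_field]], source = call$source))
  list(value = "unannotated", source = "none")
}

rec_field <- function(rec, field) {
  v <- rec[[field]]
  if (is.null(v) || length(v) == 0L) NA else v[[1]]
}

#' Assign priority to an active parent compound
#'
#' Runs the parent-compound decision tree: exposure, then absorption, then
#' blood-brain-barrier distribution. Annotations on the record always take
#' precedence over predicted calls; gates with neither annotation nor
#' prediction are recorded as unknown and do not demote.
#'
#' @param rec A chemical record (one-row `data.frame` or named list) with at
#'   least `id` and `exposure_category`; `absorption_annotation`,
#'   `distribution_annotation` and `metabolism_code` are used when present.
#' @param absorption Optional `absorption_call` (from
#'   [classify_absorption()]) used when the record has no absorption
#'   annotation.
#' @param distribution Optional `distribution_call` (from [classify_bbb()])
#'   used when the record has no distribution annotation.
#' @return A `priority_call`: `chemical_id`, `priority` (`"high"`/`"low"`),
#'   machine-readable `reasons`, `rank_notes`, and a `gate_trace` data frame
#'   covering every gate evaluated, in order.
#' @export
assign_priority_parent <- function(rec, absorption = NULL, distribution = NULL) {
  id <- rec_field(rec, "id")
  notes <- metabolism_rank_notes(rec_field(rec, "metabolism_code"))
  trace <- trace_row(character(0), character(0), character(0), character(0))

  # exposure gate
  exp_cat <- rec_field(rec, "exposure_category")
  exp_in <- if (is.na(exp_cat)) "unannotated" else as.character(exp_cat)
  if (!is.na(exp_cat) && exp_cat == 4L) {
    trace <- rbind(trace, trace_row("exposure", exp_in, "low_priority", "annotation"))
    return(new_priority_call(id, "no_exposure", notes, trace))
  }
  trace <- rbind(trace, trace_row(
    "exposure", exp_in,
    if (is.na(exp_cat)) "unknown_pass" else "pass",
    if (is.na(exp_cat)) "none" else "annotation"))

  # absorption gate
  abs <- resolve_gate(rec_field(rec, "absorption_annotation"), absorption, "cls")
  abs_out <- switch(abs$value,
                    Negligible = "low_priority",
                    Limited = "pass_limited",
                    Yes = "pass",
                    "unknown_pass")
  trace <- rbind(trace, trace_row("absorption", abs$value, abs_out, abs$source))
  if (abs_out == "low_priority")
    return(new_priority_call(id, "negligible_absorption", notes, trace))
  if (abs_out == "pass_limited") notes <- c(notes, "limited_absorption")

  # distribution (BBB) gate
  dist <- resolve_gate(rec_field(rec, "distribution_annotation"), distribution,
                       "bbb_permeable")
  dist_out <- switch(dist$value,
                     No = "low_priority",
                     Yes = "pass",
                     "unknown_pass")
  trace <- rbind(trace, trace_row("distribution", dist$value, dist_out, dist$source))
  if (dist_out == "low_priority")
    return(new_priority_call(id, "no_bbb_distribution", notes, trace))

  new_priority_call(id, character(0), notes, trace)
}

#' Assign priority to an active metabolite
#'
#' A metabolite with its own environmental exposure (category 1-3) is routed
#' through the parent-compound tree on its own annotations. Without
#' independent exposure, the metabolite is demoted when its parent has no
#' exposure (category 4) or negligible absorption; otherwise the metabolite's
#' own distribution decides, as in the parent gate.
#'
#' @param met The metabolite's chemical record (active).
#' @param parent The parent compound's chemical record.
#' @param parent_absorption Optional predicted `absorption_call` for the
#'   parent (annotations on the parent record take precedence).
#' @param met_distribution Optional predicted `distribution_call` for the
#'   metabolite.
#' @inherit assign_priority_parent return
#' @export
assign_priority_metabolite <- function(met, parent, parent_absorption = NULL,
                                       met_distribution = NULL) {
  id <- rec_field(met, "id")
  met_exp <- rec_field(met, "exposure_category")
  if (!is.na(met_exp) && met_exp %in% 1:3) {
    call <- assign_priority_parent(met, distribution = met_distribution)
    call$route <- "metabolite_with_own_exposure"
    return(call)
  }
  notes <- metabolism_rank_notes(rec_field(met, "metabolism_code"))
  trace <- trace_row("exposure", if (is.na(met_exp)) "unannotated" else as.character(met_exp),
                     "no_direct_exposure", if (is.na(met_exp)) "none" else "annotation")

  parent_exp <- rec_field(parent, "exposure_category")
  if (!is.na(parent_exp) && parent_exp == 4L) {
    trace <- rbind(trace, trace_row("parent_exposure", as.character(parent_exp),
                                    "low_priority", "annotation"))
    return(new_priority_call(id, "no_exposure", notes, trace, route = "metabolite"))
  }
  trace <- rbind(trace, trace_row(
    "parent_exposure",
    if (is.na(parent_exp)) "unannotated" else as.character(parent_exp),
    if (is.na(parent_exp)) "unknown_pass" else "pass",
    if (is.na(parent_exp)) "none" else "annotation"))

  pabs <- resolve_gate(rec_field(parent, "absorption_annotation"),
                       parent_absorption, "cls")
  if (identical(pabs$value, "Negligible")) {
    trace <- rbind(trace, trace_row("parent_absorption", pabs$value,
                                    "low_priority", pabs$source))
    return(new_priority_call(id, "negligible_absorption", notes, trace,
                             route = "metabolite"))
  }
  trace <- rbind(trace, trace_row(
    "parent_absorption", pabs$value,
    if (pabs$value %in% c("Yes", "Limited")) "pass" else "unknown_pass",
    pabs$source))
  if (identical(pabs$value, "Limited")) notes <- c(notes, "limited_absorption")

  dist <- resolve_gate(rec_field(met, "distribution_annotation"),
                       met_distribution, "bbb_permeable")
  dist_out <- switch(dist$value, No = "low_priority", Yes = "pass", "unknown_pass")
  trace <- rbind(trace, trace_row("distribution", dist$value, dist_out, dist$source))
  if (dist_out == "low_priority")
    return(new_priority_call(id, "no_bbb_distribution", notes, trace,
                             route = "metabolite"))
  new_priority_call(id, character(0), notes, trace, route = "metabolite")
}

#' Propagate nearest-neighbor priority onto flagged inactives
#'
#' A flagged inactive inherits low priority if (and only if) its single
#' nearest active neighbor is itself low priority; the remaining flagged
#' inactives are the possible in vitro false negatives.
#'
#' @param hits Similarity hits from [screen_inactives()].
#' @param calls The actives' priority calls: the `calls` data frame of a
#'   `triage_report`, or a list of `priority_call` objects.
#' @return `hits` with `inherited_priority` (`"low"` where inherited) and a
#'   logical `possible_false_negative` column.
#' @export
propagate_neighbor_priority <- function(hits, calls) {
  pr <- calls_priority_map(calls)
  missing <- setdiff(hits$neighbor_id[hits$flagged], names(pr))
  if (length(missing))
    stop_admet(sprintf("no priority call for neighbor(s): %s",
                       paste(missing, collapse = ", ")),
               "admet_contract_error")
  inherit <- hits$flagged & pr[hits$neighbor_id] == "low"
  hits$inherited_priority <- ifelse(inherit, "low", NA_character_)
  hits$possible_false_negative <- hits$flagged & !inherit
  hits
}

calls_priority_map <- function(calls) {
  if (is.data.frame(calls))
    return(stats::setNames(calls$priority, calls$chemical_id))
  stats::setNames(vapply(calls, `[[`, character(1), "priority"),
                  vapply(calls, `[[`, character(1), "chemical_id"))
}

# ---- promiscuity ------------------------------------------------------------

#' Default structural-alert set for assay promiscuity
#'
#' A deliberately small starter set of patterns for compounds prone to
#' nonspecific assay signals: triarylmethane dye cations (absorbance
#' interference), permanently charged azinium aromatics, and the rhodanine
#' PAINS core. Users can extend or replace the set; per-record overrides
#' always win.
#'
#' @return `data.frame` with columns `name` and `smarts`.
#' @export
default_promiscuity_alerts <- function() {
  data.frame(
    name = c("triarylmethane_dye", "quaternary_azinium", "rhodanine_core"),
    smarts = c("C(=C1C=CC(=[N+])C=C1)(c)c", "[n+;H0]", "O=C1CSC(=S)N1"),
    stringsAsFactors = FALSE
  )
}

validate_alerts <- function(alerts) {
  stopifnot(is.data.frame(alerts), all(c("name", "smarts") %in% names(alerts)))
  for (i in seq_len(nrow(alerts))) {
    ok <- tryCatch({ ob_smarts_count("CCO", alerts$smarts[i]); TRUE },
                   error = function(e) FALSE)
    if (!ok)
      stop_admet(sprintf("malformed alert SMARTS '%s' (%s)",
                         alerts$smarts[i], alerts$name[i]),
                 "admet_config_error")
  }
  alerts
}

#' Flag potentially promiscuous (assay-interfering) chemicals
#'
#' Matches washed structures against a substructure alert set. A per-record
#' `promiscuity_override` (TRUE/FALSE) takes precedence over pattern
#' matching. Flags annotate triage output as `promiscuity_suspect` rank
#' notes; they do not change priority unless the workflow is configured to
#' demote.
#'
#' @param records Chemical table.
#' @param alerts Alert set, see [default_promiscuity_alerts()].
#' @return `data.frame` with `id`, `promiscuity_suspect` (logical),
#'   `matched_alerts` (pipe-separated) and `source`
#'   (`"override"`/`"alert"`/`"none"`).
#' @export
flag_promiscuity <- function(records, alerts = default_promiscuity_alerts()) {
  alerts <- validate_alerts(alerts)
  n <- nrow(records)
  out <- data.frame(id = records$id, promiscuity_suspect = rep(FALSE, n),
                    matched_alerts = rep("", n), source = rep("none", n),
                    stringsAsFactors = FALSE)
  overrides <- if ("promiscuity_override" %in% names(records))
    records$promiscuity_override else rep(NA, nrow(records))
  for (i in seq_len(nrow(records))) {
    if (!is.na(overrides[i])) {
      out$promiscuity_suspect[i] <- isTRUE(overrides[i])
      out$source[i] <- "override"
      next
    }
    if (is.na(records$smiles[i])) next
    washed <- tryCatch(wash_smiles(records$smiles[i], id = records$id[i]),
                       error = function(e) NULL)
    if (is.null(washed)) next
    matched <- alerts$name[vapply(alerts$smarts, function(p)
      ob_smarts_count(washed$washed_smiles, p) > 0, logical(1))]
    if (length(matched)) {
      out$promiscuity_suspect[i] <- TRUE
      out$matched_alerts[i] <- paste(matched, collapse = "|")
      out$source[i] <- "alert"
    }
  }
  out
}

# ---- full workflow ----------------------------------------------------------

#' Validate a triage dataset
#'
#' Checks id uniqueness across actives and inactives, that every
#' non-metabolite active has an exposure annotation, and that parent links
#' resolve. A metabolite whose parent is absent from the dataset is an error
#' only when the metabolite also lacks its own exposure category (the parent
#' is never consulted otherwise).
#'
#' @param actives,inactives Chemical tables; `inactives` may be `NULL`.
#' @return Invisibly `TRUE`; stops with a classed error otherwise.
#' @export
validate_records <- function(actives, inactives = NULL) {
  dataset <- if (is.null(inactives)) actives else
    rbind(actives[.chemical_columns], inactives[.chemical_columns])
  validate_chemical_table(dataset)
  no_exp <- is.na(actives$exposure_category) & is.na(actives$parent_id)
  if (any(no_exp))
    stop_admet(sprintf("active record(s) without exposure category: %s",
                       paste(actives$id[no_exp], collapse = ", ")),
               "admet_annotation_error")
  has_parent <- !is.na(actives$parent_id)
  unresolved <- has_parent & !(actives$parent_id %in% dataset$id)
  needs_parent <- unresolved & is.na(actives$exposure_category)
  if (any(needs_parent))
    stop_admet(sprintf("unresolved parent_id for metabolite record(s): %s",
                       paste(actives$id[needs_parent], collapse = ", ")),
               "admet_linkage_error")
  invisible(TRUE)
}

predict_gate_calls <- function(rec) {
  if (is.na(rec$smiles)) return(list(absorption = NULL, distribution = NULL))
  d <- tryCatch(compute_descriptors(wash_smiles(rec$smiles, id = rec$id)),
                error = function(e) NULL)
  if (is.null(d)) return(list(absorption = NULL, distribution = NULL))
  list(absorption = classify_absorption(d), distribution = classify_bbb(d))
}

#' Run the full exposure-ADME triage workflow
#'
#' Washes structures, assigns parent/metabolite priorities to every active
#' (annotations first, descriptor-based predictions where a gate is
#' unannotated and a structure is available), screens inactives for nearest
#' active neighbors, propagates low priority to flagged inactives whose
#' neighbor is low priority, and flags promiscuity suspects.
#'
#' @param actives Chemical table of assay actives.
#' @param inactives Optional chemical table of assay inactives to screen.
#' @param config A [triage_config()].
#' @return A `triage_report`: list with `calls` (per-active priorities,
#'   reasons and rank notes), `hits` (similarity hits with inheritance),
#'   `promiscuity`, `gate_traces`, `summary` counts and `config_echo`.
#' @examples
#' \donttest{
#' fx <- load_table1_fixture()
#' report <- run_workflow(fx$actives, fx$inactives)
#' report$summary$n_low
#' }
#' @export
run_workflow <- function(actives, inactives = NULL, config = triage_config()) {
  stopifnot(inherits(config, "triage_config"))
  validate_records(actives, inactives)
  dataset_ids <- c(actives$id, if (!is.null(inactives)) inactives$id)

  calls <- vector("list", nrow(actives))
  names(calls) <- actives$id
  for (i in seq_len(nrow(actives))) {
    rec <- actives[i, , drop = FALSE]
    needs_pred <- is.na(rec$absorption_annotation) ||
      is.na(rec$distribution_annotation)
    pred <- if (needs_pred) predict_gate_calls(rec)
            else list(absorption = NULL, distribution = NULL)
    if (!is.na(rec$parent_id) && rec$parent_id %in% dataset_ids) {
      dataset <- rbind(actives[.chemical_columns],
                       if (!is.null(inactives)) inactives[.chemical_columns])
      parent <- dataset[dataset$id == rec$parent_id, , drop = FALSE]
      calls[[i]] <- assign_priority_metabolite(rec, parent,
                                               met_distribution = pred$distribution)
    } else {
      calls[[i]] <- assign_priority_parent(rec, absorption = pred$absorption,
                                           distribution = pred$distribution)
    }
  }

  prom <- flag_promiscuity(actives, alerts = config$alerts)
  for (i in seq_len(nrow(prom))) {
    if (!prom$promiscuity_suspect[i]) next
    calls[[prom$id[i]]]$rank_notes <-
      unique(c(calls[[prom$id[i]]]$rank_notes, "promiscuity_suspect"))
    if (isTRUE(config$demote_promiscuous)) {
      calls[[prom$id[i]]]$reasons <-
        unique(c(calls[[prom$id[i]]]$reasons, "promiscuity_suspect"))
      calls[[prom$id[i]]]$priority <- "low"
    }
  }

  calls_df <- data.frame(
    chemical_id = unname(vapply(calls, `[[`, character(1), "chemical_id")),
    priority = unname(vapply(calls, `[[`, character(1), "priority")),
    reasons = I(unname(lapply(calls, `[[`, "reasons"))),
    rank_notes = I(unname(lapply(calls, `[[`, "rank_notes"))),
    route = unname(vapply(calls, `[[`, character(1), "route")),
    stringsAsFactors = FALSE, row.names = NULL
  )

  hits <- NULL
  if (!is.null(inactives) && nrow(inactives) > 0L) {
    hits <- screen_inactives(inactives, actives, threshold = config$threshold)
    hits <- propagate_neighbor_priority(hits, calls_df)
  }

  reasons_chr <- vapply(calls_df$reasons, paste, character(1), collapse = "|")
  n_low <- sum(calls_df$priority == "low")
  n_flagged <- if (is.null(hits)) 0L else sum(hits$flagged)
  n_inherited <- if (is.null(hits)) 0L else
    sum(hits$flagged & !is.na(hits$inherited_priority) & hits$inherited_priority == "low")
  prom_ids <- prom$id[prom$promiscuity_suspect]
  summary <- list(
    n_active = nrow(actives),
    n_low = n_low,
    n_low_by_exposure = sum(reasons_chr == "no_exposure"),
    n_low_by_absorption = sum(reasons_chr == "negligible_absorption"),
    n_low_by_bbb = sum(reasons_chr == "no_bbb_distribution"),
    n_high = sum(calls_df$priority == "high"),
    n_flagged_inactives = n_flagged,
    n_flagged_low_inherited = n_inherited,
    n_possible_false_negatives = n_flagged - n_inherited,
    n_promiscuity_suspects = length(prom_ids),
    n_high_non_promiscuous = sum(calls_df$priority == "high" &
                                   !(calls_df$chemical_id %in% prom_ids))
  )

  structure(list(
    calls = calls_df,
    hits = hits,
    promiscuity = prom,
    gate_traces = lapply(calls, `[[`, "gate_trace"),
    summary = summary,
    config_echo = config
  ), class = "triage_report")
}

#' @export
print.triage_report <- function(x, ...) {
  s <- x$summary
  cat("Exposure-ADME triage report\n")
  cat(sprintf("  actives: %d  (high: %d, low: %d)\n", s$n_active, s$n_high, s$n_low))
  cat(sprintf("  low by exposure: %d, by absorption: %d, by BBB: %d\n",
              s$n_low_by_exposure, s$n_low_by_absorption, s$n_low_by_bbb))
  if (!is.null(x$hits))
    cat(sprintf("  flagged inactives: %d (inherited low: %d, possible false negatives: %d)\n",
                s$n_flagged_inactives, s$n_flagged_low_inherited,
                s$n_possible_false_negatives))
  cat(sprintf("  promiscuity suspects: %d (high priority excluding them: %d)\n",
              s$n_promiscuity_suspects, s$n_high_non_promiscuous))
  invisible(x)
}
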