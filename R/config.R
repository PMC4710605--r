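# config: run configuration with YAML round trip. The effective
# configuration is echoed verbatim into every report for reproducibility.

#' Triage run configuration
#'
#' @param threshold Tanimoto flagging threshold in `(0, 1]`; the comparison
#'   is inclusive (`>=`). Default 0.75.
#' @param ro5 Absorption thresholds, see [ro5_thresholds()].
#' @param bbb Distribution rules, see [bbb_rules()].
#' @param demote_promiscuous When TRUE, promiscuity suspects are demoted to
#'   low priority instead of only annotated.
#' @param alerts Promiscuity alert set, see [default_promiscuity_alerts()].
#' @param seed Optional integer seed recorded for generator reproducibility.
#' @return An object of class `triage_config`.
#' @export
triage_config <- function(threshold = 0.75, ro5 = ro5_thresholds(),
                          bbb = bbb_rules(), demote_promiscuous = FALSE,
                          alerts = default_promiscuity_alerts(), seed = NULL) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  structure(list(threshold = threshold, ro5 = ro5, bbb = bbb,
                 demote_promiscuous = isTRUE(demote_promiscuous),
                 alerts = validate_alerts(alerts), seed = seed),
            class = "triage_config")
}

#' Read / write a triage configuration as YAML
#'
#' Unspecified fields fall back to package defaults; the written file
#' reproduces the effective configuration bit-exactly on re-read.
#'
#' @param path YAML file path.
#' @return `read_triage_config()` returns a [triage_config()];
#'   `write_triage_config()` returns the path invisibly.
#' @export
read_triage_config <- function(path) {
  raw <- yaml::read_yaml(path)
  alerts <- if (is.null(raw$alerts)) default_promiscuity_alerts() else
    do.call(rbind, lapply(raw$alerts, function(a)
      data.frame(name = a$name, smarts = a$smarts, stringsAsFactors = FALSE)))
  triage_config(
    threshold = raw$threshold %||% 0.75,
    ro5 = utils::modifyList(ro5_thresholds(), raw$ro5 %||% list()),
    bbb = utils::modifyList(bbb_rules(), raw$bbb_rules %||% list(),
                            keep.null = TRUE),
    demote_promiscuous = raw$demote_promiscuous %||% FALSE,
    alerts = alerts,
    seed = raw$seed
  )
}

#' @rdname read_triage_config
#' @param config A [triage_config()].
#' @export
write_triage_config <- function(config, path) {
  stopifnot(inherits(config, "triage_config"))
  out <- list(
    threshold = config$threshold,
    ro5 = config$ro5,
    bbb_rules = config$bbb,
    demote_promiscuous = config$demote_promiscuous,
    alerts = lapply(seq_len(nrow(config$alerts)), function(i)
      list(name = config$alerts$name[i], smarts = config$alerts$smarts[i])),
    seed = config$seed
  )
  yaml::write_yaml(out, path)
  invisible(path)
}
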