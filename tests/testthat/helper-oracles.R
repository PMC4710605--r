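# Independent oracles and small builders shared across the suite.

# Straight recoding of the parent-compound decision tree, kept deliberately
# independent of the package implementation: a flat rule list over the
# annotation values, no gate machinery.
oracle_parent_priority <- function(exposure, absorption, distribution) {
  if (!is.na(exposure) && exposure == 4)
    return(list(priority = "low", reasons = "no_exposure"))
  if (identical(absorption, "Negligible"))
    return(list(priority = "low", reasons = "negligible_absorption"))
  if (identical(distribution, "No"))
    return(list(priority = "low", reasons = "no_bbb_distribution"))
  list(priority = "high", reasons = character(0))
}

# Exhaustive nearest-neighbor scan recomputing the similarity from the set
# definition, independent of the package's bit-matrix code path.
oracle_nearest <- function(query, active_mat) {
  sims <- apply(active_mat, 1, function(a) {
    inter <- sum(query == 1 & a == 1)
    uni <- sum(query == 1 | a == 1)
    if (uni == 0) 0 else inter / uni
  })
  list(max = max(sims), argmax = rownames(active_mat)[sims == max(sims)])
}

random_fp <- function(p = 0.2) as.integer(stats::runif(166) < p)

# Minimal chemical record for triage unit tests.
make_record <- function(id = "x", exposure = NA_integer_,
                        absorption = NA_character_,
                        distribution = NA_character_,
                        metabolism = NA_character_,
                        parent = NA_character_, smiles = NA_character_) {
  list(id = id, exposure_category = exposure,
       absorption_annotation = absorption,
       distribution_annotation = distribution,
       metabolism_code = metabolism, parent_id = parent, smiles = smiles)
}

make_absorption_call <- function(cls, violations = character(0)) {
  structure(list(cls = cls, violations = violations, source = "predicted"),
            class = "absorption_call")
}

make_distribution_call <- function(bbb, failed = character(0)) {
  structure(list(bbb_permeable = bbb, failed_rules = failed,
                 source = "predicted"),
            class = "distribution_call")
}
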