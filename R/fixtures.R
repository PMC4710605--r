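# fixtures: the packaged case-study inputs (30 printed actives plus the
# worked parent/metabolite pairs) and synthetic screening-library generators
# with planted, guaranteed-similar analogs and guaranteed-dissimilar decoys.

#' Load the packaged case-study fixture
#'
#' Thirty assay-active acetylcholinesterase inhibitors with their printed
#' AC50, exposure category, absorption/distribution annotations, metabolism
#' codes and priorities, plus the worked inactive chemicals (parents and
#' structural analogs) discussed alongside them. Structures of named
#' chemicals are standard registry structures (see the `registry` column);
#' failed pharmaceuticals with undisclosed structures carry no SMILES and
#' participate in annotation-driven triage only.
#'
#' @return A `fixture_set`: list with chemical tables `actives` (30 rows) and
#'   `inactives` (8 rows).
#' @examples
#' fx <- load_table1_fixture()
#' nrow(fx$actives)
#' @export
load_table1_fixture <- function() {
  actives <- read_chemical_table(
    system.file("extdata", "table1_actives.csv", package = "admetriage",
                mustWork = TRUE), "csv")
  inactives <- read_chemical_table(
    system.file("extdata", "worked_inactives.csv", package = "admetriage",
                mustWork = TRUE), "csv")
  stopifnot(nrow(actives) == 30L)
  structure(list(actives = actives, inactives = inactives),
            class = "fixture_set")
}

#' Enumerate every gate-annotation combination for oracle testing
#'
#' One synthetic active record per element of
#' exposure {1,2,3,4,unannotated} x absorption {Yes,Limited,Negligible,NA} x
#' distribution {Yes,No,NA} (60 records), with a deterministic id encoding
#' the combination.
#'
#' @return Chemical table with 60 rows.
#' @export
generate_triage_grid <- function() {
  grid <- expand.grid(
    exposure = c("1", "2", "3", "4", "unannotated"),
    absorption = c("Yes", "Limited", "Negligible", "NA"),
    distribution = c("Yes", "No", "NA"),
    stringsAsFactors = FALSE
  )
  tab <- data.frame(
    id = sprintf("grid_e%s_a%s_d%s", grid$exposure, grid$absorption,
                 grid$distribution),
    name = NA_character_,
    smiles = NA_character_,
    assay_outcome = "active",
    ac50_uM = NA_real_,
    exposure_category = suppressWarnings(as.integer(grid$exposure)),
    metabolism_code = NA_character_,
    parent_id = NA_character_,
    absorption_annotation = grid$absorption,
    distribution_annotation = grid$distribution,
    promiscuity_override = NA,
    stringsAsFactors = FALSE
  )
  tab
}

# ---- synthetic analogs ------------------------------------------------------

# Editable positions outside bracket atoms, so charges/isotopes are never
# rewritten by a structural edit.
mask_brackets <- function(smiles) {
  chars <- strsplit(smiles, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "[") depth <- depth + 1L
    inside <- depth > 0L
    if (chars[i] == "]") depth <- depth - 1L
    if (inside) chars[i] <- " "
  }
  paste(chars, collapse = "")
}

find_fixed <- function(masked, token) {
  hits <- gregexpr(token, masked, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer(0) else as.integer(hits)
}

apply_random_edit <- function(smiles) {
  masked <- mask_brackets(smiles)
  edits <- list()
  add_edit <- function(pos, len, repl)
    edits[[length(edits) + 1L]] <<- list(pos = pos, len = len, repl = repl)

  halogens <- c("Cl", "Br", "F", "I")
  for (h in halogens) {
    for (p in find_fixed(masked, h))
      for (repl in setdiff(halogens, h)) add_edit(p, nchar(h), repl)
  }
  for (p in find_fixed(masked, "=O")) add_edit(p, 2L, "=S")
  for (p in find_fixed(masked, "=S")) add_edit(p, 2L, "=O")
  for (p in find_fixed(masked, "CC")) add_edit(p, 2L, "CCC")
  # methyl extension at the tail of the string
  add_edit(nchar(smiles) + 1L, 0L, "C")

  if (!length(edits)) return(smiles)
  e <- edits[[sample.int(length(edits), 1L)]]
  paste0(substr(smiles, 1, e$pos - 1L), e$repl,
         substr(smiles, e$pos + e$len, nchar(smiles)))
}

#' Generate structural analogs of a scaffold with guaranteed similarity
#'
#' Derives analogs by 1..`max_edits` random edits from a fixed vocabulary
#' (halogen swap, O/S swap, chain extension, methyl addition) and keeps only
#' candidates whose MACCS Tanimoto to the scaffold is at least `threshold`
#' (rejection sampling, re-scored with the package's own fingerprints).
#' Deterministic for a given seed.
#'
#' @param scaffold_smiles Scaffold SMILES (single fragment).
#' @param n_analogs Number of analogs requested.
#' @param max_edits Maximum edits per analog.
#' @param threshold Minimum Tanimoto to the scaffold, inclusive.
#' @param seed Integer seed; no global RNG state is consumed.
#' @param scaffold_id Id used to label the analogs.
#' @return Chemical table of inactive analog records with columns
#'   `true_scaffold` and `tanimoto_to_scaffold`. A warning is raised (and a
#'   partial set returned) if the attempt budget is exhausted.
#' @export
generate_analog_series <- function(scaffold_smiles, n_analogs, max_edits = 2L,
                                   threshold = 0.75, seed = 1L,
                                   scaffold_id = "scaffold") {
  stopifnot(n_analogs >= 0)
  scaffold_can <- canonical_smiles(scaffold_smiles)
  if (is.na(scaffold_can))
    stop_admet(sprintf("unparsable scaffold SMILES '%s'", scaffold_smiles),
               "admet_parse_error")
  empty <- analog_records(character(0), scaffold_id, numeric(0))
  if (n_analogs == 0L) return(empty)
  scaffold_fp <- compute_maccs(scaffold_can)

  with_seed(seed, {
    analogs <- character(0)
    sims <- numeric(0)
    budget <- 60L * n_analogs
    while (length(analogs) < n_analogs && budget > 0L) {
      budget <- budget - 1L
      cand <- scaffold_smiles
      for (k in seq_len(sample.int(max_edits, 1L)))
        cand <- apply_random_edit(cand)
      can <- canonical_smiles(cand)
      if (is.na(can) || can == scaffold_can || can %in% analogs) next
      sim <- tryCatch(tanimoto(compute_maccs(can), scaffold_fp),
                      error = function(e) NA_real_)
      if (is.na(sim) || sim < threshold) next
      analogs <- c(analogs, can)
      sims <- c(sims, sim)
    }
    if (length(analogs) < n_analogs)
      warning(sprintf("analog budget exhausted for %s: %d of %d generated",
                      scaffold_id, length(analogs), n_analogs))
    analog_records(analogs, scaffold_id, sims)
  })
}

analog_records <- function(smiles, scaffold_id, sims) {
  n <- length(smiles)
  data.frame(
    id = if (n) sprintf("%s_analog_%02d", scaffold_id, seq_len(n)) else character(0),
    name = if (n) sprintf("synthetic analog %d of %s", seq_len(n), scaffold_id) else character(0),
    smiles = smiles,
    assay_outcome = rep("inactive", n),
    ac50_uM = rep(NA_real_, n),
    exposure_category = rep(NA_integer_, n),
    metabolism_code = rep(NA_character_, n),
    parent_id = rep(NA_character_, n),
    absorption_annotation = rep(NA_character_, n),
    distribution_annotation = rep(NA_character_, n),
    promiscuity_override = rep(NA, n),
    true_scaffold = rep(scaffold_id, n),
    tanimoto_to_scaffold = sims,
    stringsAsFactors = FALSE
  )
}

# ---- decoys ------------------------------------------------------------------

#' Built-in pool of diverse decoy structures
#'
#' Common drugs, natural products and simple organics spanning chemistries
#' unrelated to organophosphate/carbamate pesticides; used as the sampling
#' pool for [generate_decoys()].
#'
#' @return Named character vector of SMILES.
#' @export
decoy_pool <- function() c(
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  naproxen = "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
  paracetamol = "CC(=O)Nc1ccc(O)cc1",
  naphthalene = "c1ccc2ccccc2c1",
  anthracene = "c1ccc2cc3ccccc3cc2c1",
  pyrene = "c1cc2ccc3cccc4ccc(c1)c2c34",
  fluorene = "C1c2ccccc2-c2ccccc21",
  biphenyl = "c1ccc(-c2ccccc2)cc1",
  toluene = "Cc1ccccc1",
  aniline = "Nc1ccccc1",
  phenol = "Oc1ccccc1",
  benzoic_acid = "OC(=O)c1ccccc1",
  benzophenone = "O=C(c1ccccc1)c1ccccc1",
  cholesterol = "CC(C)CCC[C@@H](C)[C@H]1CC[C@H]2[C@@H]3CC=C4C[C@@H](O)CC[C@]4(C)[C@H]3CC[C@]12C",
  estradiol = "CC12CCC3c4ccc(O)cc4CCC3C1CCC2O",
  testosterone = "CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O",
  glucose = "OCC1OC(O)C(O)C(O)C1O",
  sucrose = "OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O",
  nicotine = "CN1CCCC1c1cccnc1",
  indole = "c1ccc2[nH]ccc2c1",
  imidazole = "c1c[nH]cn1",
  pyridine = "c1ccncc1",
  pyrimidine = "c1cncnc1",
  adenine = "Nc1ncnc2[nH]cnc12",
  uracil = "O=c1cc[nH]c(=O)[nH]1",
  thymine = "Cc1c[nH]c(=O)[nH]c1=O",
  cytosine = "Nc1cc[nH]c(=O)n1",
  benzimidazole = "c1ccc2[nH]cnc2c1",
  diazepam = "CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1",
  hexane = "CCCCCC",
  cyclohexane = "C1CCCCC1",
  octanol = "CCCCCCCCO",
  stearic_acid = "CCCCCCCCCCCCCCCCCC(=O)O",
  glycerol = "OCC(O)CO",
  citric_acid = "OC(=O)CC(O)(CC(=O)O)C(=O)O",
  urea = "NC(N)=O",
  acetone = "CC(C)=O",
  dmso = "CS(C)=O",
  saccharin = "O=C1NS(=O)(=O)c2ccccc12",
  ascorbic_acid = "OC[C@H](O)[C@H]1OC(=O)C(O)=C1O",
  tryptophan = "NC(Cc1c[nH]c2ccccc12)C(=O)O",
  phenylalanine = "NC(Cc1ccccc1)C(=O)O",
  serotonin = "NCCc1c[nH]c2ccc(O)cc12",
  dopamine = "NCCc1ccc(O)c(O)c1",
  histamine = "NCCc1c[nH]cn1",
  melatonin = "COc1ccc2[nH]cc(CCNC(C)=O)c2c1",
  atrazine = "CCNc1nc(Cl)nc(NC(C)C)n1",
  warfarin = "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
  coumarin = "O=c1ccc2ccccc2o1",
  vanillin = "COc1cc(C=O)ccc1O",
  eugenol = "COc1cc(CC=C)ccc1O",
  limonene = "CC(=C)C1CCC(C)=CC1",
  menthol = "CC(C)C1CCC(C)CC1O",
  camphor = "CC1(C)C2CCC1(C)C(=O)C2"
)

#' Sample decoy records guaranteed dissimilar to every scaffold
#'
#' Draws from [decoy_pool()] (deterministically per seed) and keeps only
#' molecules whose MACCS Tanimoto to every scaffold is below `threshold`,
#' re-checked with the package's own fingerprint code.
#'
#' @param n Number of decoys requested.
#' @param scaffolds Character vector of scaffold SMILES.
#' @param threshold Exclusion threshold (strictly below).
#' @param seed Integer seed.
#' @return Chemical table of inactive decoy records with a
#'   `max_tanimoto_to_scaffolds` column. Warns and returns a partial set if
#'   the pool is exhausted.
#' @export
generate_decoys <- function(n, scaffolds, threshold = 0.75, seed = 1L) {
  stopifnot(n >= 0)
  pool <- decoy_pool()
  scaffold_fps <- lapply(scaffolds, function(s) compute_maccs(canonical_smiles(s)))
  with_seed(seed, {
    order_ <- sample.int(length(pool))
    kept <- character(0); kept_names <- character(0); maxsim <- numeric(0)
    for (i in order_) {
      if (length(kept) >= n) break
      can <- canonical_smiles(pool[i])
      if (is.na(can)) next
      fp <- compute_maccs(can)
      sims <- vapply(scaffold_fps, function(f) tanimoto(fp, f), numeric(1))
      if (max(sims) >= threshold) next
      kept <- c(kept, can); kept_names <- c(kept_names, names(pool)[i])
      maxsim <- c(maxsim, max(sims))
    }
    if (length(kept) < n)
      warning(sprintf("decoy pool exhausted: %d of %d decoys generated",
                      length(kept), n))
    nk <- length(kept)
    data.frame(
      id = if (nk) sprintf("decoy_%02d_%s", seq_len(nk), kept_names) else character(0),
      name = kept_names,
      smiles = kept,
      assay_outcome = rep("inactive", nk),
      ac50_uM = rep(NA_real_, nk),
      exposure_category = rep(NA_integer_, nk),
      metabolism_code = rep(NA_character_, nk),
      parent_id = rep(NA_character_, nk),
      absorption_annotation = rep(NA_character_, nk),
      distribution_annotation = rep(NA_character_, nk),
      promiscuity_override = rep(NA, nk),
      max_tanimoto_to_scaffolds = maxsim,
      stringsAsFactors = FALSE
    )
  })
}

# ---- composite synthetic library --------------------------------------------

default_scaffolds <- function() c(
  methomyl = "CNC(=O)O/N=C(\\C)SC",
  propoxur = "CNC(=O)Oc1ccccc1OC(C)C",
  mevinphos = "COP(=O)(OC)O/C(C)=C/C(=O)OC"
)

#' Generate a synthetic screening library with known structure
#'
#' Emulates a screening inventory at desk scale: scaffold "actives" with
#' randomized gate annotations, planted analogs guaranteed to be flagged at
#' the generation threshold, and decoys guaranteed not to be. Same seed,
#' same library.
#'
#' @param scaffolds Named character vector of scaffold SMILES; defaults to
#'   three pesticide scaffolds from the packaged case study.
#' @param n_analogs Analogs planted per scaffold.
#' @param n_decoys Total decoys.
#' @param threshold Generation threshold (analogs >=, decoys <).
#' @param max_edits Maximum structural edits per analog.
#' @param seed Integer seed.
#' @return A `synthetic_library`: list with `actives`, `inactives`,
#'   `planted_ids`, `decoy_ids`, `threshold` and `seed`.
#' @export
generate_screening_library <- function(scaffolds = default_scaffolds(),
                                       n_analogs = 3L, n_decoys = 10L,
                                       threshold = 0.75, max_edits = 2L,
                                       seed = 1L) {
  if (is.null(names(scaffolds)))
    names(scaffolds) <- sprintf("scaffold_%02d", seq_along(scaffolds))
  actives <- with_seed(seed, data.frame(
    id = names(scaffolds),
    name = names(scaffolds),
    smiles = unname(scaffolds),
    assay_outcome = "active",
    ac50_uM = round(stats::rlnorm(length(scaffolds), meanlog = 1, sdlog = 1), 3),
    exposure_category = sample(1:4, length(scaffolds), replace = TRUE),
    metabolism_code = sample(c("+", "-", "+-", "=", "NA", "U"),
                             length(scaffolds), replace = TRUE),
    parent_id = NA_character_,
    absorption_annotation = sample(c("Yes", "Limited", NA), length(scaffolds),
                                   replace = TRUE),
    distribution_annotation = sample(c("Yes", "No", NA), length(scaffolds),
                                     replace = TRUE),
    promiscuity_override = NA,
    stringsAsFactors = FALSE
  ))
  analogs <- do.call(rbind, lapply(seq_along(scaffolds), function(i)
    generate_analog_series(scaffolds[i], n_analogs, max_edits = max_edits,
                           threshold = threshold, seed = seed + i,
                           scaffold_id = names(scaffolds)[i])))
  decoys <- generate_decoys(n_decoys, unname(scaffolds), threshold = threshold,
                            seed = seed)
  shared <- intersect(names(analogs), names(decoys))
  inactives <- rbind(analogs[shared], decoys[shared])
  structure(list(
    actives = actives,
    inactives = inactives,
    planted_ids = analogs$id,
    decoy_ids = decoys$id,
    threshold = threshold,
    seed = seed
  ), class = "synthetic_library")
}
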