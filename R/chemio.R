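# chemio: reading chemical tables, SMILES parsing and structure washing.
#
# All structure handling is delegated to Open Babel via ChemmineOB; this
# module adds the salt-stripping / neutralization policy and the tabular
# record contracts used by the rest of the pipeline.

# ---- low-level Open Babel wrappers -----------------------------------------

ob_convert <- function(smiles, to = "CAN") {
  out <- tryCatch(ChemmineOB::convertFormat("SMILES", to, smiles),
                  error = function(e) "")
  out <- sub("[ \t\r\n]+$", "", out)
  out
}

ob_with_mol <- function(smiles, f) {
  ChemmineOB::forEachMol("SMILES", smiles, f)[[1]]
}

ob_props <- function(smiles) ob_with_mol(smiles, function(m) ChemmineOB::prop_OB(m))

ob_smarts_count <- function(smiles, pattern) {
  ob_with_mol(smiles, function(m)
    ChemmineOB::smartsSearch_OB(list(m), pattern, uniqueMatches = TRUE))
}

#' Canonical SMILES via Open Babel
#'
#' @param smiles A single SMILES string.
#' @return The canonical SMILES, or `NA_character_` if the string does not
#'   parse.
#' @export
canonical_smiles <- function(smiles) {
  if (!is_scalar_string(smiles) || !nzchar(smiles)) return(NA_character_)
  out <- ob_convert(smiles, "CAN")
  if (!nzchar(out)) NA_character_ else out
}

# ---- parse_structure --------------------------------------------------------

#' Parse a SMILES string into a structure handle
#'
#' Thin validation layer over the Open Babel SMILES reader. Multi-fragment
#' (salt-form) inputs are accepted; washing decides which fragment is kept.
#'
#' @param smiles SMILES string, possibly multi-fragment.
#' @param id Optional record id used to label parse errors.
#' @return An object of class `admet_mol`: a list with `input_smiles`,
#'   `canonical_smiles`, `formula`, `heavy_atoms` and `n_fragments`.
#' @examples
#' parse_structure("CCO")
#' @export
parse_structure <- function(smiles, id = NULL) {
  label <- if (is.null(id)) "" else sprintf(" (record '%s')", id)
  if (!is_scalar_string(smiles) || !nzchar(smiles))
    stop_admet(sprintf("empty or missing SMILES%s", label), "admet_parse_error")
  can <- canonical_smiles(smiles)
  if (is.na(can))
    stop_admet(sprintf("unparsable SMILES '%s'%s", smiles, label),
               "admet_parse_error")
  props <- ob_props(can)
  structure(list(
    input_smiles = smiles,
    canonical_smiles = can,
    formula = props$formula,
    heavy_atoms = heavy_atom_count(props$formula),
    n_fragments = length(strsplit(can, ".", fixed = TRUE)[[1]])
  ), class = "admet_mol")
}

# ---- washing ----------------------------------------------------------------

# Charged-group pairs that must never be "neutralized": nitro groups,
# N-oxides and aromatic azinium oxides carry internally compensated charges.
.protected_charge_patterns <- c(
  "[N+](=O)[O-]", "[O-][N+](=O)", "[N+]([O-])=O",
  "[O-][N+]", "[N+][O-]", "[n+][O-]", "[O-][n+]"
)

# Fixed neutralization table: protic cations lose a proton, common anions
# gain one. Quaternary ammoniums and other H-free cations keep their
# permanent charge; exotic anions (azides, carbanions) are left untouched.
.neutralization_table <- list(
  list(from = "[NH3+]", to = "N",    note = "deprotonated [NH3+]"),
  list(from = "[NH2+]", to = "N",    note = "deprotonated [NH2+]"),
  list(from = "[NH+]",  to = "N",    note = "deprotonated [NH+]"),
  list(from = "[nH+]",  to = "n",    note = "deprotonated [nH+]"),
  list(from = "[O-]",   to = "O",    note = "protonated [O-]"),
  list(from = "[S-]",   to = "S",    note = "protonated [S-]"),
  list(from = "[NH-]",  to = "N",    note = "protonated [NH-]")
)

neutralize_smiles <- function(smiles) {
  masked <- smiles
  masks <- character(0)
  for (i in seq_along(.protected_charge_patterns)) {
    pat <- .protected_charge_patterns[i]
    key <- sprintf("\001%d\001", i)
    if (grepl(pat, masked, fixed = TRUE)) {
      masked <- gsub(pat, key, masked, fixed = TRUE)
      masks[key] <- pat
    }
  }
  notes <- character(0)
  for (tr in .neutralization_table) {
    if (grepl(tr$from, masked, fixed = TRUE)) {
      masked <- gsub(tr$from, tr$to, masked, fixed = TRUE)
      notes <- c(notes, tr$note)
    }
  }
  for (key in names(masks)) masked <- gsub(key, masks[key], masked, fixed = TRUE)
  list(smiles = masked, notes = notes)
}

#' Wash a structure: strip salts, neutralize, canonicalize
#'
#' Keeps the largest fragment by heavy-atom count (ties broken by molecular
#' weight, then by canonical-SMILES order), applies a fixed table of standard
#' acid/base neutralizations (permanent charges such as quaternary ammoniums
#' are kept), and emits the canonical SMILES of the result. Washing is
#' idempotent.
#'
#' @param mol An `admet_mol` from [parse_structure()], or a SMILES string.
#' @param id Optional source record id recorded in the result.
#' @return A `structure_record`: list with `source_id`, `washed_smiles`,
#'   `n_fragments_removed`, `is_organic` and `wash_notes`.
#' @examples
#' wash_structure("CC(=O)[O-].[Na+]")$washed_smiles
#' @export
wash_structure <- function(mol, id = NULL) {
  if (is.character(mol)) mol <- parse_structure(mol, id = id)
  stopifnot(inherits(mol, "admet_mol"))
  frags <- strsplit(mol$canonical_smiles, ".", fixed = TRUE)[[1]]
  notes <- character(0)

  if (length(frags) > 1L) {
    info <- lapply(frags, function(f) {
      p <- ob_props(f)
      list(heavy = heavy_atom_count(p$formula), mw = p$MW)
    })
    heavy <- vapply(info, `[[`, numeric(1), "heavy")
    mw <- vapply(info, `[[`, numeric(1), "mw")
    ord <- order(-heavy, -mw, frags)
    kept <- frags[ord[1]]
    notes <- c(notes, sprintf("removed %d salt/solvent fragment(s)",
                              length(frags) - 1L))
  } else {
    kept <- frags
  }

  neut <- neutralize_smiles(kept)
  washed <- neut$smiles
  notes <- c(notes, neut$notes)
  can <- canonical_smiles(washed)
  if (is.na(can)) {
    # neutralization produced something unreadable: keep the stripped
    # fragment as-is rather than failing the record
    can <- canonical_smiles(kept)
    notes <- c(notes, "neutralization reverted (unparsable result)")
  }
  if (is.na(can) || !nzchar(can))
    stop_admet("empty molecule after washing", "admet_wash_error")

  props <- ob_props(can)
  organic <- contains_carbon(props$formula)
  if (!organic) notes <- c(notes, "inorganic (no carbon): descriptor calls are low-confidence")

  structure(list(
    source_id = id %||% NA_character_,
    washed_smiles = can,
    n_fragments_removed = length(frags) - 1L,
    is_organic = organic,
    wash_notes = notes
  ), class = "structure_record")
}

#' @rdname wash_structure
#' @param smiles SMILES string washed in one step.
#' @export
wash_smiles <- function(smiles, id = NULL) wash_structure(smiles, id = id)

# ---- chemical tables --------------------------------------------------------

.chemical_columns <- c("id", "name", "smiles", "assay_outcome", "ac50_uM",
                       "exposure_category", "metabolism_code", "parent_id",
                       "absorption_annotation", "distribution_annotation",
                       "promiscuity_override")

.assay_outcomes <- c("active", "inactive", "untested")

#' Read a chemical table from CSV or SDF
#'
#' The CSV dialect is RFC 4180, UTF-8, header mandatory. The literal string
#' `"NA"` in annotation columns is an annotation value (Table-style
#' "not applicable"), not a missing value; missing annotations are empty
#' cells. SDF input (V2000) maps SD tags of the same names onto the columns
#' and takes SMILES from the connection table.
#'
#' @param path File path.
#' @param format `"csv"` or `"sdf"`.
#' @return A `data.frame` of chemical records, one row per chemical. Columns
#'   beyond the standard set are preserved as-is.
#' @export
read_chemical_table <- function(path, format = c("csv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop_admet(sprintf("file not found: %s", path), "admet_io_error")
  tab <- if (format == "csv") read_chemical_csv(path) else read_chemical_sdf(path)
  validate_chemical_table(tab)
  tab
}

read_chemical_csv <- function(path) {
  tab <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(0), check.names = FALSE,
                         fileEncoding = "UTF-8")
  mandatory <- c("id", "smiles", "assay_outcome")
  missing <- setdiff(mandatory, names(tab))
  if (length(missing))
    stop_admet(sprintf("chemical table %s lacks mandatory column(s): %s",
                       path, paste(missing, collapse = ", ")),
               "admet_schema_error")
  coerce_chemical_table(tab)
}

read_chemical_sdf <- function(path) {
  sdf <- ChemmineR::read.SDFset(path)
  smi <- vapply(seq_along(sdf@SDF), function(i) {
    can <- tryCatch(
      ChemmineOB::convertFormat("SDF", "CAN",
                                paste(ChemmineR::sdf2str(sdf@SDF[[i]]),
                                      collapse = "\n")),
      error = function(e) "")
    sub("[ \t\r\n]+$", "", sub("\t.*$", "", can))
  }, character(1))
  blocks <- ChemmineR::datablock(sdf)
  tags <- unique(unlist(lapply(blocks, names)))
  tab <- data.frame(smiles = smi, stringsAsFactors = FALSE)
  for (tg in tags)
    tab[[tg]] <- vapply(blocks, function(b) if (tg %in% names(b)) b[[tg]] else "",
                        character(1))
  if (!"id" %in% names(tab)) tab$id <- ChemmineR::sdfid(sdf)
  coerce_chemical_table(tab)
}

coerce_chemical_table <- function(tab) {
  for (col in setdiff(.chemical_columns, names(tab)))
    tab[[col]] <- rep("", nrow(tab))
  for (col in .chemical_columns)
    tab[[col]][is.na(tab[[col]])] <- ""
  empty_to_na <- function(x) ifelse(nzchar(x), x, NA_character_)
  out <- tab
  out$id <- tab$id
  out$name <- empty_to_na(tab$name)
  out$smiles <- empty_to_na(tab$smiles)
  out$assay_outcome <- tab$assay_outcome
  out$ac50_uM <- suppressWarnings(as.numeric(empty_to_na(tab$ac50_uM)))
  out$exposure_category <- suppressWarnings(as.integer(empty_to_na(tab$exposure_category)))
  out$metabolism_code <- empty_to_na(tab$metabolism_code)
  out$parent_id <- empty_to_na(tab$parent_id)
  out$absorption_annotation <- empty_to_na(tab$absorption_annotation)
  out$distribution_annotation <- empty_to_na(tab$distribution_annotation)
  ovr <- empty_to_na(tab$promiscuity_override)
  out$promiscuity_override <- ifelse(is.na(ovr), NA, toupper(ovr) %in% "TRUE")
  out[, c(.chemical_columns, setdiff(names(tab), .chemical_columns)), drop = FALSE]
}

validate_chemical_table <- function(tab) {
  dup <- unique(tab$id[duplicated(tab$id)])
  if (length(dup))
    stop_admet(sprintf("duplicate record id(s): %s", paste(dup, collapse = ", ")),
               "admet_integrity_error")
  bad <- !(tab$assay_outcome %in% .assay_outcomes)
  if (any(bad))
    stop_admet(sprintf("invalid assay_outcome for record(s): %s",
                       paste(tab$id[bad], collapse = ", ")),
               "admet_schema_error")
  bad_ac50 <- !is.na(tab$ac50_uM) & tab$ac50_uM <= 0
  if (any(bad_ac50))
    stop_admet(sprintf("non-positive AC50 for record(s): %s",
                       paste(tab$id[bad_ac50], collapse = ", ")),
               "admet_integrity_error")
  bad_exp <- !is.na(tab$exposure_category) & !(tab$exposure_category %in% 1:4)
  if (any(bad_exp))
    stop_admet(sprintf("exposure_category outside 1..4 for record(s): %s",
                       paste(tab$id[bad_exp], collapse = ", ")),
               "admet_integrity_error")
  invisible(tab)
}

# ---- reports ----------------------------------------------------------------

#' Write a triage report to disk
#'
#' The CSV form flattens list-valued fields (reasons, rank notes, ties) into
#' pipe-separated strings and is round-trip safe via [read_report()]. The
#' JSON form serializes the full report including summary counts and the
#' effective configuration.
#'
#' @param report A `triage_report` from [run_workflow()], or a plain
#'   `data.frame` of calls/hits.
#' @param path Output file path.
#' @param format `"csv"` or `"json"`.
#' @export
write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass_report(report), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    return(invisible(path))
  }
  tab <- if (inherits(report, "triage_report")) report$calls else report
  stopifnot(is.data.frame(tab))
  flat <- tab
  for (col in names(flat))
    if (is.list(flat[[col]]))
      flat[[col]] <- vapply(flat[[col]], function(x) paste(x, collapse = "|"),
                            character(1))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(flat, con, row.names = FALSE, na = "")
  invisible(path)
}

unclass_report <- function(report) {
  if (!inherits(report, "triage_report")) return(report)
  rep <- unclass(report)
  rep$calls <- flatten_list_cols(rep$calls)
  if (!is.null(rep$hits)) rep$hits <- flatten_list_cols(rep$hits)
  rep
}

flatten_list_cols <- function(tab) {
  for (col in names(tab))
    if (is.list(tab[[col]]))
      tab[[col]] <- vapply(tab[[col]], function(x) paste(x, collapse = "|"),
                           character(1))
  tab
}

#' @rdname write_report
#' @return `read_report()` returns the calls table with empty cells as `NA`.
#' @export
read_report <- function(path) {
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = "", fileEncoding = "UTF-8")
}
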