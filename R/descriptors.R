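# descriptors: physicochemical properties and the absorption / distribution
# classification rules.
#
# logP is Open Babel's atom-contribution (Crippen-type) estimate; TPSA is the
# Ertl topological polar surface area; the hydrogen-bond-acceptor count is
# the classic N + O heavy-atom count used by the Rule of 5.

.rotor_smarts <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' Construct a descriptor set
#'
#' Mostly used internally by [compute_descriptors()]; exported so that rule
#' classifiers can be exercised on hand-built descriptor values.
#'
#' @param mw Molecular weight, g/mol.
#' @param logp Octanol-water partition estimate (log Kow), unitless.
#' @param hbd Hydrogen-bond donors (integer >= 0).
#' @param hba Hydrogen-bond acceptors, N + O count (integer >= 0).
#' @param rotatable_bonds Rotatable-bond count (integer >= 0).
#' @param tpsa Topological polar surface area, A^2 (>= 0).
#' @param net_formal_charge Net formal charge (integer).
#' @param low_confidence TRUE when the structure is inorganic/organometallic
#'   and the estimates are best-effort.
#' @return An object of class `descriptor_set`.
#' @export
descriptor_set <- function(mw, logp, hbd, hba, rotatable_bonds, tpsa,
                           net_formal_charge = 0L, low_confidence = FALSE) {
  stopifnot(mw > 0, hbd >= 0, hba >= 0, rotatable_bonds >= 0, tpsa >= 0)
  structure(list(
    mw = as.numeric(mw), logp = as.numeric(logp),
    hbd = as.integer(hbd), hba = as.integer(hba),
    rotatable_bonds = as.integer(rotatable_bonds),
    tpsa = as.numeric(tpsa),
    net_formal_charge = as.integer(net_formal_charge),
    low_confidence = isTRUE(low_confidence)
  ), class = "descriptor_set")
}

#' Compute physicochemical descriptors for a washed structure
#'
#' @param structure A `structure_record` from [wash_structure()], or a SMILES
#'   string (washed on the fly).
#' @return A [descriptor_set()]. `low_confidence` is set for inorganic
#'   structures, whose fragment-based estimates (logP, TPSA) are
#'   best-effort only.
#' @examples
#' compute_descriptors("CCO")
#' @export
compute_descriptors <- function(structure) {
  if (is.character(structure)) structure <- wash_structure(structure)
  stopifnot(inherits(structure, "structure_record"))
  smi <- structure$washed_smiles
  p <- ob_props(smi)
  counts <- parse_formula(p$formula)
  hba <- sum(counts[intersect(c("N", "O"), names(counts))])
  rot <- as.integer(ob_smarts_count(smi, .rotor_smarts))
  descriptor_set(
    mw = p$MW, logp = p$logP, hbd = p$HBD, hba = hba,
    rotatable_bonds = rot, tpsa = p$TPSA,
    net_formal_charge = smiles_formal_charge(smi),
    low_confidence = !structure$is_organic
  )
}

# ---- absorption (Rule of 5, Veber-extended) ---------------------------------

#' Default absorption (Rule-of-5) thresholds
#'
#' Violations are strict: a descriptor exactly at a threshold does not
#' violate it. The six criteria are the classic Rule-of-5 bounds extended by
#' the rotatable-bond and polar-surface-area limits commonly applied to oral
#' bioavailability.
#'
#' @return Named list of thresholds.
#' @export
ro5_thresholds <- function() {
  list(mw_max = 500, logp_max = 5, hbd_max = 5, hba_max = 10,
       rotatable_bonds_max = 10, tpsa_max = 140)
}

#' Classify oral-absorption potential from descriptors
#'
#' @param d A [descriptor_set()].
#' @param thresholds Threshold list, see [ro5_thresholds()].
#' @return An `absorption_call`: list with `cls` (`"Yes"` when free of
#'   violations, `"Limited"` otherwise), `violations` and
#'   `source = "predicted"`. The class `"Negligible"` is reserved for
#'   annotation input and never produced by the predictor.
#' @export
classify_absorption <- function(d, thresholds = ro5_thresholds()) {
  stopifnot(inherits(d, "descriptor_set"))
  v <- character(0)
  if (d$mw > thresholds$mw_max) v <- c(v, "mw_gt_500")
  if (d$logp > thresholds$logp_max) v <- c(v, "logp_gt_5")
  if (d$hbd > thresholds$hbd_max) v <- c(v, "hbd_gt_5")
  if (d$hba > thresholds$hba_max) v <- c(v, "hba_gt_10")
  if (d$rotatable_bonds > thresholds$rotatable_bonds_max) v <- c(v, "rotbonds_gt_10")
  if (d$tpsa > thresholds$tpsa_max) v <- c(v, "tpsa_gt_140")
  structure(list(
    cls = if (length(v)) "Limited" else "Yes",
    violations = v,
    source = "predicted"
  ), class = "absorption_call")
}

# ---- distribution (blood-brain barrier) -------------------------------------

#' Default blood-brain-barrier permeability rules
#'
#' A physicochemical stand-in for trained BBB classifiers: CNS-permeant
#' chemicals are small, moderately lipophilic, weak hydrogen-bond donors with
#' limited polar surface and no net negative charge. Every enabled rule must
#' pass for a `"Yes"` call. Set an entry to `NULL` or `NA` (`.na` in YAML
#' configs) to disable that rule.
#'
#' @param tpsa_max Maximum TPSA, A^2.
#' @param mw_max Maximum molecular weight, g/mol.
#' @param logp_min,logp_max Allowed logP window.
#' @param hbd_max Maximum hydrogen-bond donors.
#' @param charge_min Minimum net formal charge (anions do not cross).
#' @return Named list of rule thresholds.
#' @export
bbb_rules <- function(tpsa_max = 90, mw_max = 450, logp_min = 1, logp_max = 4,
                      hbd_max = 3, charge_min = 0) {
  list(tpsa_max = tpsa_max, mw_max = mw_max, logp_min = logp_min,
       logp_max = logp_max, hbd_max = hbd_max, charge_min = charge_min)
}

#' Classify blood-brain-barrier permeability from descriptors
#'
#' @param d A [descriptor_set()].
#' @param rules Rule list from [bbb_rules()]; `NULL` entries are disabled.
#' @return A `distribution_call`: list with `bbb_permeable` (`"Yes"`/`"No"`),
#'   `failed_rules` and `source = "predicted"`.
#' @export
classify_bbb <- function(d, rules = bbb_rules()) {
  stopifnot(inherits(d, "descriptor_set"))
  failed <- character(0)
  chk <- function(name, passes) {
    r <- rules[[name]]
    if (is.null(r) || (length(r) == 1L && is.na(r))) return(invisible())
    if (!passes(r)) failed <<- c(failed, name)
  }
  chk("tpsa_max", function(r) d$tpsa <= r)
  chk("mw_max", function(r) d$mw <= r)
  chk("logp_min", function(r) d$logp >= r)
  chk("logp_max", function(r) d$logp <= r)
  chk("hbd_max", function(r) d$hbd <= r)
  chk("charge_min", function(r) d$net_formal_charge >= r)
  structure(list(
    bbb_permeable = if (length(failed)) "No" else "Yes",
    failed_rules = failed,
    source = "predicted"
  ), class = "distribution_call")
}
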