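# fingerprints: MACCS 166-key structural fingerprints, Tanimoto similarity
# and nearest-active-neighbor screening.
#
# Key definitions are the public MDL MACCS SMARTS set as implemented by Open
# Babel; bit i of the vector is MACCS key i.

MACCS_NBITS <- 166L

#' Compute the 166-key MACCS fingerprint of a washed structure
#'
#' @param structure A `structure_record`, an `admet_mol`, or a SMILES string.
#' @return An integer 0/1 vector of length 166 with class `maccs_fp`; the
#'   number of set bits is available as `attr(, "popcount")`. A structure
#'   matching no key yields an all-zero fingerprint with a warning.
#' @examples
#' fp <- compute_maccs("c1ccccc1")
#' attr(fp, "popcount")
#' @export
compute_maccs <- function(structure) {
  smi <- if (is.character(structure)) {
    s <- canonical_smiles(structure)
    if (is.na(s)) stop_admet(sprintf("unparsable SMILES '%s'", structure),
                             "admet_parse_error")
    s
  } else if (inherits(structure, "structure_record")) {
    structure$washed_smiles
  } else if (inherits(structure, "admet_mol")) {
    structure$canonical_smiles
  } else stop("unsupported input to compute_maccs()")
  bits <- ob_with_mol(smi, function(m)
    as.integer(ChemmineOB::fingerprint_OB(list(m), "MACCS")))[seq_len(MACCS_NBITS)]
  pc <- sum(bits)
  if (pc == 0L)
    warning(sprintf("all-zero MACCS fingerprint for '%s': no key matched", smi))
  base::structure(bits, popcount = pc, class = "maccs_fp")
}

#' Fingerprint a vector of structures into a bit matrix
#'
#' @param smiles Named character vector of (washed) SMILES; names become row
#'   names.
#' @return Integer matrix, one row per structure, 166 columns (MACCS keys).
#' @export
maccs_fingerprints <- function(smiles) {
  stopifnot(is.character(smiles))
  out <- t(vapply(smiles, function(s) as.integer(compute_maccs(s)),
                  integer(MACCS_NBITS)))
  colnames(out) <- paste0("key", seq_len(MACCS_NBITS))
  out
}

#' Tanimoto similarity between two fingerprints
#'
#' |intersection| / |union| of the set bits. Two all-zero fingerprints carry
#' no structural evidence, so their similarity is defined as 0 (with a
#' warning), not 1.
#'
#' @param a,b 0/1 vectors of equal length (166 for MACCS keys).
#' @return Similarity in `[0, 1]`.
#' @examples
#' tanimoto(c(1, 1, 1, 0), c(0, 1, 1, 1))
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b))
    stop_admet(sprintf("fingerprint length mismatch: %d vs %d",
                       length(a), length(b)), "admet_contract_error")
  a <- as.logical(a); b <- as.logical(b)
  union <- sum(a | b)
  if (union == 0L) {
    warning("Tanimoto of two all-zero fingerprints defined as 0: no structural evidence")
    return(0)
  }
  sum(a & b) / union
}

# Row-wise Tanimoto of a query bit vector against a bit matrix.
tanimoto_row <- function(query, mat) {
  q <- as.integer(query)
  inter <- as.vector(mat %*% q)
  uni <- rowSums(mat) + sum(q) - inter
  ifelse(uni == 0, 0, inter / uni)
}

#' Nearest active neighbor of a query fingerprint
#'
#' Finds the active with the maximal Tanimoto similarity to the query. Ties
#' are broken by lowest active AC50 (most potent first), then by
#' lexicographic id; all equally similar actives are reported in `ties`.
#'
#' @param query A `maccs_fp` or 0/1 vector of length 166.
#' @param actives Integer bit matrix of active fingerprints with row names
#'   (from [maccs_fingerprints()]).
#' @param ac50 Optional numeric vector of active AC50 values (uM), aligned
#'   with the rows of `actives`, used for tie-breaking.
#' @param threshold Flagging threshold; the hit is flagged when its Tanimoto
#'   is `>= threshold` (inclusive).
#' @param query_id Id recorded on the hit.
#' @return A one-row `data.frame` (`SimilarityHit`): `query_id`,
#'   `neighbor_id`, `tanimoto`, `flagged`, `inherited_priority` (NA until
#'   [propagate_neighbor_priority()]), and list-column `ties`.
#' @export
nearest_active_neighbor <- function(query, actives, ac50 = NULL,
                                    threshold = 0.75, query_id = NA_character_) {
  if (is.null(dim(actives)) || nrow(actives) == 0L)
    stop_admet("empty active set in nearest-neighbor query", "admet_contract_error")
  if (is.null(rownames(actives)))
    rownames(actives) <- paste0("active", seq_len(nrow(actives)))
  sims <- tanimoto_row(query, actives)
  best <- max(sims)
  tied <- which(sims == best)
  ids <- rownames(actives)[tied]
  if (length(tied) > 1L) {
    key_ac50 <- if (is.null(ac50)) rep(Inf, length(tied)) else {
      v <- ac50[tied]; v[is.na(v)] <- Inf; v
    }
    winner <- ids[order(key_ac50, ids)][1]
  } else winner <- ids
  data.frame(
    query_id = query_id,
    neighbor_id = winner,
    tanimoto = best,
    flagged = best >= threshold,
    inherited_priority = NA_character_,
    ties = I(list(if (length(ids) > 1L) ids else character(0))),
    stringsAsFactors = FALSE
  )
}

#' Screen inactive chemicals against the active set
#'
#' Washes and fingerprints both sets, finds each inactive's nearest active
#' neighbor, and flags inactives whose similarity meets the threshold as
#' possible in vitro false negatives. Records whose structures are missing
#' or unparsable are skipped (collected in `attr(, "skipped")`), never
#' aborting the batch.
#'
#' @param inactives,actives Chemical tables (see [read_chemical_table()]).
#'   Actives without a SMILES are excluded from the reference set.
#' @param threshold Tanimoto flagging threshold in `(0, 1]`, inclusive
#'   comparison; default 0.75.
#' @return A `data.frame` of similarity hits, one per screened inactive,
#'   sorted by descending Tanimoto; `attr(, "skipped")` lists skipped record
#'   ids with the reason.
#' @export
screen_inactives <- function(inactives, actives, threshold = 0.75) {
  stopifnot(is.data.frame(inactives), is.data.frame(actives),
            threshold > 0, threshold <= 1)
  skipped <- data.frame(id = character(0), reason = character(0),
                        stringsAsFactors = FALSE)
  skip <- function(id, reason)
    skipped <<- rbind(skipped, data.frame(id = id, reason = reason,
                                          stringsAsFactors = FALSE))

  fp_table <- function(tab, role) {
    rows <- list()
    for (i in seq_len(nrow(tab))) {
      id <- tab$id[i]
      if (is.na(tab$smiles[i])) { skip(id, sprintf("%s without structure", role)); next }
      fp <- tryCatch(as.integer(compute_maccs(wash_smiles(tab$smiles[i], id = id))),
                     error = function(e) NULL)
      if (is.null(fp)) { skip(id, "unparsable structure"); next }
      rows[[id]] <- fp
    }
    if (!length(rows)) return(NULL)
    mat <- do.call(rbind, rows)
    rownames(mat) <- names(rows)
    mat
  }

  fa <- fp_table(actives, "active")
  if (is.null(fa))
    stop_admet("no fingerprintable active structures", "admet_contract_error")
  ac50 <- actives$ac50_uM[match(rownames(fa), actives$id)]
  fi <- fp_table(inactives, "inactive")

  hits <- NULL
  if (!is.null(fi)) {
    hits <- do.call(rbind, lapply(rownames(fi), function(id)
      nearest_active_neighbor(fi[id, ], fa, ac50 = ac50,
                              threshold = threshold, query_id = id)))
    hits <- hits[order(-hits$tanimoto, hits$query_id), , drop = FALSE]
    rownames(hits) <- NULL
  } else {
    hits <- data.frame(query_id = character(0), neighbor_id = character(0),
                       tanimoto = numeric(0), flagged = logical(0),
                       inherited_priority = character(0),
                       ties = I(list()), stringsAsFactors = FALSE)
  }
  attr(hits, "skipped") <- skipped
  attr(hits, "threshold") <- threshold
  hits
}
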