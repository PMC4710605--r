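# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a fixed RNG seed without touching global state
#'
#' The previous state of \code{.Random.seed} is restored on exit, so
#' generators never leak randomness into (or depend on) the caller's session.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Parse a Hill-order molecular formula ("C5H10N2O2S", "Cl2Hg", "C25H30N3+")
# into a named count vector. Trailing charge tokens are ignored.
parse_formula <- function(formula) {
  formula <- gsub("[+-][0-9]*$", "", formula)
  m <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (length(m) == 0L) return(stats::setNames(integer(0), character(0)))
  sym <- sub("[0-9]*$", "", m)
  n <- as.integer(sub("^[A-Z][a-z]?", "", m))
  n[is.na(n)] <- 1L
  tapply(n, sym, sum)
}

heavy_atom_count <- function(formula) {
  cnt <- parse_formula(formula)
  sum(cnt[setdiff(names(cnt), "H")])
}

contains_carbon <- function(formula) {
  "C" %in% names(parse_formula(formula))
}

# Net formal charge read off the bracket atoms of a SMILES string.
smiles_formal_charge <- function(smiles) {
  brackets <- regmatches(smiles, gregexpr("\\[[^]]*\\]", smiles))[[1]]
  if (length(brackets) == 0L) return(0L)
  charge_of <- function(b) {
    m <- regmatches(b, gregexpr("([+-])([0-9]*)", b))[[1]]
    if (length(m) == 0L) return(0L)
    sum(vapply(m, function(tok) {
      sign <- if (substr(tok, 1, 1) == "+") 1L else -1L
      mag <- substr(tok, 2, nchar(tok))
      sign * (if (nzchar(mag)) as.integer(mag) else 1L)
    }, integer(1)))
  }
  sum(vapply(brackets, charge_of, integer(1)))
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

stop_admet <- function(msg, class) {
  stop(structure(class = c(class, "admetriage_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
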