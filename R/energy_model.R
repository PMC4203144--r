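PAIR_NAMES <- c("CG", "GC", "GU", "UG", "AU", "UA")

.energy_cache <- new.env(parent = emptyenv())

#' Load a nearest-neighbor RNA duplex/folding energy model
#'
#' Reads a versioned TSV of dG37 parameters (kcal/mol): the 6x6 stack table
#' over Watson-Crick and G:U wobble pairs, hairpin/bulge/internal loop
#' initiation by loop length, affine multiloop terms, duplex initiation,
#' terminal AU/GU penalty and the per-column mismatch penalty used for
#' ungapped duplexes. The default parameter set is
#' `turner2004-simplified-v1`, shipped with the package.
#'
#' @param path path to a parameter TSV; `NULL` for the shipped default.
#' @return an object of class `energy_model`: a list with `stack` (6x6
#'   matrix, dimnames 5'-pair x 3'-pair), `hairpin`/`bulge`/`internal`
#'   (numeric vectors indexed by loop length up to 30), `ml_close`,
#'   `ml_branch`, `ml_unpaired`, `duplex_init`, `terminal_au`,
#'   `mismatch_penalty`, `loop_extrap_slope`, `max_loop`, `pair_bonus`
#'   and `parameter_set_id`.
#' @export
load_energy_model <- function(path = NULL) {
  default <- is.null(path)
  if (default && !is.null(.energy_cache$default)) return(.energy_cache$default)
  if (default) {
    path <- system.file("extdata", "turner2004_simplified.tsv",
                        package = "mirheat", mustWork = TRUE)
  }
  first <- readLines(path, n = 1L)
  set_id <- if (grepl("parameter_set_id:", first)) {
    trimws(sub(".*parameter_set_id:", "", first))
  } else "unnamed"
  df <- read_tsv_checked(path, c("section", "key1", "key2", "dG"))
  stk <- df[df$section == "stack", ]
  stack <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES))
  stack[cbind(stk$key1, stk$key2)] <- stk$dG
  if (anyNA(stack)) stop("incomplete stack table in ", path)
  pull_len <- function(section, max_n) {
    sub <- df[df$section == section, ]
    v <- rep(NA_real_, max_n)
    v[as.integer(sub$key1)] <- sub$dG
    v
  }
  kv <- df[df$section == "const", ]
  const <- stats::setNames(kv$dG, kv$key1)
  model <- structure(list(
    stack = stack,
    hairpin = pull_len("hairpin", 30L),
    bulge = pull_len("bulge", 30L),
    internal = pull_len("internal", 30L),
    ml_close = unname(const[["ml_close"]]),
    ml_branch = unname(const[["ml_branch"]]),
    ml_unpaired = unname(const[["ml_unpaired"]]),
    duplex_init = unname(const[["duplex_init"]]),
    terminal_au = unname(const[["terminal_au"]]),
    mismatch_penalty = unname(const[["mismatch_penalty"]]),
    loop_extrap_slope = unname(const[["loop_extrap_slope"]]),
    max_loop = as.integer(const[["max_loop"]]),
    pair_bonus = 0,
    parameter_set_id = set_id
  ), class = "energy_model")
  wc <- c("CG", "GC", "AU", "UA")
  if (any(model$stack[wc, wc] >= 0)) stop("WC stacks must be negative")
  if (default) .energy_cache$default <- model
  model
}

#' Pair-maximization parameterization
#'
#' An energy model in which every admissible pair contributes -1 and all
#' loop terms are zero, so that minimizing energy is exactly maximizing
#' the number of base pairs (the Nussinov objective). Used to cross-check
#' the folding engine against an independent Nussinov implementation.
#'
#' @return an `energy_model`.
#' @export
pair_max_model <- function() {
  structure(list(
    stack = matrix(0, 6, 6, dimnames = list(PAIR_NAMES, PAIR_NAMES)),
    hairpin = rep(0, 30), bulge = rep(0, 30), internal = rep(0, 30),
    ml_close = 0, ml_branch = 0, ml_unpaired = 0,
    duplex_init = 0, terminal_au = 0, mismatch_penalty = 0,
    loop_extrap_slope = 0, max_loop = 30L, pair_bonus = -1,
    parameter_set_id = "pair-maximization"
  ), class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model>", x$parameter_set_id, "\n")
  cat("  duplex_init", x$duplex_init, "kcal/mol; terminal AU/GU",
      x$terminal_au, "; MM column", x$mismatch_penalty, "\n")
  invisible(x)
}

# loop initiation with linear extrapolation past the tabulated 30 nt
loop_penalty <- function(model, kind, len) {
  tab <- model[[kind]]
  n <- length(tab)
  ifelse(len <= n, tab[pmax(len, 1L)],
         tab[n] + model$loop_extrap_slope * (len - n))
}

# pair name ("AU" etc.) or NA if the two bases cannot pair (WC or wobble)
pair_name <- function(b5, b3) {
  p <- paste0(b5, b3)
  ifelse(p %in% PAIR_NAMES, p, NA_character_)
}
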