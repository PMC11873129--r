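#' @keywords internal
"_PACKAGE"

utils::globalVariables(".data")

# Shared helpers. Seed handling: every stochastic entry point takes an
# explicit seed (or inherits one from SimConfig) and restores the caller's
# RNG state on exit, so generators are pure functions of their arguments.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# deterministic sub-streams off one master seed
substream <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) + as.integer(offset)) %% .Machine$integer.max
}

stop_if_not <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  length(unique(x)) <= 2 && all(x %in% c(0, 1))
}

#' Format a per-region Bonferroni significance threshold for printing
#'
#' Thresholds of 0.05 divided by the number of modules are printed with two
#' significant figures below 0.005 and three decimal places above, the mixed
#' precision conventional in module-trait association tables (e.g. 27, 18 and
#' 8 modules print as 0.0019, 0.0028 and 0.006).
#'
#' @param x numeric threshold(s).
#' @return character vector of formatted thresholds.
#' @export
#' @examples
#' format_sig_threshold(0.05 / c(27, 18, 8))
format_sig_threshold <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    if (v >= 0.005) format(round(v, 3), scientific = FALSE)
    else format(signif(v, 2), scientific = FALSE)
  }, character(1))
}

# module colour sequence (largest module first), after the conventional
# colour ordering used for co-methylation modules; "grey" is reserved for
# unassigned probes.
module_colors <- function(n) {
  base <- c(
    "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
    "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
    "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
    "royalblue", "darkred", "darkgreen", "darkturquoise", "darkgrey",
    "orange", "darkorange", "white", "skyblue", "saddlebrown", "steelblue",
    "paleturquoise", "violet", "darkolivegreen", "darkmagenta"
  )
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("module%03d", seq_len(n - length(base))))
}
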