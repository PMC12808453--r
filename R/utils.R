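#' Round half-up to a fixed number of decimals
#'
#' Base R's `round()` rounds half to even; published percentage tables in
#' comparative genomics are conventionally rounded half-up (91.45 -> 91.5).
#' A tiny guard absorbs binary floating-point representation error.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @examples
#' roundHalfUp(91.45, 1)  # 91.5
#' roundHalfUp(0.5)       # 1
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage from a count pair, rounded half-up
#'
#' @param n Numerator count.
#' @param total Denominator count.
#' @param digits Decimal places of the printed percentage (0 or 1 in the
#'   package's tables).
#' @return `100 * n / total`, rounded half-up.
#' @examples
#' percentHalfUp(2140, 2339, 1)  # 91.5
#' percentHalfUp(154, 273)       # 56
#' @export
percentHalfUp <- function(n, total, digits = 0) {
  stopifnot(total > 0)
  roundHalfUp(100 * n / total, digits)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. Keeps every generator operation on its own
# reproducible stream.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic small integer derived from a character label (for per-type
# scaffold streams).
labelSeed <- function(label, base = 1000L) {
  as.integer(base + sum(utf8ToInt(label) * seq_along(utf8ToInt(label))))
}

# Split a protein string into a character vector of residues.
splitResidues <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Summarise type assignments into per-type counts
#'
#' @param assignments data.frame with a `type` column (one row per record).
#' @return data.frame with columns `type`, `n`, plus an attribute-free final
#'   row is not added; use `sum(out$n)` for the total.
#' @export
typeCountSummary <- function(assignments) {
  stopifnot(is.data.frame(assignments), "type" %in% names(assignments))
  tab <- table(assignments$type)
  data.frame(type = names(tab), n = as.integer(tab),
             stringsAsFactors = FALSE)
}
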