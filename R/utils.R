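# Internal helpers shared across modules.

#' Well name from row and column indices
#'
#' Wells are named "A01".."P24" (row letters A-P, two-digit column).
#'
#' @param row integer row index, 1-based (1 = "A").
#' @param col integer column index, 1-based.
#' @return character vector of well names.
#' @export
well_name <- function(row, col) {
  stopifnot(all(row >= 1), all(row <= 26), all(col >= 1))
  sprintf("%s%02d", LETTERS[row], col)
}

#' Parse well names into row and column indices
#'
#' @param well character vector like "B02".
#' @return data.frame with columns `row`, `col` (1-based).
#' @export
well_rc <- function(well) {
  stopifnot(grepl("^[A-Z][0-9]{2,}$", well))
  data.frame(
    row = match(substr(well, 1, 1), LETTERS),
    col = as.integer(substring(well, 2))
  )
}

# derive a child seed below 2^31 from a parent seed and a stream tag
child_seed <- function(seed, tag) {
  h <- digest::digest(list(as.integer(seed), as.character(tag)), algo = "xxhash32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L) %% 2147483647L) + 1L
}

# evaluate expr with a local RNG state seeded from (seed, tag)
with_seed <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(child_seed(seed, tag))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == round(x) && x >= 0
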