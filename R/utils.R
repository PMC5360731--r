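#' Round half away from zero
#'
#' Commercial rounding: 68.75 -> 69, 96.97 -> 97, 42.86 -> 43, -0.5 -> -1.
#' Used for every reported percentage so printed summaries are reproducible
#' (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(68.75, 96.97, 42.86, 26.79))
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# integer percentage with the package-wide rounding rule
pct_of <- function(n, total) {
  if (total == 0) return(NA_real_)
  round_half_up(100 * n / total)
}

# Deterministic per-purpose seed derived from a root seed, kept < 2^31 - 1.
# All randomness in the package flows from one root seed through named
# substreams so stages can be re-run independently yet reproducibly.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483629L)
}

# Run code with a temporary RNG state; restores .Random.seed afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# matrix/tibble interconversion -----------------------------------------

# Accept either a wide tibble (first column = id) or a numeric matrix with
# rownames; return a numeric matrix with rownames.
as_id_matrix <- function(x, id_col = NULL) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) abort("matrix input must have rownames")
    return(x)
  }
  x <- as_tibble(x)
  if (is.null(id_col)) id_col <- names(x)[1]
  ids <- as.character(x[[id_col]])
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate ids: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  m <- as.matrix(x[setdiff(names(x), id_col)])
  mode(m) <- "numeric"
  rownames(m) <- ids
  m
}

matrix_to_tibble <- function(m, id_col = "gene_id") {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(!!id_col := rownames(m)), out)
  out
}
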