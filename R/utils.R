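#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_dbl map_int map_lgl imap keep
NULL

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards. All seeded entry points funnel through
# here so that library calls never clobber user RNG state.
with_seed_ <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing number.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of distinct child seeds from one parent seed, staying
# within 32-bit integer range.
derive_seeds_ <- function(seed, n) {
  (as.integer(seed) + seq_len(n) - 1L) %% .Machine$integer.max
}

assert_namespace_ <- function(namespace) {
  if (!is.character(namespace) || length(namespace) != 1L ||
      !namespace %in% c("MF", "BP", "CC")) {
    abort("`namespace` must be one of \"MF\", \"BP\", \"CC\".")
  }
  namespace
}

NAMESPACES <- c("MF", "BP", "CC")
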