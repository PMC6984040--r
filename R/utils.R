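# Internal helpers shared across modules.

# Fan a master seed out into `n` independent stage seeds (kept < 2^31).
fan_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
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
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(expr)
}

# Cosine similarity between two vectors; errors on zero vectors.
cosine_sim <- function(x, y, who = NULL) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) {
    abort(paste0("zero feature vector", if (!is.null(who)) paste0(" for ", who)))
  }
  sum(x * y) / (nx * ny)
}

#' Compare two cyclic orderings for equivalence
#'
#' Two orderings of the same index set are cyclically equal when one is a
#' rotation of the other. Useful for checking recovered temporal orderings,
#' which are defined only up to a global rotation of phase.
#'
#' @param a,b Integer vectors, both permutations of the same set.
#' @return `TRUE` if `b` is a rotation of `a`.
#' @export
#' @examples
#' cyclic_equal(c(1, 2, 3, 4), c(3, 4, 1, 2))
cyclic_equal <- function(a, b) {
  n <- length(a)
  if (length(b) != n || !setequal(a, b)) return(FALSE)
  for (s in seq_len(n)) {
    if (all(a == b[((seq_len(n) + s - 2L) %% n) + 1L])) return(TRUE)
  }
  FALSE
}

# Fraction of ordered ROI pairs on which two cyclic orderings agree, scoring
# each unordered pair by whether the cyclic gap from i to j has the same
# orientation in both orderings.
pairwise_order_agreement <- function(a, b) {
  n <- length(a)
  pos_a <- match(seq_len(n), a)
  pos_b <- match(seq_len(n), b)
  agree <- 0L; total <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ga <- (pos_a[j] - pos_a[i]) %% n
      gb <- (pos_b[j] - pos_b[i]) %% n
      # same orientation: both gaps on the same side of the cycle
      same <- (ga < n / 2) == (gb < n / 2)
      agree <- agree + as.integer(same)
      total <- total + 1L
    }
  }
  agree / total
}
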