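# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Run `code` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

## Deterministic child seed for component streams (schedule/patterns/behavior/...),
## kept below 2^31 so set.seed() accepts it on any platform.
child_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stream) * 7919L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x) || x < min) {
    stopf("'%s' must be a single integer >= %d (got %s)", name, min, format(x))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x > max) {
    stopf("'%s' must be a single number in [%s, %s]", name, format(min), format(max))
  }
  as.numeric(x)
}

check_numeric_vector <- function(x, name, min_len = 1L) {
  if (!is.numeric(x) || length(x) < min_len || anyNA(x) || any(!is.finite(x))) {
    stopf("'%s' must be a finite numeric vector of length >= %d", name, min_len)
  }
  as.numeric(x)
}

## All n! permutations of 1:n as an (n! x n) matrix; used by the exhaustive
## between-subject permutation mode. Guarded upstream to small n.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 0L
  for (i in seq_len(n)) {
    idx <- seq_len(nrow(sub)) + row
    out[idx, i] <- n
    out[idx, -i] <- sub
    row <- row + nrow(sub)
  }
  out
}
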