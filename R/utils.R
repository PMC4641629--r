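#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# session RNG stream.
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

# Derive a deterministic per-component sub-seed from one global seed so stages
# (stations, community, casts, fields, clustering, permutations) can be
# regenerated independently. Kept below 2^31 - 1.
substream <- function(seed, component) {
  offsets <- c(
    stations = 101L, community = 211L, casts = 307L, fields = 401L,
    cluster = 503L, perm = 601L, select = 701L
  )
  off <- offsets[[component]]
  if (is.null(off)) stop("unknown substream component: ", component)
  as.integer((as.numeric(seed) * 7919 + off) %% 2147483647)
}

# Row argmax with explicit tie detection: returns index (NA when the maximum is
# attained by more than one column).
argmax_with_ties <- function(x, tol = 0) {
  m <- max(x)
  hits <- which(x >= m - tol)
  if (length(hits) > 1L) NA_integer_ else hits
}

`%||%` <- function(a, b) if (is.null(a)) b else a
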