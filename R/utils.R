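#' Cosine similarity between two non-negative vectors
#'
#' @param x,y numeric vectors of equal length.
#' @return similarity in \[0, 1\] for non-negative inputs; `NA` if either
#'   vector is all zero.
#' @export
cosine_similarity <- function(x, y) {
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(NA_real_)
  sum(x * y) / (nx * ny)
}

## Pairwise cosine distance matrix between columns of `m` (dist object).
cosine_dist <- function(m) {
  nrm <- sqrt(colSums(m^2))
  nrm[nrm == 0] <- 1
  u <- sweep(m, 2, nrm, "/")
  s <- crossprod(u)
  s[s > 1] <- 1
  s[s < 0] <- 0
  stats::as.dist(1 - s)
}

## Evaluate `code` under a temporary RNG state seeded with `seed`;
## the caller's RNG stream is untouched. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Deterministic 32-bit substream seed derived from a master seed and a label.
## Keeps every derived seed strictly below 2^31.
substream_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + as.numeric(offset)) %% 2147483587) + 1L
}

## Column-normalize a non-negative matrix so each column sums to 1.
normalize_columns <- function(m) {
  cs <- colSums(m)
  cs[cs == 0] <- 1
  sweep(m, 2, cs, "/")
}
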