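## Shared fixtures and independent oracles for the test suite.

chan_tab <- cn48_channels()
chan_idx <- function(name) chan_tab$index[match(name, chan_tab$name)]

## Archetype-shaped reference signatures used across attribution/mapping
## tests: concentrated spectra mirroring diploid, tetraploid, structural-CIN
## and whole-arm-LOH processes.
archetype_signatures <- function() {
  mk <- function(w, names) {
    v <- numeric(48)
    v[chan_idx(names)] <- w
    v / sum(v)
  }
  cbind(
    dip = mk(c(0.85, 0.15), c("het:2:>40Mb", "het:2:10Mb-40Mb")),
    tet = mk(c(0.85, 0.15), c("het:3-4:>40Mb", "het:3-4:10Mb-40Mb")),
    cin = mk(c(0.3, 0.25, 0.25, 0.2),
             c("loh:2:100kb-1Mb", "loh:2:1Mb-10Mb", "het:2:1Mb-10Mb",
               "het:2:100kb-1Mb")),
    loh = mk(c(0.6, 0.4), c("loh:1:>40Mb", "loh:1:10Mb-40Mb")))
}

## Single-channel unit signature.
unit_signature <- function(name) {
  v <- numeric(48)
  v[chan_idx(name)] <- 1
  v
}

## Best cosine match of each truth column among the columns of W.
best_match_cosines <- function(W, truth) {
  vapply(seq_len(ncol(truth)), function(j)
    max(apply(W, 2, cosine_similarity, truth[, j])), numeric(1))
}

## Brute-force two-sided Fisher oracle: enumerate the hypergeometric
## distribution over all tables with the observed margins; p = total
## probability of tables no more likely than the observed one.
fisher_oracle <- function(a, b, c, d) {
  m <- a + b       # row 1 margin (overlap)
  n <- c + d       # row 2 margin
  k <- a + c       # column 1 margin (assigned)
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- lo:hi
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Exhaustive active-set NNLS oracle: the NNLS optimum is the best
## residual among all supports whose unconstrained LS solution is
## non-negative (KKT support enumeration); feasible for K <= 5.
nnls_oracle <- function(A, b, tol = 1e-9) {
  K <- ncol(A)
  best <- list(x = numeric(K), resid = sum(b^2))
  for (size in seq_len(K)) {
    for (cols in asplit(combn(K, size), 2)) {
      Ai <- A[, cols, drop = FALSE]
      x <- tryCatch(qr.solve(crossprod(Ai), crossprod(Ai, b)),
                    error = function(e) NULL)
      if (is.null(x) || any(x < -tol)) next
      r <- sum((b - Ai %*% x)^2)
      if (r < best$resid - 1e-12) {
        full <- numeric(K)
        full[cols] <- pmax(x, 0)
        best <- list(x = full, resid = r)
      }
    }
  }
  best
}

## Random valid profile on a small genome for property tests.
random_profile <- function(id, genome = load_genome("hg19"), n_chrom = 4,
                           max_seg = 6) {
  chroms <- sample(genome$chrom$chrom, n_chrom)
  rows <- lapply(chroms, function(ch) {
    len <- chrom_length(genome, ch)
    k <- sample.int(max_seg, 1)
    bounds <- sort(sample.int(len - 1, 2 * k))
    data.frame(chrom = ch,
               start = bounds[seq(1, 2 * k, 2)],
               end = bounds[seq(2, 2 * k, 2)],
               major_cn = sample(0:6, k, replace = TRUE),
               minor_cn = sample(0:3, k, replace = TRUE))
  })
  seg <- do.call(rbind, rows)
  seg$minor_cn <- pmin(seg$minor_cn, seg$major_cn)
  cn_profile(id, seg, genome = genome)
}

## Hand-built mapped-segment data.frame realizing a 2x2 overlap/assignment
## table against the region [1, 1e6] on chromosome 1.
mapped_from_table <- function(a, b, c, d) {
  n_in <- a + b
  n_out <- c + d
  mk <- function(n, inside, assigned) {
    if (n == 0) return(NULL)
    start <- if (inside) seq(1, by = 10, length.out = n) else
      seq(5e6, by = 10, length.out = n)
    data.frame(chrom = "1", start = start, end = start + 5,
               mappable = TRUE,
               assigned = if (assigned) "X" else "Y",
               stringsAsFactors = FALSE)
  }
  out <- rbind(mk(a, TRUE, TRUE), mk(b, TRUE, FALSE),
               mk(c, FALSE, TRUE), mk(d, FALSE, FALSE))
  out
}

toy_region <- data.frame(chrom = "1", start = 1, end = 1e6,
                         label = "event", stringsAsFactors = FALSE)
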