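#' Poisson resampling of a count matrix
#'
#' Replaces every entry by a Poisson draw with mean equal to the original
#' entry, emulating counting noise on the catalogue before each NMF
#' replicate.
#'
#' @param mat non-negative count matrix.
#' @param seed optional integer seed (deterministic given the seed).
#' @return matrix of the same shape.
#' @export
poisson_resample <- function(mat, seed = NULL) {
  if (any(mat < 0)) stop("negative entries in count matrix")
  with_seed(seed, {
    out <- mat
    out[] <- stats::rpois(length(mat), lambda = as.numeric(mat))
    out
  })
}

## Generalized Kullback-Leibler divergence D(V || WH); the NMF objective
## for count data. Terms with V = 0 contribute WH only.
kl_divergence <- function(V, WH) {
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

## One KL-NMF fit by multiplicative updates. V is channels x samples.
## Returns W (channels x k), H (k x samples), the objective trace and the
## final divergence. Objective is non-increasing across iterations.
nmf_kl <- function(V, k, max_iter = 10000, tol = 1e-8, eps = 1e-12,
                  trace_every = 10) {
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  ones_m <- rep(1, m); ones_n <- rep(1, n)
  trace <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    WH <- W %*% H + eps
    H <- H * (crossprod(W, V / WH)) / (colSums(W) + eps)
    WH <- W %*% H + eps
    W <- W * ((V / WH) %*% t(H)) / matrix(rowSums(H) + eps, n, k, byrow = TRUE)
    if (it %% trace_every == 0 || it == max_iter) {
      obj <- kl_divergence(V, W %*% H + eps)
      trace <- c(trace, obj)
      if (is.finite(prev) && abs(prev - obj) <= tol * max(abs(prev), 1)) {
        prev <- obj
        break
      }
      prev <- obj
    }
  }
  list(W = W, H = H, divergence = prev, trace = trace)
}

#' Run Poisson-resampled NMF replicates
#'
#' Fits `n_replicates` KL-NMF factorizations of rank `k`, each on an
#' independent Poisson resample of the catalogue with an independent random
#' initialization.
#'
#' @param mat samples x 48 non-negative count matrix (transposed to
#'   channels x samples internally).
#' @param k factorization rank (1 <= k <= min(48, S)).
#' @param n_replicates number of replicates (default 250).
#' @param seed master seed; replicate r uses a derived substream.
#' @param resample Poisson-resample before each fit (default `TRUE`).
#' @param max_iter,tol multiplicative-update controls.
#' @return list of replicate fits, each `list(W, H, divergence, trace)` with
#'   W of shape 48 x k.
#' @export
run_nmf <- function(mat, k, n_replicates = 250, seed = NULL, resample = TRUE,
                    max_iter = 10000, tol = 1e-8) {
  if (k < 1) stop("k must be >= 1")
  if (k > min(ncol(mat), nrow(mat)))
    stop("k exceeds min(channels, samples) = ", min(ncol(mat), nrow(mat)))
  V0 <- t(mat)  # channels x samples
  lapply(seq_len(n_replicates), function(r) {
    with_seed(substream_seed(seed, 1000L * k + r), {
      V <- if (resample) {
        Vr <- V0
        Vr[] <- stats::rpois(length(V0), lambda = as.numeric(V0))
        Vr
      } else V0
      fit <- nmf_kl(V, k, max_iter = max_iter, tol = tol)
      rownames(fit$W) <- colnames(mat)
      fit
    })
  })
}

#' Cluster NMF replicates into consensus signatures
#'
#' Pools the signature columns of all replicates, partitions them into `k`
#' clusters by k-medoids on cosine distance, and returns re-normalized
#' cluster centroids as consensus signatures with a silhouette-based
#' stability score. Consensus activities are refit by NNLS of each sample
#' against the consensus signatures.
#'
#' @param replicates list of fits from [run_nmf()].
#' @param k rank (number of clusters).
#' @param mat the original samples x 48 matrix used for the activity refit
#'   (optional; if missing, activities are the average over replicates'
#'   matched H).
#' @return `list(W, H, stability)`: W is 48 x k column-stochastic, H is
#'   k x S attributed counts (if `mat` given), stability the mean silhouette
#'   width over clusters (1 for k = 1).
#' @export
cluster_replicates <- function(replicates, k, mat = NULL) {
  if (length(replicates) < 2) stop("need >= 2 replicates")
  cols <- do.call(cbind, lapply(replicates, function(r) r$W))
  cols <- normalize_columns(cols)
  if (k == 1) {
    W <- matrix(rowMeans(cols), ncol = 1)
    W <- normalize_columns(W)
    stability <- 1.0
    cl <- rep(1L, ncol(cols))
  } else {
    d <- cosine_dist(cols)
    pm <- cluster::pam(d, k = k, diss = TRUE)
    cl <- pm$clustering
    sil <- cluster::silhouette(cl, d)
    stability <- mean(tapply(sil[, "sil_width"], cl, mean))
    W <- vapply(seq_len(k), function(j) {
      ctr <- rowMeans(cols[, cl == j, drop = FALSE])
      ctr / sum(ctr)
    }, numeric(nrow(cols)))
  }
  rownames(W) <- rownames(replicates[[1]]$W)
  colnames(W) <- paste0("S", seq_len(k))
  H <- NULL
  if (!is.null(mat)) {
    V <- t(mat)
    H <- vapply(seq_len(ncol(V)), function(j)
      pracma::lsqnonneg(W, V[, j])$x, numeric(k))
    H <- matrix(H, nrow = k, dimnames = list(colnames(W), rownames(mat)))
  }
  list(W = W, H = H, stability = stability, clustering = cl)
}

#' Select the number of signatures
#'
#' The selected rank is the largest k whose stability reaches
#' `stability_min` and whose reconstruction error improves on k - 1 by more
#' than `rel_tol` of the worst (largest) searched error — a scree-style
#' elbow normalization that keeps the threshold comparable across ranks;
#' the smallest searched k needs only the stability condition. If no k
#' qualifies, the k with maximal stability is returned with
#' `flagged = TRUE`.
#'
#' @param ks integer vector of searched ranks (contiguous, ascending).
#' @param stability stability score per rank.
#' @param error reconstruction error per rank (non-negative).
#' @param stability_min minimum acceptable stability (default 0.8).
#' @param rel_tol minimum error improvement over k - 1 as a fraction of the
#'   largest searched error (default 0.05).
#' @return `list(selected_k, flagged, qualifying)`.
#' @export
select_k <- function(ks, stability, error, stability_min = 0.8,
                     rel_tol = 0.05) {
  stopifnot(length(ks) == length(stability), length(ks) == length(error))
  imp <- c(TRUE, -diff(error) > rel_tol * max(error, 1e-300))
  ok <- stability >= stability_min & imp
  if (any(ok)) {
    list(selected_k = max(ks[ok]), flagged = FALSE, qualifying = ks[ok])
  } else {
    list(selected_k = ks[which.max(stability)], flagged = TRUE,
         qualifying = integer(0))
  }
}

#' De novo signature extraction over a range of ranks
#'
#' For each rank, runs Poisson-resampled NMF replicates, clusters them into
#' consensus signatures, and records stability and the reconstruction error
#' of the consensus fit on the original catalogue (KL divergence per
#' segment); then selects the rank with [select_k()].
#'
#' @param mat samples x 48 count matrix.
#' @param k_range ranks to search (default 1:8).
#' @param n_replicates NMF replicates per rank (default 250; reduce for
#'   exploratory runs).
#' @param seed master seed.
#' @param stability_min,rel_tol passed to [select_k()].
#' @param max_iter,tol passed to the NMF core.
#' @return object of class `cn_extraction`: list with `by_k` (per-rank
#'   consensus W, H, stability, error), `selected_k`, `flagged`,
#'   `signatures` (48 x selected_k) and `activities`.
#' @export
extract_signatures <- function(mat, k_range = 1:8, n_replicates = 250,
                               seed = NULL, stability_min = 0.8,
                               rel_tol = 0.05, max_iter = 2000, tol = 1e-6) {
  V <- t(mat)
  total <- sum(mat)
  by_k <- lapply(k_range, function(k) {
    reps <- run_nmf(mat, k, n_replicates = n_replicates, seed = seed,
                    max_iter = max_iter, tol = tol)
    cons <- cluster_replicates(reps, k, mat = mat)
    err <- kl_divergence(V, cons$W %*% cons$H + 1e-12) / max(total, 1)
    list(k = k, W = cons$W, H = cons$H, stability = cons$stability,
         error = err)
  })
  names(by_k) <- paste0("k", k_range)
  sel <- select_k(k_range,
                  vapply(by_k, `[[`, numeric(1), "stability"),
                  vapply(by_k, `[[`, numeric(1), "error"),
                  stability_min = stability_min, rel_tol = rel_tol)
  best <- by_k[[paste0("k", sel$selected_k)]]
  structure(list(by_k = by_k, selected_k = sel$selected_k,
                 flagged = sel$flagged, signatures = best$W,
                 activities = best$H),
            class = "cn_extraction")
}

#' @export
print.cn_extraction <- function(x, ...) {
  cat("cn_extraction: searched k =",
      paste(vapply(x$by_k, `[[`, numeric(1), "k"), collapse = ","),
      "; selected k =", x$selected_k,
      if (x$flagged) "(flagged: fallback to max stability)" else "", "\n")
  tab <- data.frame(k = vapply(x$by_k, `[[`, numeric(1), "k"),
                    stability = round(vapply(x$by_k, `[[`, numeric(1),
                                             "stability"), 3),
                    error = signif(vapply(x$by_k, `[[`, numeric(1),
                                          "error"), 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Consolidate signatures from multiple extractions
#'
#' Pools the columns of several signature sets and clusters them by
#' average-linkage hierarchical clustering on cosine dissimilarity. The
#' number of clusters maximizes
#' `min(within-cluster average cosine to centroid) - lambda * max(between-centroid cosine)`,
#' so that every member resembles its consolidated signature while the
#' consolidated signatures stay distinct from each other.
#'
#' @param sig_sets list of 48 x K column-stochastic matrices (or a single
#'   matrix).
#' @param lambda trade-off weight on between-centroid similarity (default 1).
#' @return 48 x K* column-stochastic consensus matrix with columns
#'   `CS1..CSK*`.
#' @export
consolidate <- function(sig_sets, lambda = 1) {
  if (is.matrix(sig_sets)) sig_sets <- list(sig_sets)
  if (!length(sig_sets)) stop("empty signature pool")
  pool <- do.call(cbind, sig_sets)
  pool <- normalize_columns(pool)
  n <- ncol(pool)
  if (n == 1) {
    colnames(pool) <- "CS1"
    return(pool)
  }
  d <- cosine_dist(pool)
  hc <- stats::hclust(d, method = "average")
  centroid <- function(members) {
    ctr <- rowMeans(pool[, members, drop = FALSE])
    ctr / sum(ctr)
  }
  score_cut <- function(k) {
    cl <- stats::cutree(hc, k = k)
    ctrs <- vapply(seq_len(k), function(j) centroid(which(cl == j)),
                   numeric(nrow(pool)))
    within <- vapply(seq_len(k), function(j) {
      mem <- which(cl == j)
      mean(vapply(mem, function(i) cosine_similarity(pool[, i], ctrs[, j]),
                  numeric(1)))
    }, numeric(1))
    between <- 0
    if (k > 1) {
      cs <- crossprod(normalize_l2(ctrs))
      diag(cs) <- -Inf
      between <- max(cs)
    }
    list(score = min(within) - lambda * between, ctrs = ctrs)
  }
  scored <- lapply(seq_len(n), score_cut)
  best <- which.max(vapply(scored, `[[`, numeric(1), "score"))
  out <- scored[[best]]$ctrs
  colnames(out) <- paste0("CS", seq_len(ncol(out)))
  rownames(out) <- rownames(pool)
  out
}

normalize_l2 <- function(m) {
  nrm <- sqrt(colSums(m^2)); nrm[nrm == 0] <- 1
  sweep(m, 2, nrm, "/")
}

#' Remove signatures expressible as linear combinations of others
#'
#' For each signature a synthetic 1,000-segment sample is built from its
#' channel distribution and multinomially resampled; each resample is fit
#' against subsets of at most `max_components` other signatures by NNLS. If
#' the median reconstruction cosine over resamples exceeds `sim_threshold`,
#' the signature is a linear combination of the others and is removed.
#' Removals are processed one at a time (largest median first), re-evaluating
#' the shrunken set after each removal. A signature that is the unique
#' carrier of any channel (only it has mass > 0.05 there) is never removed.
#'
#' @param signatures 48 x K column-stochastic matrix, K >= 2.
#' @param n_segments synthetic sample size (default 1000).
#' @param sim_threshold reconstruction cosine above which a signature is
#'   deemed redundant (default 0.95, strict `>`).
#' @param max_components maximum number of other signatures allowed in the
#'   reconstruction (default 3).
#' @param n_resamples multinomial resamples per signature (default 100).
#' @param seed master seed.
#' @return pruned 48 x K' matrix (column names preserved).
#' @export
prune_linear_combinations <- function(signatures, n_segments = 1000,
                                      sim_threshold = 0.95,
                                      max_components = 3, n_resamples = 100,
                                      seed = NULL) {
  sigs <- normalize_columns(signatures)
  if (is.null(colnames(sigs))) colnames(sigs) <- paste0("S", seq_len(ncol(sigs)))
  unique_carrier <- function(m) {
    ## TRUE per column if some channel has mass > 0.05 only in that column
    vapply(seq_len(ncol(m)), function(j) {
      others <- m[, -j, drop = FALSE]
      any(m[, j] > 0.05 & apply(others <= 0.05, 1, all))
    }, logical(1))
  }
  round_pass <- 0L
  repeat {
    K <- ncol(sigs)
    if (K < 2) break
    carrier <- unique_carrier(sigs)
    med_cos <- rep(NA_real_, K)
    for (j in seq_len(K)) {
      if (carrier[j]) next
      others <- sigs[, -j, drop = FALSE]
      subsets <- subset_indices(ncol(others), max_components)
      cosines <- with_seed(substream_seed(seed, 100L * round_pass + j), {
        vapply(seq_len(n_resamples), function(r) {
          v <- as.numeric(stats::rmultinom(1, n_segments, sigs[, j]))
          best <- 0
          for (s in subsets) {
            Ws <- others[, s, drop = FALSE]
            fit <- pracma::lsqnonneg(Ws, v)
            cs <- cosine_similarity(Ws %*% fit$x, v)
            if (!is.na(cs) && cs > best) best <- cs
          }
          best
        }, numeric(1))
      })
      med_cos[j] <- stats::median(cosines)
    }
    removable <- which(!is.na(med_cos) & med_cos > sim_threshold)
    if (!length(removable)) break
    drop_j <- removable[which.max(med_cos[removable])]
    sigs <- sigs[, -drop_j, drop = FALSE]
    round_pass <- round_pass + 1L
  }
  sigs
}

## All non-empty index subsets of 1..n with size <= kmax.
subset_indices <- function(n, kmax) {
  out <- list()
  for (k in seq_len(min(kmax, n))) {
    cmb <- utils::combn(n, k)
    for (i in seq_len(ncol(cmb))) out[[length(out) + 1]] <- cmb[, i]
  }
  out
}
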