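## NNLS refit of sample vector v against signature columns `active`;
## returns coefficients (on the active set) and the reconstruction cosine.
nnls_refit <- function(v, sigs, active) {
  if (!length(active)) return(list(x = numeric(0), cosine = 0))
  W <- sigs[, active, drop = FALSE]
  fit <- pracma::lsqnonneg(W, v)
  cs <- cosine_similarity(W %*% fit$x, v)
  list(x = fit$x, cosine = if (is.na(cs)) 0 else cs)
}

#' Penalized NNLS signature assignment for one sample
#'
#' Sparse attribution of a reference signature set to a 48-channel count
#' vector. Stages: (i) NNLS over all signatures; (ii) initial removal —
#' iteratively drop the signature whose removal costs the least
#' reconstruction cosine while that cost stays below
#' `initial_remove_penalty`; (iii) a second removal pass at
#' `remove_penalty`; (iv) addition — re-add a dropped signature only when it
#' gains more than `add_penalty` cosine; then a final NNLS refit on the
#' active set. Default penalties: add 0.1, remove 0.01, initial remove 0.05.
#'
#' @param v non-negative 48-vector of channel counts.
#' @param signatures 48 x K column-stochastic matrix with column names.
#' @param add_penalty,remove_penalty,initial_remove_penalty cosine-delta
#'   penalties controlling sparsity.
#' @return `list(counts, cosine, active, flagged)`: `counts` is the named
#'   length-K vector of attributed segment counts (zero outside the active
#'   set); `flagged` is `TRUE` for a zero-count sample.
#' @export
assign_signatures <- function(v, signatures, add_penalty = 0.1,
                              remove_penalty = 0.01,
                              initial_remove_penalty = 0.05) {
  K <- ncol(signatures)
  labs <- colnames(signatures)
  if (is.null(labs)) labs <- paste0("S", seq_len(K))
  zero <- stats::setNames(numeric(K), labs)
  if (any(v < 0)) stop("negative channel counts")
  if (sum(v) == 0)
    return(list(counts = zero, cosine = NA_real_, active = integer(0),
                flagged = TRUE))
  active <- seq_len(K)
  cur <- nnls_refit(v, signatures, active)
  ## Drop signatures greedily (cheapest first) while the reconstruction
  ## cosine stays within `penalty` of the cosine at the start of the pass.
  removal_pass <- function(active, cur, penalty) {
    base <- cur$cosine
    repeat {
      if (length(active) <= 1) break
      drops <- lapply(active, function(s)
        nnls_refit(v, signatures, setdiff(active, s)))
      deltas <- base - vapply(drops, `[[`, numeric(1), "cosine")
      best <- which.min(deltas)
      if (deltas[best] < penalty) {
        active <- setdiff(active, active[best])
        cur <- drops[[best]]
      } else break
    }
    list(active = active, cur = cur)
  }
  st <- removal_pass(active, cur, initial_remove_penalty)
  st <- removal_pass(st$active, st$cur, remove_penalty)
  active <- st$active; cur <- st$cur
  repeat {
    inactive <- setdiff(seq_len(K), active)
    if (!length(inactive)) break
    adds <- lapply(inactive, function(s)
      nnls_refit(v, signatures, sort(c(active, s))))
    gains <- vapply(adds, `[[`, numeric(1), "cosine") - cur$cosine
    best <- which.max(gains)
    if (gains[best] > add_penalty) {
      active <- sort(c(active, inactive[best]))
      cur <- adds[[best]]
    } else break
  }
  counts <- zero
  counts[active] <- cur$x * colSums(signatures)[active]
  list(counts = counts, cosine = cur$cosine, active = active, flagged = FALSE)
}

#' Attribute a signature set across a cohort
#'
#' @param mat samples x 48 count matrix.
#' @param signatures 48 x K column-stochastic matrix.
#' @param ... passed to [assign_signatures()].
#' @return object of class `cn_attribution`: list with `counts` (S x K
#'   attributed segment counts), `normalized` (rows summing to 1 over active
#'   signatures), `cosine` (per-sample reconstruction cosine) and `flagged`.
#' @export
attribute_cohort <- function(mat, signatures, ...) {
  fits <- lapply(seq_len(nrow(mat)), function(i)
    assign_signatures(as.numeric(mat[i, ]), signatures, ...))
  K <- ncol(signatures)
  counts <- matrix(unlist(lapply(fits, `[[`, "counts")), ncol = K,
                   byrow = TRUE,
                   dimnames = list(rownames(mat), names(fits[[1]]$counts)))
  rs <- rowSums(counts)
  normalized <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, normalized = normalized,
                 cosine = vapply(fits, `[[`, numeric(1), "cosine"),
                 flagged = vapply(fits, `[[`, logical(1), "flagged")),
            class = "cn_attribution")
}

#' @export
print.cn_attribution <- function(x, ...) {
  cat("cn_attribution:", nrow(x$counts), "samples x", ncol(x$counts),
      "signatures; median reconstruction cosine",
      round(stats::median(x$cosine, na.rm = TRUE), 4), "\n")
  invisible(x)
}

#' Best-of assignment between pan-cancer and type-specific signature sets
#'
#' Assigns the sample under both signature sets and keeps whichever
#' reconstructs it with the higher cosine; ties go to the pan-cancer set.
#'
#' @param v non-negative 48-vector.
#' @param pan_signatures,type_signatures column-stochastic 48 x K matrices.
#' @param ... passed to [assign_signatures()].
#' @return the winning assignment (as from [assign_signatures()]) plus a
#'   `set` element, `"pan"` or `"type"`.
#' @export
best_of_assign <- function(v, pan_signatures, type_signatures, ...) {
  a_pan <- assign_signatures(v, pan_signatures, ...)
  a_typ <- assign_signatures(v, type_signatures, ...)
  pick_type <- !is.na(a_typ$cosine) &&
    (is.na(a_pan$cosine) || a_typ$cosine > a_pan$cosine)
  out <- if (pick_type) a_typ else a_pan
  out$set <- if (pick_type) "type" else "pan"
  out
}

#' Monte-Carlo reconstruction significance
#'
#' For each sample, compares its reconstruction cosine against a null of
#' multinomially reshuffled samples: the total count is redistributed
#' uniformly over the sample's occupied channels and re-assigned with the
#' same procedure. `p = (1 + #{null >= observed}) / (1 + n_null)`; q-values
#' are Benjamini-Hochberg adjusted across the cohort.
#'
#' @param mat samples x 48 count matrix.
#' @param signatures 48 x K column-stochastic matrix.
#' @param attribution optional precomputed [attribute_cohort()] result.
#' @param n_null null draws per sample (default 1000).
#' @param seed master seed.
#' @param ... passed to [assign_signatures()].
#' @return data.frame with `sample`, `cosine`, `p`, `q`.
#' @export
reconstruction_q <- function(mat, signatures, attribution = NULL,
                             n_null = 1000, seed = NULL, ...) {
  if (is.null(attribution)) attribution <- attribute_cohort(mat, signatures, ...)
  S <- nrow(mat)
  p <- vapply(seq_len(S), function(i) {
    v <- as.numeric(mat[i, ])
    obs <- attribution$cosine[i]
    if (is.na(obs)) return(NA_real_)
    occ <- which(v > 0)
    with_seed(substream_seed(seed, i), {
      nulls <- vapply(seq_len(n_null), function(b) {
        vb <- numeric(length(v))
        vb[occ] <- stats::rmultinom(1, sum(v), rep(1, length(occ)))
        assign_signatures(vb, signatures, ...)$cosine
      }, numeric(1))
      (1 + sum(nulls >= obs - 1e-12)) / (1 + n_null)
    })
  }, numeric(1))
  data.frame(sample = rownames(mat) %||% as.character(seq_len(S)),
             cosine = attribution$cosine, p = p,
             q = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shannon diversity of an attribution vector
#'
#' `H = -sum(p_i log p_i)` over the normalized attributions, with
#' `0 * log 0 = 0`.
#'
#' @param x non-negative attribution vector with positive sum.
#' @return diversity index >= 0 (0 for a single active signature).
#' @export
shannon_diversity <- function(x) {
  if (any(x < 0)) stop("negative attributions")
  s <- sum(x)
  if (s == 0) stop("Shannon diversity undefined for an all-zero vector")
  p <- x[x > 0] / s
  -sum(p * log(p))
}
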