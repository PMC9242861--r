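#' Length-weighted ploidy of a profile
#'
#' Ploidy is the covered-length-weighted mean total copy number,
#' sum(len_i * TCN_i) / sum(len_i).
#'
#' @param profile a `cn_profile` with at least one segment.
#' @return ploidy >= 0.
#' @export
compute_ploidy <- function(profile) {
  seg <- profile$segments
  if (nrow(seg) == 0) stop("ploidy undefined for an empty profile")
  len <- seg$end - seg$start + 1
  sum(len * (seg$major_cn + seg$minor_cn)) / sum(len)
}

#' Fraction of the covered genome in LOH
#'
#' The LOH numerator counts segments with A > 0, B = 0 only; homozygous
#' deletions contribute to the denominator but not the numerator.
#'
#' @param profile a `cn_profile` with at least one segment.
#' @return pLOH in \[0, 1\].
#' @export
compute_ploh <- function(profile) {
  seg <- profile$segments
  if (nrow(seg) == 0) stop("pLOH undefined for an empty profile")
  len <- seg$end - seg$start + 1
  loh <- seg$major_cn > 0 & seg$minor_cn == 0
  sum(len[loh]) / sum(len)
}

#' Classify whole-genome-doubling status
#'
#' A sample is once genome-doubled if its ploidy lies strictly above the line
#' -3/2 * pLOH + 3 (LOH-adjusted ploidy of 3 or greater), and twice doubled
#' if strictly above -5/2 * pLOH + 5 (LOH-adjusted ploidy of 5); boundary
#' equality rounds down to the lower level.
#'
#' @param ploidy ploidy >= 0 (vectorized).
#' @param ploh pLOH in \[0, 1\] (vectorized).
#' @return integer WGD level: 0, 1 or 2.
#' @export
classify_wgd <- function(ploidy, ploh) {
  if (any(ploidy < 0)) stop("ploidy must be non-negative")
  if (any(ploh < 0 | ploh > 1)) stop("ploh must lie in [0, 1]")
  ifelse(ploidy > -5 / 2 * ploh + 5, 2L,
         ifelse(ploidy > -3 / 2 * ploh + 3, 1L, 0L))
}

#' Ploidy, pLOH and WGD calls for a cohort
#'
#' @param profiles list of `cn_profile`.
#' @return data.frame with `sample`, `ploidy`, `ploh`, `wgd_level`.
#' @export
wgd_calls <- function(profiles) {
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  pl <- vapply(profiles, compute_ploidy, numeric(1))
  ph <- vapply(profiles, compute_ploh, numeric(1))
  data.frame(sample = vapply(profiles, function(p) p$sample_id, character(1)),
             ploidy = pl, ploh = ph, wgd_level = classify_wgd(pl, ph),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Artificial genome doubling of a 48-channel vector or signature matrix
#'
#' Within every (heterozygosity, size) stratum the mass of each TCN class is
#' moved to the next-highest class: the TCN-1 channel empties, TCN 2 receives
#' old TCN 1, 3-4 receives 2, 5-8 receives 3-4, and 9+ receives the sum of
#' the old 5-8 and 9+ classes. Homozygous-deletion channels (TCN 0) are left
#' unchanged, as are the LOH and size labels, so total mass and every
#' stratum's mass are preserved. The map is linear, so it acts identically on
#' raw count vectors and normalized signatures.
#'
#' @param x numeric 48-vector, or a 48 x K matrix doubled column-wise.
#' @return object of the same shape.
#' @export
double_signature <- function(x) {
  if (is.matrix(x)) {
    if (nrow(x) != 48) stop("signature matrix must have 48 rows")
    return(apply(x, 2, double_signature))
  }
  if (length(x) != 48) stop("signature vector must have length 48")
  if (any(x < 0)) stop("signature mass must be non-negative")
  chan <- cn48_channels()
  y <- x
  for (hs in c("loh", "het")) {
    sizes <- unique(chan$size[chan$het_state == hs])
    for (sz in sizes) {
      sel <- chan$het_state == hs & chan$size == sz
      tcn <- chan$tcn[sel]
      idx <- which(sel)[order(match(tcn, TCN_LABELS))]  # ascending TCN
      old <- x[idx]
      new <- numeric(length(old))
      new[-1] <- old[-length(old)]
      new[length(new)] <- new[length(new)] + old[length(old)]
      y[idx] <- new
    }
  }
  y
}

#' Genome-doubling analogue pairs within a signature set
#'
#' Finds ordered pairs (i, j), i != j, whose artificially doubled i-th
#' signature matches the j-th at cosine similarity above `threshold` —
#' signature pairs with analogous patterns distinguished only by doubling
#' status.
#'
#' @param signatures 48 x K column-stochastic matrix with column names.
#' @param threshold cosine similarity cut-off (default 0.85, strict `>`).
#' @return data.frame with `original`, `doubled_match`, `cosine`.
#' @export
gd_pairs <- function(signatures, threshold = 0.85) {
  K <- ncol(signatures)
  labs <- colnames(signatures)
  if (is.null(labs)) labs <- paste0("S", seq_len(K))
  out <- list()
  doubled <- double_signature(signatures)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    cs <- cosine_similarity(doubled[, i], signatures[, j])
    if (!is.na(cs) && cs > threshold)
      out[[length(out) + 1]] <- data.frame(original = labs[i],
                                           doubled_match = labs[j],
                                           cosine = cs,
                                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(original = character(), doubled_match = character(),
                      cosine = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
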