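## 48-channel encoding of allele-specific copy-number segments.
##
## Channels are the valid combinations of heterozygosity state, total copy
## number (TCN) class and segment-size class:
##   homdel (TCN 0)            x 3 size bins  =  3
##   LOH    (TCN 1,2,3-4,5-8,9+) x 5 size bins = 25
##   het    (TCN 2,3-4,5-8,9+)   x 5 size bins = 20
## Size bins are half-open with inclusive upper bounds:
## (0,100kb], (100kb,1Mb], (1Mb,10Mb], (10Mb,40Mb], (40Mb,Inf); the homdel
## size axis collapses to (0,100kb], (100kb,1Mb], (1Mb,Inf).

SIZE_LABELS  <- c("0-100kb", "100kb-1Mb", "1Mb-10Mb", "10Mb-40Mb", ">40Mb")
SIZE_LABELS_HD <- c("0-100kb", "100kb-1Mb", ">1Mb")
TCN_LABELS <- c("0", "1", "2", "3-4", "5-8", "9+")

#' Heterozygosity state of a segment
#'
#' `het` if both alleles present (A > 0, B > 0), `loh` if only the major
#' allele remains (A > 0, B = 0), `homdel` if both are lost (A = B = 0).
#'
#' @param major_cn,minor_cn integer allele copy numbers (vectorized).
#' @return character vector in `{"homdel","loh","het"}`.
#' @export
het_state <- function(major_cn, minor_cn) {
  if (any(major_cn < 0 | minor_cn < 0)) stop("negative allele copy number")
  ifelse(minor_cn > 0, "het", ifelse(major_cn > 0, "loh", "homdel"))
}

#' Total-copy-number class of a segment
#'
#' Classes: 0 (homozygous deletion), 1 (deletion leading to LOH),
#' 2 (wild type, incl. copy-neutral LOH), 3-4 (minor gain), 5-8 (moderate
#' gain), 9+ (high-level amplification).
#'
#' @param tcn non-negative integer total copy number (vectorized).
#' @return character vector of class labels.
#' @export
tcn_class <- function(tcn) {
  if (any(tcn < 0)) stop("negative total copy number")
  cut_idx <- findInterval(tcn, c(0, 1, 2, 3, 5, 9))
  TCN_LABELS[cut_idx]
}

#' Size class of a segment
#'
#' Five bins for het/LOH segments; three for homozygous deletions (whose
#' largest category is >1 Mb). Upper bin bounds are inclusive.
#'
#' @param length_bp segment length in base pairs (>= 1, vectorized).
#' @param het_state `"homdel"`, `"loh"` or `"het"` (recycled).
#' @return character vector of size labels.
#' @export
size_class <- function(length_bp, het_state) {
  if (any(length_bp <= 0)) stop("non-positive segment length")
  n <- max(length(length_bp), length(het_state))
  length_bp <- rep_len(length_bp, n)
  het_state <- rep_len(het_state, n)
  i5 <- 1 + findInterval(length_bp, c(1e5, 1e6, 1e7, 4e7), left.open = FALSE,
                         rightmost.closed = FALSE)
  ## findInterval with default closure puts x == bound into the upper bin;
  ## shift exact bounds down to make upper bounds inclusive.
  on_bound <- length_bp %in% c(1e5, 1e6, 1e7, 4e7)
  i5[on_bound] <- i5[on_bound] - 1
  i3 <- pmin(i5, 3)
  ifelse(het_state == "homdel", SIZE_LABELS_HD[i3], SIZE_LABELS[i5])
}

#' The 48-channel catalogue table
#'
#' @return data.frame with `index` (1-48), `het_state`, `tcn`, `size`, and
#'   channel `name` (`"het:3-4:>40Mb"` style), in the fixed package order:
#'   homdel channels first (by size), then LOH (by TCN then size), then het.
#' @export
cn48_channels <- function() {
  rows <- list(
    data.frame(het_state = "homdel", tcn = "0", size = SIZE_LABELS_HD,
               stringsAsFactors = FALSE))
  for (tc in c("1", "2", "3-4", "5-8", "9+"))
    rows[[length(rows) + 1]] <- data.frame(het_state = "loh", tcn = tc,
                                           size = SIZE_LABELS,
                                           stringsAsFactors = FALSE)
  for (tc in c("2", "3-4", "5-8", "9+"))
    rows[[length(rows) + 1]] <- data.frame(het_state = "het", tcn = tc,
                                           size = SIZE_LABELS,
                                           stringsAsFactors = FALSE)
  tab <- do.call(rbind, rows)
  tab$index <- seq_len(nrow(tab))
  tab$name <- paste(tab$het_state, tab$tcn, tab$size, sep = ":")
  tab[, c("index", "het_state", "tcn", "size", "name")]
}

#' Classify segments into 48-channel indices
#'
#' Composition of [het_state()], [tcn_class()] and [size_class()]; every
#' valid segment maps to exactly one channel.
#'
#' @param major_cn,minor_cn integer allele copy numbers (vectorized).
#' @param length_bp segment length in bp.
#' @return integer channel indices (1-48).
#' @export
classify_segment <- function(major_cn, minor_cn, length_bp) {
  hs <- het_state(major_cn, minor_cn)
  tc <- tcn_class(major_cn + minor_cn)
  sz <- size_class(length_bp, hs)
  chan <- cn48_channels()
  idx <- match(paste(hs, tc, sz, sep = ":"), chan$name)
  if (any(is.na(idx))) stop("unclassifiable segment (internal error)")
  idx
}

#' 48-channel count vector of one profile
#'
#' @param profile a `cn_profile`.
#' @return named integer vector of length 48; sums to the segment count.
#' @export
count_cn48 <- function(profile) {
  chan <- cn48_channels()
  counts <- integer(48)
  names(counts) <- chan$name
  seg <- profile$segments
  if (nrow(seg)) {
    idx <- classify_segment(seg$major_cn, seg$minor_cn, seg$end - seg$start + 1)
    t0 <- tabulate(idx, nbins = 48)
    counts[] <- t0
  }
  counts
}

#' Build the samples x 48 catalogue matrix
#'
#' @param profiles list of `cn_profile` with unique sample ids.
#' @return integer matrix (S x 48) with sample-id rownames and channel-name
#'   colnames; row sums equal per-sample segment counts.
#' @export
build_matrix <- function(profiles) {
  if (inherits(profiles, "cn_profile")) profiles <- list(profiles)
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- t(vapply(profiles, count_cn48, integer(48)))
  if (length(profiles) == 0)
    m <- matrix(0L, 0, 48, dimnames = list(NULL, cn48_channels()$name))
  rownames(m) <- ids
  m
}

#' Filter samples by homozygous-deletion burden
#'
#' Samples whose summed homozygous-deletion (A = B = 0) length exceeds
#' `max_homdel_mb` megabases are removed (strict `>`; a sample at exactly the
#' threshold is kept).
#'
#' @param profiles list of `cn_profile`.
#' @param max_homdel_mb threshold in Mb (default 25).
#' @return list with `kept` and `removed` profile lists and `burden_mb`,
#'   the per-sample homdel burden.
#' @export
filter_homdel_burden <- function(profiles, max_homdel_mb = 25) {
  burden <- vapply(profiles, function(p) {
    seg <- p$segments
    hd <- seg$major_cn == 0 & seg$minor_cn == 0
    sum(seg$end[hd] - seg$start[hd] + 1) / 1e6
  }, numeric(1))
  over <- burden > max_homdel_mb
  list(kept = profiles[!over], removed = profiles[over], burden_mb = burden)
}

#' Per-profile summary statistics
#'
#' @param profile a `cn_profile`.
#' @return list with `n_segments`, `ploidy` (length-weighted mean TCN) and
#'   `ploh` (fraction of covered length in LOH); `ploidy`/`ploh` are `NA`
#'   for an empty profile.
#' @export
profile_summary <- function(profile) {
  n <- nrow(profile$segments)
  if (n == 0) return(list(n_segments = 0L, ploidy = NA_real_, ploh = NA_real_))
  list(n_segments = n, ploidy = compute_ploidy(profile),
       ploh = compute_ploh(profile))
}
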