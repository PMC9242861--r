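#' Per-segment signature posteriors for one sample
#'
#' Under a multinomial-mixture reading of the factorization, a segment in
#' channel c generated by the sample's attributed signatures has posterior
#' `p_i proportional to attribution_i * signatures[c, i]`. Segments whose
#' products are all zero cannot be mapped and are flagged `mappable = FALSE`.
#'
#' @param profile a `cn_profile`.
#' @param attribution attributed counts for this sample (named length-K
#'   vector, e.g. one row of `attribute_cohort()$counts`).
#' @param signatures 48 x K column-stochastic matrix.
#' @return data.frame of the profile's segments with `channel`, `mappable`,
#'   `assigned` (argmax signature label, ties to the lowest column index)
#'   and one posterior column per signature (`p_<label>`).
#' @export
segment_posteriors <- function(profile, attribution, signatures) {
  seg <- profile$segments
  labs <- colnames(signatures)
  if (is.null(labs)) labs <- paste0("S", seq_len(ncol(signatures)))
  out <- seg
  out$sample <- profile$sample_id
  out$channel <- if (nrow(seg))
    classify_segment(seg$major_cn, seg$minor_cn, seg$end - seg$start + 1)
  else integer(0)
  post <- matrix(NA_real_, nrow(seg), ncol(signatures),
                 dimnames = list(NULL, paste0("p_", labs)))
  assigned <- rep(NA_character_, nrow(seg))
  mappable <- logical(nrow(seg))
  for (i in seq_len(nrow(seg))) {
    w <- as.numeric(attribution) * signatures[out$channel[i], ]
    if (sum(w) > 0) {
      post[i, ] <- w / sum(w)
      assigned[i] <- labs[which.max(w)]
      mappable[i] <- TRUE
    }
  }
  out$mappable <- mappable
  out$assigned <- assigned
  cbind(out, post)
}

#' Map attributed signatures across a cohort
#'
#' @param profiles list of `cn_profile`.
#' @param attribution a `cn_attribution` from [attribute_cohort()] whose row
#'   order matches `profiles`.
#' @param signatures 48 x K column-stochastic matrix.
#' @return row-bound data.frame of [segment_posteriors()] results, one row
#'   per segment, with a `sample` column.
#' @export
map_cohort <- function(profiles, attribution, signatures) {
  do.call(rbind, lapply(seq_along(profiles), function(i)
    segment_posteriors(profiles[[i]], attribution$counts[i, ], signatures)))
}

## Window index range [i1, i2] (1-based) covered by [start, end] for a
## half-open tiling [k*w+1, (k+1)*w].
window_span <- function(start, end, w) {
  cbind(floor((start - 1) / w) + 1, floor((end - 1) / w) + 1)
}

## Count segments per window for one chromosome's tiling.
count_windows <- function(start, end, w, n_win) {
  if (!length(start)) return(integer(n_win))
  sp <- window_span(start, end, w)
  sp[, 2] <- pmin(sp[, 2], n_win)
  idx <- unlist(lapply(seq_len(nrow(sp)), function(i) sp[i, 1]:sp[i, 2]))
  tabulate(idx, nbins = n_win)
}

#' Genome-window enrichment of a mapped signature
#'
#' Tiles the genome into fixed-size windows and counts cohort segments
#' argmax-assigned to the target signature that overlap each window (>= 1 bp).
#' The null redistributes the same segments, lengths preserved, to uniformly
#' random genome positions `n_boot` times;
#' `p = (1 + #{null >= obs}) / (1 + n_boot)` per window, with a
#' Westfall-Young max-statistic step-down adjustment computed from the same
#' bootstrap draws.
#'
#' @param mapped data.frame from [map_cohort()].
#' @param genome a `cn_genome`.
#' @param signature target signature label.
#' @param window window size in bp (default 1e6).
#' @param n_boot bootstrap draws (>= 1).
#' @param seed master seed.
#' @return data.frame with `chrom`, `start`, `end`, `observed`, `null_mean`,
#'   `p`, `q`.
#' @export
window_enrichment <- function(mapped, genome, signature, window = 1e6,
                              n_boot = 1000, seed = NULL) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  if (any(genome$chrom$length < window))
    warning("window larger than the smallest chromosome")
  seg <- mapped[!is.na(mapped$assigned) & mapped$assigned == signature, ,
                drop = FALSE]
  if (nrow(seg) == 0) stop("no segments assigned to signature ", signature)
  chroms <- genome$chrom$chrom
  lens <- genome$chrom$length
  n_win <- pmax(1L, as.integer(ceiling(lens / window)))
  offsets <- c(0L, cumsum(n_win))  # window-index offset per chromosome
  total_win <- sum(n_win)
  obs <- integer(total_win)
  for (ci in seq_along(chroms)) {
    s <- seg[seg$chrom == chroms[ci], , drop = FALSE]
    obs[(offsets[ci] + 1):offsets[ci + 1]] <-
      count_windows(s$start, s$end, window, n_win[ci])
  }
  seg_len <- seg$end - seg$start + 1
  null_counts <- with_seed(substream_seed(seed, 7L), {
    vapply(seq_len(n_boot), function(b) {
      ## place each segment uniformly among all feasible genome positions
      nb <- integer(total_win)
      avail <- outer(lens, seg_len, function(L, l) pmax(L - l + 1, 0))
      for (si in seq_along(seg_len)) {
        ci <- sample.int(length(chroms), 1, prob = avail[, si])
        st <- floor(stats::runif(1, 0, avail[ci, si])) + 1
        cw <- count_windows(st, st + seg_len[si] - 1, window, n_win[ci])
        rng <- (offsets[ci] + 1):offsets[ci + 1]
        nb[rng] <- nb[rng] + cw
      }
      nb
    }, integer(total_win))
  })
  p <- (1 + rowSums(null_counts >= obs)) / (1 + n_boot)
  ## Westfall-Young step-down on the same draws
  ord <- order(obs, decreasing = TRUE)
  succ_max <- apply(null_counts[rev(ord), , drop = FALSE], 2, cummax)
  succ_max <- succ_max[nrow(succ_max):1, , drop = FALSE]  # row j: max over ord[j..m]
  q_ord <- (1 + rowSums(succ_max >= obs[ord])) / (1 + n_boot)
  q_ord <- cummax(q_ord)
  q <- numeric(total_win)
  q[ord] <- q_ord
  win_chrom <- rep(chroms, n_win)
  win_start <- unlist(lapply(seq_along(chroms),
                             function(ci) (seq_len(n_win[ci]) - 1) * window + 1))
  data.frame(chrom = win_chrom, start = win_start,
             end = pmin(win_start + window - 1, rep(lens, n_win)),
             observed = obs, null_mean = rowMeans(null_counts), p = p, q = q,
             stringsAsFactors = FALSE)
}

#' Read a BED file of labeled regions
#'
#' @param path BED path (0-based half-open; converted to 1-based inclusive).
#' @param chr_prefix chromosome-name policy (see [read_segments()]).
#' @return data.frame with `chrom`, `start`, `end`, `label`.
#' @export
read_bed <- function(path, chr_prefix = "strip") {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           comment.char = "#")
  data.frame(chrom = normalize_chrom(tab[[1]], chr_prefix),
             start = as.numeric(tab[[2]]) + 1, end = as.numeric(tab[[3]]),
             label = if (ncol(tab) >= 4) as.character(tab[[4]]) else
               paste0("region", seq_len(nrow(tab))),
             stringsAsFactors = FALSE)
}

segments_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start, end = df$end))
}

#' Region-overlap association of a mapped signature
#'
#' Pools segments across samples into a 2x2 table of (overlaps a region) x
#' (assigned to the signature) and applies a two-sided Fisher's exact test.
#' The odds ratio is reported both raw (`(a*d)/(b*c)`, possibly infinite)
#' and with a Haldane 0.5 correction when any cell is zero.
#'
#' @param mapped data.frame from [map_cohort()] (unmappable segments are
#'   dropped).
#' @param regions data.frame with `chrom`, `start`, `end` (1-based
#'   inclusive; see [read_bed()]).
#' @param signature target signature label.
#' @return one-row data.frame with the table cells, `odds_ratio`,
#'   `odds_ratio_haldane`, `p`, `degenerate`.
#' @export
region_association <- function(mapped, regions, signature) {
  seg <- mapped[mapped$mappable, , drop = FALSE]
  if (nrow(seg) == 0) stop("no mappable segments")
  if (nrow(regions) == 0) stop("empty region set")
  ov <- IRanges::overlapsAny(segments_granges(seg), segments_granges(regions))
  asg <- seg$assigned == signature
  a <- sum(ov & asg); b <- sum(ov & !asg)
  cc <- sum(!ov & asg); d <- sum(!ov & !asg)
  tab <- matrix(c(a, b, cc, d), 2, 2)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  or_raw <- (a * d) / (b * cc)
  or_h <- if (a == 0 || b == 0 || cc == 0 || d == 0)
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5)) else or_raw
  data.frame(signature = signature, overlap_assigned = a,
             overlap_other = b, rest_assigned = cc, rest_other = d,
             odds_ratio = or_raw, odds_ratio_haldane = or_h, p = p,
             degenerate = degenerate, stringsAsFactors = FALSE)
}

#' Region association across all signatures with BH adjustment
#'
#' @inheritParams region_association
#' @param signatures character vector of labels to test (default: all
#'   assigned labels present in `mapped`).
#' @return data.frame, one row per signature, with a BH-adjusted `q` column.
#' @export
region_association_all <- function(mapped, regions, signatures = NULL) {
  if (is.null(signatures))
    signatures <- sort(unique(stats::na.omit(mapped$assigned)))
  out <- do.call(rbind, lapply(signatures, function(s)
    region_association(mapped, regions, s)))
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Arm-level aneuploidy map from a near-diploid/tetraploid signature pair
#'
#' Restricts the cohort to samples explained entirely by the two named
#' signatures (their normalized attributions sum to 1 within `tol`) with a
#' mixed attribution (product > `product_threshold`), then reports, per
#' chromosome arm, the fraction of retained samples whose length-majority
#' total copy number on the arm exceeds (gain) or falls below (loss) the
#' diploid baseline of 2.
#'
#' @param attribution a `cn_attribution` (normalized rows are used).
#' @param profiles list of `cn_profile` matching the attribution rows.
#' @param pair length-2 character vector naming the two signatures.
#' @param genome a `cn_genome` providing arm boundaries.
#' @param product_threshold minimum attribution product (default 0.15,
#'   strict `>`).
#' @param tol tolerance on the pair-sum test (default 1e-6).
#' @return data.frame with `chrom`, `arm`, `n`, `frac_gain`, `frac_loss`;
#'   zero rows (with a warning) if no sample qualifies.
#' @export
aneuploidy_map <- function(attribution, profiles, pair, genome,
                           product_threshold = 0.15, tol = 1e-6) {
  norm <- attribution$normalized
  if (!all(pair %in% colnames(norm))) stop("pair signatures not in attribution")
  s <- norm[, pair[1]] + norm[, pair[2]]
  prod <- norm[, pair[1]] * norm[, pair[2]]
  keep <- abs(s - 1) <= tol & prod > product_threshold
  arms <- genome_arms(genome)
  if (!any(keep)) {
    warning("no samples qualify for the aneuploidy map")
    return(cbind(arms[0, ], n = integer(0), frac_gain = numeric(0),
                 frac_loss = numeric(0)))
  }
  kept <- profiles[keep]
  majority_tcn <- function(profile, chrom, a_start, a_end) {
    seg <- profile$segments
    seg <- seg[seg$chrom == chrom & seg$start <= a_end & seg$end >= a_start, ,
               drop = FALSE]
    if (nrow(seg) == 0) return(NA_real_)
    ovl <- pmin(seg$end, a_end) - pmax(seg$start, a_start) + 1
    tcn <- seg$major_cn + seg$minor_cn
    wt <- tapply(ovl, tcn, sum)
    as.numeric(names(wt)[which.max(wt)])
  }
  res <- lapply(seq_len(nrow(arms)), function(i) {
    tcn <- vapply(kept, majority_tcn, numeric(1), arms$chrom[i],
                  arms$start[i], arms$end[i])
    tcn <- tcn[!is.na(tcn)]
    data.frame(chrom = arms$chrom[i], arm = arms$arm[i], n = length(tcn),
               frac_gain = if (length(tcn)) mean(tcn > 2) else NA_real_,
               frac_loss = if (length(tcn)) mean(tcn < 2) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Signature enrichment across sample strata
#'
#' For each signature and stratum (e.g. WGD level), a one-sided Fisher's
#' exact test on the 2x2 table of (normalized attribution > `threshold`) x
#' (sample in stratum), BH-adjusted across all tests.
#'
#' @param attribution a `cn_attribution` (normalized rows are used).
#' @param strata factor/character vector of stratum labels per sample.
#' @param threshold attribution presence cut-off (default 0.05, strict `>`).
#' @param alternative passed to [stats::fisher.test()] (default
#'   `"greater"`, i.e. enrichment).
#' @return data.frame with `signature`, `stratum`, cells, `odds_ratio`, `p`,
#'   `q`; empty strata are skipped with a warning.
#' @export
stratum_enrichment <- function(attribution, strata, threshold = 0.05,
                               alternative = "greater") {
  norm <- attribution$normalized
  strata <- as.character(strata)
  if (length(strata) != nrow(norm)) stop("strata length != number of samples")
  levels <- sort(unique(strata))
  out <- list()
  for (sig in colnames(norm)) {
    present <- norm[, sig] > threshold
    for (st in levels) {
      inst <- strata == st
      if (!any(inst)) { warning("empty stratum ", st, " skipped"); next }
      a <- sum(present & inst); b <- sum(present & !inst)
      cc <- sum(!present & inst); d <- sum(!present & !inst)
      ft <- stats::fisher.test(matrix(c(a, cc, b, d), 2, 2),
                               alternative = alternative)
      out[[length(out) + 1]] <- data.frame(
        signature = sig, stratum = st, present_in = a, present_out = b,
        absent_in = cc, absent_out = d,
        odds_ratio = unname(ft$estimate), p = ft$p.value,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res
}
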