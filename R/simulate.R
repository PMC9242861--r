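#' Configuration for the copy-number-evolution simulator
#'
#' Each simulated genome starts diploid — (1, 1) on every chromosome of
#' `genome` (autosomes by default) — and accumulates events: whole-chromosome
#' and arm-level missegregations, focal gains/losses, zero to two
#' whole-genome doublings, and optionally chromothripsis. Per-sample event
#' counts are Poisson draws at the configured rates; CIN events are split
#' uniformly before/after the WGD(s); chromothripsis is applied last.
#'
#' @param n_samples cohort size.
#' @param chrom_rate expected whole-chromosome missegregations per genome.
#' @param arm_rate expected arm-level events per genome.
#' @param focal_rate expected focal events per genome.
#' @param focal_size_range focal length bounds in bp, drawn log-uniformly
#'   (default 100 kb - 10 Mb, populating every size bin).
#' @param gain_loss_ratio expected gains per loss among CIN events
#'   (default 1; 0 means losses only).
#' @param focal_gain_copies copies added by a focal gain (default 1).
#' @param n_wgd whole-genome doublings: an integer 0-2 applied to every
#'   sample, or a length-3 probability vector over (0, 1, 2).
#' @param chromothripsis_prob per-sample probability of a chromothripsis
#'   event (default 0).
#' @param ct_region_range chromothripsis region length bounds (bp,
#'   log-uniform).
#' @param ct_breaks number of oscillating breakpoints per event (>= 2).
#' @param ct_amplify amplify retained chromothripsis pieces (default
#'   `FALSE`).
#' @param ct_gain_copies copies added to retained pieces when amplifying.
#' @param genome a `cn_genome` (default hg19 autosomes).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 100, chrom_rate = 0, arm_rate = 0,
                       focal_rate = 0, focal_size_range = c(1e5, 1e7),
                       gain_loss_ratio = 1, focal_gain_copies = 1,
                       n_wgd = 0, chromothripsis_prob = 0,
                       ct_region_range = c(1e6, 3e7), ct_breaks = 10,
                       ct_amplify = FALSE, ct_gain_copies = 7,
                       genome = NULL) {
  if (is.null(genome)) genome <- load_genome("hg19", include_x = FALSE)
  stopifnot(n_samples >= 1, chrom_rate >= 0, arm_rate >= 0, focal_rate >= 0,
            gain_loss_ratio >= 0, focal_size_range[1] > 0,
            focal_size_range[1] <= focal_size_range[2],
            ct_region_range[1] > 0, ct_region_range[1] <= ct_region_range[2],
            ct_breaks >= 2)
  if (length(n_wgd) == 3) {
    if (abs(sum(n_wgd) - 1) > 1e-9) stop("n_wgd probabilities must sum to 1")
  } else if (!(length(n_wgd) == 1 && n_wgd %in% 0:2)) {
    stop("n_wgd must be 0, 1, 2 or a length-3 probability vector")
  }
  if (focal_size_range[2] > max(genome$chrom$length))
    stop("focal size exceeds the largest chromosome")
  structure(as.list(environment()), class = "sim_config")
}

## Diploid haplotype-resolved starting state: one (h1 = 1, h2 = 1) segment
## per chromosome.
diploid_state <- function(genome) {
  data.frame(chrom = genome$chrom$chrom, start = 1, end = genome$chrom$length,
             h1 = 1, h2 = 1, stringsAsFactors = FALSE)
}

## Ensure `pos` starts a segment on `chrom` (split the covering segment).
split_at <- function(state, chrom, pos) {
  i <- which(state$chrom == chrom & state$start < pos & state$end >= pos)
  if (length(i)) {
    row <- state[i, ]
    state$end[i] <- pos - 1
    row$start <- pos
    state <- rbind(state, row)
    state <- state[order(chrom_order(state$chrom), state$start), ]
    rownames(state) <- NULL
  }
  state
}

## Apply a copy-number delta on one haplotype over [start, end]; copy
## numbers floor at 0 (a loss on a lost haplotype is a no-op).
apply_delta <- function(state, chrom, start, end, hap, delta) {
  state <- split_at(state, chrom, start)
  state <- split_at(state, chrom, end + 1)
  i <- state$chrom == chrom & state$start >= start & state$end <= end
  col <- paste0("h", hap)
  state[[col]][i] <- pmax(state[[col]][i] + delta, 0)
  state
}

## Apply one logged event to a haplotype state.
apply_event <- function(state, ev) {
  switch(ev$type,
    wgd = { state$h1 <- 2 * state$h1; state$h2 <- 2 * state$h2; state },
    cna = apply_delta(state, ev$chrom, ev$start, ev$end, ev$hap, ev$delta),
    stop("unknown event type ", ev$type))
}

#' Replay a truth event log from the diploid genome
#'
#' @param events list of events (each `list(type, chrom, start, end, hap,
#'   delta)` or `list(type = "wgd")`), in order.
#' @param genome a `cn_genome`.
#' @param sample_id id for the emitted profile.
#' @return the `cn_profile` produced by applying the log to a diploid
#'   genome, merged with [merge_adjacent()].
#' @export
replay_truth <- function(events, genome, sample_id = "replay") {
  state <- diploid_state(genome)
  for (ev in events) state <- apply_event(state, ev)
  emit_profile(state, sample_id, genome)
}

## Collapse a haplotype state into a cn_profile (major/minor ordering,
## abutting equal segments merged).
emit_profile <- function(state, sample_id, genome) {
  seg <- data.frame(chrom = state$chrom, start = state$start, end = state$end,
                    major_cn = pmax(state$h1, state$h2),
                    minor_cn = pmin(state$h1, state$h2),
                    stringsAsFactors = FALSE)
  merge_adjacent(cn_profile(sample_id, seg, genome = genome))
}

#' Whole-genome doubling of a profile
#'
#' Duplicates every segment's allele copy numbers, (A, B) -> (2A, 2B):
#' ploidy exactly doubles and pLOH is unchanged.
#'
#' @param profile a `cn_profile`.
#' @return doubled `cn_profile`.
#' @export
apply_wgd <- function(profile) {
  profile$segments$major_cn <- 2 * profile$segments$major_cn
  profile$segments$minor_cn <- 2 * profile$segments$minor_cn
  profile
}

## Draw chromothripsis piece events for one region: `n_breaks` sorted
## uniform internal breakpoints partition [start, end] into n_breaks + 1
## pieces; alternating pieces lose one copy of `hap` (oscillation between
## the current state and state - 1); if `amplify`, retained pieces gain
## `gain_copies`.
chromothripsis_events <- function(chrom, start, end, n_breaks, hap,
                                  amplify = FALSE, gain_copies = 7) {
  if (n_breaks < 2) stop("chromothripsis needs n_breaks >= 2")
  if (end - start < n_breaks) stop("region shorter than n_breaks + 1 bp")
  bks <- sort(start + sample.int(end - start, n_breaks))
  bounds <- c(start, bks, end + 1)
  evs <- list()
  for (i in seq_len(length(bounds) - 1)) {
    p_start <- bounds[i]; p_end <- bounds[i + 1] - 1
    lost <- i %% 2 == 0
    if (lost) {
      evs[[length(evs) + 1]] <- list(type = "cna", class = "chromothripsis",
                                     chrom = chrom, start = p_start,
                                     end = p_end, hap = hap, delta = -1)
    } else if (amplify) {
      evs[[length(evs) + 1]] <- list(type = "cna", class = "chromothripsis",
                                     chrom = chrom, start = p_start,
                                     end = p_end, hap = hap,
                                     delta = gain_copies)
    }
  }
  evs
}

#' Apply a chromothripsis event to a profile
#'
#' Partitions `region` at `n_breaks` sorted uniform breakpoints; alternating
#' pieces lose one copy of one haplotype, producing oscillation between two
#' copy states; with `amplify`, retained pieces gain `gain_copies` copies.
#'
#' @param profile a `cn_profile`.
#' @param chrom,start,end the affected region (single chromosome).
#' @param n_breaks number of breakpoints (>= 2).
#' @param amplify amplify retained pieces.
#' @param gain_copies copies added when amplifying.
#' @param hap haplotype hit (1 or 2; the major-allele haplotype by default).
#' @param seed optional seed for the breakpoint draw.
#' @return modified `cn_profile`.
#' @export
apply_chromothripsis <- function(profile, chrom, start, end, n_breaks,
                                 amplify = FALSE, gain_copies = 7, hap = 1,
                                 seed = NULL) {
  state <- data.frame(chrom = profile$segments$chrom,
                      start = profile$segments$start,
                      end = profile$segments$end,
                      h1 = profile$segments$major_cn,
                      h2 = profile$segments$minor_cn,
                      stringsAsFactors = FALSE)
  evs <- with_seed(seed,
    chromothripsis_events(chrom, start, end, n_breaks, hap, amplify,
                          gain_copies))
  for (ev in evs) state <- apply_event(state, ev)
  emit_profile(state, profile$sample_id, profile$genome)
}

## Draw the CIN/WGD/chromothripsis event log for one sample.
draw_events <- function(config) {
  g <- config$genome
  chroms <- g$chrom$chrom
  arms <- genome_arms(g)
  p_gain <- config$gain_loss_ratio / (1 + config$gain_loss_ratio)
  draw_cna <- function(kind) {
    gain <- stats::runif(1) < p_gain
    hap <- sample(1:2, 1)
    if (kind == "chrom") {
      ci <- sample(seq_along(chroms), 1)
      list(type = "cna", class = "chrom", chrom = chroms[ci], start = 1,
           end = g$chrom$length[ci], hap = hap,
           delta = if (gain) 1 else -1)
    } else if (kind == "arm") {
      ai <- sample(seq_len(nrow(arms)), 1)
      list(type = "cna", class = "arm", chrom = arms$chrom[ai],
           start = arms$start[ai], end = arms$end[ai], hap = hap,
           delta = if (gain) 1 else -1)
    } else {
      len <- round(exp(stats::runif(1, log(config$focal_size_range[1]),
                                    log(config$focal_size_range[2]))))
      ok <- which(g$chrom$length >= len)
      ci <- ok[sample.int(length(ok), 1)]
      st <- floor(stats::runif(1, 0, g$chrom$length[ci] - len + 1)) + 1
      list(type = "cna", class = "focal", chrom = chroms[ci], start = st,
           end = st + len - 1, hap = hap,
           delta = if (gain) config$focal_gain_copies else -1)
    }
  }
  n_ev <- c(chrom = stats::rpois(1, config$chrom_rate),
            arm = stats::rpois(1, config$arm_rate),
            focal = stats::rpois(1, config$focal_rate))
  cin <- list()
  for (kind in names(n_ev))
    for (i in seq_len(n_ev[[kind]]))
      cin[[length(cin) + 1]] <- draw_cna(kind)
  if (length(cin) > 1) cin <- cin[sample(length(cin))]
  nw <- if (length(config$n_wgd) == 3)
    sample(0:2, 1, prob = config$n_wgd) else config$n_wgd
  events <- list()
  if (nw > 0 && length(cin)) {
    pre <- stats::runif(length(cin)) < 0.5
    events <- c(cin[pre],
                rep(list(list(type = "wgd")), nw),
                cin[!pre])
  } else {
    events <- c(cin, rep(list(list(type = "wgd")), nw))
  }
  if (stats::runif(1) < config$chromothripsis_prob) {
    len <- round(exp(stats::runif(1, log(config$ct_region_range[1]),
                                  log(config$ct_region_range[2]))))
    ok <- which(g$chrom$length >= len)
    ci <- ok[sample.int(length(ok), 1)]
    st <- floor(stats::runif(1, 0, g$chrom$length[ci] - len + 1)) + 1
    events <- c(events,
                chromothripsis_events(chroms[ci], st, st + len - 1,
                                      config$ct_breaks, sample(1:2, 1),
                                      config$ct_amplify,
                                      config$ct_gain_copies))
  }
  events
}

#' Simulate a cohort of allele-specific copy-number profiles
#'
#' Deterministic given `seed`: each sample's event log is drawn from the
#' configured process rates and the profile is emitted by replaying the log
#' from the diploid genome, so the truth log reproduces the profile exactly.
#'
#' @param config a [sim_config()].
#' @param seed master seed.
#' @param prefix sample-id prefix (default `"sim"`).
#' @return `list(profiles, truth)`: `profiles` is a named list of
#'   `cn_profile`; `truth` a named list of per-sample event logs.
#' @export
simulate_cohort <- function(config, seed = NULL, prefix = "sim") {
  stopifnot(inherits(config, "sim_config"))
  ids <- sprintf("%s%03d", prefix, seq_len(config$n_samples))
  truth <- lapply(seq_len(config$n_samples), function(i)
    with_seed(substream_seed(seed, i), draw_events(config)))
  names(truth) <- ids
  profiles <- lapply(ids, function(id)
    replay_truth(truth[[id]], config$genome, sample_id = id))
  names(profiles) <- ids
  list(profiles = profiles, truth = truth)
}

#' Three-process study cohort
#'
#' Fixed benchmark cohort mixing three well-separated copy-number processes:
#' a diploid baseline (no events), a pure whole-genome doubling, and a
#' focal-LOH CIN process (60 expected focal losses per genome, log-uniform
#' 100 kb - 10 Mb). The process spectra are mutually separated (pairwise
#' cosine < 0.5), so the planted signatures are identifiable by extraction.
#'
#' @param n length-3 vector of per-process sample counts (default
#'   `c(70, 70, 60)`).
#' @param seed master seed.
#' @param genome a `cn_genome` (default hg19 autosomes).
#' @return list with `profiles`, `process` (label per sample), `truth`
#'   (event logs) and `spectra` (48 x 3 matrix of empirical per-process
#'   channel distributions).
#' @export
sim_three_process_cohort <- function(n = c(70, 70, 60), seed = NULL,
                                     genome = NULL) {
  if (is.null(genome)) genome <- load_genome("hg19", include_x = FALSE)
  cfgs <- list(
    diploid = sim_config(n_samples = n[1], genome = genome),
    wgd     = sim_config(n_samples = n[2], n_wgd = 1, genome = genome),
    focal_loh = sim_config(n_samples = n[3], focal_rate = 60,
                           gain_loss_ratio = 0, genome = genome))
  sims <- lapply(seq_along(cfgs), function(i)
    simulate_cohort(cfgs[[i]], seed = substream_seed(seed, 10000L * i),
                    prefix = c("dip", "wgd", "cin")[i]))
  profiles <- do.call(c, lapply(sims, `[[`, "profiles"))
  truth <- do.call(c, lapply(sims, `[[`, "truth"))
  process <- rep(names(cfgs), n)
  spectra <- vapply(names(cfgs), function(pr) {
    m <- build_matrix(profiles[process == pr])
    cs <- colSums(m)
    cs / sum(cs)
  }, numeric(48))
  list(profiles = profiles, process = process, truth = truth,
       spectra = spectra)
}

#' Catalogue-level mixture cohort from known signatures
#'
#' Draws samples whose 48-channel counts are multinomial mixtures of the
#' given signatures: per sample, mixing weights are Dirichlet(`alpha`),
#' the segment count is uniform on `seg_range`, and channel counts are a
#' single multinomial draw from the mixed spectrum. Used to validate
#' attribution recovery against known ground truth.
#'
#' @param signatures 48 x K column-stochastic matrix.
#' @param n_samples cohort size.
#' @param seg_range integer range of per-sample segment counts
#'   (default 50-500).
#' @param alpha Dirichlet concentration (scalar or length-K).
#' @param seed master seed.
#' @return list with `counts` (n x 48 matrix) and `weights` (n x K true
#'   mixing fractions).
#' @export
sim_mixture_catalogue <- function(signatures, n_samples,
                                  seg_range = c(50, 500), alpha = 1,
                                  seed = NULL) {
  K <- ncol(signatures)
  alpha <- rep_len(alpha, K)
  with_seed(seed, {
    weights <- t(vapply(seq_len(n_samples), function(i) {
      gam <- stats::rgamma(K, shape = alpha)
      gam / sum(gam)
    }, numeric(K)))
    counts <- t(vapply(seq_len(n_samples), function(i) {
      nseg <- sample(seg_range[1]:seg_range[2], 1)
      as.numeric(stats::rmultinom(1, nseg, signatures %*% weights[i, ]))
    }, numeric(48)))
    colnames(counts) <- rownames(signatures) %||% cn48_channels()$name
    rownames(counts) <- sprintf("mix%03d", seq_len(n_samples))
    colnames(weights) <- colnames(signatures)
    list(counts = counts, weights = weights)
  })
}
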