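sigs <- archetype_signatures()

test_that("segment posteriors follow attribution x channel weight, normalized", {
  p <- cn_profile("s", data.frame(
    chrom = c("1", "2"), start = c(1, 1), end = c(5e7, 5e5),
    major_cn = c(1, 2), minor_cn = c(1, 0)))  # het:2:>40Mb, loh:2:100kb-1Mb
  ## one attributed signature: posterior 1 wherever mappable
  att <- c(dip = 30, tet = 0, cin = 0, loh = 0)
  mp <- segment_posteriors(p, att, sigs)
  expect_equal(mp$p_dip[1], 1)
  expect_equal(mp$assigned[1], "dip")
  expect_false(mp$mappable[2])     # no attributed signature covers loh:2
  ## zero channel weight forces zero posterior
  att2 <- c(dip = 20, tet = 10, cin = 0, loh = 0)
  mp2 <- segment_posteriors(p, att2, sigs)
  expect_equal(mp2$p_tet[1], 0)
  ## derived case: attribution (60, 40), channel weights (0.5, 0.25)
  two <- cbind(a = 0.5 * unit_signature("het:2:>40Mb") +
                 0.5 * unit_signature("het:2:10Mb-40Mb"),
               b = 0.25 * unit_signature("het:2:>40Mb") +
                 0.75 * unit_signature("loh:1:0-100kb"))
  mp3 <- segment_posteriors(p, c(a = 60, b = 40), two)
  expect_equal(mp3$p_a[1], 0.75)
  expect_equal(mp3$p_b[1], 0.25)
  ## posteriors sum to 1 on mappable segments
  expect_equal(unname(rowSums(mp3[mp3$mappable, c("p_a", "p_b")])),
               rep(1, sum(mp3$mappable)))
})

test_that("a planted pile-up attains the minimal achievable window p", {
  genome <- load_genome("hg19", include_x = FALSE)
  set.seed(71)
  ## 10 segments piled into one window, 30 scattered
  pile <- data.frame(chrom = "1", start = seq(2e6, 2.9e6, 1e5), end = NA)
  pile$end <- pile$start + 5e4
  scatter_chrom <- sample(genome$chrom$chrom, 30, replace = TRUE)
  scatter_start <- floor(runif(30, 1, chrom_length(genome, scatter_chrom) - 1e5))
  scat <- data.frame(chrom = scatter_chrom, start = scatter_start,
                     end = scatter_start + 5e4)
  mapped <- rbind(pile, scat)
  mapped$mappable <- TRUE
  mapped$assigned <- "X"
  enr <- window_enrichment(mapped, genome, "X", n_boot = 99, seed = 72)
  hot <- enr[enr$chrom == "1" & enr$start == 2e6 + 1, ]
  expect_equal(hot$observed, 10)
  expect_equal(hot$p, 1 / 100)     # minimal achievable at 99 draws
  expect_true(all(enr$q >= enr$p - 1e-12))
  expect_error(window_enrichment(mapped, genome, "X", n_boot = 0), "n_boot")
})

test_that("region association matches the brute-force hypergeometric oracle", {
  res <- region_association(mapped_from_table(10, 20, 30, 40), toy_region, "X")
  expect_equal(res$odds_ratio, (10 * 40) / (20 * 30))
  expect_equal(res$p, fisher_oracle(10, 20, 30, 40), tolerance = 1e-9)
  ## complete separation: raw OR infinite, Haldane estimate finite
  res2 <- region_association(mapped_from_table(5, 0, 0, 7), toy_region, "X")
  expect_true(is.infinite(res2$odds_ratio) || is.nan(res2$odds_ratio))
  expect_true(is.finite(res2$odds_ratio_haldane))
  ## degenerate margin flagged
  res3 <- region_association(mapped_from_table(0, 0, 3, 4), toy_region, "X")
  expect_true(res3$degenerate)
  ## BH adjustment across signatures is monotone in p
  mixed <- rbind(mapped_from_table(15, 5, 5, 15),
                 within(mapped_from_table(4, 6, 6, 4), assigned[assigned == "X"] <- "Z"))
  all_res <- region_association_all(mixed, toy_region)
  expect_true(all(all_res$q >= all_res$p))
})

test_that("aneuploidy map applies the pair-sum and product filters and recovers planted gains", {
  genome <- load_genome("hg19", include_x = FALSE)
  pairsigs <- sigs[, c("dip", "tet")]
  diploid_seg <- function() data.frame(chrom = genome$chrom$chrom, start = 1,
                                       end = genome$chrom$length,
                                       major_cn = 1, minor_cn = 1)
  ## planted gain of chromosome 8q in every qualifying sample
  arms <- genome_arms(genome)
  q8 <- arms[arms$chrom == "8" & arms$arm == "q", ]
  profiles <- lapply(1:6, function(i) {
    seg <- diploid_seg()
    i8 <- which(seg$chrom == "8")
    seg <- rbind(seg[-i8, ],
                 data.frame(chrom = "8", start = c(1, q8$start),
                            end = c(q8$start - 1, q8$end),
                            major_cn = c(1, 2), minor_cn = c(1, 1)))
    cn_profile(paste0("s", i), seg, genome = genome)
  })
  att <- structure(list(normalized = rbind(
    s1 = c(dip = 0.5, tet = 0.5),    # retained: product 0.25
    s2 = c(0.6, 0.4),                # retained
    s3 = c(0.9, 0.1),                # excluded: product 0.09
    s4 = c(0.45, 0.45),              # excluded: sum != 1 (third signature)
    s5 = c(0.7, 0.3),                # retained
    s6 = c(0.5, 0.5))), class = "cn_attribution")
  amap <- aneuploidy_map(att, profiles, c("dip", "tet"), genome)
  q8row <- amap[amap$chrom == "8" & amap$arm == "q", ]
  expect_equal(q8row$n, 4)           # exactly the qualifying samples
  expect_equal(q8row$frac_gain, 1)
  p8row <- amap[amap$chrom == "8" & amap$arm == "p", ]
  expect_equal(p8row$frac_gain, 0)
  expect_true(all(amap$frac_gain[amap$chrom != "8"] == 0))
  ## no qualifying samples: empty result with a warning
  att0 <- structure(list(normalized = rbind(s1 = c(dip = 0.95, tet = 0.05))),
                    class = "cn_attribution")
  expect_warning(empty <- aneuploidy_map(att0, profiles[1], c("dip", "tet"),
                                         genome), "qualify")
  expect_equal(nrow(empty), 0)
})

test_that("stratum enrichment uses a strict attribution threshold", {
  norm <- rbind(a = c(X = 0.5, Y = 0.5), b = c(0.05, 0.95),
                c = c(0.051, 0.949), d = c(0, 1))
  att <- structure(list(normalized = norm), class = "cn_attribution")
  strata <- c("wgd0", "wgd0", "wgd1", "wgd1")
  res <- stratum_enrichment(att, strata)
  xw1 <- res[res$signature == "X" & res$stratum == "wgd1", ]
  ## 0.051 counts as present, 0.05 does not
  expect_equal(xw1$present_in, 1)
  expect_equal(xw1$present_out, 1)   # only sample a (0.5), not b (0.05)
  expect_true(all(res$q >= res$p))
  ## a signature present only in one stratum attains the smallest p there
  norm2 <- rbind(a = c(X = 0.9, Y = 0.1), b = c(0.8, 0.2),
                 c = c(0.01, 0.99), d = c(0.02, 0.98))
  att2 <- structure(list(normalized = norm2), class = "cn_attribution")
  res2 <- stratum_enrichment(att2, c("g0", "g0", "g1", "g1"))
  x_res <- res2[res2$signature == "X", ]
  expect_equal(x_res$stratum[which.min(x_res$p)], "g0")
})
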