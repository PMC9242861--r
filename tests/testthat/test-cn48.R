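test_that("heterozygosity, TCN and size classifiers follow their definitions", {
  expect_equal(het_state(1, 1), "het")
  expect_equal(het_state(2, 0), "loh")
  expect_equal(het_state(0, 0), "homdel")
  expect_error(het_state(-1, 0), "negative")

  expect_equal(tcn_class(0), "0")
  expect_equal(tcn_class(1), "1")
  expect_equal(tcn_class(2), "2")
  expect_equal(tcn_class(4), "3-4")
  expect_equal(tcn_class(8), "5-8")
  expect_equal(tcn_class(9), "9+")
  expect_equal(tcn_class(37), "9+")
  expect_error(tcn_class(-2), "negative")

  expect_equal(size_class(5e7, "het"), ">40Mb")
  expect_equal(size_class(1e5, "loh"), "0-100kb")       # inclusive upper bound
  expect_equal(size_class(1e5 + 1, "loh"), "100kb-1Mb")
  expect_equal(size_class(4e7, "het"), "10Mb-40Mb")
  expect_equal(size_class(2e6, "homdel"), ">1Mb")
  expect_equal(size_class(2e6, "het"), "1Mb-10Mb")
  expect_error(size_class(0, "het"), "length")
})

test_that("classification is exhaustive, exclusive and spans exactly 48 categories", {
  grid <- expand.grid(major = 0:12, minor = 0:12,
                      len = c(1, 99999, 1e5, 1e5 + 1, 999999, 1e6, 1e6 + 1,
                              5e6, 1e7, 1e7 + 1, 4e7, 4e7 + 1, 2e8))
  grid <- grid[grid$minor <= grid$major, ]
  idx <- classify_segment(grid$major, grid$minor, grid$len)
  expect_true(all(idx >= 1 & idx <= 48))
  expect_equal(length(idx), nrow(grid))        # exactly one category per case
  expect_setequal(unique(idx), 1:48)           # every category is reachable
  chan <- cn48_channels()
  expect_equal(nrow(chan), 48)
  expect_equal(sum(chan$het_state == "homdel"), 3)
  expect_equal(sum(chan$het_state == "loh"), 25)
  expect_equal(sum(chan$het_state == "het"), 20)
  ## the shipped channel-name sidecar matches the in-code table
  sidecar <- read.delim(system.file("extdata", "cn48_channels.tsv",
                                    package = "cnsig"),
                        colClasses = c(tcn = "character"))
  expect_equal(sidecar$name, chan$name)
  expect_equal(sidecar$index, chan$index)
  ## archetype compositions
  expect_equal(chan$name[classify_segment(1, 1, 5e7)], "het:2:>40Mb")
  expect_equal(chan$name[classify_segment(2, 0, 5e5)], "loh:2:100kb-1Mb")
  expect_equal(chan$name[classify_segment(6, 3, 5e6)], "het:9+:1Mb-10Mb")
})

test_that("catalogue matrix rows sum to segment counts and are order-invariant", {
  set.seed(21)
  profiles <- lapply(paste0("s", 1:6), random_profile)
  m <- build_matrix(profiles)
  expect_equal(dim(m), c(6, 48))
  expect_equal(unname(rowSums(m)),
               vapply(profiles, function(p) nrow(p$segments), numeric(1)))
  ## permuting segment order never changes the count vector
  p <- profiles[[1]]
  p_shuf <- p
  p_shuf$segments <- p$segments[sample(nrow(p$segments)), ]
  p_shuf$segments <- p_shuf$segments[order(
    cnsig:::chrom_order(p_shuf$segments$chrom), p_shuf$segments$start), ]
  expect_equal(count_cn48(p_shuf), count_cn48(p))
  ## cohort concatenation = row-wise concatenation
  m2 <- rbind(build_matrix(profiles[1:3]), build_matrix(profiles[4:6]))
  expect_equal(m2, m)
  ## duplicate ids rejected
  expect_error(build_matrix(list(p, p)), "duplicate")
})

test_that("empty profiles give all-zero rows and undefined summaries", {
  p <- cn_profile("empty", data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), major_cn = numeric(),
                                      minor_cn = numeric()))
  expect_equal(sum(count_cn48(p)), 0)
  s <- profile_summary(p)
  expect_equal(s$n_segments, 0L)
  expect_true(is.na(s$ploidy) && is.na(s$ploh))
})

test_that("homozygous-deletion burden filter removes strictly over-threshold samples", {
  mk <- function(id, homdel_mb) {
    seg <- data.frame(chrom = "1", start = 1, end = 1e8,
                      major_cn = 1, minor_cn = 1)
    if (homdel_mb > 0)
      seg <- rbind(seg, data.frame(chrom = "2", start = 1,
                                   end = homdel_mb * 1e6,
                                   major_cn = 0, minor_cn = 0))
    cn_profile(id, seg)
  }
  profiles <- list(none = mk("none", 0), at25 = mk("at25", 25),
                   over = mk("over", 30))
  f <- filter_homdel_burden(profiles)
  expect_setequal(names(f$kept), c("none", "at25"))  # 25 Mb exactly is kept
  expect_setequal(names(f$removed), "over")
  expect_equal(unname(f$burden_mb["over"]), 30)
})

test_that("profile summaries length-weight the LOH fraction", {
  p0 <- cn_profile("a", data.frame(chrom = "1", start = 1, end = 1e6,
                                   major_cn = 1, minor_cn = 1))
  expect_equal(profile_summary(p0)$ploh, 0)
  p1 <- cn_profile("b", data.frame(chrom = "1", start = 1, end = 1e6,
                                   major_cn = 1, minor_cn = 0))
  expect_equal(profile_summary(p1)$ploh, 1)
  ## 30% of covered length LOH
  p3 <- cn_profile("c", data.frame(chrom = "1", start = c(1, 3000001),
                                   end = c(3e6, 1e7),
                                   major_cn = c(1, 1), minor_cn = c(0, 1)))
  expect_equal(profile_summary(p3)$ploh, 0.3)
  expect_equal(profile_summary(p3)$n_segments, 2)
})
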