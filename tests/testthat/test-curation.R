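test_that("sample QC applies the published thresholds strictly", {
  s <- mk_samples(6, 0)
  s$lrr_sd <- c(0.35, 0.15, 0.15, 0.30, 0.15, 0.15)
  s$wf[2] <- -0.5
  s$baf_drift[5] <- NA
  counts <- setNames(c(0L, 0L, 51L, 0L, 0L, 50L), s$sample_id)
  res <- sample_qc_filter(s, counts)
  expect_equal(res$pass$sample_id, s$sample_id[6])  # 50 calls is allowed
  rep <- res$report
  expect_equal(rep$reasons[rep$sample_id == s$sample_id[1]], "lrr_sd")
  expect_equal(rep$reasons[rep$sample_id == s$sample_id[2]], "wf")
  expect_equal(rep$reasons[rep$sample_id == s$sample_id[3]], "n_cnv_calls")
  # boundary: lrr_sd exactly 0.3 fails the strict < 0.3 rule
  expect_equal(rep$reasons[rep$sample_id == s$sample_id[4]], "lrr_sd")
  expect_equal(rep$reasons[rep$sample_id == s$sample_id[5]],
               "missing_metric")
})

test_that("a sample failing several criteria reports every reason", {
  s <- mk_samples(1, 0)
  s$lrr_sd <- 0.4; s$wf <- 0.6; s$call_rate <- 0.9
  res <- sample_qc_filter(s, integer())
  expect_equal(res$report$reasons, "lrr_sd,wf,call_rate")
})

test_that("fragment merging follows the 20% intervening-marker rule", {
  map <- tiny_map(300)
  # segments of 40 and 50 markers, gap 10: 10 < 0.2 * 90 -> merged
  a <- rbind(mk_call("s1", "1", map$pos[11], map$pos[50], 3, 40, 30),
             mk_call("s1", "1", map$pos[61], map$pos[110], 3, 50, 40))
  m <- merge_adjacent_fragments(a, map)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, map$pos[11])
  expect_equal(m$end, map$pos[110])
  expect_equal(m$n_markers, 100L)           # both segments plus the gap
  expect_equal(m$confidence, 70)            # sum of the parts
  # same segments, gap 20: 20 >= 0.2 * 90 -> kept apart
  b <- rbind(mk_call("s1", "1", map$pos[11], map$pos[50], 3, 40, 30),
             mk_call("s1", "1", map$pos[71], map$pos[120], 3, 50, 40))
  expect_equal(nrow(merge_adjacent_fragments(b, map)), 2)
  # different copy state never merges
  d <- rbind(mk_call("s1", "1", map$pos[11], map$pos[50], 3, 40, 30),
             mk_call("s1", "1", map$pos[52], map$pos[110], 1, 59, 40))
  expect_equal(nrow(merge_adjacent_fragments(d, map)), 2)
})

test_that("fragment merging is idempotent and rejects overlapping input", {
  map <- tiny_map(400)
  set.seed(17)
  pieces <- lapply(1:8, function(i) {
    s <- 40 * i; mk_call("s1", "1", map$pos[s], map$pos[s + sample(5:20, 1)],
                         3, 10, 5)
  })
  calls <- do.call(rbind, pieces)
  calls$n_markers <- as.integer((calls$end - calls$start) / 1000 + 1)
  m1 <- merge_adjacent_fragments(calls, map)
  m2 <- merge_adjacent_fragments(m1, map)
  expect_equal(m1, m2, ignore_attr = TRUE)
  bad <- rbind(mk_call("s1", "1", map$pos[10], map$pos[30], 3),
               mk_call("s1", "1", map$pos[25], map$pos[50], 3))
  expect_error(merge_adjacent_fragments(bad, map), "caller contract")
})

test_that("caller intersection keeps only dual-called CNVs", {
  map <- tiny_map(300)
  a <- mk_call("s1", "1", map$pos[100], map$pos[200], 3, 101, 30, "callerA")
  b <- mk_call("s1", "1", map$pos[150], map$pos[250], 3, 101, 20, "callerB")
  cons <- intersect_two_callsets(a, b, map)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, map$pos[150])
  expect_equal(cons$end, map$pos[200])
  expect_equal(cons$n_markers, 51L)          # recomputed from the map
  expect_equal(cons$confidence, 20)          # min of the pair
  expect_equal(cons$caller, "consensus")
  # class mismatch -> nothing
  b2 <- mk_call("s1", "1", map$pos[150], map$pos[250], 1, 101, 20, "callerB")
  expect_equal(nrow(intersect_two_callsets(a, b2, map)), 0)
  # single-caller call -> nothing
  expect_equal(nrow(intersect_two_callsets(a, a[0, ], map)), 0)
  # CN3 meets CN4: same class intersects by default, not under strict
  b3 <- mk_call("s1", "1", map$pos[150], map$pos[250], 4, 101, 20, "callerB")
  expect_equal(nrow(intersect_two_callsets(a, b3, map)), 1)
  expect_equal(nrow(intersect_two_callsets(a, b3, map,
                                           strict_state = TRUE)), 0)
})

test_that("intersection output is contained in both inputs (property)", {
  map <- tiny_map(500)
  set.seed(19)
  rand_calls <- function(caller) {
    do.call(rbind, lapply(1:12, function(i) {
      s <- sample(1:450, 1); e <- min(500, s + sample(5:60, 1))
      mk_call(paste0("s", sample(1:3, 1)), "1", map$pos[s], map$pos[e],
              sample(c(1L, 3L), 1), e - s + 1L, runif(1, 5, 50), caller)
    }))
  }
  a <- rand_calls("callerA"); b <- rand_calls("callerB")
  cons <- intersect_two_callsets(a, b, map)
  for (i in seq_len(nrow(cons))) {
    iv <- genomic_interval(cons$chrom[i], cons$start[i], cons$end[i])
    within <- function(set) any(
      set$sample_id == cons$sample_id[i] & set$chrom == iv$chrom &
        set$start <= iv$start & set$end >= iv$end &
        copy_class(set$copy_state) == copy_class(cons$copy_state[i]))
    expect_true(within(a) && within(b))
  }
})

test_that("the filter cascade removes exactly the planted failures", {
  map <- tiny_map(600)
  artifacts <- data.frame(chrom = "1", start = map$pos[380],
                          end = map$pos[440], name = "segdup")
  catalog <- data.frame(chrom = "1", start = map$pos[470],
                        end = map$pos[530], name = "common",
                        frequency = 0.25)
  calls <- rbind(
    # 8 kb duplication: fails the 10 kb size rule only
    mk_call("s1", "1", map$pos[10], map$pos[18], 3, 9, 50, "consensus"),
    # 25 kb call with 9 markers: fails the marker rule
    within(mk_call("s2", "1", map$pos[40], map$pos[65], 3, 9, 50,
                   "consensus"), n_markers <- 9L),
    # 60% covered by the artifact region
    mk_call("s3", "1", map$pos[390], map$pos[439], 3, 50, 50, "consensus"),
    # 60% covered by a 25%-frequency catalog CNV
    mk_call("s4", "1", map$pos[480], map$pos[529], 3, 50, 50, "consensus"),
    # deletion below the confidence cutoff 25
    mk_call("s5", "1", map$pos[100], map$pos[140], 1, 41, 20, "consensus"),
    # clean rare duplication, confidence 12 (above the DUP cutoff 10)
    mk_call("s6", "1", map$pos[200], map$pos[260], 3, 61, 12, "consensus"))
  res <- filter_calls(calls, artifacts, catalog)
  expect_equal(unname(res$removed),
               c(1L, 1L, 1L, 1L, 1L))  # size, markers, artifact, common, conf
  expect_equal(names(res$removed),
               c("size", "markers", "artifact", "common", "confidence"))
  expect_equal(res$calls$sample_id, "s6")
  # contraction + conservation of counts
  expect_equal(nrow(calls) - sum(res$removed), nrow(res$calls))
})

test_that("deletion and duplication confidence cutoffs differ", {
  calls <- rbind(
    mk_call("s1", "1", 1e6, 1.05e6, 1, 50, 20, "consensus"),
    mk_call("s2", "1", 1e6, 1.05e6, 3, 50, 12, "consensus"))
  res <- filter_calls(calls, NULL, NULL)
  expect_equal(res$calls$sample_id, "s2")
  expect_equal(unname(res$removed["confidence"]), 1L)
})

test_that("the control-frequency filter uses distinct control carriers", {
  samples <- mk_samples(10, 100)
  th <- filter_thresholds()
  base <- function(id) mk_call(id, "1", 1e6, 1.06e6, 3, 60, 50, "consensus")
  # 2 distinct controls among 100 (2%) -> whole cluster removed, including
  # the case member
  calls <- rbind(base("s0001"), base("s0011"), base("s0012"))
  res <- control_frequency_filter(calls, samples, th)
  expect_equal(nrow(res$calls), 0)
  expect_equal(res$removed, 3L)
  # exactly 1% (not greater) -> retained
  calls2 <- rbind(base("s0011"), base("s0011"))  # same control twice
  res2 <- control_frequency_filter(calls2, samples, th)
  expect_equal(nrow(res2$calls), 2)
  # case-only cluster at 5% of cases -> retained (rule is about controls)
  calls3 <- rbind(base("s0001"), base("s0002"))
  expect_equal(nrow(control_frequency_filter(calls3, samples, th)$calls), 2)
  expect_error(control_frequency_filter(calls, mk_samples(5, 0), th),
               "no controls")
})

test_that("control-frequency clustering needs reciprocal overlap", {
  samples <- mk_samples(2, 50)
  th <- filter_thresholds()
  # a small case call inside a large control call: of_a is 1 but the
  # reciprocal fraction is 0.1, so they are different events
  calls <- rbind(
    mk_call("s0001", "1", 1.0e6, 1.01e6, 3, 11, 50, "consensus"),
    mk_call("s0003", "1", 1.0e6, 1.10e6, 3, 101, 50, "consensus"),
    mk_call("s0004", "1", 1.0e6, 1.10e6, 3, 101, 50, "consensus"))
  res <- control_frequency_filter(calls, samples, th)
  expect_equal(res$calls$sample_id, "s0001")
  expect_equal(res$removed, 2L)
})
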